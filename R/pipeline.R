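# End-to-end orchestration: simulate (or ingest) a two-scanner study, run
# every image-quality metric per acquisition cell, and feed the results
# through the harmonization chain (dose rescaling, change ratios, IR-level
# matching). This is the programmatic equivalent of the five-step protocol
# standardization procedure: classify the protocol, rescale the dose via
# NPS, acquire over a dose/IR factorial, quantify the IQ change, match the
# IR level.

#' Compute all image-quality metrics for one acquisition cell
#'
#' Runs the full metric chain on the four module series of a simulated (or
#' ingested) cell: NPS metrics on the uniformity module, contrast/CNR on
#' the sensitometry composite, TTF from the edge disk (parametric edge
#' model when the measured CNR < 15), and NPWE d' for the 12 mm/25 HU and
#' 7 mm/10 HU tasks using the cell's own measured 2D NPS and TTF.
#'
#' @param cell A [synth_cell()] result (named list of module series).
#' @param grid [roi_grid()] used for NPS estimation.
#' @param view [viewing_model()] or `NULL` (identity eye filter).
#' @param ttf_mode TTF mode passed to [compute_ttf()].
#' @param n_grid NPWE quadrature points per axis.
#' @param esf_band Half-width (mm) of the ESF radial band.
#' @return List: `iq` (ctiq_iqvec), `metrics`, `contrast`, `ttf`, `detect`,
#'   `auc_nps`, `key`.
#' @export
analyze_cell <- function(cell, grid = roi_grid(), view = NULL,
                         ttf_mode = "auto", n_grid = 512, esf_band = 3) {
  metrics <- noise_metrics(cell$uniformity, grid)

  sens_layout <- attr(cell$sensitometry, "layout")
  sens <- contrast_cnr(composite_image(cell$sensitometry), sens_layout)

  edge_layout <- attr(cell$edge_disk, "layout")
  edge_comp <- composite_image(cell$edge_disk)
  edge_cnr <- contrast_cnr(edge_comp, edge_layout)
  # the 12 mm disk offers ~230 band pixels; a third-of-a-pixel bin keeps
  # every radial bin populated while still oversampling the edge
  esf <- extract_esf(edge_comp, edge_layout[[1]], band_mm = esf_band,
                     bin_width = min(cell$edge_disk$pixel_spacing) / 3)
  ttf <- compute_ttf(esf, mode = ttf_mode, cnr = abs(edge_cnr$cnr[1]))

  detect <- list(
    d_prime_npwe(ttf, metrics, task_spec(12, 25), view = view,
                 n_grid = n_grid),
    d_prime_npwe(ttf, metrics, task_spec(7, 10), view = view,
                 n_grid = n_grid))

  iq <- assemble_iq_vector(metrics, sens, detect, key = cell$key)
  list(iq = iq, metrics = metrics, contrast = sens, ttf = ttf,
       detect = detect, auc_nps = metrics$auc_nps, key = cell$key)
}

#' Analyze every cell of a study into an IQ table
#'
#' @param study A [synth_study()] result (list of cells).
#' @param ... Passed to [analyze_cell()].
#' @return Data frame with one row per cell: `scanner`, `protocol_class`,
#'   `ctdi_vol`, `recon_label`, `auc_nps` and the eight IQ metric columns.
#' @export
analyze_study <- function(study, ...) {
  rows <- lapply(study, function(cell) {
    res <- analyze_cell(cell, ...)
    cbind(as.data.frame(res$key, stringsAsFactors = FALSE),
          data.frame(auc_nps = res$auc_nps),
          as.data.frame(as.list(unclass(res$iq))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harmonize a two-scanner study from its IQ table
#'
#' Performs the cross-scanner steps on an [analyze_study()] table:
#' estimates the CTDI_vol rescale factor from the FBP AUC_NPS curves of
#' the two scanners, computes per-scanner IQ change-ratio matrices
#' (IR vs FBP), and matches the reference reconstruction of scanner A to
#' the candidate levels of scanner B by pooled Spearman correlation.
#'
#' @param iq_table Data frame from [analyze_study()].
#' @param reference_scanner,reference_label Scanner and recon label of the
#'   reference reconstruction (e.g. the clinical hybrid-IR level).
#' @param candidate_scanner Scanner whose levels are candidates; defaults
#'   to the other scanner in the table.
#' @param candidate_labels Candidate recon labels; defaults to all non-FBP
#'   labels of the candidate scanner.
#' @param tie_delta Tie threshold forwarded to [match_ir_level()].
#' @return List of class `ctiq_harmonization`: `scale`, `change_ratio`
#'   (per-scanner list of matrices), `match`.
#' @export
harmonize_study <- function(iq_table, reference_scanner, reference_label,
                            candidate_scanner = NULL,
                            candidate_labels = NULL, tie_delta = 0.005) {
  scanners <- unique(iq_table$scanner)
  if (is.null(candidate_scanner)) {
    candidate_scanner <- setdiff(scanners, reference_scanner)[1]
  }
  if (is.na(candidate_scanner)) stopf("no candidate scanner in table")

  fbp <- iq_table[iq_table$recon_label == "FBP", , drop = FALSE]
  curve <- function(sc) {
    sub <- fbp[fbp$scanner == sc, , drop = FALSE]
    data.frame(ctdi = sub$ctdi_vol, auc_nps = sub$auc_nps)
  }
  scale <- if (sum(fbp$scanner == reference_scanner) >= 2 &&
               sum(fbp$scanner == candidate_scanner) >= 2) {
    estimate_ctdi_scale(curve(reference_scanner), curve(candidate_scanner))
  } else NULL

  change_ratio <- lapply(stats::setNames(scanners, scanners), function(sc) {
    iq_change_ratio(iq_table[iq_table$scanner == sc, , drop = FALSE])
  })

  ref <- iq_table[iq_table$scanner == reference_scanner &
                    iq_table$recon_label == reference_label, , drop = FALSE]
  if (!nrow(ref)) stopf("reference %s/%s not found in table",
                        reference_scanner, reference_label)
  cand_tab <- iq_table[iq_table$scanner == candidate_scanner, , drop = FALSE]
  candidate_labels <- candidate_labels %||%
    setdiff(unique(cand_tab$recon_label), "FBP")
  candidates <- lapply(stats::setNames(candidate_labels, candidate_labels),
                       function(lab) {
                         cand_tab[cand_tab$recon_label == lab, , drop = FALSE]
                       })
  match <- match_ir_level(ref, candidates, tie_delta = tie_delta)
  structure(list(scale = scale, change_ratio = change_ratio, match = match),
            class = "ctiq_harmonization")
}

#' @export
print.ctiq_harmonization <- function(x, ...) {
  if (!is.null(x$scale)) print(x$scale)
  print(x$match)
  invisible(x)
}

#' Default run configuration
#'
#' @param seed Master seed.
#' @param protocol_class `"body"` or `"brain"`.
#' @param ctdi_list Dose grid in mGy; defaults to the protocol's standard
#'   grid (body 5, 10, 15, 20, 30, 40; brain 60, 70, 80).
#' @param efficiency_b Dose efficiency of the second scanner relative to
#'   the first (default 1/1.15: B needs 15% more dose for equal noise).
#' @param hybrid_levels,modelbased_levels IR levels simulated per family.
#' @param shape,spacing,n_slices,blur_sigma Image geometry.
#' @param n_grid NPWE quadrature points per axis.
#' @return Named list, suitable for [run_pipeline()].
#' @export
default_config <- function(seed = 1, protocol_class = "body",
                           ctdi_list = NULL, efficiency_b = 1 / 1.15,
                           hybrid_levels = 1:3, modelbased_levels = 1:2,
                           shape = c(256, 256), spacing = 1, n_slices = 16,
                           blur_sigma = 0.6, n_grid = 512) {
  ctdi_list <- ctdi_list %||%
    switch(protocol_class, body = c(5, 10, 15, 20, 30, 40),
           brain = c(60, 70, 80))
  list(seed = seed, protocol_class = protocol_class, ctdi_list = ctdi_list,
       efficiency_b = efficiency_b, hybrid_levels = hybrid_levels,
       modelbased_levels = modelbased_levels, shape = shape,
       spacing = spacing, n_slices = n_slices, blur_sigma = blur_sigma,
       n_grid = n_grid)
}

#' Run the whole harmonization pipeline and write its outputs
#'
#' Executes the five-step standardization scheme on a simulated two-scanner
#' study: (1) fix the protocol class, (2) estimate the dose rescale factor
#' from FBP AUC_NPS curves of both scanners over the dose grid, (3) acquire
#' the full dose x reconstruction factorial — scanner B at its rescaled
#' doses — (4) quantify the IQ change of each IR level versus FBP, and
#' (5) match the reference IR level of scanner A to the candidate levels of
#' scanner B by Spearman correlation of the IQ vectors. Writes
#' `study_manifest.json` (cells and seeds), `iq_vectors.csv`,
#' `change_ratio_<scanner>.csv`, `scale.json` and `match_report.json` into
#' `outdir`. Outputs are bit-reproducible for a fixed configuration and
#' seed.
#'
#' @param config List from [default_config()] (possibly edited).
#' @param outdir Output directory.
#' @param reference_label Reference reconstruction label on scanner A.
#' @return Invisibly, a list with `scale`, `iq_table` and `harmonization`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile(),
                         reference_label = "hybrid-3") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prof_a <- scanner_profile("CT_A", efficiency = 1)
  prof_b <- scanner_profile("CT_B", efficiency = config$efficiency_b)
  recons <- c(list(ir_emulation(level = 0)),
              lapply(config$hybrid_levels,
                     function(l) ir_emulation("hybrid", l)),
              lapply(config$modelbased_levels,
                     function(l) ir_emulation("model-based", l)))
  ctdi_ref <- stats::median(config$ctdi_list)
  grid <- roi_grid(min(64, config$shape[1] %/% 4))

  # step 2: FBP-only uniformity scans -> AUC_NPS curves -> dose rescale
  fbp <- ir_emulation(level = 0)
  auc_curve <- function(profile, doses) {
    do.call(rbind, lapply(doses, function(d) {
      cell <- synth_cell(profile, protocol_class = config$protocol_class,
                         ctdi = d, ctdi_ref = ctdi_ref, recon = fbp,
                         seed = config$seed, shape = config$shape,
                         spacing = config$spacing,
                         n_slices = config$n_slices,
                         modules = "uniformity")
      data.frame(ctdi = d,
                 auc_nps = noise_metrics(cell$uniformity, grid)$auc_nps)
    }))
  }
  scale <- estimate_ctdi_scale(auc_curve(prof_a, config$ctdi_list),
                               auc_curve(prof_b, config$ctdi_list))

  # step 3: full factorial; scanner B acquired at rescaled doses but
  # tabulated on the nominal (reference) dose grid
  manifest <- NULL
  rows <- list()
  for (spec in list(list(prof = prof_a, dose_scale = 1),
                    list(prof = prof_b, dose_scale = scale$scale))) {
    for (d in config$ctdi_list) {
      for (rec in recons) {
        d_act <- d * spec$dose_scale
        cell <- synth_cell(spec$prof, protocol_class = config$protocol_class,
                           ctdi = d_act, ctdi_ref = ctdi_ref, recon = rec,
                           seed = config$seed, shape = config$shape,
                           spacing = config$spacing,
                           n_slices = config$n_slices,
                           blur_sigma = config$blur_sigma,
                           modules = c("uniformity", "sensitometry",
                                       "edge_disk"))
        res <- analyze_cell(cell, grid = grid, n_grid = config$n_grid)
        row <- cbind(as.data.frame(res$key, stringsAsFactors = FALSE),
                     data.frame(auc_nps = res$auc_nps),
                     as.data.frame(as.list(unclass(res$iq))))
        row$ctdi_actual <- d_act
        row$ctdi_vol <- d
        rows[[length(rows) + 1L]] <- row
        manifest <- rbind(manifest, data.frame(
          scanner = spec$prof$name, protocol_class = config$protocol_class,
          ctdi_nominal = d, ctdi_actual = d_act, recon_label = rec$label,
          seed = cell_seed(config$seed, spec$prof$name,
                           config$protocol_class, d_act, rec$label,
                           "uniformity"), stringsAsFactors = FALSE))
      }
    }
  }
  iq_table <- do.call(rbind, rows)
  rownames(iq_table) <- NULL
  jsonlite::write_json(list(config = config, scale = scale$scale,
                            cells = manifest),
                       file.path(outdir, "study_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(iq_table, file.path(outdir, "iq_vectors.csv"),
                   row.names = FALSE)

  # steps 4-5
  harm <- harmonize_study(iq_table, reference_scanner = "CT_A",
                          reference_label = reference_label)
  harm$scale <- scale
  for (sc in names(harm$change_ratio)) {
    utils::write.csv(harm$change_ratio[[sc]],
                     file.path(outdir, paste0("change_ratio_", sc, ".csv")))
  }
  if (!is.null(harm$scale)) {
    jsonlite::write_json(list(scale = harm$scale$scale,
                              ratios = harm$scale$ratios),
                         file.path(outdir, "scale.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(
    list(best = harm$match$best_label,
         ties = harm$match$ties,
         rhos = as.list(harm$match$candidate_rhos)),
    file.path(outdir, "match_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scale = scale, iq_table = iq_table, harmonization = harm,
                 outdir = outdir))
}
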