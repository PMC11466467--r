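# Cross-scanner protocol harmonization: (1) match the noise level between
# scanners by finding the dose rescale factor that equates the area under
# the radial NPS curve; (2) assemble a fixed-order image-quality vector per
# (scanner, dose, reconstruction); (3) quantify the effect of IR as the
# change ratio (IQ_IR - IQ_FBP)/IQ_FBP averaged over doses; (4) find the
# candidate IR level whose IQ vectors correlate best (Spearman) with the
# reference reconstruction.

IQ_METRIC_NAMES <- c("noise_sd", "nps_p", "freq_p", "freq_m",
                     "cnr_LDPE", "cnr_Derlin",
                     "dprime_12mm_25HU", "dprime_7mm_10HU")

#' Estimate the dose rescale factor equating noise between two scanners
#'
#' Given AUC_NPS versus CTDI_vol curves for a reference scanner (A) and a
#' second scanner (B), finds for each reference dose the dose at which B
#' reaches the same AUC_NPS — by linear interpolation of the curve in
#' log-log space, where the variance ~ 1/dose law makes AUC_NPS nearly a
#' power law in dose — and returns the mean dose ratio CTDI_B / CTDI_A.
#' Reference points whose AUC_NPS falls outside the measured range of
#' curve B are skipped (at least two usable points are required).
#'
#' @param curve_a,curve_b Data frames with columns `ctdi` (mGy) and
#'   `auc_nps` (HU^2 mm); at least two dose points each, AUC_NPS strictly
#'   decreasing in dose.
#' @return List of class `ctiq_scale`: `scale` (mean ratio), `ratios`
#'   (per-reference-dose data frame), `n_used`, `n_skipped`.
#' @export
estimate_ctdi_scale <- function(curve_a, curve_b) {
  for (cv in list(curve_a, curve_b)) {
    if (nrow(cv) < 2) stopf("each AUC_NPS curve needs >= 2 dose points")
    o <- order(cv$ctdi)
    if (any(diff(cv$auc_nps[o]) >= 0)) {
      stopf("AUC_NPS must be strictly decreasing in dose")
    }
    if (any(cv$ctdi <= 0) || any(cv$auc_nps <= 0)) {
      stopf("doses and AUC_NPS must be positive for log-log interpolation")
    }
  }
  a <- curve_a[order(curve_a$ctdi), ]
  b <- curve_b[order(curve_b$ctdi), ]
  lb_dose <- log(b$ctdi); lb_auc <- log(b$auc_nps)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    target <- log(a$auc_nps[i])
    if (target > max(lb_auc) || target < min(lb_auc)) {
      return(data.frame(ctdi_a = a$ctdi[i], ctdi_b = NA_real_,
                        ratio = NA_real_))
    }
    ld <- stats::approx(lb_auc, lb_dose, xout = target)$y
    data.frame(ctdi_a = a$ctdi[i], ctdi_b = exp(ld),
               ratio = exp(ld) / a$ctdi[i])
  })
  ratios <- do.call(rbind, rows)
  used <- ratios[!is.na(ratios$ratio), ]
  if (nrow(used) < 2) {
    stopf(paste0("matching AUC_NPS outside curve B's range for %d of %d ",
                 "reference doses; curves do not overlap enough"),
          sum(is.na(ratios$ratio)), nrow(ratios))
  }
  structure(list(scale = mean(used$ratio), ratios = ratios,
                 n_used = nrow(used),
                 n_skipped = sum(is.na(ratios$ratio))),
            class = "ctiq_scale")
}

#' @export
print.ctiq_scale <- function(x, ...) {
  cat(sprintf("<ctiq_scale> CTDI_B/CTDI_A = %.3f (from %d dose points)\n",
              x$scale, x$n_used))
  invisible(x)
}

#' Assemble the fixed-order image-quality vector of an acquisition
#'
#' The harmonization procedure compares acquisitions through an ordered
#' vector of eight metrics: noise SD, NPS peak, peak frequency, mean
#' frequency, CNR of the LDPE and Derlin inserts, and the detectability
#' indices of the 12 mm/25 HU and 7 mm/10 HU tasks.
#'
#' @param metrics A [noise_metrics()] result.
#' @param contrast A [contrast_cnr()] data frame containing rows labelled
#'   `LDPE` and `Derlin`.
#' @param detect List of [d_prime_npwe()] results for the 12 mm/25 HU and
#'   7 mm/10 HU tasks (matched by task diameter).
#' @param key Named list identifying the acquisition cell (scanner,
#'   protocol_class, ctdi_vol, recon_label).
#' @return Named numeric vector of class `ctiq_iqvec` with a `key`
#'   attribute; names and order are always `IQ_METRIC_NAMES`.
#' @export
assemble_iq_vector <- function(metrics, contrast, detect, key = list()) {
  stopifnot(inherits(metrics, "ctiq_noisemetrics"))
  v <- c(noise_sd = metrics$noise_sd, nps_p = metrics$nps_p,
         freq_p = metrics$freq_p, freq_m = metrics$freq_m)
  for (lab in c("LDPE", "Derlin")) {
    row <- contrast[contrast$label == lab, , drop = FALSE]
    if (!nrow(row)) stopf("missing contrast result for insert '%s'", lab)
    # IQ vectors carry the effective (magnitude) CNR: negative-contrast
    # inserts are as visible as positive ones
    v[paste0("cnr_", lab)] <- abs(row$cnr[1])
  }
  diameters <- vapply(detect, function(d) d$task$diameter, numeric(1))
  for (spec in list(c(12, "dprime_12mm_25HU"), c(7, "dprime_7mm_10HU"))) {
    i <- which(abs(diameters - as.numeric(spec[1])) < 1e-6)
    if (!length(i)) stopf("missing detectability result for the %s mm task",
                          spec[1])
    v[spec[2]] <- detect[[i[1]]]$d_prime
  }
  v <- v[IQ_METRIC_NAMES]
  if (any(!is.finite(v))) {
    stopf("non-finite IQ metric: %s",
          paste(IQ_METRIC_NAMES[!is.finite(v)], collapse = ", "))
  }
  structure(v, key = key, class = c("ctiq_iqvec", "numeric"))
}

#' Average IQ change ratio of each reconstruction relative to FBP
#'
#' For every metric and reconstruction label, computes the mean over the
#' dose set of `(IQ_IR - IQ_FBP) / IQ_FBP`, with FBP compared at the same
#' dose. The FBP row is exactly zero. This is the heatmap-style summary of
#' how strongly each IR level perturbs each image-quality metric.
#'
#' @param iq_table Data frame with columns `recon_label`, `ctdi_vol` and
#'   the eight `IQ_METRIC_NAMES` columns (one row per acquisition cell);
#'   an FBP row must exist at every dose.
#' @param fbp_label Label identifying the FBP rows.
#' @return Matrix (recon labels x metrics) of mean change ratios.
#' @export
iq_change_ratio <- function(iq_table, fbp_label = "FBP") {
  need <- c("recon_label", "ctdi_vol", IQ_METRIC_NAMES)
  miss <- setdiff(need, names(iq_table))
  if (length(miss)) stopf("iq_table missing columns: %s",
                          paste(miss, collapse = ", "))
  doses <- sort(unique(iq_table$ctdi_vol))
  fbp <- iq_table[iq_table$recon_label == fbp_label, , drop = FALSE]
  if (!all(doses %in% fbp$ctdi_vol)) {
    stopf("FBP ('%s') must be present at every dose", fbp_label)
  }
  labels <- unique(iq_table$recon_label)
  out <- matrix(NA_real_, length(labels), length(IQ_METRIC_NAMES),
                dimnames = list(labels, IQ_METRIC_NAMES))
  for (lab in labels) {
    sub <- iq_table[iq_table$recon_label == lab, , drop = FALSE]
    ratios <- sapply(IQ_METRIC_NAMES, function(m) {
      r <- vapply(sub$ctdi_vol, function(d) {
        base <- fbp[fbp$ctdi_vol == d, m][1]
        if (!is.finite(base) || base == 0) {
          stopf("FBP value of %s at %g mGy is zero; change ratio undefined",
                m, d)
        }
        (sub[sub$ctdi_vol == d, m][1] - base) / base
      }, numeric(1))
      mean(r)
    })
    out[lab, ] <- ratios
  }
  out[fbp_label, ] <- 0
  out
}

#' Spearman rank correlation
#'
#' Average-rank transform of both vectors (ties averaged) followed by the
#' Pearson correlation of the ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 paired observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("Spearman correlation undefined: zero rank variance")
  }
  stats::cor(rx, ry)
}

#' Match the IR level of a candidate scanner to a reference reconstruction
#'
#' The reference reconstruction's IQ vectors over the (rescaled) dose grid
#' are concatenated across doses and metrics into one sequence and
#' Spearman-correlated with each candidate level's sequence; the level with
#' the highest rho is the best match. Candidates within `tie_delta` of the
#' best rho are reported as a tie set (protocols can be insensitive to the
#' level over a small dose range). Per-metric rhos (across doses) are also
#' reported when the dose grid has at least 3 points.
#'
#' @param reference Data frame with `ctdi_vol` plus the `IQ_METRIC_NAMES`
#'   columns, one row per dose, for the reference reconstruction.
#' @param candidates Named list of data frames of the same shape, one per
#'   candidate level.
#' @param tie_delta Rho difference below which candidates tie.
#' @return Object of class `ctiq_match`: `candidate_rhos`, `best_label`,
#'   `ties`, `n`, `per_metric` (matrix or NULL).
#' @export
match_ir_level <- function(reference, candidates, tie_delta = 0.005) {
  if (!length(candidates) || is.null(names(candidates))) {
    stopf("candidates must be a non-empty named list")
  }
  ref <- reference[order(reference$ctdi_vol), , drop = FALSE]
  ref_doses <- ref$ctdi_vol
  ref_seq <- as.vector(as.matrix(ref[IQ_METRIC_NAMES]))
  rhos <- numeric(0)
  per_metric <- NULL
  for (lab in names(candidates)) {
    cand <- candidates[[lab]]
    cand <- cand[order(cand$ctdi_vol), , drop = FALSE]
    if (nrow(cand) != nrow(ref) ||
        max(abs(cand$ctdi_vol - ref_doses)) > 1e-6 * max(ref_doses)) {
      stopf("candidate '%s' is not on the reference dose grid", lab)
    }
    cand_seq <- as.vector(as.matrix(cand[IQ_METRIC_NAMES]))
    rhos[lab] <- spearman_rho(ref_seq, cand_seq)
    if (nrow(ref) >= 3) {
      pm <- vapply(IQ_METRIC_NAMES, function(m) {
        tryCatch(spearman_rho(ref[[m]], cand[[m]]), error = function(e) NA)
      }, numeric(1))
      per_metric <- rbind(per_metric, pm)
      rownames(per_metric)[nrow(per_metric)] <- lab
    }
  }
  best <- names(rhos)[which.max(rhos)]
  ties <- names(rhos)[max(rhos) - rhos < tie_delta]
  structure(list(candidate_rhos = rhos, best_label = best, ties = ties,
                 n = length(ref_seq), per_metric = per_metric),
            class = "ctiq_match")
}

#' @export
print.ctiq_match <- function(x, ...) {
  cat("<ctiq_match> candidate rhos:\n")
  print(round(x$candidate_rhos, 4))
  cat(sprintf("best: %s%s\n", x$best_label,
              if (length(x$ties) > 1) {
                sprintf(" (tie set: %s)", paste(x$ties, collapse = ", "))
              } else ""))
  invisible(x)
}
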