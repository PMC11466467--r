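make_iq_row <- function(ctdi, recon, mult = 1) {
  base <- c(noise_sd = 10, nps_p = 150, freq_p = 0.25, freq_m = 0.27,
            cnr_LDPE = 70, cnr_Derlin = 90, dprime_12mm_25HU = 9,
            dprime_7mm_10HU = 3)
  as.data.frame(as.list(base * mult)) |>
    cbind(data.frame(recon_label = recon, ctdi_vol = ctdi))
}

test_that("spearman_rho matches brute-force rank correlation", {
  expect_equal(spearman_rho(1:5, exp(1:5)), 1)
  expect_equal(spearman_rho(1:5, -(1:5)^3), -1)
  # frozen oracle: ranks (1,2,3,4) vs (1,3,2,4), Pearson = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # independent cross-check against the stock implementation
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  }
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "zero rank variance")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(15)
    y <- rnorm(15)
    r0 <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r0)
    expect_equal(spearman_rho(x, 3 * y - 100), r0)
    expect_equal(spearman_rho(rank(x), pnorm(y)), r0)
  }
})

test_that("identical scanners yield a dose scale of exactly one", {
  doses <- c(5, 10, 20, 40)
  curve <- data.frame(ctdi = doses, auc_nps = 500 / doses)
  sc <- estimate_ctdi_scale(curve, curve)
  expect_equal(sc$scale, 1, tolerance = 1e-12)
})

test_that("the scale estimate is consistent under dose rescaling", {
  doses <- c(5, 10, 20, 40)
  a <- data.frame(ctdi = doses, auc_nps = 480 / doses^0.98)
  for (k in c(0.5, 1.3, 2)) {
    b <- a
    b$ctdi <- b$ctdi * k
    sc <- estimate_ctdi_scale(a, b)
    expect_equal(sc$scale, k, tolerance = 1e-9)
  }
})

test_that("a planted efficiency ratio is recovered from power-law curves", {
  doses <- c(5, 10, 15, 20, 30, 40)
  a <- data.frame(ctdi = doses, auc_nps = 500 / doses)
  b <- data.frame(ctdi = doses, auc_nps = 500 * 1.15 / doses)
  sc <- estimate_ctdi_scale(a, b)
  expect_equal(sc$scale, 1.15, tolerance = 1e-9)
  expect_gte(sc$n_used, 5)
})

test_that("degenerate AUC_NPS curves are rejected", {
  good <- data.frame(ctdi = c(5, 10, 20), auc_nps = c(100, 50, 25))
  expect_error(estimate_ctdi_scale(good[1, ], good), ">= 2")
  bad <- data.frame(ctdi = c(5, 10, 20), auc_nps = c(100, 120, 25))
  expect_error(estimate_ctdi_scale(bad, good), "decreasing")
  far <- data.frame(ctdi = c(5, 10, 20), auc_nps = c(1e5, 5e4, 2.5e4))
  expect_error(estimate_ctdi_scale(good, far), "range")
})

test_that("IQ vectors have fixed order and reject missing inputs", {
  s <- white_series(n = 128, n_slices = 4, seed = 61)
  nm <- noise_metrics(s, roi_grid(32, 16))
  contrast <- data.frame(label = c("Derlin", "LDPE"), cnr = c(-90, 70),
                         contrast = c(245, -183))
  detect <- list(d_prime_npwe(NULL, 100, task_spec(7, 10)),
                 d_prime_npwe(NULL, 100, task_spec(12, 25)))
  iq <- assemble_iq_vector(nm, contrast, detect, key = list(x = 1))
  expect_equal(names(iq), ctiq:::IQ_METRIC_NAMES)
  # CNR entries are magnitudes; detect entries matched by diameter
  expect_equal(iq[["cnr_Derlin"]], 90)
  expect_equal(iq[["dprime_12mm_25HU"]], detect[[2]]$d_prime)

  # permuting the inputs does not change the output order
  iq2 <- assemble_iq_vector(nm, contrast[2:1, ], detect[2:1], list(x = 1))
  expect_identical(unclass(iq2)[], unclass(iq)[])

  expect_error(assemble_iq_vector(nm, contrast[1, , drop = FALSE], detect),
               "LDPE")
  expect_error(assemble_iq_vector(nm, contrast, detect[1]), "12 mm")
})

test_that("change ratios are zero for FBP and exact for pure rescaling", {
  tab <- rbind(make_iq_row(5, "FBP"), make_iq_row(10, "FBP"),
               make_iq_row(5, "ir-1", 0.8), make_iq_row(10, "ir-1", 0.8),
               make_iq_row(5, "ir-2"), make_iq_row(10, "ir-2"))
  cr <- iq_change_ratio(tab)
  expect_true(all(cr["FBP", ] == 0))
  # identical vectors: all-zero row
  expect_true(all(abs(cr["ir-2", ]) < 1e-12))
  # every metric scaled by r = 0.8: ratio is exactly r - 1
  expect_equal(unname(cr["ir-1", ]), rep(-0.2, 8), tolerance = 1e-12)

  no_fbp <- tab[tab$recon_label != "FBP", ]
  expect_error(iq_change_ratio(no_fbp), "FBP")
  zero <- rbind(make_iq_row(5, "FBP", 0), make_iq_row(5, "ir-1"))
  expect_error(iq_change_ratio(zero), "zero")
})

test_that("matching finds itself and reports degenerate ties", {
  ref <- rbind(make_iq_row(5, "ref", 1.0), make_iq_row(10, "ref", 0.8),
               make_iq_row(20, "ref", 0.6))
  cands <- list(self = ref,
                off1 = rbind(make_iq_row(5, "c", 1.3),
                             make_iq_row(10, "c", 0.75),
                             make_iq_row(20, "c", 0.5)))
  m <- match_ir_level(ref, cands)
  expect_equal(m$best_label, "self")
  expect_equal(unname(m$candidate_rhos["self"]), 1)

  same <- list(a = cands$off1, b = cands$off1, c = cands$off1)
  m2 <- match_ir_level(ref, same)
  expect_setequal(m2$ties, c("a", "b", "c"))

  misaligned <- cands$off1
  misaligned$ctdi_vol <- c(5, 10, 21)
  expect_error(match_ir_level(ref, list(x = misaligned)), "dose grid")
})
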