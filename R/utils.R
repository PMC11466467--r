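# Internal numerical helpers shared by the frequency-domain modules.

#' @keywords internal
#' @noRd
fft_freq <- function(n, delta = 1) {
  # DFT sample frequencies in cycles/mm, unshifted (DC first), like the
  # standard FFT ordering: 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
  # all divided by n*delta.
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * delta)
}

#' @keywords internal
#' @noRd
fft_shift <- function(x) {
  # Move DC to the centre of a vector or matrix.
  if (is.matrix(x)) {
    n1 <- nrow(x); n2 <- ncol(x)
    i1 <- c(seq(floor(n1 / 2) + 1L, n1), seq_len(floor(n1 / 2)))
    i2 <- c(seq(floor(n2 / 2) + 1L, n2), seq_len(floor(n2 / 2)))
    x[i1, i2, drop = FALSE]
  } else {
    n <- length(x)
    x[c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))]
  }
}

#' @keywords internal
#' @noRd
radial_freq_grid <- function(n_row, n_col, spacing) {
  # |f| on the unshifted FFT grid; spacing = c(row, col) pixel size in mm.
  fr <- fft_freq(n_row, spacing[1])
  fc <- fft_freq(n_col, spacing[2])
  sqrt(outer(fr^2, fc^2, "+"))
}

#' @keywords internal
#' @noRd
trapz_area <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' @keywords internal
#' @noRd
tukey_window <- function(n, alpha = 0.5) {
  # Tapered cosine window; alpha is the fraction of the window inside the
  # cosine lobes. alpha = 0 is rectangular, alpha = 1 is Hann.
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Stable across platforms and sessions: a small multiplicative string hash
#' folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the cell.
#' @return integer seed in [1, 2^31 - 2].
#' @keywords internal
#' @noRd
cell_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
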