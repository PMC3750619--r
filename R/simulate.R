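#' Simulate a standardised two-class expression matrix
#'
#' Generates a synthetic sample-by-gene matrix emulating a small two-class
#' microarray study after preprocessing: two groups of multivariate
#' Gaussian rows with exchangeable within-row correlation `rho`, a mean
#' shift of `shift` units on the first `n_informative` genes of the second
#' class, and (optionally) a fraction of rows displaced by
#' `outlier_magnitude` in every coordinate to mimic gross contamination.
#' With `shift = 0` and `outlier_frac = 0` both classes come from one
#' distribution, the null fixture for [rank_test()].
#'
#' The defaults mirror a prostate-style study: 25 samples per class
#' measured on 100 genes, of which 10 would be informative were a shift
#' applied. Output is fully determined by `seed`; the caller's random state
#' is untouched.
#'
#' @param n_per_class samples per class. Default 25.
#' @param d number of genes. Default 100.
#' @param n_informative number of leading genes carrying the class shift
#'   (`<= d`). Default 10.
#' @param shift per-informative-gene mean difference between classes,
#'   expression units. Default 0.
#' @param rho exchangeable correlation between genes within a sample, in
#'   `[0, 1)`. Default 0.
#' @param outlier_frac fraction of rows (over both classes) displaced, in
#'   `[0, 0.5)`. Default 0.
#' @param outlier_magnitude displacement added to every coordinate of an
#'   outlying row. Default 50.
#' @param seed integer seed. Default 0.
#' @return a list with `x` (the `2 * n_per_class` by `d` matrix, rows named
#'   `s1..`, columns `g1..`), `labels` (character, `"0"` for the first
#'   class and `"1"` for the second) and `outliers` (indices of displaced
#'   rows, possibly empty).
#' @export
simulate_two_class <- function(n_per_class = 25, d = 100, n_informative = 10,
                               shift = 0, rho = 0, outlier_frac = 0,
                               outlier_magnitude = 50, seed = 0) {
  if (n_per_class < 2) stop("invalid config: n_per_class must be >= 2",
                            call. = FALSE)
  if (d < 1) stop("invalid config: d must be >= 1", call. = FALSE)
  if (n_informative < 0 || n_informative > d)
    stop("invalid config: n_informative must lie in [0, d]", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("invalid config: rho must lie in [0, 1)", call. = FALSE)
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop("invalid config: outlier_frac must lie in [0, 0.5)", call. = FALSE)
  n <- 2L * as.integer(n_per_class)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    if (rho > 0) {
      common <- stats::rnorm(n)
      x <- sqrt(rho) * common + sqrt(1 - rho) * x
    }
    cls2 <- seq.int(n_per_class + 1L, n)
    if (n_informative > 0 && shift != 0)
      x[cls2, seq_len(n_informative)] <-
        x[cls2, seq_len(n_informative), drop = FALSE] + shift
    n_out <- floor(outlier_frac * n)
    outliers <- integer(0)
    if (n_out > 0) {
      outliers <- sort(sample.int(n, n_out))
      x[outliers, ] <- x[outliers, , drop = FALSE] + outlier_magnitude
    }
    dimnames(x) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(d)))
    list(x = x,
         labels = rep(c("0", "1"), each = n_per_class),
         outliers = outliers)
  })
}
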