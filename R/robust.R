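#' Depth-trimmed mean
#'
#' Component-wise mean of the samples remaining after discarding the
#' proportion `alpha` of least-deep (most external) rows according to their
#' Modified Band Depth. The `ceiling((1 - alpha) * n)` deepest rows are
#' retained, so `alpha = 0` keeps every sample and reproduces the ordinary
#' column mean exactly.
#'
#' @param x numeric matrix, samples in rows (n >= 2, finite entries).
#' @param alpha proportion of observations trimmed out, in `[0, 1)`.
#'   Default 0.2.
#' @param depth optional precomputed `"mbd"` object for `x` (avoids
#'   recomputation when several statistics are derived from one ordering).
#' @return an object of class `"tmean"`: a list with
#'   \describe{
#'     \item{tm}{length-d trimmed mean, in the units of `x`.}
#'     \item{retained}{sorted indices of the retained (deepest) rows.}
#'     \item{tm.x}{the retained rows of `x` themselves.}
#'   }
#' @examples
#' x <- rbind(matrix(rnorm(20 * 10), 20), matrix(rnorm(2 * 10, 50), 2))
#' tmean(x, alpha = 0.2)$tm   # barely moved by the two gross outliers
#' @export
tmean <- function(x, alpha = 0.2, depth = NULL) {
  x <- as_depth_matrix(x, "samples")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("invalid trimming proportion: alpha must lie in [0, 1)",
         call. = FALSE)
  if (is.null(depth)) depth <- mbd(x)
  keep <- ceiling((1 - alpha) * nrow(x))
  retained <- sort(depth$ordering[seq_len(keep)])
  kept <- x[retained, , drop = FALSE]
  structure(list(tm = colMeans(kept), retained = retained, tm.x = kept),
            class = "tmean")
}

#' Envelope of the p most central samples
#'
#' For the `ceiling(p * n)` deepest rows of `x`, returns the per-column
#' minimum and maximum — the band those central samples span in parallel
#' coordinates. Envelopes are nested in `p`: the band at a smaller
#' proportion lies inside the band at a larger one.
#'
#' @inheritParams tmean
#' @param p proportion of most central samples, in `(0, 1]`.
#' @return an object of class `"band_envelope"`: list with `lower` and
#'   `upper` (length-d vectors), `p`, and `samples` (indices of the central
#'   rows defining the band).
#' @export
central_band <- function(x, p, depth = NULL) {
  x <- as_depth_matrix(x, "samples")
  check_proportion(p, "p")
  if (is.null(depth)) depth <- mbd(x)
  idx <- depth$ordering[seq_len(ceiling(p * nrow(x)))]
  central <- x[idx, , drop = FALSE]
  structure(list(lower = apply(central, 2L, min),
                 upper = apply(central, 2L, max),
                 p = p, samples = sort(idx)),
            class = "band_envelope")
}

#' Nested central bands for several proportions
#'
#' @inheritParams tmean
#' @param proportions strictly increasing proportions in `(0, 1]`.
#' @return list of [central_band()] envelopes, one per proportion, each
#'   contained in the next.
#' @export
central_partition <- function(x, proportions = c(0.25, 0.5, 0.75, 1),
                              depth = NULL) {
  x <- as_depth_matrix(x, "samples")
  if (length(proportions) == 0L || anyNA(proportions) ||
      any(diff(proportions) <= 0))
    stop("invalid band limits: proportions must be strictly increasing",
         call. = FALSE)
  for (p in proportions) check_proportion(p, "proportions")
  if (is.null(depth)) depth <- mbd(x)
  lapply(proportions, function(p) central_band(x, p, depth = depth))
}

#' Scale curve: dispersion of the central regions
#'
#' For each proportion `p` in `p_grid`, the area of the band spanned by the
#' `ceiling(p * n)` most central samples. The area is the trapezoidal
#' integral of `upper - lower` over the variable index `1..d` (unit
#' spacing); with a single central sample the band is degenerate and the
#' area is 0, and for `d = 1` the integration domain has zero width so all
#' areas are 0. The curve is non-decreasing in `p`, and its slope shows how
#' dispersion accumulates from the center outwards.
#'
#' @inheritParams tmean
#' @param p_grid increasing proportions in `(0, 1]`; defaults to
#'   `(1:n)/n`, the proportions at which the central-set size actually
#'   changes.
#' @return an object of class `"scale_curve"`: a data frame with columns
#'   `p` and `area` (units: expression units x variable index).
#' @examples
#' x <- matrix(rnorm(25 * 40), 25)
#' sc <- scale_curve(x)
#' all(diff(sc$area) >= 0)  # dispersion accumulates outwards
#' @export
scale_curve <- function(x, p_grid = NULL, depth = NULL) {
  x <- as_depth_matrix(x, "samples")
  n <- nrow(x)
  if (is.null(p_grid)) p_grid <- seq_len(n) / n
  if (anyNA(p_grid) || any(diff(p_grid) <= 0))
    stop("invalid band limits: p_grid must be strictly increasing",
         call. = FALSE)
  for (p in p_grid) check_proportion(p, "p_grid")
  if (is.null(depth)) depth <- mbd(x)
  area <- vapply(p_grid, function(p) {
    env <- central_band(x, p, depth = depth)
    band_area(env$upper - env$lower)
  }, numeric(1))
  structure(data.frame(p = p_grid, area = area),
            class = c("scale_curve", "data.frame"))
}

# Trapezoid over unit-spaced variable indices; zero when d == 1.
band_area <- function(width) {
  d <- length(width)
  if (d < 2L) return(0)
  sum((width[-1L] + width[-d]) / 2)
}
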