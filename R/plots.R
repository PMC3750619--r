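# Parallel-coordinate visualisations. These functions only draw: every
# number they display comes from mbd()/tmean()/central_band()/scale_curve().
# When `file` is given the plot is written as PNG and the path returned.

with_png <- function(file, width, height, code) {
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  force(code)
  invisible(file)
}

#' Parallel-coordinate plot with the deepest sample highlighted
#'
#' Draws every sample as a polyline over the variable index. By default all
#' samples share one colour and the deepest (most representative) profile
#' is overdrawn in `col_deepest`; with `grayscale = TRUE` each sample is
#' instead shaded by its depth rank, light (deep) to dark (external).
#'
#' @param x numeric matrix, samples in rows.
#' @param grayscale shade samples by depth rank instead of flat colour.
#' @param col,col_deepest line colours for the default mode.
#' @param file optional PNG path; when given the plot is written there and
#'   the path returned invisibly.
#' @param width,height device size in pixels when `file` is used.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return the `mbd` object of `x`, invisibly (or `file` when writing).
#' @export
plot_depth <- function(x, grayscale = FALSE, col = "gray", col_deepest = "red",
                       file = NULL, width = 800, height = 600, ...) {
  x <- as_depth_matrix(x, "samples")
  dp <- mbd(x)
  with_png(file, width, height, {
    if (grayscale) {
      shade <- grDevices::gray(seq(0.75, 0.1, length.out = nrow(x)))
      cols <- character(nrow(x))
      cols[dp$ordering] <- shade
    } else cols <- rep(col, nrow(x))
    graphics::matplot(t(x), type = "l", lty = 1, col = cols,
                      xlab = "variable", ylab = "expression", ...)
    graphics::lines(x[dp$ordering[1L], ], col = col_deepest, lwd = 2)
  })
  if (is.null(file)) invisible(dp) else invisible(file)
}

#' Nested central-band plot
#'
#' Shades the envelopes of the most central samples for each proportion in
#' `proportions`, light (central) over dark (peripheral), optionally
#' overlaying a reference collection as plain lines; depths are computed
#' with respect to `xref` when it is given.
#'
#' @inheritParams plot_depth
#' @param proportions increasing proportions of central samples to band.
#' @param xref optional reference matrix: depths of `x`'s rows are taken
#'   with respect to it and its samples are overlaid as `col_ref` lines.
#' @param col_ref colour of the reference overlay lines.
#' @export
plot_bands <- function(x, proportions = c(0.25, 0.5, 0.75, 1), xref = NULL,
                       col_ref = "blue", col_deepest = "red",
                       file = NULL, width = 800, height = 600, ...) {
  x <- as_depth_matrix(x, "samples")
  dp <- if (is.null(xref)) mbd(x) else mbd(x, xref = xref)
  bands <- lapply(proportions, function(p) central_band(x, p, depth = dp))
  with_png(file, width, height, {
    ylim <- range(x, if (!is.null(xref)) xref)
    graphics::matplot(t(x), type = "n", xlab = "variable",
                      ylab = "expression", ylim = ylim, ...)
    shade <- grDevices::gray(seq(0.35, 0.85, length.out = length(bands)))
    for (j in rev(seq_along(bands)))    # widest band first, central on top
      graphics::polygon(c(seq_len(ncol(x)), rev(seq_len(ncol(x)))),
                        c(bands[[j]]$upper, rev(bands[[j]]$lower)),
                        col = shade[j], border = NA)
    if (!is.null(xref))
      graphics::matlines(t(xref), lty = 1, col = col_ref)
    graphics::lines(x[dp$ordering[1L], ], col = col_deepest, lwd = 2)
  })
  if (is.null(file)) invisible(bands) else invisible(file)
}

#' Trimmed means across a sequence of trimming proportions
#'
#' Draws the depth-trimmed mean of `x` for each value of `alphas`, coloured
#' along a two-colour gradient from the ordinary-mean end (`ramp[1]`, the
#' smallest alpha) to the deepest-sample end (`ramp[2]`, the largest).
#'
#' @inheritParams plot_depth
#' @param alphas increasing trimming proportions in `[0, 1)`.
#' @param ramp length-2 colour vector for the gradient.
#' @param add add to the current plot (for cross-group comparison).
#' @export
plot_tmeans <- function(x, alphas = seq(0, 0.9, by = 0.1),
                        ramp = c("blue", "gray"), add = FALSE,
                        file = NULL, width = 800, height = 600, ...) {
  x <- as_depth_matrix(x, "samples")
  dp <- mbd(x)
  tms <- vapply(alphas, function(a) tmean(x, alpha = a, depth = dp)$tm,
                numeric(ncol(x)))
  with_png(file, width, height, {
    cols <- grDevices::colorRampPalette(ramp)(length(alphas))
    if (add) graphics::matlines(tms, lty = 1, col = cols)
    else graphics::matplot(tms, type = "l", lty = 1, col = cols,
                           xlab = "variable", ylab = "expression", ...)
  })
  if (is.null(file)) invisible(tms) else invisible(file)
}

#' Plot the p most central curves distinctly
#'
#' The central `ceiling(p * n)` samples are drawn with solid lines —
#' optionally coloured centre-outwards along `gradient_ramp` — and the
#' remaining external samples as gray dashed lines.
#'
#' @inheritParams plot_depth
#' @param p proportion of most central samples to highlight.
#' @param gradient colour the central curves by depth rank.
#' @param gradient_ramp length-2 colour vector; the first colour marks the
#'   deepest sample.
#' @export
plot_central <- function(x, p = 0.25, gradient = FALSE,
                         gradient_ramp = c("red", "yellow"),
                         file = NULL, width = 800, height = 600, ...) {
  x <- as_depth_matrix(x, "samples")
  dp <- mbd(x)
  k <- ceiling(p * nrow(x))
  central <- dp$ordering[seq_len(k)]
  with_png(file, width, height, {
    graphics::matplot(t(x), type = "n", xlab = "variable",
                      ylab = "expression", ...)
    graphics::matlines(t(x[-central, , drop = FALSE]), lty = 2, col = "gray")
    cols <- if (gradient) grDevices::colorRampPalette(gradient_ramp)(k)
            else rep(gradient_ramp[1L], k)
    for (j in rev(seq_len(k)))          # deepest drawn last, on top
      graphics::lines(x[central[j], ], col = cols[j], lwd = 1.5)
  })
  if (is.null(file)) invisible(central) else invisible(file)
}

#' Scale-curve plot, optionally per class
#'
#' @inheritParams plot_depth
#' @param labels optional per-row class labels; one curve per class.
#' @export
plot_scalecurve <- function(x, labels = NULL,
                            file = NULL, width = 800, height = 600, ...) {
  x <- as_depth_matrix(x, "samples")
  curves <- if (is.null(labels)) list(all = scale_curve(x))
            else lapply(split(seq_len(nrow(x)), as.character(labels)),
                        function(i) scale_curve(x[i, , drop = FALSE]))
  with_png(file, width, height, {
    ylim <- range(vapply(curves, function(s) range(s$area), numeric(2)))
    graphics::plot(NA, xlim = c(0, 1), ylim = ylim, xlab = "p",
                   ylab = "area of the p-central band", ...)
    for (j in seq_along(curves))
      graphics::lines(curves[[j]]$p, curves[[j]]$area, lty = j, lwd = 1.5)
    if (length(curves) > 1L)
      graphics::legend("topleft", legend = names(curves),
                       lty = seq_along(curves), bty = "n")
  })
  if (is.null(file)) invisible(curves) else invisible(file)
}
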