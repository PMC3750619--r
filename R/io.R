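#' Read and write expression matrices
#'
#' Delimited-text interchange format for sample-by-gene matrices: the first
#' row holds variable names, the first column holds sample identifiers, and
#' an optional final column named `label` carries per-sample class labels.
#' All remaining cells must be numeric. The separator is taken from the
#' file extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is
#' given.
#'
#' `write_expression` prints values with 17 significant digits, so finite
#' doubles round-trip exactly.
#'
#' @param file path to a CSV/TSV file.
#' @param sep field separator; `NULL` (default) infers it from the
#'   extension.
#' @return `read_expression`: a list with `x` (numeric matrix, sample ids
#'   as rownames, variable names as colnames) and `labels` (character
#'   vector, or `NULL` when the file has no `label` column).
#' @export
read_expression <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(file)
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 2L)
    stop("parse error: expected a sample-id column plus data columns",
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ids: '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  raw <- raw[, -1L, drop = FALSE]
  labels <- NULL
  if (ncol(raw) >= 1L && names(raw)[ncol(raw)] == "label") {
    labels <- raw[[ncol(raw)]]
    raw <- raw[, -ncol(raw), drop = FALSE]
  }
  if (ncol(raw) < 1L)
    stop("parse error: no numeric data columns found", call. = FALSE)
  x <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
              dimnames = list(ids, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at row '%s', column '%s'",
                   raw[[j]][bad[1L]], ids[bad[1L]], names(raw)[j]),
           call. = FALSE)
    x[, j] <- v
  }
  list(x = x, labels = labels)
}

#' @rdname read_expression
#' @param x numeric matrix to write (rownames become sample ids; defaults
#'   `s1..sn` / `v1..vd` are supplied when dimnames are missing).
#' @param labels optional per-row labels, written as a final `label`
#'   column.
#' @export
write_expression <- function(x, file, labels = NULL, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(file)
  x <- as_depth_matrix(x, "samples", min_rows = 1L)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  out <- data.frame(sample_id = rownames(x),
                    apply(x, 2L, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    out$label <- as.character(labels)
  }
  utils::write.table(out, file, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

infer_sep <- function(file) {
  if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
}

#' Microarray-style preprocessing of raw expression values
#'
#' Applies, in order: (i) clipping of all values to `[floor, ceiling]`;
#' (ii) removal of genes whose post-clipping expression varies less than
#' `min_fold`-fold relatively (max/min) or less than `min_abs` units
#' absolutely (max - min) across the samples — a gene is dropped when
#' either criterion fails; (iii) a base-10 logarithmic transformation; and
#' (iv) standardisation of each sample (row) to zero mean and unit variance
#' across the surviving genes. The defaults (10 / 16000 units, 5-fold, 500
#' units) are the thresholds customarily used for Affymetrix-style
#' expression summaries.
#'
#' @param x numeric matrix of raw expression values, samples in rows.
#' @param floor,ceiling clipping thresholds, expression units.
#' @param min_fold minimum max/min ratio a gene must reach to be kept.
#' @param min_abs minimum max - min range (units) a gene must reach.
#' @return numeric matrix of standardised log10 expression for the
#'   surviving genes; every row has mean 0 and unit (sample) variance.
#' @export
preprocess_expression <- function(x, floor = 10, ceiling = 16000,
                                  min_fold = 5, min_abs = 500) {
  x <- as_depth_matrix(x, "samples")
  if (floor <= 0 || ceiling <= floor)
    stop("invalid thresholds: need 0 < floor < ceiling", call. = FALSE)
  x <- pmin(pmax(x, floor), ceiling)
  hi <- apply(x, 2L, max)
  lo <- apply(x, 2L, min)
  keep <- (hi / lo >= min_fold) & (hi - lo >= min_abs)
  if (!any(keep))
    stop("empty matrix after filtering: no gene passed the variation filter",
         call. = FALSE)
  x <- log10(x[, keep, drop = FALSE])
  if (ncol(x) < 2L)
    stop("empty matrix after filtering: need >= 2 genes to standardise",
         call. = FALSE)
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0))
    stop("invalid matrix: a sample is constant across the surviving genes",
         call. = FALSE)
  (x - mu) / s
}

#' Rank genes by the between/within-groups sum-of-squares criterion
#'
#' For each gene, B/W is the ratio of the between-class sum of squares of
#' the class means about the grand mean (weighted by class size) to the
#' within-class sum of squares. Large values mark genes whose expression
#' separates the classes. A gene with zero within-class variance but
#' distinct class means has an infinite ratio and ranks first; a gene
#' constant across all samples (0/0) is assigned 0 and ranks last.
#'
#' @param x numeric matrix, samples in rows.
#' @param labels class label per row; at least 2 classes, each with at
#'   least 2 samples.
#' @param n_top optionally return only the `n_top` best gene indices.
#' @return a list with `ranking` (gene indices by decreasing B/W; ties keep
#'   original gene order) and `bw` (the per-gene ratios, `Inf` allowed).
#' @export
bw_rank_genes <- function(x, labels, n_top = NULL) {
  x <- as_depth_matrix(x, "samples")
  if (length(labels) != nrow(x))
    stop("dimension mismatch: one label per row is required", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("B/W undefined: at least two classes are required", call. = FALSE)
  grand <- colMeans(x)
  B <- numeric(ncol(x))
  W <- numeric(ncol(x))
  for (g in classes) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    B <- B + nrow(xg) * (mg - grand)^2
    W <- W + colSums((xg - matrix(mg, nrow(xg), ncol(xg), byrow = TRUE))^2)
  }
  bw <- ifelse(W > 0, B / W, ifelse(B > 0, Inf, 0))
  ranking <- order(-bw, seq_along(bw))
  if (!is.null(n_top)) ranking <- ranking[seq_len(min(n_top, length(ranking)))]
  list(ranking = ranking, bw = bw)
}
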