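# Shared fixture builders. Everything is generated in code under explicit
# seeds; no data files.

# Gaussian matrix, optionally with ties injected by rounding a subset of
# columns (duplicated values across rows exercise the multiplicity path).
random_matrix <- function(n, d, ties = FALSE) {
  x <- matrix(rnorm(n * d), n, d)
  if (ties && d >= 1) {
    k <- max(1L, d %/% 3L)
    cols <- sample.int(d, k)
    x[, cols] <- round(x[, cols, drop = FALSE])
  }
  x
}

# A clean cluster plus gross outliers displaced in every coordinate.
contaminated_matrix <- function(n_clean = 20, n_out = 2, d = 30,
                                magnitude = 50) {
  rbind(matrix(rnorm(n_clean * d), n_clean, d),
        matrix(rnorm(n_out * d) + magnitude, n_out, d))
}

# One train/test split of the separated-Gaussian two-class benchmark:
# 20 learning + 5 test rows per class.
benchmark_split <- function(seed, d = 50, shift = 3) {
  sim <- simulate_two_class(n_per_class = 25, d = d, n_informative = 10,
                            shift = shift, seed = seed)
  train <- c(1:20, 26:45)
  test <- setdiff(seq_len(50), train)
  list(xl = sim$x[train, ], yl = sim$labels[train],
       xt = sim$x[test, ], yt = sim$labels[test])
}
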