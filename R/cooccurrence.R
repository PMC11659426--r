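#' Checkerboard co-occurrence (CC) score
#'
#' A normalized, sign-reversed checkerboard statistic over a taxa-by-sample
#' presence/absence matrix. With N samples, M taxa, per-taxon occupancies
#' \eqn{N_i}, pairwise co-occurrence counts \eqn{N_{ij}} and
#' \eqn{p_i = N_i / N}:
#' \deqn{CC = 1 - \frac{\sum_{i<j} (N_i - N_{ij})(N_j - N_{ij})}
#'                    {\sum_{i<j} (N_i - N p_i p_j)(N_j - N p_i p_j)}}
#' For fixed occupancies, CC grows as taxa co-occur more often; low values
#' mean segregation. The normalization keeps the scale roughly constant as
#' the number of samples grows, unlike the classical C-score. Computed in
#' closed form from occupancy power sums and the sample-by-sample Gram
#' matrix, O(M N^2).
#'
#' @param pa A `presence_absence` object (see [to_presence_absence()]).
#' @return The CC score (a real number, typically near or below 1).
#' @examples
#' m <- diag(2L); dimnames(m) <- list(c("t1", "t2"), c("s1", "s2"))
#' cc_score(presence_absence(m)) # perfect checkerboard: -3
#' @export
cc_score <- function(pa) {
  stopifnot(inherits(pa, "presence_absence"))
  A <- pa$values
  M <- nrow(A); N <- ncol(A)
  if (M < 2L) stop2("need at least 2 taxa")
  Ni <- as.numeric(pa$occupancy)
  S1 <- sum(Ni); S2 <- sum(Ni^2); S3 <- sum(Ni^3); S4 <- sum(Ni^4)
  denom <- 0.5 * ((S1^2 - S2) - (2 / N) * (S1 * S2 - S3) + (S2^2 - S4) / N^2)
  if (denom == 0) stop2("degenerate input: CC denominator is 0")
  cvec <- colSums(A)                      # taxa per sample
  r <- as.numeric(A %*% cvec)             # r_i = sum_j N_ij (incl. j = i)
  C <- crossprod(A)                       # N x N Gram; ||N_ij||_F^2 preserved
  num <- 0.5 * ((S1^2 - S2) - 2 * (sum(Ni * r) - S2) + (sum(C^2) - S2))
  1 - num / denom
}

#' Generalized Morisita abundance-overlap (MA) score
#'
#' With \eqn{p_{ij}} the relative abundance of taxon i in sample j and N
#' samples:
#' \deqn{MA = \frac{\sum_i \left[(\sum_j p_{ij})^2 - \sum_j p_{ij}^2\right]}
#'                 {(N - 1) \sum_i \sum_j p_{ij}^2}}
#' MA = 1 iff all samples have identical composition; MA = 0 iff every taxon
#' occurs in exactly one sample (complete segregation).
#'
#' @param t A proportions-mode [community_table()] (counts are converted).
#' @return The MA score in `[0, 1]`.
#' @export
ma_score <- function(t) {
  stopifnot(inherits(t, "community_table"))
  p <- to_proportions(t)$values
  N <- ncol(p)
  if (N < 2L) stop2("need at least 2 samples")
  ss <- sum(p^2)
  if (ss == 0) stop2("all-zero table")
  sum(rowSums(p)^2 - rowSums(p^2)) / ((N - 1) * ss)
}

#' Fixed-fixed (SIM9) null matrices by checkerboard swaps
#'
#' Randomizes a presence/absence matrix while preserving both the number of
#' samples per taxon (row sums) and the number of taxa per sample (column
#' sums), via a Markov chain of checkerboard swaps: a random 2x2 submatrix of
#' the form `[[1,0],[0,1]]` or `[[0,1],[1,0]]` is flipped. Because the
#' proposal (pick 2 random rows and 2 random columns) is symmetric, the chain
#' sampled at fixed ATTEMPT counts is uniform over all matrices with the given
#' marginals; thinning on accepted swaps instead would oversample states with
#' many swappable submatrices. `burn_in` and `thin` therefore count attempts.
#' Defaults: `burn_in` = 100 x (rows x columns), `thin` = 10 x (rows x
#' columns), generous for matrices of the size used here.
#'
#' @param pa A `presence_absence` object containing at least one checkerboard
#'   submatrix (otherwise the chain is frozen and an error is raised).
#' @param n_null Number of matrices to emit (default 1000).
#' @param burn_in,thin Chain parameters in attempted swaps; `NULL` = defaults.
#' @param seed Integer seed.
#' @return List of `n_null` `presence_absence` objects with the original
#'   labels and marginals.
#' @export
sim9_null <- function(pa, n_null = 1000, burn_in = NULL, thin = NULL,
                      seed = NULL) {
  stopifnot(inherits(pa, "presence_absence"))
  if (!has_checkerboard(pa$values))
    stop2("degenerate null: matrix has no checkerboard submatrix (frozen chain)")
  cells <- prod(dim(pa$values))
  if (is.null(burn_in)) burn_in <- 100 * cells
  if (is.null(thin)) thin <- 10 * cells
  mats <- with_seed(seed,
                    sim9_chain(pa$values, as.integer(n_null),
                               as.numeric(burn_in), as.numeric(thin)))
  dn <- dimnames(pa$values)
  lapply(mats, function(m) {
    dimnames(m) <- dn
    presence_absence(m)
  })
}

#' IT abundance null: read reallocation proportional to both marginals
#'
#' Reassigns every read of a counts table to a cell (i, j) with probability
#' proportional to (remaining row-i quota) x (remaining column-j quota),
#' until each taxon's total and each sample's total are exactly met. Because
#' the cell probability factorizes at every step, the scheme is realized
#' exactly by pairing a uniform random shuffle of the read-level taxon labels
#' with the sample labels: distributionally identical to the sequential fill,
#' O(total reads) per matrix.
#'
#' @param t A counts-mode [community_table()] (integer counts).
#' @param n_null Number of tables (default 1000).
#' @param seed Integer seed.
#' @return List of `n_null` counts-mode [community_table()]s with the
#'   original row and column totals, exactly.
#' @export
it_null <- function(t, n_null = 1000, seed = NULL) {
  stopifnot(inherits(t, "community_table"))
  if (t$mode != "counts") stop2("IT null needs a counts-mode table")
  v <- t$values
  if (any(v != round(v))) stop2("IT null needs integer counts")
  M <- nrow(v); N <- ncol(v)
  rt <- as.integer(round(rowSums(v)))
  ct <- as.integer(round(colSums(v)))
  if (sum(rt) == 0) stop2("empty table")
  row_lab <- rep.int(seq_len(M), rt)
  col_lab <- rep.int(seq_len(N), ct)
  dn <- dimnames(v)
  with_seed(seed, lapply(seq_len(n_null), function(k) {
    rp <- if (length(row_lab) > 1L) sample(row_lab) else row_lab
    cells <- tabulate(rp + M * (col_lab - 1L), nbins = M * N)
    m <- matrix(cells, M, N, dimnames = dn)
    community_table(m, "counts")
  }))
}

#' Null-model test of a co-distribution score
#'
#' Compares an observed score against its distribution under a compatible
#' null model: the CC score under the fixed-fixed SIM9 null (binary data),
#' or the MA score under the IT abundance null (counts; every null table is
#' renormalized to proportions before scoring). Tail p-values use the
#' add-one convention, so `p_low = (1 + #\{null <= observed\}) / (1 + n_null)`;
#' a small `p_low` means taxa overlap less than expected by chance, i.e.
#' segregation.
#'
#' @param data A `presence_absence` (for `score = "cc"`) or counts-mode
#'   [community_table()] (for `score = "ma"`).
#' @param score `"cc"` or `"ma"`.
#' @param null `"sim9"` or `"it"`; defaults to the score's canonical null.
#' @param n_null Number of null datasets (default 1000).
#' @param seed Integer seed.
#' @param ... Passed to the null generator (e.g. `burn_in`, `thin`).
#' @return An object of class `null_test_result`: list with `observed`,
#'   `null_scores`, `p_low`, `p_high`, `null_mean`, `null_sd`, `score`,
#'   `null`, `n_null`, `seed`.
#' @export
null_test <- function(data, score = c("cc", "ma"), null = NULL,
                      n_null = 1000, seed = NULL, ...) {
  score <- match.arg(score)
  if (is.null(null)) null <- if (score == "cc") "sim9" else "it"
  if (score == "cc" && null != "sim9")
    stop2("the CC score is tested against the sim9 null")
  if (score == "ma" && null != "it")
    stop2("the MA score is tested against the it null")
  if (score == "cc") {
    if (inherits(data, "community_table")) data <- to_presence_absence(data)
    stopifnot(inherits(data, "presence_absence"))
    observed <- cc_score(data)
    nulls <- sim9_null(data, n_null = n_null, seed = seed, ...)
    null_scores <- vapply(nulls, cc_score, numeric(1))
  } else {
    stopifnot(inherits(data, "community_table"))
    observed <- ma_score(data)
    nulls <- it_null(data, n_null = n_null, seed = seed, ...)
    null_scores <- vapply(nulls, ma_score, numeric(1))
  }
  tol <- 1e-12
  p_low <- (1 + sum(null_scores <= observed + tol)) / (1 + n_null)
  p_high <- (1 + sum(null_scores >= observed - tol)) / (1 + n_null)
  structure(list(observed = observed, null_scores = null_scores,
                 p_low = p_low, p_high = p_high,
                 null_mean = mean(null_scores), null_sd = sd(null_scores),
                 score = score, null = null, n_null = n_null, seed = seed),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("%s score vs %s null: observed = %.4f, null mean = %.4f (sd %.4f)\n",
              toupper(x$score), x$null, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p_low = %.4g, p_high = %.4g [%d null datasets]\n",
              x$p_low, x$p_high, x$n_null))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in (0, 1), default 0.05.
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @examples
#' round(bonferroni_threshold(0.05, 7), 4)  # 0.0071
#' round(bonferroni_threshold(0.05, 21), 4) # 0.0024
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop2("alpha must be in (0, 1)")
  if (n_tests < 1) stop2("n_tests must be >= 1")
  alpha / n_tests
}
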