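#' Mantel rank-correlation test between two distance matrices
#'
#' Spearman rank correlation between the lower triangles of two labelled
#' distance matrices, with significance from simultaneous permutation of the
#' rows and columns of the second matrix (the standard Mantel procedure).
#' Matrices are aligned by label, not by position. The one-sided p-value uses
#' the add-one convention `p = (1 + #{rho* >= rho}) / (1 + n_perm)` for
#' `tail = "greater"` (testing distance decay, i.e. positive correlation),
#' so p is never 0.
#'
#' @param d1,d2 Labelled symmetric distance matrices over the same sample set.
#' @param n_perm Number of permutations (default 1000).
#' @param tail `"greater"` (default; positive-association alternative) or
#'   `"less"`.
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility; `NULL` uses the current RNG state).
#' @param exact If `TRUE`, enumerate all `n!` label permutations instead of
#'   sampling (only sensible for small n; the identity permutation plays the
#'   add-one role).
#' @return An object of class `mantel_result`: list with `rho`, `p`,
#'   `tail`, `n_perm`, `n_samples`, `seed`.
#' @examples
#' d <- as.matrix(dist(1:5)); dimnames(d) <- list(letters[1:5], letters[1:5])
#' mantel_test(d, d^2, n_perm = 99, seed = 1)$rho # rank invariance: 1
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, tail = c("greater", "less"),
                        seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  check_distance_matrix(d1); check_distance_matrix(d2)
  if (!setequal(rownames(d1), rownames(d2)))
    stop2("label sets of the two matrices differ")
  if (n_perm < 1) stop2("n_perm must be >= 1")
  ids <- rownames(d1)
  d2 <- d2[ids, ids]
  n <- length(ids)
  lt <- lower.tri(d1)
  x <- d1[lt]; y <- d2[lt]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop2("degenerate input: constant lower triangle, rho undefined")
  rx <- rank(x)
  # permuting rows+columns rearranges the fixed multiset of triangle entries,
  # so rank once and use Pearson on permuted rank matrices
  ry_mat <- matrix(0, n, n)
  ry_mat[lt] <- rank(y)
  ry_mat <- ry_mat + t(ry_mat)
  rho <- cor(rx, ry_mat[lt])
  stat <- function(perm) cor(rx, ry_mat[perm, perm][lt])
  if (exact) {
    perms <- all_permutations(n)
    rho_star <- vapply(perms, stat, numeric(1))
    # identity permutation is among the n! and plays the add-one role
    count <- if (tail == "greater") sum(rho_star >= rho - 1e-12)
             else sum(rho_star <= rho + 1e-12)
    p <- count / length(perms)
    n_perm <- length(perms) - 1L
  } else {
    rho_star <- with_seed(seed, vapply(seq_len(n_perm),
                                       function(k) stat(sample.int(n)),
                                       numeric(1)))
    count <- if (tail == "greater") sum(rho_star >= rho - 1e-12)
             else sum(rho_star <= rho + 1e-12)
    p <- (1 + count) / (1 + n_perm)
  }
  structure(list(rho = rho, p = p, tail = tail, n_perm = n_perm,
                 n_samples = n, seed = seed, null_rhos = rho_star),
            class = "mantel_result")
}

# all permutations of 1..n (n <= 8 guard)
all_permutations <- function(n) {
  if (n > 8L) stop2("full enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (Spearman): rho = %.4f, one-sided P (%s) = %.4g [%d permutations, n = %d]\n",
              x$rho, x$tail, x$p, x$n_perm, x$n_samples))
  invisible(x)
}
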