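# Independent brute-force oracles and small fixture builders.
# Oracles deliberately use naive loops, not the package's vectorized paths.

rand_counts_table <- function(n_taxa, n_samples, lambda = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  community_table(m, "counts")
}

rand_binary_matrix <- function(n_taxa, n_samples, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n_taxa * n_samples, 1, p), n_taxa, n_samples,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

labelled_dist <- function(m, ids = NULL) {
  m <- as.matrix(m)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  m
}

# CC score by the literal pairwise double loop
cc_score_brute <- function(A) {
  M <- nrow(A); N <- ncol(A)
  Ni <- rowSums(A)
  num <- den <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) if (j < i) {
    Nij <- sum(A[i, ] * A[j, ])
    pi <- Ni[i] / N; pj <- Ni[j] / N
    num <- num + (Ni[i] - Nij) * (Ni[j] - Nij)
    den <- den + (Ni[i] - N * pi * pj) * (Ni[j] - N * pi * pj)
  }
  unname(1 - num / den)
}

# MA score by literal per-taxon loops on the proportion matrix
ma_score_brute <- function(P) {
  N <- ncol(P)
  num <- 0
  for (i in seq_len(nrow(P)))
    num <- num + sum(P[i, ])^2 - sum(P[i, ]^2)
  num / ((N - 1) * sum(P^2))
}

# hand-formula dissimilarities on two proportion vectors
bray_hand <- function(p, q) sum(abs(p - q)) / sum(p + q)
hellinger_hand <- function(p, q) sqrt(sum((sqrt(p) - sqrt(q))^2))
ruzicka_hand <- function(p, q) 1 - sum(pmin(p, q)) / sum(pmax(p, q))

# Spearman rho over lower triangles, straight from cor()
mantel_rho_brute <- function(d1, d2) {
  ids <- rownames(d1)
  cor(d1[lower.tri(d1)], d2[ids, ids][lower.tri(d2)], method = "spearman")
}

# enumerate all binary matrices with the given margins (small cases only)
enumerate_fixed_fixed <- function(rs, cs) {
  M <- length(rs); N <- length(cs)
  stopifnot(M * N <= 20)
  out <- list()
  for (code in 0:(2^(M * N) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(M * N)]
    m <- matrix(bits, M, N)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs))
      out[[length(out) + 1L]] <- m
  }
  out
}

# exact table distribution of the sequential IT fill: place one read at a
# time into cell (i, j) with prob proportional to remaining row quota x
# remaining column quota; recursion over quota states
it_exact_distribution <- function(rt, ct) {
  M <- length(rt); N <- length(ct)
  acc <- new.env()
  rec <- function(tab, r, c, prob) {
    if (sum(r) == 0) {
      key <- paste(tab, collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    w <- outer(r, c)
    tot <- sum(w)
    for (i in seq_len(M)) for (j in seq_len(N)) if (w[i, j] > 0) {
      tab2 <- tab; tab2[i, j] <- tab2[i, j] + 1L
      r2 <- r; r2[i] <- r2[i] - 1L
      c2 <- c; c2[j] <- c2[j] - 1L
      rec(tab2, r2, c2, prob * w[i, j] / tot)
    }
  }
  rec(matrix(0L, M, N), rt, ct, 1)
  probs <- unlist(as.list(acc))
  probs
}
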