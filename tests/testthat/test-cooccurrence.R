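test_that("CC score matches hand values and the brute-force pairwise loop", {
  # identical presence rows: numerator 0, CC = 1
  m <- rbind(t1 = c(1L, 1L, 0L), t2 = c(1L, 1L, 0L))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(cc_score(presence_absence(m)), 1)
  # 2x2 perfect checkerboard: CC = -3
  cb <- diag(2L); dimnames(cb) <- list(c("t1", "t2"), c("s1", "s2"))
  expect_equal(cc_score(presence_absence(cb)), -3)
  for (k in 1:100) {
    A <- rand_binary_matrix(8, 6, p = 0.4, seed = 1500 + k)
    if (all(rowSums(A) == ncol(A))) next
    expect_equal(cc_score(presence_absence(A)), cc_score_brute(A),
                 tolerance = 1e-12)
  }
  # full matrix: denominator 0
  full <- matrix(1L, 3, 3, dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  expect_error(cc_score(presence_absence(full)), "denominator")
})

test_that("CC score is invariant to row and column permutations", {
  A <- rand_binary_matrix(10, 7, seed = 9)
  base <- cc_score(presence_absence(A))
  for (k in 1:10) {
    set.seed(k)
    B <- A[sample(nrow(A)), sample(ncol(A))]
    expect_equal(cc_score(presence_absence(B)), base, tolerance = 1e-12)
  }
})

test_that("MA score matches hand values, the brute loop, and its range", {
  p <- cbind(s1 = c(0.8, 0.2), s2 = c(0.2, 0.8)); rownames(p) <- c("a", "b")
  expect_equal(ma_score(community_table(p, "proportions")), 8 / 17)
  # identical compositions: MA = 1
  same <- cbind(s1 = c(0.3, 0.7), s2 = c(0.3, 0.7), s3 = c(0.3, 0.7))
  rownames(same) <- c("a", "b")
  expect_equal(ma_score(community_table(same, "proportions")), 1)
  # one sample per taxon: MA = 0
  seg <- diag(3); dimnames(seg) <- list(paste0("t", 1:3), paste0("s", 1:3))
  expect_equal(ma_score(community_table(seg, "proportions")), 0)
  for (k in 1:100) {
    t <- rand_counts_table(7, 5, lambda = 3, seed = 2500 + k)
    v <- ma_score(t)
    expect_equal(v, ma_score_brute(to_proportions(t)$values), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
  }
})

test_that("MA = 1 exactly when columns are proportional", {
  base <- c(0.5, 0.3, 0.2)
  prop <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(prop) <- paste0("t", 1:3)
  expect_equal(ma_score(community_table(prop, "proportions")), 1, tolerance = 1e-12)
  for (k in 1:20) {
    t <- rand_counts_table(6, 4, lambda = 4, seed = 3500 + k)
    p <- to_proportions(t)$values
    if (max(apply(p, 1, function(r) diff(range(r)))) > 1e-9)
      expect_lt(ma_score(t), 1)
  }
})

test_that("SIM9 preserves marginals exactly and visits both 2x2 states", {
  cb <- diag(2L); dimnames(cb) <- list(c("t1", "t2"), c("s1", "s2"))
  nulls <- sim9_null(presence_absence(cb), n_null = 50, burn_in = 0, thin = 1,
                     seed = 4)
  states <- unique(vapply(nulls, function(x) paste(x$values, collapse = ""),
                          character(1)))
  expect_setequal(states, c("1001", "0110")) # the only two fixed-marginal states
  A <- rand_binary_matrix(12, 8, seed = 77)
  pa <- presence_absence(A)
  for (x in sim9_null(pa, n_null = 30, seed = 5)) {
    expect_identical(rowSums(x$values), rowSums(A))
    expect_identical(colSums(x$values), colSums(A))
  }
  frozen <- rbind(t1 = c(1L, 1L), t2 = c(1L, 0L)); colnames(frozen) <- c("s1", "s2")
  expect_error(sim9_null(presence_absence(frozen), n_null = 5, seed = 1),
               "frozen")
})

test_that("SIM9 is uniform over the enumerable fixed-marginal state space", {
  A <- rbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L),
             c(0L, 0L, 1L, 1L))
  dimnames(A) <- list(paste0("t", 1:4), paste0("s", 1:4))
  space <- enumerate_fixed_fixed(rowSums(A), colSums(A))
  keys <- vapply(space, function(m) paste(m, collapse = ""), character(1))
  draws <- sim9_null(presence_absence(A), n_null = 4000, burn_in = 1000,
                     thin = 200, seed = 11)
  got <- vapply(draws, function(x) paste(x$values, collapse = ""), character(1))
  expect_true(all(got %in% keys))
  counts <- table(factor(got, levels = keys))
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("IT null preserves both marginals exactly and is degenerate for one taxon", {
  t <- rand_counts_table(6, 5, lambda = 6, seed = 12)
  for (x in it_null(t, n_null = 40, seed = 3)) {
    expect_identical(rowSums(x$values), rowSums(t$values))
    expect_identical(colSums(x$values), colSums(t$values))
  }
  one <- community_table(cbind(s1 = 4, s2 = 2) |>
                           (\(m) { rownames(m) <- "t1"; m })(), "counts")
  for (x in it_null(one, n_null = 5, seed = 2))
    expect_equal(x$values, one$values) # values exact; storage may differ
})

test_that("IT cell distribution matches exact enumeration of the fill scheme", {
  t <- community_table(matrix(c(1L, 1L, 1L, 1L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       "counts")
  exact <- it_exact_distribution(c(2L, 2L), c(2L, 2L))
  draws <- it_null(t, n_null = 4000, seed = 9)
  keys <- vapply(draws, function(x) paste(x$values, collapse = ","), character(1))
  emp <- table(factor(keys, levels = names(exact))) / length(keys)
  expect_true(all(names(table(keys)) %in% names(exact)))
  for (k in names(exact)) {
    se <- sqrt(exact[[k]] * (1 - exact[[k]]) / 4000)
    expect_lt(abs(emp[[k]] - exact[[k]]), 4 * se + 0.005)
  }
})

test_that("null_test computes add-one tail p-values and extreme tails", {
  A <- rand_binary_matrix(10, 6, p = 0.5, seed = 31)
  nt <- null_test(presence_absence(A), "cc", n_null = 99, seed = 13)
  expect_equal(nt$p_low,
               (1 + sum(nt$null_scores <= nt$observed + 1e-12)) / 100)
  expect_gte(nt$p_low + nt$p_high, 1)
  expect_equal(nt$null_mean, mean(nt$null_scores))
  t <- rand_counts_table(8, 5, lambda = 5, seed = 32)
  ntm <- null_test(t, "ma", n_null = 49, seed = 14)
  expect_length(ntm$null_scores, 49)
  expect_error(null_test(t, "cc", null = "it", n_null = 9, seed = 1), "sim9")
})

test_that("Bonferroni thresholds reproduce the standard adjusted levels", {
  expect_equal(round(bonferroni_threshold(0.05, 21), 4), 0.0024)
  expect_equal(round(bonferroni_threshold(0.05, 7), 4), 0.0071)
  expect_equal(round(bonferroni_threshold(0.05, 441), 5), 0.00011)
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})
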