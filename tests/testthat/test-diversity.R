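test_that("CV profile matches hand arithmetic and excludes zero-mean rows", {
  p <- cbind(s1 = c(0.2, 0.8), s2 = c(0, 1)); rownames(p) <- c("a", "b")
  prof <- cv_profile(community_table(p, "proportions"))
  expect_equal(prof$mean, c(0.1, 0.9))
  expect_equal(prof$cv, c(sqrt(2), sqrt(2) / 9), tolerance = 1e-12)
  pop <- cv_profile(community_table(p, "proportions"), sd_type = "population")
  expect_equal(pop$cv, c(1, 1 / 9), tolerance = 1e-12)
  cts <- rbind(a = c(3L, 1L), b = c(0L, 0L), c = c(2L, 4L))
  colnames(cts) <- c("s1", "s2")
  withzero <- cv_profile(community_table(cts, "counts"))
  expect_identical(withzero$id, c("a", "c"))
  expect_identical(attr(withzero, "n_zero_mean"), 1L)
})

test_that("CV profile agrees with a naive per-row loop on random tables", {
  for (k in 1:20) {
    t <- rand_counts_table(15, 6, lambda = 4, seed = 5000 + k)
    prof <- cv_profile(t)
    p <- to_proportions(t)$values
    got <- setNames(prof$cv, prof$id)
    for (i in rownames(p)) {
      mu <- mean(p[i, ])
      if (mu == 0) { expect_false(i %in% prof$id); next }
      expect_equal(unname(got[i]), sd(p[i, ]) / mu, tolerance = 1e-12)
    }
  }
  one <- community_table(cbind(s1 = c(a = 1, b = 1)), "counts")
  expect_error(cv_profile(one), "2 samples")
})

test_that("core-biome curve reproduces the hypergeometric hand values", {
  # occupancies 10, 2, 1 over 10 samples
  m <- matrix(0L, 3, 10, dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
  m[1, ] <- 1L; m[2, 1:2] <- 1L; m[3, 1] <- 1L
  cur <- core_biome_curve(presence_absence(m))
  expect_equal(cur$shared[1], 1.3)
  expect_equal(cur$shared[2], 1 + 1 / 45, tolerance = 1e-12)
  expect_equal(cur$shared[10], 1)
  expect_true(all(diff(cur$shared) <= 1e-12)) # non-increasing
  # endpoints: mean richness at n = 1, universal taxa at n = N
  A <- rand_binary_matrix(12, 6, p = 0.5, seed = 61)
  ec <- core_biome_curve(presence_absence(A))
  expect_equal(ec$shared[1], mean(colSums(A)), tolerance = 1e-12)
  expect_equal(ec$shared[6], sum(rowSums(A) == 6))
})

test_that("subsampled core-biome curve agrees with the exact closed form", {
  A <- rand_binary_matrix(8, 6, p = 0.5, seed = 62)
  pa <- presence_absence(A)
  ex <- core_biome_curve(pa)
  mc <- core_biome_curve(pa, method = "subsample", n_draws = 2000, seed = 7)
  # per-draw shared counts lie in [0, 8], so their sd is at most 4
  expect_true(all(abs(mc$shared - ex$shared) < 3 * 4 / sqrt(2000)))
  expect_identical(core_biome_curve(pa, method = "subsample", n_draws = 500,
                                    seed = 9),
                   core_biome_curve(pa, method = "subsample", n_draws = 500,
                                    seed = 9))
})

test_that("collector's curve reproduces exact rarefaction hand values", {
  t <- community_table(cbind(s1 = c(a = 2L, b = 1L, c = 1L)), "counts")
  cur <- collectors_curve(t, "s1", depths = c(1, 2, 4))
  expect_equal(cur$richness, c(1, 11 / 6, 3), tolerance = 1e-12)
  # enumeration oracle: average unique taxa over all read subsets of size d
  reads <- rep.int(1:3, c(2, 1, 1))
  for (d in 1:4) {
    subsets <- utils::combn(seq_along(reads), d)
    want <- mean(apply(subsets, 2, function(s) length(unique(reads[s]))))
    expect_equal(collectors_curve(t, "s1", d)$richness, want, tolerance = 1e-12)
  }
})

test_that("collector's curve is increasing, saturates, and validates input", {
  t <- rand_counts_table(10, 3, lambda = 6, seed = 71)
  tot <- sum(t$values[, "s02"])
  cur <- collectors_curve(t, "s02", depths = seq_len(tot))
  expect_true(all(diff(cur$richness) >= -1e-12))
  expect_equal(cur$richness[tot], sum(t$values[, "s02"] > 0))
  mc <- collectors_curve(t, "s02", depths = c(1, tot %/% 2, tot),
                         method = "subsample", n_draws = 2000, seed = 5)
  exd <- collectors_curve(t, "s02", depths = c(1, tot %/% 2, tot))
  # per-draw richness lies in [1, 10], so its sd is at most 4.5
  expect_true(all(abs(mc$richness - exd$richness) < 3 * 4.5 / sqrt(2000)))
  expect_error(collectors_curve(t, "s02", tot + 1), "exceeds")
  expect_error(collectors_curve(t, "s02", 0), ">= 1")
  expect_error(collectors_curve(t, "nope", 1), "unknown sample")
  expect_error(collectors_curve(to_proportions(t), "s02", 1), "counts")
})
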