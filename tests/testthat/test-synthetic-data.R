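small_cfg <- function(...) {
  generator_config(n_samples = 10, n_taxa = 200, n_functional_groups = 10, ...)
}

test_that("generation is deterministic and structurally sound", {
  cfg <- small_cfg(seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$table$values, d2$table$values)
  expect_identical(d1$coordinates, d2$coordinates)
  expect_identical(d1$environment, d2$environment)
  expect_identical(d1$taxonomy$lineage, d2$taxonomy$lineage)
  expect_identical(dim(d1$table$values), c(200L, 10L))
  expect_true(all(d1$table$values >= 0))
  expect_length(unique(d1$taxon_groups), 10)
  expect_true(all(abs(colSums(d1$functional$values) - 1) <= 1e-9))
  expect_true(all(d1$coordinates$latitude_deg >= cfg$lat_range[1] &
                  d1$coordinates$latitude_deg <= cfg$lat_range[2]))
  expect_identical(d1$config, cfg)
  # a different seed gives a different table
  expect_false(identical(generate_dataset(small_cfg(seed = 43))$table$values,
                         d1$table$values))
  # negative segregation runs and changes the outcome
  dn <- generate_dataset(small_cfg(segregation = -0.8, seed = 42))
  expect_false(identical(dn$table$values, d1$table$values))
  expect_true(all(colSums(dn$table$values) > 0))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(generator_config(n_samples = 1), ">= 2")
  expect_error(generator_config(segregation = 1.5), "segregation")
  expect_error(generator_config(occupancy = 0), "occupancy")
  expect_error(generator_config(n_taxa = 5, n_functional_groups = 6),
               "infeasible")
  cfg <- generator_config(env_effects = c(1, 2), n_env = 3)
  expect_equal(cfg$env_effects, c(1, 2, 0)) # padded to n_env
})

test_that("datasets round-trip through TSV + JSON on disk", {
  d <- generate_dataset(small_cfg(env_effects = c(1, 0, 0), seed = 7))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  r <- read_dataset(dir)
  expect_equal(r$table$values, d$table$values) # values exact; storage may widen
  expect_true(all(r$table$values == d$table$values))
  expect_equal(r$coordinates, d$coordinates)
  expect_equal(as.matrix(r$environment), as.matrix(d$environment),
               tolerance = 1e-12)
  expect_equal(r$functional$values, d$functional$values, tolerance = 1e-9)
  expect_identical(unname(r$taxon_groups[names(d$taxon_groups)]),
                   unname(d$taxon_groups))
  expect_equal(r$config$seed, 7)
  expect_equal(r$config$n_taxa, 200)
})

test_that("functional groups are far more stable than their member taxa", {
  d <- generate_dataset(small_cfg(seed = 11))
  taxon_cv <- cv_profile(d$table)
  group_cv <- cv_profile(d$functional)
  expect_gt(median(taxon_cv$cv) / median(group_cv$cv), 3)
})

test_that("segregation plants a detectable co-occurrence deficit", {
  hits_cc <- hits_ma <- logical(10)
  for (r in 1:10) {
    d <- generate_dataset(small_cfg(segregation = 1, seed = 600 + r))
    nt <- null_test(to_presence_absence(d$table), "cc", n_null = 99,
                    seed = r)
    hits_cc[r] <- nt$observed < nt$null_mean && nt$p_low < 0.05
    ma <- null_test(d$table, "ma", n_null = 99, seed = r)
    hits_ma[r] <- ma$observed < ma$null_mean && ma$p_low < 0.05
  }
  expect_gte(sum(hits_cc), 8)
  expect_gte(sum(hits_ma), 8)
})

test_that("neutral datasets rarely trigger the co-occurrence test", {
  p_low <- vapply(1:20, function(r) {
    d <- generate_dataset(small_cfg(seed = 700 + r))
    null_test(to_presence_absence(d$table), "cc", n_null = 99, seed = r)$p_low
  }, numeric(1))
  expect_lte(sum(p_low < 0.05), 4)
})

test_that("distance decay induces a Mantel-detectable spatial signal", {
  for (r in 1:4) {
    d <- generate_dataset(generator_config(
      n_samples = 12, n_taxa = 300, n_functional_groups = 15, occupancy = 1,
      distance_decay = 0.01, spatial_sd = 2, seed = 400 + r))
    bc <- pairwise_dissimilarity(d$table, "bray_curtis")
    g <- geographic_distances(d$coordinates)
    mt <- mantel_test(bc, g, n_perm = 199, seed = r)
    expect_gt(mt$rho, 0)
    expect_lt(mt$p, 0.05)
  }
})

test_that("a planted environmental driver is recovered by stepwise MRM", {
  n_found <- 0
  for (r in 1:4) {
    d <- generate_dataset(small_cfg(occupancy = 1, env_effects = c(2, 0, 0),
                                    seed = 100 + r))
    bc <- pairwise_dissimilarity(d$table, "bray_curtis")
    cands <- c(list(geographic_km = geographic_distances(d$coordinates)),
               lapply(as.list(d$environment), function(v)
                 abs_diff_matrix(setNames(v, rownames(d$environment)))))
    fit <- stepwise_mrm(bc, cands, n_perm = 199, seed = r)
    n_found <- n_found + ("env_1" %in% fit$selected)
  }
  expect_gte(n_found, 3)
})
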