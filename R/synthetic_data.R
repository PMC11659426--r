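#' Configuration for the synthetic community generator
#'
#' Defaults emulate the shape of a subsurface-sediment amplicon +
#' metagenome survey: 10 geolocated samples along a ~300 km coastal
#' transect, a few thousand sparse, heavy-tailed taxa, several thousand
#' reads per sample, and functional groups whose summed proportions are
#' stable across samples while membership turns over (functional
#' redundancy).
#'
#' @param n_samples Number of samples (default 10).
#' @param n_taxa Number of taxa (default 2000).
#' @param reads_per_sample Mean library size (default 5500; depths vary
#'   lognormally around it with `depth_sdlog`).
#' @param depth_sdlog Lognormal sd of library sizes (default 0.2).
#' @param abundance_sdlog Lognormal log-sd of base taxon abundances
#'   (default 2; heavy-tailed).
#' @param occupancy Per-taxon per-sample detection probability (default 0.5;
#'   drives sparsity).
#' @param segregation s in `[-1, 1]`: 0 = neutral; s > 0 depresses
#'   within-functional-group co-presence (competitive exclusion, one-or-few
#'   winners per group per sample); s < 0 enhances it (aggregation).
#' @param n_functional_groups Number of functional groups; taxa are assigned
#'   round-robin, so redundancy = `n_taxa / n_functional_groups` (default 100).
#' @param distance_decay Rate lambda (per km) at which community similarity
#'   decays with geographic distance; 0 disables the spatial field.
#' @param spatial_sd Log-scale sd of the spatially correlated field applied
#'   when `distance_decay > 0` (default 1).
#' @param env_effects Numeric vector (recycled/padded to `n_env`) of
#'   per-covariate effect sizes on log taxon weights (default all 0).
#' @param n_env Number of environmental covariates generated (default 3).
#' @param lat_range,lon_range Coordinate box (defaults span a ~300 km
#'   coastal strip).
#' @param seed Integer seed; same seed, byte-identical dataset.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 10, n_taxa = 2000,
                             reads_per_sample = 5500, depth_sdlog = 0.2,
                             abundance_sdlog = 2, occupancy = 0.5,
                             segregation = 0, n_functional_groups = 100,
                             distance_decay = 0, spatial_sd = 1,
                             env_effects = numeric(0), n_env = 3,
                             lat_range = c(43, 46.3),
                             lon_range = c(-124.3, -123.8), seed = NULL) {
  if (n_samples < 2 || n_taxa < 2) stop2("need >= 2 samples and >= 2 taxa")
  if (reads_per_sample < 1) stop2("reads_per_sample must be positive")
  if (abs(segregation) > 1) stop2("segregation must lie in [-1, 1]")
  if (occupancy <= 0 || occupancy > 1) stop2("occupancy must be in (0, 1]")
  if (n_functional_groups > n_taxa)
    stop2("more functional groups than taxa is infeasible")
  beta <- rep_len(c(env_effects, rep(0, n_env)), n_env)
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 reads_per_sample = reads_per_sample, depth_sdlog = depth_sdlog,
                 abundance_sdlog = abundance_sdlog, occupancy = occupancy,
                 segregation = segregation,
                 n_functional_groups = n_functional_groups,
                 distance_decay = distance_decay, spatial_sd = spatial_sd,
                 env_effects = beta, n_env = n_env,
                 lat_range = lat_range, lon_range = lon_range, seed = seed),
            class = "generator_config")
}

# balanced random taxonomy: genera indexed in a fixed 2x4x3x3x3 tree;
# ~5% of taxa are truncated at a random rank (unclassified below it)
make_taxonomy <- function(taxon_ids) {
  n <- length(taxon_ids)
  sizes <- c(domain = 2, phylum = 4, class = 3, order = 3, family = 3, genus = 3)
  idx <- matrix(0L, n, 6)
  idx[, 1] <- sample.int(sizes[1], n, replace = TRUE)
  for (k in 2:6) idx[, k] <- sample.int(sizes[k], n, replace = TRUE)
  labels <- c("D", "P", "C", "O", "F", "G")
  lin <- matrix(NA_character_, n, 6, dimnames = list(taxon_ids, TAX_RANKS))
  path <- rep("", n)
  for (k in 1:6) {
    path <- paste0(path, labels[k], idx[, k])
    lin[, k] <- path
    path <- paste0(path, ".")
  }
  trunc <- runif(n) < 0.05
  if (any(trunc)) {
    at <- sample.int(6, sum(trunc), replace = TRUE)
    for (w in which(trunc)) {
      k <- at[match(w, which(trunc))]
      if (k < 6) lin[w, (k + 1):6] <- NA_character_
    }
  }
  taxonomy_map(as.data.frame(lin, stringsAsFactors = FALSE))
}

#' Generate a synthetic study-shaped dataset
#'
#' Taxa receive lognormal base abundances and a functional-group label.
#' Group abundance budgets (the sum of member base abundances) are fixed
#' across samples, so functional structure is stable by construction; all
#' variation acts on the within-group shares: a per-taxon-per-sample
#' Bernoulli detection mask (sparsity), a winner-takes-most competitive
#' exclusion within each group when `segregation > 0` (or a shared group
#' boost when < 0), a spatially correlated lognormal field with correlation
#' `exp(-lambda d)` between samples, and linear environmental effects with
#' per-taxon sensitivities. Reads are then drawn multinomially per sample at
#' lognormally varying depths.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `synthetic_dataset`: list with `table`
#'   (counts [community_table()]), `taxonomy` ([taxonomy_map()]),
#'   `coordinates` (data.frame sample_id/latitude_deg/longitude_deg),
#'   `environment` (samples x covariates data.frame), `functional`
#'   ([functional_profile()] summed per group), `taxon_groups` (named
#'   group labels per taxon) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples; M <- cfg$n_taxa
    taxa <- sprintf("taxon_%04d", seq_len(M))
    samples <- sprintf("sample_%02d", seq_len(n))
    grp <- sprintf("group_%03d", (seq_len(M) - 1L) %% cfg$n_functional_groups + 1L)
    names(grp) <- taxa

    a <- rlnorm(M, 0, cfg$abundance_sdlog)
    coords <- data.frame(
      sample_id = samples,
      latitude_deg = runif(n, cfg$lat_range[1], cfg$lat_range[2]),
      longitude_deg = runif(n, cfg$lon_range[1], cfg$lon_range[2]),
      row.names = samples, stringsAsFactors = FALSE)

    logw <- matrix(log(a), M, n) # taxa x samples, start from base abundance
    if (cfg$distance_decay > 0) {
      D <- geographic_distances(coords)
      K <- exp(-cfg$distance_decay * D)
      L <- chol(K + diag(1e-10, n))
      field <- matrix(rnorm(M * n), M, n) %*% L # rows ~ N(0, K)
      logw <- logw + cfg$spatial_sd * field
    }
    env <- matrix(rnorm(cfg$n_env * n), n, cfg$n_env,
                  dimnames = list(samples, sprintf("env_%d", seq_len(cfg$n_env))))
    if (any(cfg$env_effects != 0)) {
      u <- matrix(rnorm(M * cfg$n_env), M, cfg$n_env) # taxon sensitivities
      logw <- logw + u %*% (t(env) * cfg$env_effects)
    }
    w <- exp(logw)
    mask <- matrix(runif(M * n), M, n) < cfg$occupancy

    s <- cfg$segregation
    if (s > 0) {
      # competitive exclusion: each group carries a stable guild of two
      # dominant contenders; per sample one contender wins the group and
      # every other member is suppressed by (1 - s). Winners escape the
      # detection mask (dominants are reliably sampled), so contenders
      # alternate at intermediate occupancy and their mutual exclusion is
      # visible to marginal-preserving nulls.
      for (g in unique(grp)) {
        rows <- which(grp == g)
        if (length(rows) < 2L) next
        contenders <- sample(rows, 2L)
        win <- contenders[sample.int(2L, n, replace = TRUE)]
        keepw <- w[cbind(win, seq_len(n))]
        w[rows, ] <- w[rows, ] * (1 - s)
        w[cbind(win, seq_len(n))] <- keepw
        mask[cbind(win, seq_len(n))] <- TRUE
      }
    } else if (s < 0) {
      for (g in unique(grp)) {
        rows <- which(grp == g)
        boost <- runif(n) < 0.5
        w[rows, !boost] <- w[rows, !boost] * (1 + s) # s < 0: damp half the samples
      }
    }
    w <- w * mask

    # fixed group budgets: shares renormalized within group, per sample
    budget <- rowsum(a, grp)[, 1]
    gsum <- rowsum(w, grp) # groups x samples
    scale <- budget[rownames(gsum)] / ifelse(gsum == 0, 1, gsum)
    w <- w * scale[match(grp, rownames(gsum)), ]

    depths <- pmax(1L, as.integer(round(rlnorm(
      n, log(cfg$reads_per_sample) - cfg$depth_sdlog^2 / 2, cfg$depth_sdlog))))
    counts <- matrix(0L, M, n, dimnames = list(taxa, samples))
    for (j in seq_len(n)) {
      p <- w[, j]
      if (sum(p) == 0) p <- rep(1, M)
      counts[, j] <- rmultinom(1L, depths[j], p)[, 1L]
    }
    tab <- community_table(counts, "counts")
    fp <- functional_profile(as.matrix(
      rowsum(to_proportions(tab)$values, grp)))
    structure(list(table = tab, taxonomy = make_taxonomy(taxa),
                   coordinates = coords, environment = as.data.frame(env),
                   functional = fp, taxon_groups = grp, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d taxa x %d samples, %d reads total, %d functional groups\n",
              nrow(x$table$values), ncol(x$table$values), sum(x$table$values),
              length(unique(x$taxon_groups))))
  invisible(x)
}

#' Write / read a synthetic dataset as plain TSV + JSON
#'
#' Emits `table.tsv` (counts), `taxonomy.tsv`, `metadata.tsv` (sample ID,
#' coordinates, environmental covariates), `gene_groups.tsv` (functional
#' profile), `taxon_groups.tsv` and `params.json` (the generating
#' configuration, including the seed).
#'
#' @param d A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a `synthetic_dataset`-shaped list (read),
#'   without the unexportable RNG-dependent internals.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community_table(d$table, file.path(dir, "table.tsv"))
  write_taxonomy_map(d$taxonomy, file.path(dir, "taxonomy.tsv"))
  meta <- cbind(d$coordinates, d$environment)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fp <- data.frame(group_id = rownames(d$functional$values),
                   d$functional$values, check.names = FALSE)
  write.table(fp, file.path(dir, "gene_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon_id = names(d$taxon_groups),
                         group = unname(d$taxon_groups)),
              file.path(dir, "taxon_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(d$config), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  tab <- read_community_table(file.path(dir, "table.tsv"))
  tax <- read_taxonomy_map(file.path(dir, "taxonomy.tsv"))
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  gg <- read.table(file.path(dir, "gene_groups.tsv"), sep = "\t",
                   header = TRUE, check.names = FALSE)
  fpm <- as.matrix(gg[, -1L, drop = FALSE]); rownames(fpm) <- gg[[1L]]
  tg <- read.table(file.path(dir, "taxon_groups.tsv"), sep = "\t", header = TRUE)
  cfg <- jsonlite::fromJSON(file.path(dir, "params.json"))
  list(table = tab, taxonomy = tax,
       coordinates = meta[, c("sample_id", "latitude_deg", "longitude_deg")],
       environment = meta[, setdiff(colnames(meta),
                                    c("sample_id", "latitude_deg", "longitude_deg")),
                          drop = FALSE],
       functional = functional_profile(fpm),
       taxon_groups = setNames(tg$group, tg$taxon_id),
       config = cfg)
}
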