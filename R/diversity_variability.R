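#' Coefficient-of-variation profile of taxa or gene groups
#'
#' For each row (taxon or gene group) of a proportions table: the mean
#' proportion across samples and the coefficient of variation
#' CV = sd / mean. Contrasting taxon CVs with gene-group CVs at comparable
#' mean proportions is the standard way to demonstrate functional redundancy
#' (stable function, variable taxonomy). Rows with zero mean are excluded
#' and counted in the `"n_zero_mean"` attribute.
#'
#' @param t A proportions-mode [community_table()] or [functional_profile()]
#'   (counts tables are converted to proportions) with >= 2 samples.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return A data.frame with columns `id`, `mean`, `cv`, ordered as the
#'   input rows; attribute `n_zero_mean`.
#' @export
cv_profile <- function(t, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  v <- if (inherits(t, "functional_profile")) t$values
       else if (inherits(t, "community_table")) to_proportions(t)$values
       else stop2("need a community_table or functional_profile")
  n <- ncol(v)
  if (n < 2L) stop2("need at least 2 samples")
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  keep <- mu > 0
  out <- data.frame(id = rownames(v)[keep], mean = mu[keep],
                    cv = s[keep] / mu[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_zero_mean") <- sum(!keep)
  out
}

#' Core-biome curve: expected number of taxa shared by n samples
#'
#' For each n in 1..N, the average number of taxa present in all of n
#' randomly chosen samples. With occupancies \eqn{k_i} this expectation has
#' the closed hypergeometric form
#' \eqn{\sum_i \binom{k_i}{n} / \binom{N}{n}}; the Monte-Carlo `subsample`
#' method averages over random sample subsets instead and serves as a
#' cross-check. The curve is non-increasing: its value at n = 1 is the mean
#' per-sample richness and at n = N the count of taxa found in every sample.
#'
#' @param pa A `presence_absence` object.
#' @param method `"exact"` (default) or `"subsample"`.
#' @param n_draws Random subsets per n for `"subsample"` (default 1000).
#' @param seed Integer seed (subsample method).
#' @return A data.frame with columns `n` and `shared`.
#' @export
core_biome_curve <- function(pa, method = c("exact", "subsample"),
                             n_draws = 1000, seed = NULL) {
  stopifnot(inherits(pa, "presence_absence"))
  method <- match.arg(method)
  N <- ncol(pa$values)
  k <- pa$occupancy
  if (method == "exact") {
    shared <- vapply(seq_len(N), function(n)
      sum(exp(lchoose(k, n) - lchoose(N, n))), numeric(1))
  } else {
    if (n_draws < 1) stop2("n_draws must be >= 1")
    shared <- with_seed(seed, vapply(seq_len(N), function(n) {
      mean(vapply(seq_len(n_draws), function(d) {
        cols <- sample.int(N, n)
        sum(rowSums(pa$values[, cols, drop = FALSE]) == n)
      }, numeric(1)))
    }, numeric(1)))
  }
  data.frame(n = seq_len(N), shared = shared)
}

#' Collector's (rarefaction) curve of one sample
#'
#' Expected number of taxa discovered when `d` reads are drawn without
#' replacement from a sample with taxon counts \eqn{c_i} and total T:
#' \eqn{\sum_i [1 - \binom{T - c_i}{d} / \binom{T}{d}]} (exact
#' hypergeometric rarefaction); the `subsample` method averages observed
#' richness over random without-replacement draws.
#'
#' @param t A counts-mode [community_table()].
#' @param sample_id Which sample (column) to rarefy.
#' @param depths Read depths at which to evaluate (each <= sample total).
#' @param method `"exact"` (default) or `"subsample"`.
#' @param n_draws Draws per depth for `"subsample"` (default 1000).
#' @param seed Integer seed (subsample method).
#' @return A data.frame with columns `depth` and `richness`.
#' @export
collectors_curve <- function(t, sample_id, depths,
                             method = c("exact", "subsample"),
                             n_draws = 1000, seed = NULL) {
  stopifnot(inherits(t, "community_table"))
  method <- match.arg(method)
  if (t$mode != "counts") stop2("collector's curves need counts")
  if (!sample_id %in% colnames(t$values)) stop2("unknown sample: ", sample_id)
  cts <- t$values[, sample_id]
  cts <- cts[cts > 0]
  total <- sum(cts)
  if (any(depths > total)) stop2("depth exceeds sample total (", total, ")")
  if (any(depths < 1)) stop2("depths must be >= 1")
  if (method == "exact") {
    rich <- vapply(depths, function(d)
      sum(1 - exp(lchoose(total - cts, d) - lchoose(total, d))), numeric(1))
  } else {
    if (n_draws < 1) stop2("n_draws must be >= 1")
    reads <- rep.int(seq_along(cts), cts)
    rich <- with_seed(seed, vapply(depths, function(d) {
      mean(vapply(seq_len(n_draws), function(k)
        length(unique(sample(reads, d))), numeric(1)))
    }, numeric(1)))
  }
  data.frame(depth = depths, richness = rich)
}
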