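#' Run the full community-assembly analysis workflow
#'
#' Wires the package's stages together the way a distance-decay /
#' null-model survey is analysed: collapse the taxa table to each requested
#' taxonomic level; compute pairwise dissimilarities per metric; Mantel test
#' of each dissimilarity matrix against geographic distance; stepwise
#' regression of each dissimilarity matrix on environmental
#' absolute-difference matrices plus geographic distance (with
#' leave-one-sample-out cross-validated R2 when predictors are selected);
#' CC-vs-SIM9 and MA-vs-IT null-model tests per level; CV profiles per level
#' and for the functional profile; and the core-biome curve at the finest
#' level. Bonferroni-adjusted thresholds are reported for the Mantel family
#' (levels x metrics) and the null-test family (levels).
#'
#' @param data A `synthetic_dataset` (see [generate_dataset()]) or a list of
#'   the same shape (`table`, `taxonomy`, `coordinates`, `environment`,
#'   optionally `functional`), e.g. from [read_dataset()].
#' @param levels Taxonomic levels to analyse; default the 7 levels
#'   `"taxon"` (no collapsing) through `"domain"`.
#' @param metrics Dissimilarity metrics (default all three).
#' @param n_perm Mantel/regression permutations (default 1000).
#' @param n_null Null-model datasets per test (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed; every stage draws from a sub-seed derived from
#'   it, so reruns are byte-identical.
#' @param out_dir Optional directory: writes `summary.json`, `mantel.tsv`,
#'   `mrm.tsv`, `nullmodels.tsv`, `cv_<level>.tsv`, `corebiome.tsv`.
#' @return A list (class `assembly_summary`) with elements `mantel`, `mrm`,
#'   `null_tests` (data.frames), `cv` (per-level list + `functional`),
#'   `core_biome`, `bonferroni`, `parameters`.
#' @export
run_full_analysis <- function(data,
                              levels = c("taxon", "genus", "family", "order",
                                         "class", "phylum", "domain"),
                              metrics = c("bray_curtis", "hellinger", "jaccard"),
                              n_perm = 1000, n_null = 1000, alpha = 0.05,
                              seed = 1, out_dir = NULL) {
  stopifnot(all(levels %in% c("taxon", TAX_RANKS)))
  tab <- data$table
  stopifnot(inherits(tab, "community_table"))
  sub_seed <- function(k) as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)

  geo <- geographic_distances(data$coordinates)
  env <- data$environment
  candidates <- c(
    lapply(setNames(colnames(env), colnames(env)), function(v)
      abs_diff_matrix(setNames(env[[v]], rownames(env)))),
    list(geographic_km = geo))

  tables <- lapply(setNames(levels, levels), function(lv) {
    t <- collapse_to_level(tab, data$taxonomy, lv)
    keep <- rowSums(t$values) > 0
    community_table(t$values[keep, , drop = FALSE], t$mode)
  })

  k <- 0L
  mantel_rows <- list(); mrm_rows <- list(); null_rows <- list()
  for (lv in levels) {
    t <- tables[[lv]]
    for (metric in metrics) {
      k <- k + 1L
      d <- pairwise_dissimilarity(t, metric)
      mt <- mantel_test(d, geo, n_perm = n_perm, seed = sub_seed(k))
      mantel_rows[[length(mantel_rows) + 1L]] <- data.frame(
        level = lv, metric = metric, rho = mt$rho, p = mt$p,
        n_perm = n_perm, stringsAsFactors = FALSE)
      k <- k + 1L
      fit <- stepwise_mrm(d, candidates, alpha = alpha, n_perm = n_perm,
                          seed = sub_seed(k))
      if (length(fit$selected))
        fit$r2_cv <- loso_cv_r2(d, fit, candidates)
      mrm_rows[[length(mrm_rows) + 1L]] <- data.frame(
        level = lv, metric = metric,
        selected = paste(fit$selected, collapse = ","),
        n_selected = length(fit$selected), r2 = fit$r2,
        r2_cv = fit$r2_cv, stringsAsFactors = FALSE)
    }
    # degenerate at coarse levels (e.g. all taxa present in every sample,
    # or a frozen marginal pattern) is expected: record NA, keep going
    k <- k + 1L
    cc <- tryCatch(null_test(to_presence_absence(t), "cc", n_null = n_null,
                             seed = sub_seed(k)),
                   error = function(e) list(score = "cc", null = "sim9"))
    k <- k + 1L
    ma <- tryCatch(null_test(t, "ma", n_null = n_null, seed = sub_seed(k)),
                   error = function(e) list(score = "ma", null = "it"))
    na_or <- function(x) if (is.null(x)) NA_real_ else x
    for (r in list(cc, ma))
      null_rows[[length(null_rows) + 1L]] <- data.frame(
        level = lv, score = r$score, null = r$null,
        observed = na_or(r$observed), null_mean = na_or(r$null_mean),
        null_sd = na_or(r$null_sd), p_low = na_or(r$p_low),
        p_high = na_or(r$p_high), n_null = n_null, stringsAsFactors = FALSE)
  }
  mantel_df <- do.call(rbind, mantel_rows)
  mrm_df <- do.call(rbind, mrm_rows)
  null_df <- do.call(rbind, null_rows)

  bonf <- list(
    mantel_threshold = bonferroni_threshold(alpha, nrow(mantel_df)),
    null_threshold = bonferroni_threshold(alpha, length(levels)),
    mrm_threshold = bonferroni_threshold(
      alpha, length(metrics) * length(levels) * length(candidates)))
  mantel_df$significant_bonferroni <- mantel_df$p < bonf$mantel_threshold
  null_df$significant_low_bonferroni <-
    !is.na(null_df$p_low) & null_df$p_low < bonf$null_threshold

  cv <- lapply(tables, cv_profile)
  if (!is.null(data$functional)) cv$functional <- cv_profile(data$functional)
  core <- core_biome_curve(to_presence_absence(tables[[1L]]))

  out <- structure(list(
    mantel = mantel_df, mrm = mrm_df, null_tests = null_df, cv = cv,
    core_biome = core, bonferroni = bonf,
    parameters = list(levels = levels, metrics = metrics, n_perm = n_perm,
                      n_null = n_null, alpha = alpha, seed = seed)),
    class = "assembly_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(mantel_df, "mantel.tsv"); wt(mrm_df, "mrm.tsv")
    wt(null_df, "nullmodels.tsv"); wt(core, "corebiome.tsv")
    for (nm in names(cv)) wt(cv[[nm]], paste0("cv_", nm, ".tsv"))
    jsonlite::write_json(
      list(mantel = mantel_df, mrm = mrm_df, null_tests = null_df,
           core_biome = core, bonferroni = bonf, parameters = out$parameters),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Community-assembly analysis summary\n")
  cat(sprintf("  %d Mantel tests (levels x metrics), Bonferroni threshold %.4g\n",
              nrow(x$mantel), x$bonferroni$mantel_threshold))
  cat(sprintf("  Mantel p < 0.05 (raw): %d; after Bonferroni: %d\n",
              sum(x$mantel$p < 0.05), sum(x$mantel$significant_bonferroni)))
  cat(sprintf("  regressions selecting >= 1 predictor: %d of %d\n",
              sum(x$mrm$n_selected > 0), nrow(x$mrm)))
  cat(sprintf("  null tests with significantly low score (raw p_low < %.2f): %d of %d\n",
              x$parameters$alpha,
              sum(x$null_tests$p_low < x$parameters$alpha, na.rm = TRUE),
              nrow(x$null_tests)))
  invisible(x)
}
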