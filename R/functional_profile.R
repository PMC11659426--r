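#' Gene-group-by-sample functional profiles
#'
#' A `functional_profile` is a proportions matrix over functional gene groups
#' (e.g. KEGG A/B/C categories, EC numbers, or custom groups): every column
#' sums to 1 within 1e-9 (all-zero columns permitted).
#'
#' @param values Numeric matrix, rows = groups, columns = samples, labelled.
#' @return An object of class `functional_profile`.
#' @export
functional_profile <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop2("functional profile needs a labelled numeric matrix")
  if (any(values < 0) || anyNA(values)) stop2("profile entries must be nonnegative")
  cs <- colSums(values)
  if (any(abs(cs[cs > 0] - 1) > 1e-9))
    stop2("functional-profile columns must sum to 1 (within 1e-9)")
  structure(list(values = values), class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("functional_profile: %d gene groups x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Aggregate contig coverages into gene-group proportions
#'
#' Implements the gene-centric aggregation arithmetic: per sample, contig
#' coverages are normalized to contig proportions; each protein-coding gene
#' (PCG) inherits the proportion of its host contig; PCG values are
#' renormalized to sum 1 per sample; each group's proportion is the sum of its
#' PCGs' proportions; finally group proportions are renormalized to 1 over the
#' retained groups. An exclusion list (e.g. non-functional catch-all KEGG
#' categories) can be applied either before or after that final
#' renormalization.
#'
#' @param contig_coverage Nonnegative matrix, rows = contigs (labelled),
#'   columns = samples.
#' @param pcg_to_contig Named character vector: PCG ID -> contig ID (each PCG
#'   maps to exactly one contig).
#' @param pcg_to_group Data.frame with columns `pcg` and `group`; a PCG may
#'   map to zero or more groups.
#' @param exclude_groups Character vector of group IDs to drop.
#' @param exclude_before_renorm If `TRUE` (default) excluded groups are
#'   removed before the final renormalization so the retained groups sum to 1;
#'   if `FALSE` they are removed after it.
#' @return A [functional_profile()] over the retained groups.
#' @export
aggregate_functional_profile <- function(contig_coverage, pcg_to_contig,
                                         pcg_to_group,
                                         exclude_groups = character(0),
                                         exclude_before_renorm = TRUE) {
  if (!is.matrix(contig_coverage)) contig_coverage <- as.matrix(contig_coverage)
  if (is.null(rownames(contig_coverage)))
    stop2("contig_coverage needs contig rownames")
  bad <- setdiff(unname(pcg_to_contig), rownames(contig_coverage))
  if (length(bad))
    stop2("PCGs reference missing contigs: ", paste(utils::head(bad, 5), collapse = ", "))
  if (!all(c("pcg", "group") %in% colnames(pcg_to_group)))
    stop2("pcg_to_group needs columns 'pcg' and 'group'")
  if (!all(pcg_to_group$pcg %in% names(pcg_to_contig)))
    stop2("pcg_to_group references unknown PCGs")

  cs <- colSums(contig_coverage)
  contig_prop <- sweep(contig_coverage, 2L, ifelse(cs == 0, 1, cs), "/")
  # PCG inherits host-contig proportion, then renormalize over PCGs
  pcg_prop <- contig_prop[pcg_to_contig, , drop = FALSE]
  rownames(pcg_prop) <- names(pcg_to_contig)
  ps <- colSums(pcg_prop)
  pcg_prop <- sweep(pcg_prop, 2L, ifelse(ps == 0, 1, ps), "/")
  # group proportion = sum of member PCG proportions
  grp <- rowsum(pcg_prop[pcg_to_group$pcg, , drop = FALSE],
                group = pcg_to_group$group, reorder = FALSE)
  grp <- as.matrix(grp)
  renorm <- function(m) {
    s <- colSums(m)
    sweep(m, 2L, ifelse(s == 0, 1, s), "/")
  }
  if (exclude_before_renorm) {
    grp <- grp[setdiff(rownames(grp), exclude_groups), , drop = FALSE]
    grp <- renorm(grp)
  } else {
    grp <- renorm(grp)
    grp <- grp[setdiff(rownames(grp), exclude_groups), , drop = FALSE]
    grp <- renorm(grp) # keep the column-sum contract after dropping rows
  }
  functional_profile(grp)
}

#' Read / write sample metadata
#'
#' Sample metadata is a TSV with columns `sample_id`, `latitude_deg`,
#' `longitude_deg`, then numeric environmental variables.
#'
#' @param path TSV path.
#' @return A data.frame with rownames = sample IDs.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", comment.char = "")
  need <- c("sample_id", "latitude_deg", "longitude_deg")
  if (!all(need %in% colnames(df)))
    stop2("metadata needs columns: ", paste(need, collapse = ", "))
  rownames(df) <- df$sample_id
  df
}
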