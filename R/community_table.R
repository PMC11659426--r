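#' Taxa-by-sample community tables
#'
#' A `community_table` holds a nonnegative taxa-by-sample matrix together with
#' a mode flag stating whether entries are read counts or per-sample relative
#' abundances (proportions). Rows are taxa, columns are samples; both carry
#' unique labels. In proportions mode every column with any nonzero entry sums
#' to 1 (within 1e-9); all-zero columns are permitted (e.g. a sample in which
#' nothing was detected after filtering).
#'
#' @param values Numeric matrix, rows = taxa, columns = samples, with unique
#'   `rownames` and `colnames`. No negative or missing entries.
#' @param mode Either `"counts"` or `"proportions"`.
#' @return An object of class `community_table`: a list with elements
#'   `values` (the labelled matrix) and `mode`.
#' @examples
#' m <- matrix(c(2, 2, 4, 0, 1, 7), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' ct <- community_table(m, "counts")
#' to_proportions(ct)$values
#' @export
community_table <- function(values, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("`values` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate taxon IDs: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample IDs: ",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop2("missing values in community table")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop2(sprintf("negative entry at taxon '%s', sample '%s'",
                  rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (mode == "proportions") {
    cs <- colSums(values)
    nz <- cs > 0
    if (any(abs(cs[nz] - 1) > 1e-9))
      stop2("proportions-mode columns must sum to 1 (within 1e-9)")
  }
  structure(list(values = values, mode = mode), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("samples:", paste(utils::head(colnames(x$values), 8L), collapse = " "),
      if (ncol(x$values) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$values)

#' Read a taxa-by-sample table from TSV (or BIOM-style JSON)
#'
#' The TSV dialect is UTF-8, tab-delimited, `.` decimal, no quoting: first
#' row holds sample IDs (the first header cell is ignored), first column
#' holds taxon IDs, the body is numeric. The BIOM-style reader accepts the
#' dense JSON layout with `rows`/`columns`/`data` keys.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @return A counts-mode [community_table()]; input row/column order is kept.
#' @export
read_community_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "biom-json") {
    b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    taxa <- vapply(b$rows, function(r) r$id, character(1))
    samples <- vapply(b$columns, function(r) r$id, character(1))
    m <- matrix(0, length(taxa), length(samples), dimnames = list(taxa, samples))
    if (identical(b$matrix_type, "dense")) {
      for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
    } else { # sparse triplets, 0-based
      for (tr in b$data) m[tr[[1]] + 1L, tr[[2]] + 1L] <- tr[[3]]
    }
    return(community_table(m, "counts"))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1L]
  raw <- read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                    check.names = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
  taxa <- raw[[1L]]
  if (anyDuplicated(taxa))
    stop2("duplicate taxon IDs in ", path, ": ",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop2("duplicate sample IDs in ", path)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop2(sprintf("non-numeric cell at row '%s', column '%s'",
                  taxa[bad[1L]], samples[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop2(sprintf("negative cell at row '%s', column '%s'",
                  taxa[bad[1L]], samples[bad[2L]]))
  }
  dimnames(num) <- list(taxa, samples)
  community_table(num, "counts")
}

#' Write a community table as TSV
#'
#' @param t A [community_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(t, path) {
  stopifnot(inherits(t, "community_table"))
  df <- data.frame(taxon_id = rownames(t$values), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a table to per-sample proportions
#'
#' Each column is divided by its total so that nonzero columns sum to 1;
#' all-zero columns are left untouched and reported via the
#' `"zero_columns"` attribute. Idempotent.
#'
#' @param t A [community_table()].
#' @return A proportions-mode [community_table()] with attribute
#'   `zero_columns` (character vector of all-zero sample IDs).
#' @export
to_proportions <- function(t) {
  stopifnot(inherits(t, "community_table"))
  cs <- colSums(t$values)
  zero <- colnames(t$values)[cs == 0]
  denom <- ifelse(cs == 0, 1, cs)
  out <- community_table(sweep(t$values, 2L, denom, "/"), "proportions")
  attr(out, "zero_columns") <- zero
  out
}

#' Binary presence/absence view of a community table
#'
#' Entry (i, j) is 1 iff taxon i reaches `threshold` in sample j. The derived
#' per-taxon occupancies (number of samples containing each taxon) are the
#' row sums.
#'
#' @param t A [community_table()].
#' @param threshold Detection floor; default 1 count. For proportions-mode
#'   tables any strictly positive threshold works (default then
#'   `.Machine$double.xmin`, i.e. "present iff nonzero").
#' @return An object of class `presence_absence`: a list with `values`
#'   (binary integer matrix, same labels) and `occupancy` (row sums).
#' @export
to_presence_absence <- function(t, threshold = NULL) {
  stopifnot(inherits(t, "community_table"))
  if (is.null(threshold))
    threshold <- if (t$mode == "counts") 1 else .Machine$double.xmin
  if (t$mode == "proportions" && threshold <= 0)
    stop2("proportions mode needs a strictly positive threshold")
  m <- (t$values >= threshold) * 1L
  storage.mode(m) <- "integer"
  presence_absence(m)
}

#' @rdname to_presence_absence
#' @param values Binary integer matrix with taxon rownames / sample colnames.
#' @export
presence_absence <- function(values) {
  if (!is.matrix(values) || !all(values %in% c(0L, 1L)))
    stop2("presence/absence values must be a binary matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("presence/absence matrix must be labelled")
  storage.mode(values) <- "integer"
  structure(list(values = values, occupancy = rowSums(values)),
            class = "presence_absence")
}

#' @export
print.presence_absence <- function(x, ...) {
  cat(sprintf("presence_absence: %d taxa x %d samples, fill %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Taxonomy maps and rank-level collapsing
#'
#' A taxonomy map assigns each taxon an ordered lineage
#' (domain, phylum, class, order, family, genus); `NA` marks ranks at which a
#' taxon is unclassified. `collapse_to_level()` sums rows of a community table
#' that share the same lineage prefix up to the requested rank. Taxa
#' unclassified at that rank are pooled by their deepest classified prefix
#' into `"unclassified-<prefix>"` rows, so per-sample totals are conserved
#' exactly.
#'
#' @param lineages A data.frame or matrix with rownames = taxon IDs and
#'   columns `domain`...`genus` (character, `NA` = unclassified).
#' @return `taxonomy_map()`: an object of class `taxonomy_map`.
#' @export
taxonomy_map <- function(lineages) {
  lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
  if (!all(TAX_RANKS %in% colnames(lineages)))
    stop2("taxonomy must have columns: ", paste(TAX_RANKS, collapse = ", "))
  if (is.null(rownames(lineages))) stop2("taxonomy needs taxon-ID rownames")
  lineages <- lineages[, TAX_RANKS]
  structure(list(lineages = lineages), class = "taxonomy_map")
}

#' @rdname taxonomy_map
#' @param path TSV with columns `taxon_id`, `domain`, ..., `genus`; empty
#'   cells mean unclassified.
#' @export
read_taxonomy_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "",
                   na.strings = c("", "NA"))
  rownames(df) <- df$taxon_id
  taxonomy_map(df[, setdiff(colnames(df), "taxon_id"), drop = FALSE])
}

#' @rdname taxonomy_map
#' @param tax A `taxonomy_map`.
#' @export
write_taxonomy_map <- function(tax, path) {
  df <- data.frame(taxon_id = rownames(tax$lineages), tax$lineages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname taxonomy_map
#' @param t A [community_table()] whose taxa all appear in `tax`.
#' @param level One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, or `"taxon"` (identity, no collapsing).
#' @export
collapse_to_level <- function(t, tax, level) {
  stopifnot(inherits(t, "community_table"), inherits(tax, "taxonomy_map"))
  if (identical(level, "taxon")) return(t)
  if (!level %in% TAX_RANKS) stop2("unknown rank: ", level)
  ids <- rownames(t$values)
  missing <- setdiff(ids, rownames(tax$lineages))
  if (length(missing))
    stop2("taxa without taxonomy entry: ", paste(utils::head(missing, 5), collapse = ", "))
  k <- match(level, TAX_RANKS)
  lin <- as.matrix(tax$lineages[ids, seq_len(k), drop = FALSE])
  key <- apply(lin, 1L, function(v) {
    if (!anyNA(v)) return(paste(v, collapse = ";"))
    depth <- which(is.na(v))[1L] - 1L
    prefix <- if (depth == 0L) "root" else paste(v[seq_len(depth)], collapse = ";")
    paste0("unclassified-", prefix)
  })
  agg <- rowsum(t$values, group = key, reorder = FALSE)
  community_table(as.matrix(agg), t$mode)
}
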