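#' Pairwise community dissimilarities
#'
#' Abundance-aware dissimilarities between samples, computed on per-sample
#' relative abundances over the union of taxa:
#' \itemize{
#'   \item Bray-Curtis: \eqn{\sum_i |p_i - q_i| / \sum_i (p_i + q_i)};
#'   \item Hellinger: \eqn{\sqrt{\sum_i (\sqrt{p_i} - \sqrt{q_i})^2}}
#'     (range \eqn{[0, \sqrt 2]});
#'   \item Jaccard: the quantitative Ruzicka form
#'     \eqn{1 - \sum_i \min(p_i, q_i) / \sum_i \max(p_i, q_i)}, equal to
#'     \eqn{2 BC / (1 + BC)}, which reduces to the classical Jaccard index on
#'     binary data.
#' }
#' Bray-Curtis and Jaccard are delegated to [vegan::vegdist()]; Hellinger is
#' the Euclidean distance between square-root-transformed proportion vectors.
#'
#' @param t A [community_table()] with at least 2 samples (converted to
#'   proportions internally).
#' @param metric `"bray_curtis"`, `"hellinger"` or `"jaccard"`.
#' @return A labelled symmetric matrix (samples x samples) with zero diagonal.
#' @export
pairwise_dissimilarity <- function(t, metric = c("bray_curtis", "hellinger", "jaccard")) {
  stopifnot(inherits(t, "community_table"))
  metric <- match.arg(metric)
  if (ncol(t$values) < 2L) stop2("need at least 2 samples")
  p <- t(to_proportions(t)$values) # samples x taxa
  d <- switch(metric,
    bray_curtis = vegan::vegdist(p, method = "bray"),
    jaccard     = vegan::vegdist(p, method = "jaccard"),
    hellinger   = dist(sqrt(p), method = "euclidean"))
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

#' Great-circle distances between sampling locations
#'
#' Haversine distances on a sphere of radius 6371.0 km.
#'
#' @param coords Data.frame/matrix with rownames = sample IDs and columns
#'   `latitude_deg` and `longitude_deg` (degrees).
#' @return Labelled symmetric matrix of distances in km, zero diagonal.
#' @export
geographic_distances <- function(coords) {
  coords <- as.data.frame(coords)
  if (!all(c("latitude_deg", "longitude_deg") %in% colnames(coords)))
    stop2("coords needs columns latitude_deg and longitude_deg")
  if (is.null(rownames(coords))) stop2("coords needs sample-ID rownames")
  lat <- coords$latitude_deg; lon <- coords$longitude_deg
  if (any(lat < -90 | lat > 90)) stop2("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop2("longitude out of [-180, 180]")
  n <- nrow(coords)
  if (n < 2L) stop2("need at least 2 coordinates")
  ids <- rownames(coords)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  pts <- cbind(lon, lat)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[j, , drop = FALSE], r = 6371000) / 1000
    m[i, j] <- d
    m[j, i] <- d
  }
  m
}

#' Pairwise absolute differences of a per-sample variable
#'
#' Builds the predictor matrices used in regression on distance matrices:
#' entry (a, b) is `|v_a - v_b|`. Missing values give `NA` rows/columns and
#' are reported via the `"n_missing"` attribute.
#'
#' @param values Named numeric vector (names = sample IDs).
#' @return Labelled symmetric matrix of absolute differences.
#' @export
abs_diff_matrix <- function(values) {
  if (is.null(names(values))) stop2("values need sample-ID names")
  if (all(is.na(values))) stop2("all values missing")
  m <- abs(outer(values, values, "-"))
  diag(m) <- 0
  attr(m, "n_missing") <- sum(is.na(values))
  m
}

#' Read / write labelled square distance matrices as TSV
#'
#' @param m Labelled symmetric numeric matrix.
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  check_distance_matrix(m)
  m
}

# shared validity contract for distance matrices
check_distance_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop2("not a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop2("row and column labels must match")
  if (max(abs(m - t(m))) > tol) stop2("matrix not symmetric")
  if (any(abs(diag(m)) > tol)) stop2("diagonal must be zero")
  invisible(m)
}
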