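#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of differing nucleotide sites between every pair of aligned
#' sequences, comparing only positions where both sequences carry an
#' unambiguous base (A, C, G or T): gaps and IUPAC ambiguity codes are
#' removed pair by pair (pairwise deletion).
#'
#' @param alignment a named character vector of equal-length aligned
#'   sequences, a character matrix (one row per sequence, one column per
#'   site), or an `ape::DNAbin` matrix/list.
#' @return A symmetric `dist_matrix`-classed matrix (zero diagonal) with
#'   sequence names as labels and attribute `units = "substitution
#'   proportion"`.
#' @export
p_distance_matrix <- function(alignment) {
  M <- .aln_to_matrix(alignment)
  n <- nrow(M)
  labs <- rownames(M)
  ok <- matrix(M %in% c("a", "c", "g", "t"), n, ncol(M))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cmp <- ok[i, ] & ok[j, ]
    if (!any(cmp))
      stopf("no comparable sites between %s and %s: p-distance undefined",
            labs[i], labs[j])
    D[i, j] <- D[j, i] <- mean(M[i, cmp] != M[j, cmp])
  }
  .dist_matrix(D, units = "substitution proportion")
}

.aln_to_matrix <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- as.character(alignment)
  if (is.list(alignment))
    alignment <- vapply(alignment, function(s) paste(s, collapse = ""), character(1))
  if (is.character(alignment) && !is.matrix(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stopf("sequences are not aligned: lengths %s",
            paste(unique(lens), collapse = ", "))
    M <- do.call(rbind, strsplit(tolower(alignment), ""))
    rownames(M) <- names(alignment) %||% paste0("seq", seq_along(alignment))
  } else if (is.matrix(alignment)) {
    M <- tolower(alignment)
    if (is.null(rownames(M))) rownames(M) <- paste0("seq", seq_len(nrow(M)))
  } else stopf("unsupported alignment representation")
  if (nrow(M) < 2L) stopf("need at least two sequences")
  M
}

.dist_matrix <- function(D, units) {
  structure(D, units = units, class = c("dist_matrix", "matrix", "array"))
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances between strain origins, on a spherical Earth of
#' radius 6371 km. Southern latitudes and western longitudes are negative
#' decimal degrees.
#'
#' @param coords data.frame with columns `strain_id`, `lat_dd`, `lon_dd`
#'   (aliases `lat`/`lon` accepted), or a 2-column matrix with rownames.
#' @return symmetric `dist_matrix` in km.
#' @export
geographic_distance_matrix <- function(coords) {
  if (is.matrix(coords)) {
    labs <- rownames(coords) %||% paste0("site", seq_len(nrow(coords)))
    lat <- coords[, 1]; lon <- coords[, 2]
  } else {
    lat <- coords$lat_dd %||% coords$lat
    lon <- coords$lon_dd %||% coords$lon
    labs <- as.character(coords$strain_id %||% seq_along(lat))
  }
  if (is.null(lat) || is.null(lon)) stopf("coordinates need lat/lon columns")
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    stopf("latitudes must lie in [-90, 90] decimal degrees")
  if (any(!is.finite(lon)) || any(lon < -180 | lon > 180))
    stopf("longitudes must lie in [-180, 180] decimal degrees")
  R <- 6371
  phi <- lat * pi / 180; lam <- lon * pi / 180
  n <- length(lat)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    D[i, j] <- D[j, i] <- 2 * R * asin(min(1, sqrt(a)))
  }
  .dist_matrix(D, units = "km")
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries of two labeled distance
#' matrices, with significance from simultaneous row/column permutation of
#' the second matrix. The p-value is one-sided ("greater": positive
#' association) with the add-one correction, hence bounded below by
#' `1/(n_perm + 1)` and deterministic for a given seed.
#'
#' @param d1,d2 symmetric matrices with matching labels in matching order
#'   (from [p_distance_matrix()], [geographic_distance_matrix()], or any
#'   labeled symmetric matrix).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed or `NULL`.
#' @return list with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  if (!is_num1(n_perm) || n_perm < 99) stopf("n_perm must be at least 99")
  n_perm <- as.integer(n_perm)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stopf("distance matrices have different dimensions")
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stopf("distance-matrix labels do not match (same labels, same order required)")
  n <- nrow(d1)
  if (n < 3L) stopf("need at least 3 objects for a Mantel test")
  ut <- which(upper.tri(d1))
  x <- d1[ut]
  r_obs <- stats::cor(x, d2[ut])
  ij <- arrayInd(ut, dim(d1))
  xc <- x - mean(x)
  denom_x <- sqrt(sum(xc^2))
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      v <- d2[cbind(p[ij[, 1]], p[ij[, 2]])]
      vc <- v - mean(v)
      sum(xc * vc) / (denom_x * sqrt(sum(vc^2)))
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p_value = p, n_perm = n_perm)
}
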