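#' Identity-by-state genetic distance matrix
#'
#' `D_ab = 1 - (shared alleles) / (2 m)`, the PLINK-style `1 - IBS`
#' metric; with 0/1/2 dosages the shared-allele count at a marker is
#' `2 - |g_a - g_b|`, so `D` is the scaled Manhattan distance.
#'
#' @param genotypes complete dosage matrix, animals x markers.
#' @return dense symmetric distance matrix, zero diagonal.
#' @export
ibs_distance_matrix <- function(genotypes) {
  if (ncol(genotypes) == 0L) stop("no shared markers")
  if (anyNA(genotypes)) stop("genotypes must be complete")
  D <- as.matrix(stats::dist(genotypes, method = "manhattan")) /
    (2 * ncol(genotypes))
  dimnames(D) <- list(rownames(genotypes), rownames(genotypes))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2` and embeds on the leading non-negative
#' eigenpairs.
#'
#' @param distance_matrix symmetric distance matrix.
#' @param n_dims requested embedding dimension; silently truncated (with
#'   a warning) when fewer positive eigenvalues exist.
#' @return list with `points` (rows = objects), `eig` (all eigenvalues).
#' @export
classical_mds <- function(distance_matrix, n_dims = 2L) {
  stopifnot(n_dims >= 1)
  n <- nrow(distance_matrix)
  fit <- suppressWarnings(
    cmdscale(distance_matrix, k = min(n_dims, n - 1L), eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < n_dims)
    warning("only ", ncol(pts), " positive-eigenvalue dimensions available")
  if (is.null(rownames(pts))) rownames(pts) <- rownames(distance_matrix)
  if (ncol(pts) == 0L)
    pts <- matrix(0, n, 1, dimnames = list(rownames(distance_matrix), NULL))
  list(points = pts, eig = fit$eig)
}

#' Rank donors by MDS distance to a base population
#'
#' Each donor is scored by its Euclidean distance, in the MDS embedding,
#' to the centroid of the base population; the closest
#' `round(fraction * n_donors)` donors are returned, ties broken by id
#' order.
#'
#' @param coords MDS coordinate matrix (rows named by animal id).
#' @param base_ids ids of the base (target) population.
#' @param donor_ids ids of the candidate donors.
#' @param fraction fraction of donors to retain, in (0, 1].
#' @return character vector of selected donor ids, closest first.
#' @export
select_donors <- function(coords, base_ids, donor_ids, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (length(donor_ids) == 0L) stop("empty donor set")
  base_ids <- as.character(base_ids)
  donor_ids <- as.character(donor_ids)
  centroid <- colMeans(coords[base_ids, , drop = FALSE])
  dc <- sweep(coords[donor_ids, , drop = FALSE], 2, centroid)
  d <- sqrt(rowSums(dc^2))
  k <- round(fraction * length(donor_ids))
  donor_ids[order(d, donor_ids)][seq_len(k)]
}

#' Centroid distance between two populations in MDS space
#'
#' Scalar summary used to report how far a screened donor subset sits
#' from the base population.
#'
#' @param coords MDS coordinates.
#' @param ids_a,ids_b the two id sets.
#' @return Euclidean distance between the two centroids.
#' @export
mds_centroid_distance <- function(coords, ids_a, ids_b) {
  ca <- colMeans(coords[as.character(ids_a), , drop = FALSE])
  cb <- colMeans(coords[as.character(ids_b), , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}
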