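#' Phylogenetically fuzzy cell composition
#'
#' Weights each cell's occupancy by phylogenetic similarity among the clade's
#' species: S = 1 - d/max(d) from the patristic matrix, P = occupancy . S,
#' rows rescaled to sum 1. A cell's row is then a fuzzy composition spreading
#' each occurrence over the occupant's relatives, so compositional turnover
#' between cells reflects phylogenetic turnover.
#'
#' @param x a \code{pam_matrix} object.
#' @param phy a \code{phylo} object, or a precomputed patristic matrix, over
#'   the clade's species.
#' @param species optional species subset (defaults to the tree's tips
#'   intersected with the PAM's species).
#' @return matrix P (retained cells x species), rows summing to 1, with
#'   attribute \code{dropped_cells}.
#' @export
fuzzy_composition <- function(x, phy, species = NULL) {
  stopifnot(inherits(x, "pam_matrix"))
  d <- if (inherits(phy, "phylo")) patristic_matrix(phy) else as.matrix(phy)
  if (is.null(species)) species <- intersect(colnames(x$occupancy), rownames(d))
  if (length(species) < 2L) stop("need at least 2 clade species present in the PAM", call. = FALSE)
  d <- d[species, species, drop = FALSE]
  mx <- max(d)
  if (mx == 0) stop("all patristic distances are zero", call. = FALSE)
  S <- 1 - d / mx
  occ <- x$occupancy[, species, drop = FALSE]
  P <- occ %*% S
  keep <- rowSums(occ) > 0L
  if (!all(keep)) warning(sum(!keep), " cell(s) with no clade species excluded")
  P <- P[keep, , drop = FALSE]
  P <- P / rowSums(P)
  attr(P, "dropped_cells") <- rownames(occ)[!keep]
  P
}

#' Ordination of fuzzy compositions
#'
#' Principal-coordinates analysis (Gower double-centring and
#' eigendecomposition) of Bray-Curtis dissimilarities among the rows of the
#' fuzzy composition matrix. Axes with negative eigenvalues are discarded;
#' of the positive-eigenvalue axes, those explaining at least
#' \code{min_explained} of the total positive-eigenvalue variance are
#' retained for clustering.
#'
#' @param P cells x species fuzzy composition matrix.
#' @param min_explained minimum per-axis share of positive-eigenvalue
#'   variance (default 0.05).
#' @return list with \code{scores} (retained axes), \code{all_scores} (all
#'   positive-eigenvalue axes), \code{explained} (per retained axis),
#'   \code{eigenvalues}.
#' @export
pcps_axes <- function(P, min_explained = 0.05) {
  if (nrow(unique(P)) < 3L) stop("degenerate composition: fewer than 3 distinct cell compositions",
                                 call. = FALSE)
  D <- as.matrix(vegan::vegdist(P, method = "bray"))
  n <- nrow(D)
  # Gower double-centring: G = -0.5 * J D^2 J
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  if (!any(pos)) stop("degenerate composition: no positive-eigenvalue axis", call. = FALSE)
  vals <- eig$values[pos]
  scores <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), nrow = length(vals))
  rownames(scores) <- rownames(P)
  expl <- vals / sum(vals)
  keep <- expl >= min_explained
  if (!any(keep)) stop("degenerate composition: no axis explains >= ",
                       min_explained * 100, "% of variance", call. = FALSE)
  list(scores = scores[, keep, drop = FALSE],
       all_scores = scores,
       explained = expl[keep],
       eigenvalues = eig$values)
}

# mean silhouette width for a labelling, Euclidean distances
mean_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  labs <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(D[i, own]) / (sum(own) - 1L) else 0
    b <- Inf
    for (l in labs) {
      if (l == labels[i]) next
      b <- min(b, mean(D[i, labels == l]))
    }
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Delineate evoregions by silhouette-selected k-means
#'
#' k-means for K = 2..kmax on the retained ordination axes; the K with the
#' largest mean silhouette width (Euclidean, on the same axes) is chosen.
#' The cap of 10 regions keeps the downstream DEC state space tractable.
#'
#' @param scores ordination scores from \code{\link{pcps_axes}} (or the list
#'   it returns).
#' @param kmax maximum number of regions (default 10).
#' @param seed integer RNG seed.
#' @param n_init k-means restarts per K.
#' @return object of class \code{evoregion_map}: list with \code{region}
#'   (named integer vector cell -> 1..K), \code{K}, \code{silhouette},
#'   \code{kmax}.
#' @export
select_evoregions <- function(scores, kmax = 10L, seed = 1L, n_init = 10L) {
  if (is.list(scores) && !is.null(scores$scores)) scores <- scores$scores
  X <- as.matrix(scores)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 cells", call. = FALSE)
  kmax <- min(kmax, n - 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best <- NULL
  for (K in 2:kmax) {
    if (K > nrow(unique(X))) break
    set.seed(seed + K)
    km <- stats::kmeans(X, centers = K, nstart = n_init, iter.max = 100L)
    sil <- mean_silhouette(X, km$cluster)
    if (is.null(best) || sil > best$silhouette)
      best <- list(labels = km$cluster, K = K, silhouette = sil)
  }
  region <- as.integer(best$labels)
  names(region) <- rownames(X)
  structure(list(region = region, K = best$K, silhouette = best$silhouette,
                 kmax = as.integer(kmax)), class = "evoregion_map")
}

#' @export
print.evoregion_map <- function(x, ...) {
  cat("Evoregion map:", x$K, "regions over", length(x$region),
      sprintf("cells (mean silhouette %.3f)\n", x$silhouette))
  invisible(x)
}

#' One-call evoregion delineation for a clade
#'
#' @param x a \code{pam_matrix} object.
#' @param phy the clade's phylogeny.
#' @inheritParams select_evoregions
#' @inheritParams pcps_axes
#' @export
evoregions <- function(x, phy, kmax = 10L, seed = 1L, min_explained = 0.05) {
  P <- fuzzy_composition(x, phy)
  ax <- pcps_axes(P, min_explained = min_explained)
  select_evoregions(ax$scores, kmax = kmax, seed = seed)
}

#' Species -> occupied-region sets (DEC tip states)
#'
#' @param map an \code{evoregion_map} (or named integer vector cell ->
#'   region).
#' @param x a \code{pam_matrix} object.
#' @param species optional species subset.
#' @return named list: species -> sorted integer vector of region labels.
#' @export
species_area_sets <- function(map, x, species = NULL) {
  region <- if (inherits(map, "evoregion_map")) map$region else map
  stopifnot(inherits(x, "pam_matrix"))
  occ <- x$occupancy
  if (!is.null(species)) occ <- occ[, species, drop = FALSE]
  out <- vector("list", ncol(occ))
  names(out) <- colnames(occ)
  for (sp in colnames(occ)) {
    cells <- rownames(occ)[occ[, sp] > 0L]
    labelled <- cells[cells %in% names(region)]
    if (length(labelled) == 0L)
      stop("species '", sp, "' occurs only in unlabelled cells", call. = FALSE)
    out[[sp]] <- sort(unique(unname(region[labelled])))
  }
  out
}
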