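#' Patristic distance matrix among tips
#'
#' @param phy a \code{phylo} object.
#' @return symmetric matrix of tip-to-tip path lengths (Ma), zero diagonal.
#' @export
patristic_matrix <- function(phy) {
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

#' Graph-Laplacian spectrum of a tree's tip-distance graph
#'
#' Builds the Laplacian L = D - A of the dense graph whose adjacency A is the
#' patristic distance matrix among tips and D the diagonal of row sums, and
#' eigendecomposes it. Tips sharing branching structure lie close in the
#' leading eigenvectors, which is what the clade-delineation clustering
#' exploits. Only tips enter the graph: tips are what define clade
#' membership.
#'
#' @param d symmetric nonnegative matrix with zero diagonal (patristic
#'   distances), or a \code{phylo} object.
#' @return object of class \code{spectral_embedding} with \code{values}
#'   (eigenvalues, descending) and \code{vectors} (columns in the same
#'   order, rows named by tip).
#' @export
laplacian_spectrum <- function(d) {
  if (inherits(d, "phylo")) d <- patristic_matrix(d)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10)) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  L <- diag(rowSums(d)) - d
  eig <- eigen(L, symmetric = TRUE)   # values already in decreasing order
  rownames(eig$vectors) <- rownames(d)
  structure(list(values = eig$values, vectors = eig$vectors), class = "spectral_embedding")
}

#' Cluster tips in Laplacian-eigenvector space
#'
#' k-means on tip coordinates in the eigenvectors of the k - 1 largest
#' Laplacian eigenvalues: for k well-separated groups the between-group
#' contrasts occupy exactly the k - 1 leading modes of the distance-graph
#' Laplacian (the trivial constant mode sits at eigenvalue 0), while the
#' k-th mode is already a within-group contrast that can mislead k-means.
#' Best of \code{n_init} restarts by within-cluster sum of squares,
#' deterministic given \code{seed}.
#'
#' @param embedding a \code{spectral_embedding}.
#' @param k number of modalities (clusters), 1..n_tips.
#' @param seed integer RNG seed.
#' @param n_init number of k-means restarts.
#' @return named integer vector of cluster labels per tip.
#' @export
spectral_cluster_tips <- function(embedding, k, seed = 1L, n_init = 25L) {
  stopifnot(inherits(embedding, "spectral_embedding"))
  n <- nrow(embedding$vectors)
  if (k < 1L || k > n) stop("k must be between 1 and the number of tips", call. = FALSE)
  if (k == 1L) {
    lab <- rep(1L, n); names(lab) <- rownames(embedding$vectors); return(lab)
  }
  X <- embedding$vectors[, seq_len(k - 1L), drop = FALSE]
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100L)
  lab <- as.integer(km$cluster)
  names(lab) <- rownames(embedding$vectors)
  lab
}

#' Delineate clades from a modality labelling
#'
#' Each modality label is a candidate clade; candidates smaller than
#' \code{min_size} are dropped. A retained clade is monophyletic when its tip
#' set equals the complete tip set of its most recent common ancestor, and is
#' flagged paraphyletic otherwise (paraphyletic clades are retained: the
#' delineation groups tips by branching dynamics, not strict monophyly).
#'
#' @param phy a \code{phylo} object.
#' @param labels named integer vector covering all tips (from
#'   \code{\link{spectral_cluster_tips}}).
#' @param min_size minimum clade size retained (default 50 species).
#' @return object of class \code{clade_partition}: list with \code{clades}
#'   (each: label, tips, size, monophyletic), \code{labels},
#'   \code{min_size}, \code{k}, and \code{excluded_fraction} (share of tips
#'   dropped by the size filter).
#' @export
extract_clades <- function(phy, labels, min_size = 50L) {
  if (!setequal(names(labels), phy$tip.label))
    stop("labels must cover exactly the tree's tips", call. = FALSE)
  labels <- labels[phy$tip.label]
  groups <- split(names(labels), labels)
  clades <- list()
  for (g in names(groups)) {
    tips <- groups[[g]]
    if (length(tips) < min_size) next
    mono <- if (length(tips) == length(phy$tip.label)) {
      TRUE
    } else if (length(tips) == 1L) {
      TRUE
    } else {
      mrca <- ape::getMRCA(phy, tips)
      mrca_tips <- ape::extract.clade(phy, mrca)$tip.label
      setequal(mrca_tips, tips)
    }
    clades[[length(clades) + 1L]] <- list(
      label = as.integer(g), tips = tips, size = length(tips), monophyletic = mono)
  }
  retained <- if (length(clades)) unlist(lapply(clades, `[[`, "tips")) else character()
  structure(list(
    clades = clades,
    labels = labels,
    min_size = as.integer(min_size),
    k = length(groups),
    excluded_fraction = 1 - length(retained) / length(labels)
  ), class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("Clade partition:", length(x$clades), "clade(s) retained of", x$k,
      sprintf("modalities (min size %d; %.1f%% of tips excluded)\n",
              x$min_size, 100 * x$excluded_fraction))
  for (cl in x$clades)
    cat(sprintf("  clade %d: %d tips, %s\n", cl$label, cl$size,
                if (cl$monophyletic) "monophyletic" else "paraphyletic"))
  invisible(x)
}

#' One-call clade delineation
#'
#' Patristic distances -> Laplacian spectrum -> k-means into \code{k}
#' spectral modalities -> size filter. Defaults follow the delineation
#' protocol for large tetrapod trees: 50 modalities, minimum clade size 50;
#' 40 and 60 modalities are the usual sensitivity settings.
#'
#' @inheritParams spectral_cluster_tips
#' @inheritParams extract_clades
#' @export
delineate_clades <- function(phy, k = 50L, min_size = 50L, seed = 1L, n_init = 25L) {
  emb <- laplacian_spectrum(phy)
  labels <- spectral_cluster_tips(emb, k = min(k, length(phy$tip.label)), seed = seed, n_init = n_init)
  extract_clades(phy, labels, min_size = min_size)
}
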