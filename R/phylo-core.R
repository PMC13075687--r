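#' Read and validate a phylogeny
#'
#' Reads a rooted phylogeny from a Newick file or string and validates it for
#' use in the pipeline: unique tip labels, strictly positive branch lengths,
#' no unary nodes. Branch lengths are interpreted as millions of years (Ma)
#' throughout the package. Ultrametricity (all tips equidistant from the
#' root) is checked with a relative tolerance of 1e-6 on tip depths;
#' non-ultrametric trees are accepted with a warning because several
#' downstream quantities (DR, patristic distances) remain well defined.
#'
#' @param source path to a Newick file, or a Newick string (detected by the
#'   presence of "(" and ";").
#' @return an \code{ape::phylo} object with attribute \code{is_ultrametric}.
#' @export
read_phylogeny <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  is_text <- grepl("\\(", source)
  phy <- if (is_text) {
    if (!grepl(";", source)) stop("Newick parse error: missing terminating ';'", call. = FALSE)
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
    tryCatch(ape::read.tree(source),
             error = function(e) stop("Newick parse error in '", source, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.null(phy)) stop("Newick parse error: input could not be read as a tree", call. = FALSE)
  validate_phylogeny(phy)
}

#' Validate a phylogeny for pipeline use
#'
#' @param phy an \code{ape::phylo} object.
#' @return the tree, with unary nodes collapsed and attribute
#'   \code{is_ultrametric} set.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- phy$tip.label[duplicated(phy$tip.label)][1L]
    stop("duplicate tip label: '", dup, "'", call. = FALSE)
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(phy$edge.length)) stop("missing branch lengths", call. = FALSE)
  # collapse unary (single-child) internal nodes, summing lengths
  phy <- ape::collapse.singles(phy)
  if (any(phy$edge.length < 0)) stop("negative branch length", call. = FALSE)
  attr(phy, "is_ultrametric") <- is_ultrametric(phy)
  if (!attr(phy, "is_ultrametric")) {
    warning("tree is not ultrametric (tip depths differ); accepted, but age-based metrics assume time calibration")
  }
  phy
}

#' Tip depths (root-to-tip path lengths)
#'
#' @param phy a \code{phylo} object.
#' @return named numeric vector, one depth (Ma) per tip.
#' @export
tip_depths <- function(phy) {
  nt <- length(phy$tip.label)
  d <- ape::node.depth.edgelength(phy)[seq_len(nt)]
  names(d) <- phy$tip.label
  d
}

#' @rdname read_phylogeny
#' @param tol relative tolerance on the spread of tip depths.
#' @export
is_ultrametric <- function(phy, tol = 1e-6) {
  d <- tip_depths(phy)
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) / mx <= tol
}

#' Write a phylogeny to Newick
#'
#' @param phy a \code{phylo} object.
#' @param file optional path; if \code{NULL} the Newick string is returned.
#' @export
write_phylogeny <- function(phy, file = NULL) {
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file = file)
}

#' Crown age of a tree
#'
#' The maximum root-to-tip path length; for an ultrametric (time-calibrated)
#' tree this is the age of the root, i.e., the crown age of the clade.
#'
#' @param phy a \code{phylo} object with at least 2 tips.
#' @return crown age in Ma.
#' @export
crown_age <- function(phy) {
  if (length(phy$tip.label) < 2L) stop("crown age undefined for a single-tip tree", call. = FALSE)
  d <- tip_depths(phy)
  mx <- max(d)
  if ((mx - min(d)) / mx > 1e-6) {
    warning("tree not ultrametric; returning maximum root-to-tip depth")
  }
  mx
}

#' Prune a tree to a set of tips
#'
#' Induced subtree on \code{keep}: unary nodes are suppressed with branch
#' lengths summed, so patristic distances among kept tips are preserved
#' exactly (depths are measured from the kept tips' most recent common
#' ancestor, i.e., any stem above it is dropped).
#'
#' @param phy a \code{phylo} object.
#' @param keep character vector of tip labels to retain (>= 2).
#' @export
prune_tree <- function(phy, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown)) stop("unknown tip label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L) stop("need at least 2 tips to prune to", call. = FALSE)
  ape::keep.tip(phy, keep)
}
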