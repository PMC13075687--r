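#' DR tip speciation rates (inverse equal-splits)
#'
#' For tip i with root-to-tip edges e_1 (pendant) ... e_N (rootmost), the
#' equal-splits measure is ES_i = sum_j len(e_j) * 2^-(j-1): each successive
#' rootward edge is discounted by the splits between it and the tip. DR_i =
#' 1/ES_i is a tip-level proxy for recent speciation rate (high where recent
#' branching is dense).
#'
#' @param phy a \code{phylo} object with strictly positive branch lengths.
#' @return data.frame with columns \code{species}, \code{es} (Ma),
#'   \code{dr} (per Ma).
#' @export
dr_statistic <- function(phy) {
  nt <- length(phy$tip.label)
  parent_of <- integer(nt + phy$Nnode)
  elen_of <- numeric(nt + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  elen_of[phy$edge[, 2]] <- phy$edge.length
  root <- nt + 1L
  pend <- elen_of[seq_len(nt)]
  if (any(pend <= 0)) stop("zero-length pendant edge: ES undefined", call. = FALSE)
  es <- numeric(nt)
  for (i in seq_len(nt)) {
    node <- i; w <- 1; s <- 0
    while (node != root) {
      s <- s + elen_of[node] * w
      w <- w / 2
      node <- parent_of[node]
    }
    es[i] <- s
  }
  data.frame(species = phy$tip.label, es = es, dr = 1 / es)
}

#' Per-cell median tip rate
#'
#' Median DR among the species co-occurring in each grid cell (even counts:
#' midpoint of the two central values, the stats::median convention).
#'
#' @param x a \code{pam_matrix} object.
#' @param rates data.frame from \code{\link{dr_statistic}} (or a named
#'   numeric vector of per-species rates).
#' @return named numeric vector of per-cell median DR; \code{NA} for empty
#'   cells.
#' @export
cell_median_rate <- function(x, rates) {
  stopifnot(inherits(x, "pam_matrix"))
  r <- if (is.data.frame(rates)) stats::setNames(rates$dr, rates$species) else rates
  occ <- x$occupancy
  missing <- setdiff(colnames(occ), names(r))
  if (length(missing)) stop("rates missing for species: ",
                            paste(utils::head(missing), collapse = ", "), call. = FALSE)
  apply(occ, 1L, function(row) {
    sp <- colnames(occ)[row > 0L]
    if (length(sp) == 0L) NA_real_ else stats::median(r[sp])
  })
}
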