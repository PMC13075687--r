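# Arrival times and assemblage ages built on the DEC reconstruction.

#' Arrival time of a species in a region
#'
#' Walks from the tip toward the root and returns the age of the deepest
#' ancestral node whose most-probable reconstructed range includes the focal
#' region. By default occupancy must be uninterrupted from the tip's parent
#' up to that node, so a region lost and regained deeper in the tree does not
#' inflate the arrival age; set \code{uninterrupted = FALSE} for the deepest
#' occupied node anywhere on the root path. When the tip's parent already
#' lacks the region, the species dispersed in after its most recent
#' speciation and receives the minimal arrival time of 10 years (1e-5 Ma).
#'
#' @param species tip label.
#' @param region integer region (area) label.
#' @param recon a \code{dec_reconstruction}.
#' @param uninterrupted logical; see above.
#' @param floor minimal arrival time in Ma (default 1e-5, i.e., 10 years).
#' @return arrival time in Ma.
#' @export
arrival_time <- function(species, region, recon, uninterrupted = TRUE, floor = 1e-5) {
  phy <- recon$phy
  tip <- match(species, phy$tip.label)
  if (is.na(tip)) stop("unknown species '", species, "'", call. = FALSE)
  if (!(region %in% recon$tip_ranges[[species]]))
    stop("species '", species, "' does not occur in region ", region, call. = FALSE)
  parent_of <- integer(length(phy$tip.label) + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  root <- length(phy$tip.label) + 1L
  node <- tip
  deepest <- NA_integer_
  repeat {
    if (node == root) break
    node <- parent_of[node]
    holds <- region %in% recon$argmax[[node]]
    if (holds) deepest <- node
    else if (uninterrupted) break
    if (node == root) break
  }
  if (is.na(deepest)) return(floor)
  max(recon$node_ages[deepest], floor)
}

#' Arrival-time table for all (species, region) pairs
#'
#' @param recon a \code{dec_reconstruction}.
#' @param area_sets named list species -> occupied regions (from
#'   \code{\link{species_area_sets}}); defaults to the reconstruction's tip
#'   ranges.
#' @inheritParams arrival_time
#' @return data.frame with columns \code{species}, \code{region},
#'   \code{arrival} (Ma).
#' @export
arrival_table <- function(recon, area_sets = NULL, uninterrupted = TRUE, floor = 1e-5) {
  if (is.null(area_sets)) area_sets <- recon$tip_ranges
  rows <- list()
  for (sp in names(area_sets)) {
    for (r in area_sets[[sp]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, region = r,
        arrival = arrival_time(sp, r, recon, uninterrupted = uninterrupted, floor = floor))
    }
  }
  do.call(rbind, rows)
}

#' Per-cell assemblage age
#'
#' The mean arrival time, in the cell's evoregion, across the species present
#' in the cell: the "evolutionary time" predictor of the path models.
#'
#' @param x a \code{pam_matrix} object.
#' @param map an \code{evoregion_map} (or named cell -> region vector).
#' @param arrivals arrival table from \code{\link{arrival_table}}.
#' @return named numeric vector of assemblage ages (Ma); \code{NA} for empty
#'   or unlabelled cells.
#' @export
assemblage_age <- function(x, map, arrivals) {
  stopifnot(inherits(x, "pam_matrix"))
  region <- if (inherits(map, "evoregion_map")) map$region else map
  key <- paste(arrivals$species, arrivals$region)
  arr <- stats::setNames(arrivals$arrival, key)
  occ <- x$occupancy
  out <- rep(NA_real_, nrow(occ))
  names(out) <- rownames(occ)
  for (cell in rownames(occ)) {
    if (!(cell %in% names(region))) next
    sp <- colnames(occ)[occ[cell, ] > 0L]
    if (length(sp) == 0L) next
    a <- arr[paste(sp, region[[cell]])]
    out[cell] <- mean(a, na.rm = TRUE)
  }
  out
}
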