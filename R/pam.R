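#' Presence-absence matrix over grid cells
#'
#' Container for a binary cells x species occupancy matrix with cell
#' coordinates. Cells are opaque ids; coordinates are decimal degrees (or
#' lattice row/column indices for simulated worlds) and are used only for
#' spatial diagnostics, never for projection math.
#'
#' @param occupancy binary matrix, rows = cells, columns = species, with
#'   dimnames.
#' @param coords data.frame with columns \code{cell_id}, \code{lat},
#'   \code{lon}, one row per occupancy row in the same order.
#' @return an object of class \code{pam_matrix}.
#' @export
pam_matrix <- function(occupancy, coords) {
  occupancy <- as.matrix(occupancy)
  if (is.null(rownames(occupancy)) || is.null(colnames(occupancy)))
    stop("occupancy needs cell and species dimnames", call. = FALSE)
  if (!all(occupancy %in% c(0, 1))) stop("occupancy entries must be 0/1", call. = FALSE)
  storage.mode(occupancy) <- "integer"
  stopifnot(is.data.frame(coords), all(c("cell_id", "lat", "lon") %in% names(coords)))
  coords$cell_id <- as.character(coords$cell_id)
  if (!identical(coords$cell_id, rownames(occupancy)))
    stop("coords$cell_id must match occupancy rownames in order", call. = FALSE)
  if (!all(is.finite(coords$lat)) || !all(is.finite(coords$lon)))
    stop("non-finite coordinates", call. = FALSE)
  empty_sp <- colSums(occupancy) == 0L
  if (any(empty_sp))
    stop("species with no occurrences: ", paste(colnames(occupancy)[empty_sp], collapse = ", "),
         call. = FALSE)
  structure(list(occupancy = occupancy, coords = coords), class = "pam_matrix")
}

#' @export
print.pam_matrix <- function(x, ...) {
  cat("Presence-absence matrix:", nrow(x$occupancy), "cells x",
      ncol(x$occupancy), "species;", sum(x$occupancy), "occurrences\n")
  invisible(x)
}

#' Read / write a presence-absence matrix
#'
#' CSV layout: columns \code{cell_id, lat, lon}, then one 0/1 column per
#' species.
#'
#' @param file path to a CSV file.
#' @export
read_pam <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "lat", "lon")
  if (!all(need %in% names(df))) stop("PAM csv must have columns cell_id, lat, lon", call. = FALSE)
  sp <- setdiff(names(df), need)
  occ <- as.matrix(df[, sp, drop = FALSE])
  rownames(occ) <- as.character(df$cell_id)
  pam_matrix(occ, df[, need])
}

#' @rdname read_pam
#' @param x a \code{pam_matrix} object.
#' @export
write_pam <- function(x, file) {
  stopifnot(inherits(x, "pam_matrix"))
  df <- cbind(x$coords, as.data.frame(x$occupancy, check.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Species richness per grid cell
#'
#' @param x a \code{pam_matrix} object.
#' @param species optional subset of species columns.
#' @return named integer vector of per-cell richness.
#' @export
richness_per_cell <- function(x, species = NULL) {
  stopifnot(inherits(x, "pam_matrix"))
  occ <- x$occupancy
  if (!is.null(species)) {
    unknown <- setdiff(species, colnames(occ))
    if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
    occ <- occ[, species, drop = FALSE]
  }
  rowSums(occ)
}

#' Geographic extent of a species set
#'
#' Number of grid cells occupied by at least one species of the subset.
#'
#' @param x a \code{pam_matrix} object.
#' @param species character vector of species ids (nonempty).
#' @export
geographic_extent <- function(x, species) {
  stopifnot(inherits(x, "pam_matrix"))
  if (length(species) == 0L) stop("empty species subset", call. = FALSE)
  sum(richness_per_cell(x, species) > 0L)
}

#' Read / write the per-cell environment table
#'
#' Columns: \code{cell_id, temperature, precipitation, npp} and optionally
#' \code{lat, lon}. Units: degrees C, mm/yr, and nonnegative energy units.
#'
#' @param file path to a CSV file.
#' @export
read_env <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "temperature", "precipitation", "npp")
  if (!all(need %in% names(df))) stop("environment csv must have columns ",
                                      paste(need, collapse = ", "), call. = FALSE)
  df$cell_id <- as.character(df$cell_id)
  df
}

#' @rdname read_env
#' @param env environment data.frame.
#' @export
write_env <- function(env, file) {
  utils::write.csv(env, file, row.names = FALSE)
  invisible(file)
}

#' Check that an environment table covers a PAM's cells
#'
#' @param env environment data.frame.
#' @param x a \code{pam_matrix} object.
#' @return the environment table reordered to the PAM's cells.
#' @export
align_env <- function(env, x) {
  stopifnot(inherits(x, "pam_matrix"))
  idx <- match(rownames(x$occupancy), env$cell_id)
  if (anyNA(idx)) stop("environment table missing cells: ",
                       paste(utils::head(rownames(x$occupancy)[is.na(idx)]), collapse = ", "),
                       call. = FALSE)
  out <- env[idx, , drop = FALSE]
  num <- c("temperature", "precipitation", "npp")
  if (anyNA(out[, num])) stop("missing environment values in PAM cells", call. = FALSE)
  rownames(out) <- NULL
  out
}
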