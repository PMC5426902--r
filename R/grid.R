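#' One-dimensional compartment grid
#'
#' Discretises a dendritic segment into equal compartments of width `dx`.
#' Reactions are evaluated only in compartments flagged in `reactive_mask`;
#' diffusion acts everywhere.  The default (100 um at 1 um resolution) is the
#' geometry used by all abstract-model runs.
#'
#' @param total_length Total length of the segment (um).
#' @param dx Compartment width (um).
#' @param reactive_mask Optional logical vector, one entry per compartment.
#'   Defaults to all-reactive.
#' @return An object of class `grid1d` with fields `n_compartments`, `dx`,
#'   `total_length`, `reactive_mask`, and the positions (um) of compartment
#'   centres in `x`.
#' @examples
#' g <- grid1d(100, 1)
#' g$n_compartments
#' @export
grid1d <- function(total_length = 100, dx = 1, reactive_mask = NULL) {
  stopifnot(total_length > 0, dx > 0)
  n <- as.integer(round(total_length / dx))
  if (abs(n * dx - total_length) > dx)
    stop("total_length is not within one compartment of n * dx")
  if (is.null(reactive_mask)) reactive_mask <- rep(TRUE, n)
  if (length(reactive_mask) != n)
    stop("reactive_mask must have one entry per compartment")
  structure(list(
    n_compartments = n, dx = dx, total_length = n * dx,
    reactive_mask = as.logical(reactive_mask),
    x = (seq_len(n) - 0.5) * dx
  ), class = "grid1d")
}

#' Place equally spaced reactive patches on a grid
#'
#' Marks `n_patches` patches of width `patch_width` as the only reactive
#' compartments, centred in the domain with centre-to-centre distance
#' `spacing`.  These patches model the spatially restricted reaction zones
#' under dendritic spines; they are also the stimulus sites.
#'
#' @param grid A [grid1d()] object.
#' @param spacing Centre-to-centre patch distance (um).
#' @param n_patches Number of patches (default 5).
#' @param patch_width Patch width (um, default 1).
#' @return The grid with `reactive_mask` set and attribute `sites`: the
#'   compartment index of each patch centre, in spatial order.
#' @export
reactive_patches <- function(grid, spacing, n_patches = 5, patch_width = 1) {
  stopifnot(inherits(grid, "grid1d"), spacing > 0, n_patches >= 1)
  span <- (n_patches - 1) * spacing
  if (span + patch_width > grid$total_length)
    stop(sprintf("patches span %g um but the grid is only %g um",
                 span + patch_width, grid$total_length))
  first <- (grid$total_length - span) / 2
  centres <- first + spacing * (seq_len(n_patches) - 1)
  sites <- pmin(pmax(1L, as.integer(ceiling(centres / grid$dx))),
                grid$n_compartments)
  if (anyDuplicated(sites))
    stop("spacing too small for the grid resolution: patches overlap")
  half <- max(0L, as.integer(round(patch_width / grid$dx)) %/% 2L)
  mask <- rep(FALSE, grid$n_compartments)
  for (s in sites) mask[max(1L, s - half):min(grid$n_compartments, s + half)] <- TRUE
  grid$reactive_mask <- mask
  attr(grid, "sites") <- sites
  grid
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> %d compartments x %g um = %g um; %d reactive\n",
              x$n_compartments, x$dx, x$total_length, sum(x$reactive_mask)))
  sites <- attr(x, "sites")
  if (!is.null(sites))
    cat("  patch centres at compartments:", paste(sites, collapse = ", "), "\n")
  invisible(x)
}

# chain-topology helpers used by the solver: compartment i's parent is i+1,
# the last compartment is the root.  gfac = A/L with unit cross-section.
chain_tree <- function(grid) {
  n <- grid$n_compartments
  if (n == 1L)
    return(list(parent = -1L, gfac = 0, vol = grid$dx))
  list(parent = c(seq_len(n - 1L), -1L),  # 0-based: node i couples to i+1
       gfac = c(rep(1 / grid$dx, n - 1L), 0),
       vol = rep(grid$dx, n))
}
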