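#' Capsule (spherocylinder) in the plane
#'
#' A cell is a rigid capsule: the set of points within `radius` of a core
#' segment of length `length` centered at `center` along the unit vector
#' `axis`. `length` is the cylinder length between the two cap centers, so
#' the pole-to-pole extent is `length + 2 * radius`.
#'
#' @param center Numeric length-2, um.
#' @param axis Numeric length-2 direction; normalized if not unit length,
#'   rejected if zero or if its norm differs from 1 by more than 1e-9 when
#'   `normalize = FALSE`.
#' @param length Cylinder length, um (>= 0).
#' @param radius Cap radius, um (> 0).
#' @param normalize Normalize `axis` instead of checking |axis| = 1.
#' @return An object of class `capsule`.
#' @export
capsule <- function(center, axis, length, radius, normalize = TRUE) {
  stopifnot(length(center) == 2, length(axis) == 2)
  if (!all(is.finite(center)) || !all(is.finite(axis)) ||
      !is.finite(length) || !is.finite(radius))
    stop("invalid geometry: non-finite capsule coordinates")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("invalid geometry: zero axis")
  if (normalize) {
    axis <- axis / nrm
  } else if (abs(nrm - 1) > 1e-9) {
    stop("invalid geometry: axis is not unit length")
  }
  if (length < 0) stop("invalid geometry: negative length")
  if (radius <= 0) stop("invalid geometry: non-positive radius")
  structure(list(center = as.numeric(center), axis = as.numeric(axis),
                 length = as.numeric(length), radius = as.numeric(radius)),
            class = "capsule")
}

as_capsule_vec <- function(a) {
  c(a$center[1], a$center[2], a$axis[1], a$axis[2], a$length, a$radius)
}

#' Surface separation between two capsules
#'
#' Minimum distance between the two core segments minus the sum of radii.
#' Negative when the capsules overlap; `-(r_a + r_b)` for identical cores.
#'
#' @param a,b `capsule` objects.
#' @return Surface separation in um.
#' @export
capsule_distance <- function(a, b) {
  stopifnot(inherits(a, "capsule"), inherits(b, "capsule"))
  cpp_capsule_distance(as_capsule_vec(a), as_capsule_vec(b))
}

#' Contact graph of a cell collection
#'
#' All unordered pairs of cells whose surface separation is at most `tol`,
#' found with a uniform grid hash (bucket edge = maximum capsule extent), so
#' the result is identical to the all-pairs computation at near-linear cost.
#'
#' @param cells A data frame with columns `x`, `y`, `angle`, `length`,
#'   `radius` (one row per cell), or a list of `capsule` objects.
#' @param tol Contact tolerance, um (>= 0). Default 0.05.
#' @return A `contact_graph`: data frame with columns `i`, `j` (row indices,
#'   `i < j`), `sep` (surface separation, um) and `overlap`
#'   (`pmax(0, -sep)`), plus attribute `n_cells`.
#' @export
build_contacts <- function(cells, tol = 0.05) {
  stopifnot(tol >= 0)
  if (is.list(cells) && !is.data.frame(cells) &&
      all(vapply(cells, inherits, logical(1), "capsule"))) {
    cells <- data.frame(
      x = vapply(cells, function(c) c$center[1], numeric(1)),
      y = vapply(cells, function(c) c$center[2], numeric(1)),
      angle = vapply(cells, function(c) atan2(c$axis[2], c$axis[1]),
                     numeric(1)),
      length = vapply(cells, function(c) c$length, numeric(1)),
      radius = vapply(cells, function(c) c$radius, numeric(1)))
  }
  res <- cpp_build_contacts(cells$x, cells$y, cells$angle, cells$length,
                            cells$radius, tol)
  g <- data.frame(i = res$i, j = res$j, sep = res$sep)
  if (nrow(g)) {
    swap <- g$i > g$j
    tmp <- g$i[swap]; g$i[swap] <- g$j[swap]; g$j[swap] <- tmp
    g <- g[order(g$i, g$j), , drop = FALSE]
    rownames(g) <- NULL
  }
  g$overlap <- pmax(0, -g$sep)
  attr(g, "n_cells") <- nrow(cells)
  attr(g, "tol") <- tol
  class(g) <- c("contact_graph", "data.frame")
  g
}

#' Per-cell contact counts from a contact graph
#'
#' @param contacts A `contact_graph`.
#' @param n_cells Number of cells (defaults to the graph attribute).
#' @param which_cells Optional logical/integer mask: count only contacts with
#'   cells in this set (e.g. count inhibitor neighbors only).
#' @return Integer vector of length `n_cells`.
#' @export
contact_counts <- function(contacts, n_cells = attr(contacts, "n_cells"),
                           which_cells = NULL) {
  if (is.null(which_cells)) {
    tabulate(c(contacts$i, contacts$j), nbins = n_cells)
  } else {
    mask <- rep(FALSE, n_cells)
    mask[which_cells] <- TRUE
    tabulate(c(contacts$i[mask[contacts$j]], contacts$j[mask[contacts$i]]),
             nbins = n_cells)
  }
}
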