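#' Neighbor index
#'
#' Log2 change, from start to end, of the inhibitor:target ratio among cells
#' at the inter-strain contact interface:
#' `log2(I_tend / T_tend) - log2(I_t0 / T_t0)`. Positive values mean
#' proportionally more inhibitors at the interface at the endpoint.
#'
#' @param I_t0,T_t0 Interface inhibitor/target counts at the start.
#' @param I_tend,T_tend Interface counts at the end.
#' @return Index in log2 units.
#' @export
neighbor_index <- function(I_t0, T_t0, I_tend, T_tend) {
  counts <- c(I_t0, T_t0, I_tend, T_tend)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("undefined neighbor index: all interface counts must be > 0")
  log2(I_tend / T_tend) - log2(I_t0 / T_t0)
}

#' Interface counts
#'
#' Counts the cells at the inter-strain contact interface: inhibitors with at
#' least one target contact and targets (including inhibited targets) with at
#' least one inhibitor contact.
#'
#' @param snap A `colony_snapshot` or internal cell table.
#' @param contacts Optional `contact_graph`; built at the default tolerance
#'   when omitted.
#' @param tol Contact tolerance used when `contacts` is missing.
#' @return Named numeric vector `c(I = ..., T = ...)`.
#' @export
interface_counts <- function(snap, contacts = NULL, tol = 0.05) {
  cells <- if ("cell_type" %in% names(snap)) snapshot_cells(snap) else snap
  if (is.null(contacts)) contacts <- build_contacts(cells, tol)
  n <- nrow(cells)
  is_inh <- cells$type == "inhibitor"
  k_inh <- contact_counts(contacts, n, which_cells = which(is_inh))
  k_tgt <- contact_counts(contacts, n, which_cells = which(!is_inh))
  c(I = sum(is_inh & k_tgt > 0), T = sum(!is_inh & k_inh > 0))
}

#' Radial annulus composition and sector statistics
#'
#' Splits the colony into concentric annuli of fixed width around the cell
#' centroid and reports, per annulus, strain counts (inhibited targets count
#' as targets), the inhibitor ratio `I / (I + T)` and — when
#' `sectors = TRUE` — the sector count and largest sector sizes from the
#' smoothed binary strip of that annulus.
#'
#' @param snap A `colony_snapshot` or internal cell table.
#' @param annulus_width Annulus width, um (default 20).
#' @param sectors Also compute sector statistics per annulus.
#' @return Data frame with columns `annulus`, `r_in_um`, `r_out_um`,
#'   `n_inhib`, `n_target`, `ratio`, and (with `sectors`) `n_sectors`,
#'   `largest_target_rad`, `largest_inhib_rad` (NA where the annulus is
#'   empty or too sparse). The smoothed strips are attached as attribute
#'   `strips`.
#' @export
radial_profile <- function(snap, annulus_width = 20, sectors = TRUE) {
  stopifnot(annulus_width > 0)
  cells <- if ("cell_type" %in% names(snap)) snapshot_cells(snap) else snap
  if (nrow(cells) == 0) stop("empty snapshot")
  cx <- mean(cells$x); cy <- mean(cells$y)
  d <- sqrt((cells$x - cx)^2 + (cells$y - cy)^2)
  idx <- floor(d / annulus_width)
  n_ann <- max(idx) + 1
  r_max <- n_ann * annulus_width
  out <- data.frame(annulus = seq_len(n_ann) - 1)
  out$r_in_um <- out$annulus * annulus_width
  out$r_out_um <- out$r_in_um + annulus_width
  is_inh <- cells$type == "inhibitor"
  out$n_inhib <- as.vector(tapply(is_inh, factor(idx, levels = out$annulus),
                                  sum, default = 0L))
  out$n_target <- as.vector(tapply(!is_inh, factor(idx, levels = out$annulus),
                                   sum, default = 0L))
  tot <- out$n_inhib + out$n_target
  out$ratio <- ifelse(tot > 0, out$n_inhib / tot, NA_real_)
  if (sectors) {
    strips <- vector("list", n_ann)
    out$n_sectors <- NA_integer_
    out$largest_target_rad <- NA_real_
    out$largest_inhib_rad <- NA_real_
    for (a in seq_len(n_ann)) {
      sel <- idx == (a - 1)
      if (!any(sel)) next
      strip <- sector_strip(cells[sel, , drop = FALSE], center = c(cx, cy))
      strips[[a]] <- strip
      if (is.null(strip)) next
      out$n_sectors[a] <- count_sectors(strip)
      sz <- sector_sizes(strip, outer_radius = out$r_out_um[a],
                         largest_annulus_radius = r_max)
      out$largest_target_rad[a] <- sz$largest_target
      out$largest_inhib_rad[a] <- sz$largest_inhib
    }
    attr(out, "strips") <- strips
  }
  attr(out, "center") <- c(cx, cy)
  attr(out, "annulus_width") <- annulus_width
  out
}

#' Circular Gaussian smoothing
#'
#' Smooths a strip on a circle with a Gaussian kernel of standard deviation
#' `sigma` bins (truncated at 4 sigma, renormalized; offsets wrap).
#'
#' @param x Numeric strip.
#' @param sigma Kernel sd in bins.
#' @return Smoothed strip, same length.
#' @export
smooth_circular <- function(x, sigma = 3) {
  n <- length(x)
  h <- ceiling(4 * sigma)
  off <- -h:h
  w <- stats::dnorm(off, sd = sigma)
  w <- w / sum(w)
  out <- numeric(n)
  for (k in seq_along(off)) {
    sh <- ((seq_len(n) - 1 + off[k]) %% n) + 1
    out <- out + w[k] * x[sh]
  }
  out
}

#' Binary sector strip of one annulus
#'
#' Discretizes the cells of an annulus by polar angle into bins of roughly
#' one mean cell diameter of arc (minimum 16 bins), takes the per-bin mean
#' cell type (inhibitor = 1, target and inhibited target = 0; empty bins are
#' filled from the circularly nearest occupied bin), and applies circular
#' Gaussian smoothing (`sigma = 3` bins) followed by 0.5-thresholding (ties
#' to inhibitor) repeatedly until the binarized strip is a fixed point of
#' the smoothing, which removes all single-bin runs.
#'
#' @param cells Cell table of one annulus (internal or snapshot layout).
#' @param center Colony center, length-2 numeric.
#' @param sigma Smoothing kernel sd in bins (default 3).
#' @param min_bins Minimum number of angular bins (default 16).
#' @return Binary strip (0/1 vector with attributes `n_bins`, `r_mid`), or
#'   `NULL` when fewer than 3 bins are occupied (too sparse).
#' @export
sector_strip <- function(cells, center = c(0, 0), sigma = 3, min_bins = 16) {
  if ("cell_type" %in% names(cells)) cells <- snapshot_cells(cells)
  if (nrow(cells) == 0) stop("empty annulus")
  dx <- cells$x - center[1]; dy <- cells$y - center[2]
  r_mid <- mean(sqrt(dx^2 + dy^2))
  diam <- mean(2 * cells$radius)
  n_bins <- max(min_bins, round(2 * pi * max(r_mid, diam) / diam))
  ang <- atan2(dy, dx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * n_bins) + 1, n_bins)
  code <- as.numeric(cells$type == "inhibitor")
  means <- tapply(code, factor(bin, levels = seq_len(n_bins)), mean)
  occupied <- which(!is.na(means))
  if (length(occupied) < 3) return(NULL)
  strip <- fill_circular_nearest(as.numeric(means))
  for (iter in 1:200) {
    b <- as.numeric(smooth_circular(strip, sigma) >= 0.5)
    if (identical(b, strip) && iter > 1) break
    strip <- b
  }
  attr(strip, "n_bins") <- n_bins
  attr(strip, "r_mid") <- r_mid
  strip
}

fill_circular_nearest <- function(x) {
  n <- length(x)
  na <- which(is.na(x))
  if (!length(na)) return(x)
  occ <- which(!is.na(x))
  for (i in na) {
    d <- pmin(abs(occ - i), n - abs(occ - i))
    x[i] <- x[occ[which.min(d)]]
  }
  x
}

#' Count sectors on a circular binary strip
#'
#' A sector boundary is a transition from inhibitor (1) to target (0) going
#' around the circle; on a circle the number of such transitions equals the
#' number of target sectors and the number of inhibitor sectors.
#'
#' @param strip Binary strip (fixed point of the smoothing).
#' @return Integer sector count (0 for a homogeneous strip).
#' @export
count_sectors <- function(strip) {
  strip <- as.numeric(strip)
  n <- length(strip)
  nxt <- c(strip[-1], strip[1])
  sum(strip == 1 & nxt == 0)
}

#' Sector sizes on a circular binary strip
#'
#' Maximal circular runs of each type, in radians (`run length * 2 pi /
#' n_bins`). The strip is notionally normalized to the radius of the largest
#' annulus analyzed; angular sizes are unaffected and the normalization
#' factor is recorded.
#'
#' @param strip Binary strip (fixed point of the smoothing).
#' @param outer_radius Outer radius of this annulus, um.
#' @param largest_annulus_radius Outer radius of the largest annulus, um.
#' @return List with `target` and `inhibitor` run sizes (radians),
#'   `largest_target`, `largest_inhib`, and `norm_factor`
#'   (`outer_radius / largest_annulus_radius`).
#' @export
sector_sizes <- function(strip, outer_radius = NA_real_,
                         largest_annulus_radius = NA_real_) {
  strip <- as.numeric(strip)
  n <- length(strip)
  per_bin <- 2 * pi / n
  runs <- circular_runs(strip)
  tg <- runs$length[runs$value == 0] * per_bin
  ih <- runs$length[runs$value == 1] * per_bin
  list(target = tg, inhibitor = ih,
       largest_target = if (length(tg)) max(tg) else 0,
       largest_inhib = if (length(ih)) max(ih) else 0,
       norm_factor = outer_radius / largest_annulus_radius)
}

# run-length encoding on a circle: first and last run merge when equal
circular_runs <- function(x) {
  r <- rle(x)
  if (length(r$values) > 1 && r$values[1] == r$values[length(r$values)]) {
    r$lengths[1] <- r$lengths[1] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  list(value = r$values, length = r$lengths)
}

#' Relative fitness of strain 1 against strain 2
#'
#' Ratio of the natural-log fold changes over the competition window:
#' `ln(S1_end / S1_start) / ln(S2_end / S2_start)`.
#'
#' @param s1_t0,s1_tend Strain 1 counts (or densities) at start and end.
#' @param s2_t0,s2_tend Strain 2 counts at start and end.
#' @return Fitness ratio (1 = equal fitness).
#' @export
relative_fitness <- function(s1_t0, s1_tend, s2_t0, s2_tend) {
  v <- c(s1_t0, s1_tend, s2_t0, s2_tend)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("undefined fitness: all counts must be > 0")
  denom <- log(s2_tend / s2_t0)
  if (denom == 0)
    stop("undefined fitness: strain 2 did not grow")
  log(s1_tend / s1_t0) / denom
}
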