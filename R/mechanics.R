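#' Effective growth rate by cell type
#'
#' Targets grow at the full rate `alpha`; inhibitor cells pay the CDI
#' carriage cost `beta` (rate `alpha * (1 - beta)`); intoxicated targets grow
#' at `alpha * (1 - delta)` where `delta` is the toxicity.
#'
#' @param cell_type Character vector in `TARGET`, `INHIBITOR`,
#'   `INHIBITED_TARGET` (case-insensitive).
#' @param alpha Base growth rate, h^-1.
#' @param delta Toxicity fraction in `[0, 1]`.
#' @param beta Inhibitor cost fraction in `[0, 1)`.
#' @return Growth rate(s), h^-1.
#' @export
effective_growth_rate <- function(cell_type, alpha, delta, beta) {
  stopifnot(delta >= 0, delta <= 1, beta >= 0, beta < 1)
  ct <- toupper(cell_type)
  bad <- !ct %in% c("TARGET", "INHIBITOR", "INHIBITED_TARGET")
  if (any(bad))
    stop("unknown cell type: ", paste(unique(cell_type[bad]), collapse = ", "))
  out <- rep(alpha, length(ct))
  out[ct == "INHIBITOR"] <- alpha * (1 - beta)
  out[ct == "INHIBITED_TARGET"] <- alpha * (1 - delta)
  out
}

type_label <- function(type, inhibited) {
  ifelse(type == "inhibitor", "INHIBITOR",
         ifelse(inhibited, "INHIBITED_TARGET", "TARGET"))
}

#' Unconstrained elongation over one timestep
#'
#' The model's growth law is exponential elongation, dL/dt = rate * L. The
#' `"euler"` method returns the stated first-order increment
#' `rate * L * dt`; the default `"exact"` method integrates the law exactly
#' over the step, `L * (exp(rate * dt) - 1)`, so that macroscopic doubling
#' times equal `ln 2 / rate` independent of `dt` (see the methods vignette).
#'
#' @param L Cell length(s), um (> 0).
#' @param rate Growth rate(s), h^-1 (>= 0).
#' @param dt Timestep, h (> 0).
#' @param method `"exact"` or `"euler"`.
#' @return Elongation(s) `dL`, um.
#' @export
unconstrained_elongation <- function(L, rate, dt,
                                     method = c("exact", "euler")) {
  stopifnot(all(L > 0), all(rate >= 0), dt > 0)
  method <- match.arg(method)
  if (method == "euler") rate * L * dt else L * expm1(rate * dt)
}

#' Grow cells and relax overlaps for one timestep
#'
#' Implements the mechanical half of a timestep. Elongation follows the
#' exponential growth law on the pole-to-pole cell length
#' (`length + 2 radius`); the increment is attenuated by the local contact
#' pressure (the summed overlap depth of the cell's contacts at entry, less
#' the solver residual tolerance):
#' `realized = dL * max(0, 1 - kappa * pressure)`, which suppresses growth in
#' the jammed colony interior while edge cells elongate freely. Lengths are
#' then updated and overlaps resolved by damped sequential pairwise
#' projection with a small torque-like axis correction, iterated until the
#' residual overlap falls below `relax_tol` or the sweep budget is spent.
#' Isolated cells realize their full elongation and do not move.
#'
#' @param cells Cell table with columns `x`, `y`, `angle`, `length`,
#'   `radius`, `type` (`"target"`/`"inhibitor"`), `inhibited` (logical).
#' @param contacts `contact_graph` built for the input poses.
#' @param dt Timestep, h.
#' @param params `sim_params` (rates, damping, kappa, tolerances).
#' @param wake `"all"` relaxes every pair; `"grown"` seeds motion only at
#'   cells that elongated this step and lets pushes propagate through force
#'   chains, skipping the static jammed core (the engine's setting).
#' @return List with `cells` (updated poses and lengths), `realized`
#'   (elongation per cell, um), `growth_rate` (realized specific rate,
#'   h^-1), `max_overlap` (residual, um), `iterations`, and `jammed` (TRUE
#'   if the residual tolerance was not reached; logged, never an error).
#' @export
relax_and_grow <- function(cells, contacts, dt, params,
                           wake = c("all", "grown")) {
  wake <- match.arg(wake)
  n <- nrow(cells)
  if (n == 0)
    return(list(cells = cells, realized = numeric(0),
                growth_rate = numeric(0), max_overlap = 0,
                iterations = 0L, jammed = FALSE))
  # overlap below the relaxation residual is solver noise, not pressure
  pressure <- numeric(n)
  if (nrow(contacts)) {
    ov <- pmax(0, contacts$overlap - params$relax_tol)
    pressure <- tabulate_weighted(c(contacts$i, contacts$j), c(ov, ov), n)
  }
  rate <- effective_growth_rate(type_label(cells$type, cells$inhibited),
                                params$alpha, params$delta, params$beta)
  # the growth law acts on the cell length measured pole to pole; the
  # increment is added to the cylinder length (division conserves pole-to-
  # pole extent, so a free lineage's total extent is exactly exponential)
  dL <- unconstrained_elongation(cells$length + 2 * cells$radius, rate, dt,
                                 method = params$growth_update)
  realized <- dL * pmax(0, 1 - params$pressure_kappa * pressure)
  cells$length <- cells$length + realized
  awake <- if (wake == "grown") realized > 0 else NULL
  res <- cpp_relax(cells$x, cells$y, cells$angle, cells$length, cells$radius,
                   params$relax_damping, params$relax_rot_gain,
                   params$relax_tol, params$relax_max_iter,
                   params$relax_skin, 10L, awake)
  cells$x <- res$x
  cells$y <- res$y
  cells$angle <- res$angle
  jammed <- res$max_overlap > params$relax_tol
  ext0 <- cells$length - realized + 2 * cells$radius
  list(cells = cells, realized = realized,
       growth_rate = realized / (ext0 * dt),
       max_overlap = res$max_overlap, iterations = res$iterations,
       jammed = jammed)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Divide cells that have reached their target length
#'
#' A cell divides once its length reaches its target length: the parent
#' capsule is split in half into two daughters whose capsules tile the
#' parent (each daughter cylinder length is `(L - 2r) / 2`, so the summed
#' pole-to-pole extents equal the parent extent exactly). Daughter axes are
#' the parent axis rotated by independent Uniform(-jitter, jitter) angles;
#' each daughter draws a fresh target length from the division-length
#' distribution (normal, truncated below at `2r`). Cell type and inhibition
#' state are inherited; any pending reaction of the parent is the caller's
#' responsibility to discard.
#'
#' @param cells Cell table (columns as in [relax_and_grow()] plus `id`,
#'   `parent_id`, `target_length`).
#' @param params `sim_params`.
#' @param next_id First unused cell id.
#' @return List with `cells`, `next_id`, `divided` (parent ids that divided).
#' @export
maybe_divide <- function(cells, params, next_id) {
  ready <- which(cells$length >= cells$target_length)
  if (!length(ready))
    return(list(cells = cells, next_id = next_id, divided = integer(0)))
  r <- cells$radius[ready]
  L <- cells$length[ready]
  if (any(L < 2 * r))
    stop("cannot split: parent cylinder length below 2 * radius")
  k <- length(ready)
  Ld <- (L - 2 * r) / 2
  off <- (L + 2 * r) / 4
  ux <- cos(cells$angle[ready]); uy <- sin(cells$angle[ready])
  jit <- matrix(stats::runif(2 * k, -params$div_angle_jitter,
                             params$div_angle_jitter), ncol = 2)
  tl <- matrix(rtruncnorm2(2 * k, params$div_length_mean,
                           params$div_length_sd, 2 * params$cell_radius),
               ncol = 2)
  mk <- function(sgn, col) data.frame(
    id = integer(k), parent_id = cells$id[ready],
    x = cells$x[ready] + sgn * off * ux,
    y = cells$y[ready] + sgn * off * uy,
    angle = cells$angle[ready] + jit[, col],
    length = Ld, radius = r,
    type = cells$type[ready], inhibited = cells$inhibited[ready],
    target_length = tl[, col], growth_rate = cells$growth_rate[ready],
    stringsAsFactors = FALSE)
  d1 <- mk(-1, 1)
  d2 <- mk(+1, 2)
  d1$id <- next_id + seq_len(k) - 1L
  d2$id <- next_id + k + seq_len(k) - 1L
  divided <- cells$id[ready]
  cells <- rbind(cells[-ready, , drop = FALSE], d1, d2)
  rownames(cells) <- NULL
  list(cells = cells, next_id = next_id + 2L * k, divided = divided)
}

# normal truncated below at `lo` by resampling (mass below lo is negligible
# at the default geometry but correctness should not depend on that)
rtruncnorm2 <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  for (tries in 1:100) {
    bad <- which(x < lo)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  x[x < lo] <- lo
  x
}
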