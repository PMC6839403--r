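SNAPSHOT_COLS <- c("id", "parent_id", "t_h", "x_um", "y_um", "angle_rad",
                   "length_um", "radius_um", "cell_type", "inhibited",
                   "growth_rate_h")

#' Inoculate a colony
#'
#' Places `N = round(density * pi * r^2 / 1000)` cells uniformly at random
#' (position and axis angle) inside the central disc of radius
#' `inoculum_radius`, assigns exactly `round(N * inhibitor_fraction)`
#' inhibitors by draw without replacement, draws each cell's initial length
#' uniformly between its birth length and its division target length, and
#' relaxes residual overlaps. Consumes R's global RNG; [run_colony()] seeds
#' it from `params$seed` first.
#'
#' @param params `sim_params`.
#' @return A `colony_state`: list with `cells`, `time`, `step`, `queue`,
#'   `next_id`, `params`, and run counters.
#' @export
inoculate <- function(params) {
  validate_sim_params(params)
  N <- round(params$inoculum_density * pi * params$inoculum_radius^2 / 1000)
  if (N == 0) {
    cells <- empty_cells()
  } else {
    rr <- params$inoculum_radius * sqrt(stats::runif(N))
    th <- stats::runif(N, 0, 2 * pi)
    tl <- rtruncnorm2(N, params$div_length_mean, params$div_length_sd,
                      2 * params$cell_radius)
    birth <- (tl - 2 * params$cell_radius) / 2
    len <- stats::runif(N, birth, tl)
    n_inhib <- round(N * params$inhibitor_fraction)
    type <- rep("target", N)
    type[sample.int(N, n_inhib)] <- "inhibitor"
    cells <- data.frame(
      id = seq_len(N), parent_id = 0L,
      x = rr * cos(th), y = rr * sin(th),
      angle = stats::runif(N, 0, 2 * pi),
      length = len, radius = params$cell_radius,
      type = type, inhibited = FALSE,
      target_length = tl, growth_rate = 0,
      stringsAsFactors = FALSE)
    res <- cpp_relax(cells$x, cells$y, cells$angle, cells$length,
                     cells$radius, params$relax_damping,
                     params$relax_rot_gain, params$relax_tol, 1000L,
                     params$relax_skin, 10L)
    if (res$max_overlap > 0.25 * params$cell_radius)
      stop("inoculum too dense to relax (residual overlap ",
           signif(res$max_overlap, 3), " um); reduce inoculum_density or ",
           "increase inoculum_radius")
    cells$x <- res$x; cells$y <- res$y; cells$angle <- res$angle
  }
  structure(list(cells = cells, time = 0, step = 0L,
                 queue = reaction_queue(),
                 next_id = nrow(cells) + 1L, params = params,
                 n_jammed = 0L, n_stale = 0L),
            class = "colony_state")
}

empty_cells <- function() {
  data.frame(id = integer(0), parent_id = integer(0), x = numeric(0),
             y = numeric(0), angle = numeric(0), length = numeric(0),
             radius = numeric(0), type = character(0),
             inhibited = logical(0), target_length = numeric(0),
             growth_rate = numeric(0), stringsAsFactors = FALSE)
}

#' Advance a colony by one timestep
#'
#' Step order: (1) rebuild the contact graph; (2) synchronize pending
#' reactions with it; (3) fire all reactions with `tau` in the step window;
#' (4) grow with type-dependent rates and relax overlaps; (5) divide cells
#' at target length (discarding pending reactions of divided parents — the
#' daughters' reactions are re-derived from their contacts on the next
#' step). Time advances by `dt`; cells are created only by division and
#' never destroyed.
#'
#' @param state A `colony_state`.
#' @return The updated `colony_state`.
#' @export
sim_step <- function(state) {
  p <- state$params
  cells <- state$cells
  if (nrow(cells) == 0) {
    state$time <- state$time + p$dt
    state$step <- state$step + 1L
    return(state)
  }
  contacts <- build_contacts(cells, p$contact_tol)
  sync_reactions(cells, contacts, state$queue, p, state$time)
  fr <- fire_reactions(cells, state$queue, state$time + p$dt)
  cells <- fr$cells
  state$n_stale <- state$n_stale + fr$n_stale
  rg <- relax_and_grow(cells, contacts, p$dt, p)
  cells <- rg$cells
  cells$growth_rate <- rg$growth_rate
  if (rg$jammed) state$n_jammed <- state$n_jammed + 1L
  dv <- maybe_divide(cells, p, state$next_id)
  for (id in dv$divided) rq_remove(state$queue, id)
  state$cells <- dv$cells
  state$next_id <- dv$next_id
  state$time <- state$time + p$dt
  state$step <- state$step + 1L
  state$last_max_overlap <- rg$max_overlap
  state
}

#' Run a colony simulation
#'
#' Seeds the RNG from `params$seed`, inoculates, advances `n_steps`
#' timesteps and collects snapshots every `snapshot_interval` steps plus the
#' final state. Deterministic given `params` (including the seed).
#'
#' @param params `sim_params`.
#' @return A `colony_run`: list with `params`, `snapshots` (list of
#'   `colony_snapshot` tables keyed by time), `final` (the last snapshot),
#'   `n_jammed` steps that hit the relaxation budget, and `wall_s`.
#' @export
run_colony <- function(params) {
  t0 <- proc.time()[["elapsed"]]
  set.seed(params$seed)
  state <- inoculate(params)
  snaps <- list()
  snaps[[1]] <- as_snapshot(state)
  if (params$n_steps >= 1) {
    for (s in seq_len(params$n_steps)) {
      state <- sim_step(state)
      if (s %% params$snapshot_interval == 0 && s != params$n_steps)
        snaps[[length(snaps) + 1L]] <- as_snapshot(state)
      if (params$verbose >= 1 && s %% params$snapshot_interval == 0) {
        cc <- table(factor(type_label(state$cells$type,
                                      state$cells$inhibited),
                           levels = c("TARGET", "INHIBITOR",
                                      "INHIBITED_TARGET")))
        message(sprintf(
          "step %4d t=%6.2fh cells=%6d (T %d / I %d / IT %d) queue=%d maxov=%.3g",
          s, state$time, nrow(state$cells), cc[1], cc[2], cc[3],
          rq_size(state$queue),
          if (is.null(state$last_max_overlap)) 0 else state$last_max_overlap))
      }
    }
    snaps[[length(snaps) + 1L]] <- as_snapshot(state)
  }
  structure(list(params = params, snapshots = snaps,
                 final = snaps[[length(snaps)]],
                 n_jammed = state$n_jammed,
                 wall_s = proc.time()[["elapsed"]] - t0),
            class = "colony_run")
}

#' @export
print.colony_run <- function(x, ...) {
  cat(sprintf(
    "colony_run: %d snapshots, final t = %.2f h, %d cells, %.1f s wall\n",
    length(x$snapshots), attr(x$final, "time"), nrow(x$final), x$wall_s))
  cat(sprintf("  inhibitor proportion %.3f; jammed steps %d; seed %d\n",
              inhibitor_proportion(x$final), x$n_jammed, x$params$seed))
  invisible(x)
}

#' Convert internal state to a snapshot table
#'
#' @param state A `colony_state`.
#' @return A `colony_snapshot` data frame with the canonical column set and
#'   attributes `time`, `seed`, `params_hash`.
#' @export
as_snapshot <- function(state) {
  cells <- state$cells
  snap <- data.frame(
    id = cells$id, parent_id = cells$parent_id,
    t_h = rep(state$time, nrow(cells)),
    x_um = cells$x, y_um = cells$y, angle_rad = cells$angle,
    length_um = cells$length, radius_um = cells$radius,
    cell_type = cells$type, inhibited = as.integer(cells$inhibited),
    growth_rate_h = cells$growth_rate, stringsAsFactors = FALSE)
  structure(snap, time = state$time, seed = state$params$seed,
            params_hash = params_hash(state$params),
            class = c("colony_snapshot", "data.frame"))
}

#' Snapshot file I/O
#'
#' Snapshots are tab-separated tables, one row per cell, with a `#`-prefixed
#' header block carrying the simulation time, RNG seed and parameter hash.
#'
#' @param snap A `colony_snapshot`.
#' @param path File path.
#' @return `path` (write) or the snapshot (read).
#' @export
write_snapshot <- function(snap, path) {
  hdr <- c(sprintf("# time_h=%.10g", attr(snap, "time")),
           sprintf("# seed=%d", attr(snap, "seed")),
           sprintf("# params_hash=%s", attr(snap, "params_hash")),
           sprintf("# n_cells=%d", nrow(snap)))
  writeLines(hdr, path)
  data.table::fwrite(as.data.frame(snap), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  meta <- list()
  for (ln in kv) {
    key <- sub("=.*$", "", ln)
    meta[[key]] <- sub("^[^=]*=", "", ln)
  }
  tab <- data.table::fread(path, sep = "\t", skip = length(hdr),
                           header = TRUE, data.table = FALSE)
  missing <- setdiff(SNAPSHOT_COLS, names(tab))
  extra <- setdiff(names(tab), SNAPSHOT_COLS)
  if (length(missing) || length(extra))
    stop("snapshot schema mismatch: missing [",
         paste(missing, collapse = ", "), "], unexpected [",
         paste(extra, collapse = ", "), "]")
  tab <- tab[, SNAPSHOT_COLS]
  structure(tab,
            time = as.numeric(meta[["time_h"]]),
            seed = if (!is.null(meta[["seed"]]))
              as.integer(meta[["seed"]]) else NA_integer_,
            params_hash = meta[["params_hash"]],
            class = c("colony_snapshot", "data.frame"))
}

#' Cell table of a snapshot in internal (mechanics) layout
#' @param snap A `colony_snapshot`.
#' @return Data frame with columns `id, parent_id, x, y, angle, length,
#'   radius, type, inhibited`.
#' @export
snapshot_cells <- function(snap) {
  data.frame(id = snap$id, parent_id = snap$parent_id, x = snap$x_um,
             y = snap$y_um, angle = snap$angle_rad, length = snap$length_um,
             radius = snap$radius_um, type = snap$cell_type,
             inhibited = as.logical(snap$inhibited),
             stringsAsFactors = FALSE)
}

#' Proportion of inhibitor cells in a snapshot or cell table
#' @param x A `colony_snapshot` or internal cell table.
#' @return Fraction of cells whose type is `"inhibitor"`.
#' @export
inhibitor_proportion <- function(x) {
  type <- if ("cell_type" %in% names(x)) x$cell_type else x$type
  if (!length(type)) return(NA_real_)
  mean(type == "inhibitor")
}

#' Colony radius (maximum cell extent from the cell centroid)
#' @param x A `colony_snapshot` or internal cell table.
#' @return Radius, um.
#' @export
colony_radius <- function(x) {
  xx <- if ("x_um" %in% names(x)) x$x_um else x$x
  yy <- if ("y_um" %in% names(x)) x$y_um else x$y
  ll <- if ("length_um" %in% names(x)) x$length_um else x$length
  rr <- if ("radius_um" %in% names(x)) x$radius_um else x$radius
  if (!length(xx)) return(0)
  cx <- mean(xx); cy <- mean(yy)
  max(sqrt((xx - cx)^2 + (yy - cy)^2) + ll / 2 + rr)
}
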