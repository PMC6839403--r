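#' Simulation parameters
#'
#' Builds the full parameter set for a colony simulation. Defaults encode the
#' standard experiment: cells grow exponentially with rate `alpha`
#' (h^-1), divide at a target length drawn from a truncated normal, and are
#' inoculated at equal inhibitor:target ratio inside a central disc. CDI is
#' controlled by four rates: `eta` (inhibition rate, h^-1 per contacting
#' inhibitor cell), `delta` (toxicity, fractional growth reduction of
#' intoxicated targets), `mu` (recovery rate, h^-1, acting once an inhibited
#' target has lost all inhibitor contacts) and `beta` (fractional growth-rate
#' cost paid by inhibitor cells).
#'
#' @param alpha Maximum specific growth rate, h^-1. Default `log(2) / 0.5`
#'   (30-minute doubling time).
#' @param eta Inhibition rate, h^-1 per contacting inhibitor cell.
#' @param delta Toxicity: fraction of growth rate removed from an inhibited
#'   target, in `[0, 1]`.
#' @param mu Recovery rate, h^-1, for inhibited targets with no inhibitor
#'   contact.
#' @param beta Cost: fractional growth-rate reduction of inhibitor cells, in
#'   `[0, 1)`.
#' @param dt Timestep, h. Default 0.05 (700 steps = 35 h).
#' @param n_steps Number of timesteps.
#' @param inoculum_radius Radius of the inoculation disc, um.
#' @param inoculum_density Inoculation density, cells per 1000 um^2.
#' @param inhibitor_fraction Fraction of inoculated cells that are inhibitors.
#' @param cell_radius Capsule cap radius, um.
#' @param div_length_mean,div_length_sd Mean and sd of the normal division
#'   target length (cylinder length between cap centers, um), truncated below
#'   at `2 * cell_radius`.
#' @param div_angle_jitter Daughter axes are the parent axis rotated by
#'   independent Uniform(-jitter, jitter) angles, rad.
#' @param contact_tol Surface separation (um) at or below which two capsules
#'   count as touching.
#' @param relax_damping Fraction of each pairwise overlap corrected per
#'   relaxation sweep (viscous drag damping).
#' @param relax_rot_gain Gain of the torque-like axis correction.
#' @param relax_tol Residual overlap tolerance, um.
#' @param relax_max_iter Relaxation sweep budget per timestep.
#' @param relax_skin Extra neighbor-list margin (um) used during relaxation.
#' @param pressure_kappa Growth attenuation coefficient, um^-1: realized
#'   elongation = unconstrained elongation x max(0, 1 - kappa * summed
#'   contact overlap in excess of the solver residual). Calibrated so deeply
#'   jammed interior cells (>= 4 contacts) realize under 10% of their
#'   unconstrained elongation and the emergent radial expansion speed
#'   approaches the full-scale experiment's colony size.
#' @param growth_update `"exact"` integrates dL/dt = alpha L exactly over the
#'   step; `"euler"` uses the first-order increment alpha * L * dt.
#' @param seed Integer seed driving all randomness (inoculation, division
#'   noise, reaction waiting times).
#' @param snapshot_interval Steps between stored snapshots (final state is
#'   always included).
#' @param verbose Integer verbosity (0 silent, 1 per-snapshot log lines).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(alpha = log(2) / 0.5,
                       eta = 0,
                       delta = 0,
                       mu = 0.01,
                       beta = 0,
                       dt = 0.05,
                       n_steps = 700L,
                       inoculum_radius = 200,
                       inoculum_density = 160,
                       inhibitor_fraction = 0.5,
                       cell_radius = 0.4,
                       div_length_mean = 3.5,
                       div_length_sd = 0.35,
                       div_angle_jitter = 0.1,
                       contact_tol = 0.05,
                       relax_damping = 0.7,
                       relax_rot_gain = 0.5,
                       relax_tol = 0.01,
                       relax_max_iter = 50L,
                       relax_skin = 0.3,
                       pressure_kappa = 50,
                       growth_update = c("exact", "euler"),
                       seed = 1L,
                       snapshot_interval = 50L,
                       verbose = 0L) {
  p <- list(alpha = alpha, eta = eta, delta = delta, mu = mu, beta = beta,
            dt = dt, n_steps = as.integer(n_steps),
            inoculum_radius = inoculum_radius,
            inoculum_density = inoculum_density,
            inhibitor_fraction = inhibitor_fraction,
            cell_radius = cell_radius,
            div_length_mean = div_length_mean,
            div_length_sd = div_length_sd,
            div_angle_jitter = div_angle_jitter,
            contact_tol = contact_tol,
            relax_damping = relax_damping,
            relax_rot_gain = relax_rot_gain,
            relax_tol = relax_tol,
            relax_max_iter = as.integer(relax_max_iter),
            relax_skin = relax_skin,
            pressure_kappa = pressure_kappa,
            growth_update = match.arg(growth_update),
            seed = as.integer(seed),
            snapshot_interval = as.integer(snapshot_interval),
            verbose = as.integer(verbose))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    "alpha must be >= 0" = p$alpha >= 0,
    "eta must be >= 0" = p$eta >= 0,
    "delta must be in [0, 1]" = p$delta >= 0 && p$delta <= 1,
    "mu must be >= 0" = p$mu >= 0,
    "beta must be in [0, 1)" = p$beta >= 0 && p$beta < 1,
    "dt must be > 0" = p$dt > 0,
    "n_steps must be >= 0" = p$n_steps >= 0,
    "inoculum_radius must be > 0" = p$inoculum_radius > 0,
    "inoculum_density must be >= 0" = p$inoculum_density >= 0,
    "inhibitor_fraction must be in [0, 1]" =
      p$inhibitor_fraction >= 0 && p$inhibitor_fraction <= 1,
    "cell_radius must be > 0" = p$cell_radius > 0,
    "div_length_mean must be > 0" = p$div_length_mean > 0,
    "contact_tol must be >= 0" = p$contact_tol >= 0
  )
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Colony simulation parameters\n")
  cat(sprintf("  growth:  alpha = %.4g /h, dt = %.3g h, %d steps (%.1f h)\n",
              x$alpha, x$dt, x$n_steps, x$n_steps * x$dt))
  cat(sprintf("  CDI:     eta = %.3g /h/cell, delta = %.3g, mu = %.3g /h, beta = %.3g\n",
              x$eta, x$delta, x$mu, x$beta))
  cat(sprintf("  inoculum: radius %.4g um, density %.4g cells/1000 um^2, inhibitor fraction %.3g\n",
              x$inoculum_radius, x$inoculum_density, x$inhibitor_fraction))
  cat(sprintf("  seed = %d, params hash = %s\n", x$seed, params_hash(x)))
  invisible(x)
}

#' Fingerprint of a parameter set
#'
#' 64-bit FNV-1a hash of the canonical key=value serialization, used to stamp
#' snapshot headers so analysis outputs can be traced to the run that
#' produced them.
#' @param params A `sim_params` list.
#' @return Hex string.
#' @export
params_hash <- function(params) {
  keys <- sort(names(params))
  s <- paste(sprintf("%s=%s", keys,
                     vapply(params[keys], function(v)
                       paste(format(v, digits = 15), collapse = ","),
                       character(1))),
             collapse = ";")
  cpp_fnv1a(s)
}

#' Read a flat key = value configuration file
#'
#' The configuration mirrors [sim_params()]: one `key = value` pair per line,
#' `#` comments, every key optional. Unknown keys raise an error naming the
#' key.
#' @param path File path.
#' @return A `sim_params` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  allowed <- names(formals(sim_params))
  bad <- setdiff(names(kv), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(kv, function(v) {
    if (v %in% c("true", "TRUE", "false", "FALSE"))
      return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(sim_params, args)
}

#' Write a configuration file for a parameter set
#' @param params A `sim_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  keys <- setdiff(names(params), "verbose")
  lines <- sprintf("%s = %s", keys,
                   vapply(params[keys], function(v)
                     paste(format(v, digits = 15), collapse = ","),
                     character(1)))
  writeLines(lines, path)
  invisible(path)
}
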