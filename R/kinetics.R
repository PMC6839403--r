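#' Inhibition propensity of a target cell
#'
#' The hazard of intoxication is `eta` per hour per contacting inhibitor
#' cell, so a target touching `k` inhibitors has propensity `eta * k` and an
#' exponential waiting time with mean `1 / (eta * k)` while the contact set
#' is unchanged.
#'
#' @param target_id Row index of the target cell.
#' @param contacts `contact_graph` for the current poses.
#' @param cell_types Character vector, `"target"` / `"inhibitor"` per cell.
#' @param eta Inhibition rate, h^-1 per contacting inhibitor.
#' @return Propensity, h^-1 (0 when no inhibitor is in contact).
#' @export
inhibition_propensity <- function(target_id, contacts, cell_types, eta) {
  k <- contact_counts(contacts, n_cells = length(cell_types),
                      which_cells = which(cell_types == "inhibitor"))
  eta * k[target_id]
}

#' Synchronize pending reactions with the current contact graph
#'
#' Enforces the next-reaction bookkeeping after contacts have been rebuilt:
#' every uninhibited target with `k >= 1` inhibitor contacts holds exactly
#' one pending `INHIBITION` reaction with propensity `eta * k` (scheduled
#' fresh on first contact, rescaled when `k` changes, removed at `k = 0` —
#' a target that loses contact before firing is never inhibited); every
#' inhibited target with zero inhibitor contacts holds exactly one pending
#' `RECOVERY` reaction at rate `mu` (removed if contact is re-established).
#'
#' @param cells Cell table (`id`, `type`, `inhibited`, ...).
#' @param contacts `contact_graph` built for `cells`.
#' @param q `reaction_queue` (modified in place).
#' @param params `sim_params` (uses `eta`, `mu`).
#' @param now Current time, h.
#' @return `q`, invisibly.
#' @export
sync_reactions <- function(cells, contacts, q, params, now) {
  n <- nrow(cells)
  inhib_rows <- which(cells$type == "inhibitor")
  k <- contact_counts(contacts, n_cells = n, which_cells = inhib_rows)
  desired_a <- numeric(n)
  desired_kind <- character(n)
  tg <- cells$type == "target" & !cells$inhibited
  it <- cells$type == "target" & cells$inhibited
  desired_a[tg] <- params$eta * k[tg]
  desired_kind[tg] <- "INHIBITION"
  rec <- it & k == 0
  desired_a[rec] <- params$mu
  desired_kind[rec] <- "RECOVERY"

  pend_a <- numeric(n)
  pend_kind <- character(n)
  if (q$n > 0L) {
    rows <- match(q$cell[seq_len(q$n)], cells$id)
    live <- !is.na(rows)
    pend_a[rows[live]] <- q$a[seq_len(q$n)][live]
    pend_kind[rows[live]] <- q$kind[seq_len(q$n)][live]
  }
  changed <- which(desired_a != pend_a | (desired_a > 0 &
                                          desired_kind != pend_kind))
  for (r in changed) {
    id <- cells$id[r]
    if (pend_a[r] > 0 && (desired_a[r] == 0 ||
                          desired_kind[r] != pend_kind[r])) {
      rq_remove(q, id)
      pend_a[r] <- 0
    }
    if (desired_a[r] > 0) {
      if (pend_a[r] > 0) {
        rq_rescale(q, id, desired_a[r], now)
      } else {
        rq_schedule(q, desired_kind[r], id, desired_a[r], now)
      }
    }
  }
  invisible(q)
}

#' Fire due reactions within a step window
#'
#' Pops reactions in increasing `tau` order while `tau <= t_end` and applies
#' them: `INHIBITION` turns a target into an inhibited target (its growth
#' multiplier `1 - delta` applies from the next mechanics step); `RECOVERY`
#' reverts an inhibited target to a plain target. A reaction whose cell id no
#' longer exists (the parent divided) is dropped as stale.
#'
#' @param cells Cell table.
#' @param q `reaction_queue`.
#' @param t_end End of the step window, h.
#' @return List with updated `cells`, `n_fired`, `n_stale`.
#' @export
fire_reactions <- function(cells, q, t_end) {
  n_fired <- 0L
  n_stale <- 0L
  repeat {
    top <- rq_peek(q)
    if (is.null(top) || top$tau > t_end) break
    rq_pop(q)
    r <- match(top$cell_id, cells$id)
    if (is.na(r)) {
      n_stale <- n_stale + 1L
      next
    }
    if (top$kind == "INHIBITION") {
      cells$inhibited[r] <- TRUE
    } else {
      cells$inhibited[r] <- FALSE
    }
    n_fired <- n_fired + 1L
  }
  list(cells = cells, n_fired = n_fired, n_stale = n_stale)
}
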