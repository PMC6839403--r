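#' Reaction queue for the next-reaction method
#'
#' An indexed binary min-heap of pending stochastic reactions keyed by
#' putative firing time. Each cell carries at most one pending reaction
#' (an uninhibited target may await `INHIBITION`; an isolated inhibited
#' target may await `RECOVERY`; the two states are mutually exclusive), so
#' the heap is indexed by cell id. `peek`/`pop` return the globally minimal
#' firing time; insert, remove and rescale are O(log n).
#'
#' The next-reaction method draws one exponential waiting time per reaction
#' when it first becomes possible and, when its propensity changes from
#' `a_old` to `a_new` at time `now`, reuses the remaining wait by rescaling
#' `tau' = now + (a_old / a_new) * (tau - now)`. With `a_new = 0` the
#' reaction is removed; if it later becomes possible again a fresh
#' exponential is drawn (memorylessness makes this exact).
#'
#' @return `reaction_queue()` returns an empty queue (an environment of class
#'   `reaction_queue`).
#' @export
reaction_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$n <- 0L
  q$tau <- numeric(64)
  q$cell <- integer(64)
  q$kind <- character(64)
  q$a <- numeric(64)
  q$pos <- new.env(parent = emptyenv()) # cell id -> heap position
  class(q) <- "reaction_queue"
  q
}

#' @rdname reaction_queue
#' @param q A `reaction_queue`.
#' @export
rq_size <- function(q) q$n

#' @rdname reaction_queue
#' @param cell_id Integer cell id.
#' @export
rq_has <- function(q, cell_id) {
  !is.null(get0(as.character(cell_id), envir = q$pos))
}

rq_swap <- function(q, i, j) {
  for (f in c("tau", "cell", "kind", "a")) {
    v <- q[[f]]; tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp; q[[f]] <- v
  }
  assign(as.character(q$cell[i]), i, envir = q$pos)
  assign(as.character(q$cell[j]), j, envir = q$pos)
}

rq_up <- function(q, i) {
  while (i > 1L) {
    p <- i %/% 2L
    if (q$tau[p] <= q$tau[i]) break
    rq_swap(q, i, p)
    i <- p
  }
  i
}

rq_down <- function(q, i) {
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= q$n && q$tau[l] < q$tau[m]) m <- l
    if (r <= q$n && q$tau[r] < q$tau[m]) m <- r
    if (m == i) break
    rq_swap(q, i, m)
    i <- m
  }
  i
}

#' Schedule a reaction
#'
#' Draws the putative firing time `tau = now + E / a`, `E ~ Exponential(1)`
#' (equivalently `Exponential(a)`), from R's global RNG and enqueues it.
#'
#' @param q A `reaction_queue`.
#' @param kind `"INHIBITION"` or `"RECOVERY"`.
#' @param cell_id Integer cell id.
#' @param a Propensity, h^-1 (> 0).
#' @param now Current simulation time, h.
#' @return The pending reaction, invisibly (list of `kind`, `cell_id`, `a`,
#'   `tau`).
#' @export
rq_schedule <- function(q, kind, cell_id, a, now) {
  stopifnot(kind %in% c("INHIBITION", "RECOVERY"))
  if (a <= 0) stop("cannot schedule a reaction with propensity <= 0")
  if (rq_has(q, cell_id))
    stop("contract violation: duplicate pending reaction for cell ", cell_id)
  tau <- now + stats::rexp(1) / a
  n <- q$n + 1L
  if (n > length(q$tau)) {
    grow <- function(v) c(v, v)
    q$tau <- grow(q$tau); q$cell <- grow(q$cell)
    q$kind <- grow(q$kind); q$a <- grow(q$a)
  }
  q$n <- n
  q$tau[n] <- tau; q$cell[n] <- as.integer(cell_id)
  q$kind[n] <- kind; q$a[n] <- a
  assign(as.character(cell_id), n, envir = q$pos)
  rq_up(q, n)
  invisible(list(kind = kind, cell_id = as.integer(cell_id), a = a,
                 tau = tau))
}

#' Rescale or remove a pending reaction after a propensity change
#'
#' @param q A `reaction_queue`.
#' @param cell_id Cell whose pending reaction changed.
#' @param a_new New propensity (>= 0); 0 removes the reaction.
#' @param now Current time, h (must not exceed the pending `tau`).
#' @return Updated pending reaction (or `NULL` if removed), invisibly.
#' @export
rq_rescale <- function(q, cell_id, a_new, now) {
  i <- get0(as.character(cell_id), envir = q$pos)
  if (is.null(i)) stop("no pending reaction for cell ", cell_id)
  if (a_new == 0) {
    rq_remove(q, cell_id)
    return(invisible(NULL))
  }
  a_old <- q$a[i]
  tau_new <- now + (a_old / a_new) * (q$tau[i] - now)
  q$tau[i] <- tau_new
  q$a[i] <- a_new
  i <- rq_up(q, i)
  rq_down(q, i)
  invisible(list(kind = q$kind[get0(as.character(cell_id), envir = q$pos)],
                 cell_id = as.integer(cell_id), a = a_new, tau = tau_new))
}

#' @rdname reaction_queue
#' @export
rq_remove <- function(q, cell_id) {
  i <- get0(as.character(cell_id), envir = q$pos)
  if (is.null(i)) return(invisible(FALSE))
  n <- q$n
  rm(list = as.character(cell_id), envir = q$pos)
  if (i != n) {
    q$tau[i] <- q$tau[n]; q$cell[i] <- q$cell[n]
    q$kind[i] <- q$kind[n]; q$a[i] <- q$a[n]
    assign(as.character(q$cell[i]), i, envir = q$pos)
  }
  q$n <- n - 1L
  if (i <= q$n) {
    i <- rq_up(q, i)
    rq_down(q, i)
  }
  invisible(TRUE)
}

#' @rdname reaction_queue
#' @export
rq_peek <- function(q) {
  if (q$n == 0L) return(NULL)
  list(kind = q$kind[1], cell_id = q$cell[1], a = q$a[1], tau = q$tau[1])
}

#' @rdname reaction_queue
#' @export
rq_pop <- function(q) {
  top <- rq_peek(q)
  if (is.null(top)) return(NULL)
  rq_remove(q, top$cell_id)
  top
}
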