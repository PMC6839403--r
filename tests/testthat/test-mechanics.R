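test_that("effective_growth_rate implements the three-type rates", {
  expect_equal(effective_growth_rate("INHIBITED_TARGET", 1.2, 1.0, 0), 0)
  expect_equal(effective_growth_rate("INHIBITED_TARGET", 1.0, 0.2, 0), 0.8)
  expect_equal(effective_growth_rate("INHIBITOR", 1.0, 0.7, 0.05), 0.95)
  expect_equal(effective_growth_rate("TARGET", 2.5, 1.0, 0.5), 2.5)
  expect_equal(
    effective_growth_rate(c("TARGET", "INHIBITOR", "INHIBITED_TARGET"),
                          1, 0.2, 0.1),
    c(1, 0.9, 0.8))
  expect_error(effective_growth_rate("ZOMBIE", 1, 0, 0), "unknown cell type")
})

test_that("unconstrained elongation follows the growth law", {
  expect_equal(unconstrained_elongation(2, 1, 0.05, method = "euler"), 0.1)
  expect_equal(unconstrained_elongation(2, 0, 0.05), 0)
  # repeated Euler application compounds to L (1 + r dt)^n and approaches
  # the exponential as dt -> 0
  L <- 1; dt <- 1e-4; r <- 1.5
  for (i in 1:1000) L <- L + unconstrained_elongation(L, r, dt,
                                                      method = "euler")
  expect_equal(L, (1 + r * dt)^1000, tolerance = 1e-9)
  expect_equal(L, exp(r * 0.1), tolerance = 1e-4)
  # exact update reproduces the exponential at any step size
  expect_equal(2 + unconstrained_elongation(2, 1.5, 0.3), 2 * exp(1.5 * 0.3))
})

test_that("relax_and_grow leaves isolated cells in place with full growth", {
  p <- sim_params()
  cells <- make_cells(x = c(0, 50), y = c(0, 0), length = 2)
  g <- build_contacts(cells, p$contact_tol)
  res <- relax_and_grow(cells, g, p$dt, p)
  expect_equal(res$cells$x, cells$x)
  expect_equal(res$cells$y, cells$y)
  expect_equal(res$cells$angle, cells$angle)
  expect_equal(res$realized,
               unconstrained_elongation(cells$length + 2 * cells$radius,
                                        p$alpha, p$dt))
  expect_false(res$jammed)
})

test_that("two overlapping coaxial cells are pushed apart symmetrically", {
  p <- sim_params(alpha = 0)  # pure relaxation
  # cores 2.6 apart, touching would need 2.8: overlap 0.2
  cells <- make_cells(x = c(0, 2.6), y = 0, length = 2, radius = 0.4)
  g <- build_contacts(cells, p$contact_tol)
  res <- relax_and_grow(cells, g, p$dt, p)
  # analytic pushout: each cell moves outward by half the overlap
  expect_lt(abs(res$cells$x[1] - (-0.1)), p$relax_tol + 1e-9)
  expect_lt(abs(res$cells$x[2] - 2.7), p$relax_tol + 1e-9)
  expect_equal(res$cells$x[1] + res$cells$x[2], 2.6, tolerance = 1e-9)
  g2 <- build_contacts(res$cells, 0)
  expect_true(nrow(g2) == 0 || max(g2$overlap) <= p$relax_tol)
})

test_that("interior cells grow less than boundary cells in a dense cluster", {
  p <- sim_params()
  set.seed(5)
  # jammed disc: 50 cells packed, grown into each other (skip relaxation by
  # building contacts on an over-dense configuration)
  cells <- make_cells(x = runif(50, -7, 7), y = runif(50, -7, 7),
                      angle = runif(50, 0, 2 * pi), length = 3)
  g <- build_contacts(cells, p$contact_tol)
  res <- relax_and_grow(cells, g, p$dt, p)
  k <- contact_counts(g)
  interior <- k >= 3
  boundary <- k <= 1
  expect_gte(sum(interior), 3)  # seed-fixed configuration
  expect_gte(sum(boundary), 3)
  frac <- res$realized / unconstrained_elongation(
    cells$length + 2 * cells$radius, p$alpha, p$dt)
  expect_lt(mean(frac[interior]), mean(frac[boundary]))
})

test_that("division splits at target length and conserves extent", {
  p <- sim_params()
  cells <- make_cells(x = 0, y = 0, length = 4, radius = 0.4)
  cells$target_length <- 4.5
  res <- maybe_divide(cells, p, next_id = 2L)
  expect_equal(nrow(res$cells), 1)            # below target: unchanged
  cells$target_length <- 4.0
  set.seed(1)
  res <- maybe_divide(cells, p, next_id = 2L)
  expect_equal(nrow(res$cells), 2)
  expect_equal(res$cells$length, c(1.6, 1.6))
  # summed pole-to-pole extents equal the parent extent
  expect_equal(sum(res$cells$length + 2 * res$cells$radius), 4 + 0.8)
  # daughters tile the parent: centers at +/- (L + 2r)/4 along the axis
  expect_equal(sort(res$cells$x), c(-1.2, 1.2))
  expect_equal(res$cells$parent_id, c(1L, 1L))
  expect_equal(sort(res$cells$id), c(2L, 3L))
  expect_equal(res$next_id, 4L)
  # a parent too short to split is a geometry error
  shorty <- make_cells(x = 0, y = 0, length = 0.5, radius = 0.4)
  shorty$target_length <- 0.4
  expect_error(maybe_divide(shorty, p, 2L), "cannot split")
})

test_that("daughter targets and orientation jitter match the configuration", {
  p <- sim_params()
  set.seed(21)
  n <- 5000
  cells <- make_cells(x = seq_len(n) * 10, y = 0, length = 4, radius = 0.4)
  cells$target_length <- 4
  res <- maybe_divide(cells, p, next_id = n + 1L)
  expect_equal(nrow(res$cells), 2 * n)
  tl <- res$cells$target_length
  se_mean <- p$div_length_sd / sqrt(2 * n)
  expect_lt(abs(mean(tl) - p$div_length_mean), 3 * se_mean)
  expect_lt(abs(sd(tl) - p$div_length_sd), 3 * p$div_length_sd / sqrt(4 * n))
  dang <- res$cells$angle  # parent angle was 0
  expect_lte(max(abs(dang)), p$div_angle_jitter)
  expect_gt(sd(dang), 0)
})

test_that("free lineage extent doubles every ln2/alpha within 1%", {
  # pressure_kappa = 0 isolates the growth law from mechanical constraint
  p <- sim_params(inoculum_radius = 5, inoculum_density = 1000 / (pi * 25),
                  n_steps = 60L, pressure_kappa = 0, seed = 2)
  run <- run_colony(p)
  s0 <- run$snapshots[[1]]
  s1 <- run$final
  expect_equal(nrow(s0), 1)
  E0 <- sum(s0$length_um + 2 * s0$radius_um)
  E1 <- sum(s1$length_um + 2 * s1$radius_um)
  t_el <- attr(s1, "time") - attr(s0, "time")
  doubling <- t_el * log(2) / log(E1 / E0)
  expect_lt(abs(doubling - log(2) / p$alpha) / (log(2) / p$alpha), 0.01)
})
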