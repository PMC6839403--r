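test_that("neighbor index evaluates the log2 ratio change", {
  expect_equal(neighbor_index(4, 4, 6, 6), 0)
  expect_equal(neighbor_index(4, 4, 8, 4), 1)
  expect_equal(neighbor_index(3, 6, 10, 5), 2)  # log2(2) - log2(0.5)
  expect_error(neighbor_index(0, 4, 6, 6), "undefined")
  # any snapshot against itself is 0
  set.seed(1)
  for (k in 1:10) {
    v <- sample.int(50, 2)
    expect_equal(neighbor_index(v[1], v[2], v[1], v[2]), 0)
  }
})

test_that("interface_counts counts cells touching the other strain", {
  # straight interface: 5 inhibitors above, 5 targets below, pairs touching
  cells <- make_cells(x = rep(seq(0, 12, by = 3), 2),
                      y = rep(c(0.42, -0.42), each = 5),
                      angle = 0, length = 2, radius = 0.4,
                      type = rep(c("inhibitor", "target"), each = 5))
  expect_equal(interface_counts(cells), c(I = 5, T = 5))
  solo <- make_cells(x = c(0, 3), y = 0, type = "target")
  expect_equal(interface_counts(solo), c(I = 0, T = 0))
  # inhibited targets count as targets
  cells$inhibited[6] <- TRUE
  expect_equal(interface_counts(cells), c(I = 5, T = 5))
})

test_that("interface_counts equals a brute-force all-pairs count", {
  set.seed(23)
  cells <- random_cells(100, box = 12)
  cells$type <- sample(c("target", "inhibitor"), 100, replace = TRUE)
  o <- contacts_oracle(cells, 0.05)
  is_inh <- cells$type == "inhibitor"
  touched_by_target <- unique(c(o$i[!is_inh[o$j]], o$j[!is_inh[o$i]]))
  touched_by_inhib <- unique(c(o$i[is_inh[o$j]], o$j[is_inh[o$i]]))
  expect_equal(
    unname(interface_counts(cells)),
    c(sum(is_inh[touched_by_target]), sum(!is_inh[touched_by_inhib])))
})

test_that("radial_profile bins cells exactly and keeps every cell", {
  set.seed(31)
  n <- 400
  r <- 60 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cells <- make_cells(x = r * cos(th), y = r * sin(th),
                      type = sample(c("target", "inhibitor"), n,
                                    replace = TRUE))
  prof <- radial_profile(cells, annulus_width = 20, sectors = FALSE)
  expect_equal(sum(prof$n_inhib + prof$n_target), n)
  # oracle: direct distance binning around the centroid
  cx <- mean(cells$x); cy <- mean(cells$y)
  idx <- floor(sqrt((cells$x - cx)^2 + (cells$y - cy)^2) / 20)
  for (a in prof$annulus) {
    expect_equal(prof$n_inhib[prof$annulus == a],
                 sum(idx == a & cells$type == "inhibitor"))
  }
  # uniform 50/50 disc: all well-populated annuli close to 0.5
  pop <- prof$n_inhib + prof$n_target >= 50
  expect_true(all(abs(prof$ratio[pop] - 0.5) < 0.2))
})

test_that("radial_profile reproduces a radial step function", {
  set.seed(5)
  n <- 600
  r <- c(runif(n / 2, 0, 39), runif(n / 2, 41, 80))
  th <- runif(n, 0, 2 * pi)
  cells <- make_cells(x = r * cos(th), y = r * sin(th),
                      type = c(rep("target", n / 2), rep("inhibitor", n / 2)))
  cells$x <- cells$x - mean(cells$x)  # keep centroid at the origin
  cells$y <- cells$y - mean(cells$y)
  prof <- radial_profile(cells, annulus_width = 20, sectors = FALSE)
  expect_lt(prof$ratio[1], 0.1)
  expect_gt(prof$ratio[4], 0.9)
  expect_error(radial_profile(cells[0, ], 20), "empty")
})

test_that("sector strips smooth to stable binary patterns", {
  # a full inhibitor ring
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  ring <- make_cells(x = 30 * cos(th), y = 30 * sin(th),
                     type = "inhibitor")
  strip <- sector_strip(ring, center = c(0, 0))
  expect_true(all(strip == 1))
  expect_equal(count_sectors(strip), 0)
  sz <- sector_sizes(strip)
  expect_equal(sz$largest_inhib, 2 * pi)
  expect_equal(sz$largest_target, 0)
  # half/half split: both largest sectors are pi (within a bin)
  half <- make_cells(x = 30 * cos(th), y = 30 * sin(th),
                     type = ifelse(th < pi, "inhibitor", "target"))
  s2 <- sector_strip(half, center = c(0, 0))
  expect_equal(count_sectors(s2), 1)
  sz2 <- sector_sizes(s2)
  bin <- 2 * pi / length(s2)
  expect_lt(abs(sz2$largest_target - pi), 3 * bin)
  expect_lt(abs(sz2$largest_inhib - pi), 3 * bin)
})

test_that("smoothing removes singletons and fixes clean blocks", {
  # singleton removal on a nearly homogeneous strip
  x <- rep(1, 40); x[7] <- 0
  sm <- as.numeric(smooth_circular(x, 3) >= 0.5)
  expect_true(all(sm == 1))
  # two clean 30-bin blocks are a fixed point (idempotence)
  blocks <- rep(c(1, 0), each = 30)
  pass1 <- as.numeric(smooth_circular(blocks, 3) >= 0.5)
  expect_equal(pass1, blocks)
  expect_equal(as.numeric(smooth_circular(pass1, 3) >= 0.5), pass1)
  # smoothing preserves the mean of a circular strip
  set.seed(2)
  y <- runif(50)
  expect_equal(mean(smooth_circular(y, 3)), mean(y))
})

test_that("count_sectors and sector_sizes follow circular run structure", {
  strip <- c(rep(1, 30), rep(0, 10), rep(1, 5), rep(0, 20))  # I30 T10 I5 T20
  expect_equal(count_sectors(strip), 2)
  sz <- sector_sizes(strip, outer_radius = 40, largest_annulus_radius = 80)
  expect_equal(sz$largest_target, 20 * 2 * pi / 65)
  expect_equal(sz$largest_inhib, 30 * 2 * pi / 65)
  expect_equal(sz$norm_factor, 0.5)
  # one target block in an inhibitor ring
  expect_equal(count_sectors(c(rep(1, 50), rep(0, 7), rep(1, 8))), 1)
  expect_equal(count_sectors(rep(0, 30)), 0)
  # rotation invariance and joint relabeling invariance
  set.seed(44)
  for (k in 1:25) {
    s <- as.numeric(smooth_circular(runif(60) > 0.5, 3) >= 0.5)
    rot <- sample.int(60, 1)
    s_rot <- c(s[-seq_len(rot)], s[seq_len(rot)])
    expect_equal(count_sectors(s_rot), count_sectors(s))
    expect_equal(count_sectors(1 - s), count_sectors(s))
  }
})

test_that("relative fitness is the ratio of log fold-changes", {
  expect_equal(relative_fitness(10, 40, 10, 40), 1)
  expect_equal(relative_fitness(10, 40, 10, 20), 2)   # ln4 / ln2
  expect_equal(relative_fitness(10, 20, 10, 40), 0.5)
  expect_error(relative_fitness(10, 20, 10, 10), "did not grow")
  expect_error(relative_fitness(0, 20, 10, 40), "undefined")
})
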