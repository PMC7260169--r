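test_that("filling fraction counts material voxels", {
  expect_equal(fill_fraction(binary_volume(array(0L, c(4, 4, 4)))), 100)
  idx <- expand.grid(x = 1:8, y = 1:8, z = 1:8)
  checker <- array(as.integer((idx$x + idx$y + idx$z) %% 2), c(8, 8, 8))
  expect_equal(fill_fraction(binary_volume(checker)), 50)
  set.seed(71)
  bern <- array(rbinom(200^3, 1, 0.69), c(200, 200, 200))
  expect_equal(fill_fraction(bern), 31, tolerance = 0.2 / 31)
  # invariance under axis permutation and reflection
  m <- array(rbinom(4 * 5 * 6, 1, 0.4), c(4, 5, 6))
  expect_equal(fill_fraction(aperm(m, c(3, 1, 2))), fill_fraction(m))
  expect_equal(fill_fraction(m[4:1, , ]), fill_fraction(m))
})

test_that("cube sampling is seeded, in bounds, and validates geometry", {
  set.seed(5)
  mask <- binary_volume(array(rbinom(60 * 70 * 80, 1, 0.6), c(60, 70, 80)))
  cubes <- sample_cubes(mask, edge = 16, n = 30, seed = 9,
                        interior_margin = 4)
  expect_length(cubes, 30)
  for (cb in cubes) {
    expect_true(all(cb$corner >= 5))
    expect_true(all(cb$corner + 15 <= c(60, 70, 80) - 4))
    expect_equal(dim(cb$data), c(16, 16, 16))
  }
  cubes2 <- sample_cubes(mask, edge = 16, n = 30, seed = 9,
                         interior_margin = 4)
  expect_identical(lapply(cubes, `[[`, "corner"),
                   lapply(cubes2, `[[`, "corner"))
  expect_error(sample_cubes(mask, edge = 100, n = 2, seed = 1,
                            interior_margin = 0), "infeasible")
})

test_that("fill statistics summarise per-cube fills", {
  cb <- function(f) structure(list(corner = c(1, 1, 1), edge = 4L,
                                   data = array(as.integer(
                                     c(rep(0, f), rep(1, 64 - f))),
                                     c(4, 4, 4))),
                              class = "cube_sample")
  same <- structure(list(cb(20), cb(20), cb(20)), class = "cube_samples")
  fs <- fill_stats(same)
  expect_equal(fs$sd, 0)
  # two cubes with fills of exactly 30 and 32 percent
  fs2 <- fill_stats(structure(list(
    structure(list(data = array(c(rep(0L, 30), rep(1L, 70)), c(10, 10, 1))),
              class = "cube_sample"),
    structure(list(data = array(c(rep(0L, 32), rep(1L, 68)), c(10, 10, 1))),
              class = "cube_sample")), class = "cube_samples"))
  expect_equal(fs2$mean, 31)
  expect_equal(fs2$sd, sqrt(2))
  expect_error(fill_stats(same[1]), "2 cubes")
})

test_that("cube fill means converge to the interior fill", {
  sc <- make_scale(c(96, 96, 200), seed = 4, correlation_length_nm = 100)
  margins <- c(sc$cfg$cuticle_thickness_voxels + 2, 2, 2)
  cubes <- sample_cubes(sc$truth, edge = 48, n = 60, seed = 4,
                        interior_margin = margins)
  fs <- fill_stats(cubes)
  # per-cube sd is a few percent at this cube-to-structure ratio, so the
  # 60-cube mean should sit within ~3 standard errors of the region fill
  expect_lt(abs(fs$mean - interior_fill_fraction(sc$truth, margins)), 2)
  expect_lt(abs(fs$mean - 31), 2)
})

test_that("S2 is definitional at lag zero and flat for saturated cubes", {
  set.seed(81)
  cube <- array(rbinom(20^3, 1, 0.55), c(20, 20, 20))
  for (dd in c("x", "y", "z")) {
    cc <- directional_correlation(cube, dd, 8)
    expect_equal(cc$s2[1], fill_fraction(cube) / 100)
    expect_true(all(cc$s2 <= cc$s2[1] + 1e-12))
    expect_true(all(cc$s2 >= 0))
  }
  solid <- array(0L, c(10, 10, 10))
  cc <- directional_correlation(solid, "z", 5)
  expect_true(all(cc$s2 == 1))
  expect_error(directional_correlation(solid, "z", 10), "r_max")
})

test_that("S2 of an iid Bernoulli cube sits at phi squared", {
  set.seed(3)
  e <- 32; phi <- 0.4
  cube <- array(ifelse(runif(e^3) < phi, 0L, 1L), c(e, e, e))
  cc <- directional_correlation(cube, "z", 6)
  for (r in c(1, 2, 5)) {
    n_pairs <- (e - r) * e^2
    # independence expectation; variance includes overlapping-pair covariance
    se <- sqrt((phi^2 * (1 - phi^2) + 2 * (phi^3 - phi^4)) / n_pairs)
    expect_lt(abs(cc$s2[r + 1] - phi^2), 3 * se)
  }
})

test_that("S2 curves respect the period of a translated lattice", {
  # layered structure, period 8 along x (material at residues 0-2)
  master <- array(as.integer((0:31) %% 8 >= 3), c(32, 8, 8))
  a <- master[1:24, , ]   # window starting at phase 0
  b <- master[9:32, , ]   # the same structure translated by one period
  c1 <- directional_correlation(a, "x", 10)
  c2 <- directional_correlation(b, "x", 10)
  expect_equal(c1$s2, c2$s2)
  # at a full-period lag over a whole number of periods, S2 returns to the
  # filling fraction exactly
  expect_equal(c1$s2[9], c1$s2[1])
  expect_equal(c1$s2[1], 3 / 8)
})

test_that("the representative cube minimises deviation from the mean curves", {
  set.seed(91)
  mk <- function(p) structure(list(corner = c(1, 1, 1), edge = 16L,
                                   data = array(rbinom(16^3, 1, 1 - p),
                                                c(16, 16, 16))),
                              class = "cube_sample")
  identical_cubes <- structure(rep(list(mk(0.4)), 4), class = "cube_samples")
  idx <- representative_cube(identical_cubes, r_max = 6)
  expect_equal(as.integer(idx), 1L)  # tie-break to the lowest index

  cubes <- structure(c(replicate(9, mk(0.4), simplify = FALSE),
                       list(structure(list(corner = c(1, 1, 1), edge = 16L,
                                           data = array(0L, c(16, 16, 16))),
                                      class = "cube_sample"))),
                     class = "cube_samples")
  win <- representative_cube(cubes, r_max = 6)
  expect_true(as.integer(win) != 10L)
  scores <- attr(win, "scores")
  expect_true(all(scores[as.integer(win)] <= scores))
  expect_equal(which.max(scores), 10L)

  single <- structure(list(mk(0.4)), class = "cube_samples")
  s1 <- representative_cube(single, r_max = 6)
  expect_equal(as.integer(s1), 1L)
  expect_equal(attr(s1, "scores"), 0)
})
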