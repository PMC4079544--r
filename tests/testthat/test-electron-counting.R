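counting_fixture <- function(occ = 0.5, spacing = 0.4) {
  site <- toy_binding_site(occ)
  map <- render_map(site$structure, spacing)
  mask <- build_mask(site$structure, map, 2.5)
  env <- build_envelope(site$structure, map, radius = 2.5, ligand_mask = mask)
  ctx <- counting_context(site$ligand_electrons, site$water_electrons,
                          site$protein_electrons, env)
  list(site = site, map = map, mask = mask, ctx = ctx)
}

test_that("leveling recovers additive offsets and is idempotent", {
  fx <- counting_fixture()
  leveled <- level_to_absolute(fx$map, fx$ctx)
  # a rendered map is already near-absolute: offset is tiny
  expect_lt(abs(leveled$f000_offset), 1e-3)
  shifted <- fx$map
  shifted$grid <- shifted$grid - 0.25
  shifted$absolute_scale <- FALSE
  releveled <- level_to_absolute(shifted, fx$ctx)
  expect_equal(releveled$f000_offset, 0.25, tolerance = 1e-3)
  expect_true(releveled$absolute_scale)
  twice <- level_to_absolute(releveled, fx$ctx)
  expect_equal(twice$grid, releveled$grid, tolerance = 1e-12)
  # zeroed F000 term: envelope content restored to the protein electrons
  refl <- structure_factors(fx$map)
  flat <- map_from_reflections(refl, zero_f000 = TRUE)
  expect_false(flat$absolute_scale)
  fixed <- level_to_absolute(flat, fx$ctx)
  vv <- voxel_volume(fixed)
  expect_equal(sum(fixed$grid[fx$ctx$envelope]) * vv,
               fx$site$protein_electrons, tolerance = 1e-9)
})

test_that("mask building matches brute-force voxel enumeration", {
  fx <- counting_fixture()
  dims <- dim(fx$map$grid)
  cell <- fx$map$cell
  lig <- fx$site$structure[fx$site$structure$role == "ligand", ]
  dx <- cell / dims
  brute <- array(FALSE, dims)
  for (ix in 1:dims[1]) for (iy in 1:dims[2]) for (iz in 1:dims[3]) {
    p <- c((ix - 1) * dx[1], (iy - 1) * dx[2], (iz - 1) * dx[3])
    for (a in seq_len(nrow(lig))) {
      d <- abs(p - c(lig$x[a], lig$y[a], lig$z[a]))
      d <- pmin(d, cell - d)
      if (sum(d^2) <= 2.5^2) { brute[ix, iy, iz] <- TRUE; break }
    }
  }
  expect_equal(as.vector(fx$mask), as.vector(brute))

  # exclusions always win over includes
  ex <- list(list(center = c(lig$x[1], lig$y[1], lig$z[1]), radius = 30))
  expect_warning(
    m0 <- build_mask(fx$site$structure, fx$map, 2.5, exclusions = ex),
    "empty")
  expect_equal(sum(m0), 0)
  small_ex <- list(list(center = c(lig$x[1], lig$y[1], lig$z[1]), radius = 1))
  m1 <- build_mask(fx$site$structure, fx$map, 2.5, exclusions = small_ex)
  expect_true(sum(m1) < sum(fx$mask))
  expect_false(any(m1 & soakfit:::sphere_voxels(
    dims, cell, c(lig$x[1], lig$y[1], lig$z[1]), 1)))
  expect_error(build_mask(fx$site$structure, fx$map, 0), "include_radius")
})

test_that("masked integration counts the electrons it should", {
  lone <- toy_structure(c(6, 8), x = c(3, 9), y = c(5, 5), z = c(5, 5),
                        b_factor = c(25, 30), occupancy = c(1, 1),
                        role = c("protein", "ligand"), cell = c(14, 10, 10))
  map <- render_map(lone, 0.4)
  mask <- build_mask(lone, map, include_radius = 2.5)
  expect_equal(integrate_electrons(map, mask), 8, tolerance = 0.02 * 8)
  half <- lone; half$occupancy[2] <- 0.5
  attr(half, "cell") <- attr(lone, "cell")
  m2 <- render_map(half, 0.4)
  expect_equal(integrate_electrons(m2, mask),
               integrate_electrons(map, mask) / 2, tolerance = 0.01)
  zero <- map; zero$grid[] <- 0
  expect_equal(integrate_electrons(zero, mask), 0)
  rel <- map; rel$absolute_scale <- FALSE
  expect_error(integrate_electrons(rel, mask), "absolute")
})

test_that("count-to-occupancy conversion applies the water correction", {
  fx <- counting_fixture()
  ctx <- fx$ctx
  expect_equal(occupancy_from_count(ctx$ligand_electrons, ctx), 1)
  expect_equal(occupancy_from_count(ctx$water_electrons, ctx), 0)
  # raw values may leave [0, 1]; clamping is not this function's job
  expect_gt(occupancy_from_count(ctx$ligand_electrons + 5, ctx), 1)
  expect_lt(occupancy_from_count(ctx$water_electrons - 5, ctx), 0)
  expect_error(counting_context(10, 10, 50, array(TRUE, c(2, 2, 2))),
               "contrast")
  # overlapping ligand/water site at half occupancy counts to one half
  raw <- count_occupancy(fx$map, fx$mask, fx$ctx)
  expect_equal(raw, 0.5, tolerance = 0.05)
})

test_that("consensus averages three estimates with clamped bounds", {
  c1 <- consensus_estimate(c(0.5, 0.5, 0.5))
  expect_equal(c1$mean_estimate, 0.5)
  expect_equal(c1$spread_sd, 0)
  expect_false(c1$clamped)
  c2 <- consensus_estimate(c(-0.1, 0.0, 0.05))
  expect_equal(c2$mean_estimate, 0.01)
  expect_true(c2$clamped)
  c3 <- consensus_estimate(c(1.1, 1.0, 0.99))
  expect_equal(c3$mean_estimate, 0.99)
  expect_true(c3$clamped)
  c4 <- consensus_estimate(c(0.6, 0.7, 0.8))
  expect_equal(c4$mean_estimate, 0.7)
  expect_equal(c4$spread_sd, population_sd(c(0.6, 0.7, 0.8)))
  expect_equal(c4$spread_sd, 0.0816, tolerance = 1e-3)
  expect_error(consensus_estimate(c(0.5, 0.5)), "three")
})

test_that("precision summary reduces spreads to max, median and mean", {
  mk <- function(sd_target) {
    # three symmetric estimates with the requested population SD
    consensus_estimate(0.5 + sd_target * sqrt(1.5) * c(-1, 0, 1))
  }
  sets <- lapply(c(0.01, 0.02, 0.10), mk)
  ps <- precision_summary(sets)
  expect_equal(unname(ps["max_sd"]), 0.10, tolerance = 1e-9)
  expect_equal(unname(ps["median_sd"]), 0.02, tolerance = 1e-9)
  expect_equal(unname(ps["mean_sd"]), mean(c(0.01, 0.02, 0.10)),
               tolerance = 1e-9)
  single <- precision_summary(sets[3])
  expect_equal(unname(single["max_sd"]), unname(single["median_sd"]))
  expect_error(precision_summary(list()), "no estimates")
})

test_that("filling from a ligand-free reference biases counts downward", {
  errs <- vapply(c(0.5, 0.9), function(occ) {
    est <- recover_toy_occupancy(occ, missing_fraction = 0.10, seed = 5)
    est$mean_estimate - occ
  }, numeric(1))
  expect_true(all(errs < 0))
})

test_that("batch counting from map files matches the in-memory path", {
  fx <- counting_fixture(occ = 0.6)
  refl <- structure_factors(fx$map)
  paths <- vapply(list(refl,
                       resolution_truncate(refl, 1.2),
                       apply_reciprocal_bfactor(
                         resolution_truncate(refl, 1.2), -8)),
                  function(r) {
    p <- tempfile(fileext = ".map")
    write_ccp4_map(map_from_reflections(r, zero_f000 = TRUE), p)
    p
  }, character(1))
  on.exit(unlink(paths))
  batch <- count_occupancy_batch(list(paths), fx$site$structure,
                                 fx$site$ligand_electrons,
                                 fx$site$water_electrons,
                                 fx$site$protein_electrons,
                                 include_radius = 2.5,
                                 envelope_radius = 2.5)
  direct <- three_model_occupancy(refl, fx$site$structure, fx$ctx,
                                  d_trunc = 1.2, b_sharpen = -8,
                                  include_radius = 2.5)
  expect_equal(batch$estimates$mean, direct$mean_estimate, tolerance = 1e-4)
  expect_equal(nrow(batch$estimates), 1)
  expect_equal(unname(batch$precision["mean_sd"]),
               direct$spread_sd, tolerance = 1e-4)
})
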