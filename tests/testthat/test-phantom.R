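test_that("empty spec yields an all-zero volume with zero vessel density", {
  sp <- phantom_spec(nx = 16, ny = 16, nz = 48, melanin_amplitude = 0,
                     vessels = list(), noise_sigma = 0)
  ph <- generate_phantom(sp)
  expect_true(all(ph$volume$amplitude == 0))
  expect_identical(ph$truth$density_true, 0)
  expect_identical(ph$truth$D_true, 0)
  expect_identical(ph$truth$mean_diameter_true, 0)
})

test_that("a straight 40 um tube across a 100x100 grid projects to ~8 pixel band", {
  # dx = dy = 10 um, tube centred between grid lines: 80 um diameter over a
  # 1000 um extent -> density 0.08
  sp <- phantom_spec(nx = 100, ny = 100, nz = 60, dx = 10, dy = 10,
                     melanin_amplitude = 0, noise_sigma = 0,
                     epidermal_thickness_um = 112.5,
                     vessels = list(vessel_tube(y_um = 495, depth_um = 300,
                                                radius_um = 40)))
  ph <- generate_phantom(sp)
  proj <- apply(ph$truth$vessel_mask, c(1, 2), any)
  expect_identical(unname(colSums(proj)[50] > 0), TRUE)
  expect_equal(ph$truth$density_true, 0.08, tolerance = 0.01)
  expect_equal(sum(proj) / length(proj), ph$truth$density_true)
})

test_that("generation is a pure function of the spec", {
  sp <- small_spec("mixed_mv", seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$amplitude, b$volume$amplitude)
  expect_identical(a$truth, b$truth)
  # a different noise seed changes the volume but not the anatomy
  sp2 <- sp; sp2$seed <- 6L
  c_ <- generate_phantom(sp2)
  expect_false(identical(a$volume$amplitude, c_$volume$amplitude))
  expect_identical(a$truth$vessel_mask, c_$truth$vessel_mask)
})

test_that("generation leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_phantom(small_spec("mixed_m", seed = 2)))
  expect_identical(.Random.seed, before)
})

test_that("density_true is recomputable from the stored vessel mask", {
  for (nm in c("epidermal_m", "epidermal_mv")) {
    ph <- generate_phantom(small_spec(nm, seed = 2))
    vm <- ph$truth$vessel_mask
    dim(vm) <- c(prod(dim(vm)[1:2]), dim(vm)[3])
    expect_identical(mean(rowSums(vm) > 0), ph$truth$density_true)
  }
})

test_that("impossible geometry is rejected with a pointer to the offender", {
  expect_error(
    phantom_spec(epidermal_thickness_um = 165,
                 vessels = list(vessel_tube(100, 180, 30))),
    "vessel 1.*epidermal boundary")
  expect_error(
    phantom_spec(nz = 24, melanin_max_depth_um = 300,
                 epidermal_thickness_um = 300),
    "exceeds the grid depth")
  expect_error(
    phantom_spec(vessels = list(vessel_tube(100, 600, 40)), nz = 96),
    "vessel 1.*grid depth")
})

test_that("presets encode their class by construction", {
  for (nm in names(expected_label)) {
    les <- phantom_preset(nm, seed = 1, "lesional")
    ctl <- phantom_preset(nm, seed = 1, "control")
    expect_s3_class(les, "phantom_spec")
    if (startsWith(nm, "epidermal"))
      expect_lte(les$melanin_max_depth_um, les$epidermal_thickness_um)
    else
      expect_gt(les$melanin_max_depth_um, les$epidermal_thickness_um)
    phi <- function(s) {
      amps <- vapply(s$vessels, `[[`, numeric(1), "amplitude")
      sum(amps * 2 * vapply(s$vessels, `[[`, numeric(1), "radius_um")) / sum(amps)
    }
    if (endsWith(nm, "_mv")) {
      expect_gt(phi(les), phi(ctl))
    } else {
      expect_lte(phi(les), phi(ctl))
    }
  }
  expect_error(phantom_preset("nope"), "unknown preset")
})

test_that("epidermal_mv lesional/control pair echoes the ~2x diameter and ~4x density contrast", {
  case <- phantom_case_preset("epidermal_mv", seed = 1)
  expect_equal(case$lesional$truth$mean_diameter_true /
                 case$control$truth$mean_diameter_true, 2, tolerance = 0.05)
  ratio <- case$lesional$truth$density_true / case$control$truth$density_true
  expect_gt(ratio, 3.5)
})

test_that("noise-free A-lines peak at the surface; extraction recovers it", {
  sp <- small_spec("mixed_m", seed = 1, noise_sigma = 0)
  ph <- generate_phantom(sp)
  no <- noise_model(0.01, "fixed")
  surf <- extract_surface(ph$volume, no)
  expect_true(all(surf$valid))
  err <- abs(surf$z_um - ph$truth$surface_um)
  expect_lte(max(err), ph$volume$dz)
})

test_that("punctate dermal deposits stay clear of vessels and reach D exactly", {
  sp <- small_spec("mixed_mv", seed = 3, noise_sigma = 0)
  ph <- generate_phantom(sp)
  mel <- ph$truth$melanin_mask & !ph$truth$vessel_mask
  expect_identical(mel, ph$truth$melanin_mask)  # disjoint by construction
  # deepest melanin voxel sits at D_true below the local surface
  d <- dim(mel)
  idx <- which(ph$truth$melanin_mask, arr.ind = TRUE)
  depth_rel <- (idx[, 3] - 1) * sp$dz -
    ph$truth$surface_analytic_um[idx[, 1:2, drop = FALSE]]
  expect_lte(max(depth_rel), ph$truth$D_true)
  expect_gt(max(depth_rel), ph$truth$D_true - sp$dz)
})
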