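band_mask <- function(nr = 64, nc = 64, rows = list(c(20, 27)), d = 10) {
  m <- matrix(FALSE, nr, nc)
  for (r in rows) m[, r[1]:r[2]] <- TRUE
  vessel_mask(m, d, d)
}

map_from <- function(px, d = 10)
  structure(list(pixels = px, plane = "XY", layer = "dermis", d1 = d, d2 = d),
            class = "map_image")

test_that("sub-floor MAPs give an empty mask, and binary tubes segment exactly", {
  z <- map_from(matrix(0, 32, 32))
  expect_false(any(segment_vessels(z, noise_model(0))$mask))
  px <- matrix(0, 64, 64)
  px[, 20:27] <- 3.2
  vs <- segment_vessels(map_from(px), noise_model(0), smooth_sigma = 0)
  expect_identical(vs$mask, px > 0)
})

test_that("density is an exact pixel ratio with ROI support", {
  expect_identical(vessel_density(band_mask(rows = list())), 0)
  full <- vessel_mask(matrix(TRUE, 10, 10), 1)
  expect_identical(vessel_density(full), 1)
  # 8-pixel band across a 100x100 ROI
  m <- matrix(FALSE, 100, 100); m[, 47:54] <- TRUE
  expect_identical(vessel_density(vessel_mask(m, 10)), 0.08)
  roi <- matrix(FALSE, 100, 100); roi[1:50, ] <- TRUE
  expect_identical(vessel_density(vessel_mask(m, 10), roi), 0.08)
  expect_error(vessel_density(full, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("density equals a brute-force pixel count on random masks", {
  set.seed(10)
  for (i in 1:50) {
    m <- matrix(runif(30 * 30) < runif(1), 30, 30)
    vm <- vessel_mask(m, 5)
    brute <- sum(m) / length(m)
    expect_identical(vessel_density(vm), brute)
  }
})

test_that("mean diameter on straight bands matches the width within one pixel", {
  for (w in 3:20) {
    vm <- band_mask(nr = 48, nc = 60, rows = list(c(21, 20 + w)), d = 1)
    expect_lte(abs(mean_vessel_diameter(vm) - w), 1)
  }
  expect_identical(mean_vessel_diameter(band_mask(rows = list())), 0)
  aniso <- vessel_mask(matrix(TRUE, 4, 4), 5, 10)
  expect_error(mean_vessel_diameter(aniso), "isotropic")
})

test_that("diameter and density are invariant to whole-pixel translations", {
  m <- matrix(FALSE, 64, 64); m[10:55, 20:29] <- TRUE
  a <- vessel_mask(m, 5)
  m2 <- matrix(FALSE, 64, 64); m2[13:58, 24:33] <- TRUE
  b <- vessel_mask(m2, 5)
  expect_identical(vessel_density(a), vessel_density(b))
  expect_identical(mean_vessel_diameter(a), mean_vessel_diameter(b))
})

test_that("dilating a mask never decreases its density", {
  set.seed(11)
  brush <- EBImage::makeBrush(3, "box")
  for (i in 1:10) {
    m <- matrix(runif(40 * 40) < 0.1, 40, 40)
    d <- as.matrix(EBImage::dilate(m * 1, brush)) > 0
    expect_gte(vessel_density(vessel_mask(d, 1)), vessel_density(vessel_mask(m, 1)))
  }
})

test_that("phantom tube diameters are recovered within 10%", {
  # radii 40 and 60 um, equal lengths -> truth-weighted mean diameter 100 um
  sp <- phantom_spec(nx = 64, ny = 64, nz = 96,
                     epidermal_thickness_um = 112.5, melanin_max_depth_um = 112.5,
                     vessels = list(small_tube(90, 40), small_tube(230, 60)),
                     noise_sigma = 0)
  ph <- generate_phantom(sp)
  expect_identical(ph$truth$mean_diameter_true, 100)
  va <- analyze_volume(ph$volume)
  expect_equal(va$vessels$Phi_um, 100, tolerance = 0.1)
})

test_that("segmentation overlaps the true projected vessels (Dice >= 0.85)", {
  case <- phantom_case_preset("epidermal_mv", seed = 9)
  va <- analyze_volume(case$lesional$volume)
  vm <- case$lesional$truth$vessel_mask
  dim(vm) <- c(128 * 128, 96)
  truth <- matrix(rowSums(vm) > 0, 128, 128)
  got <- va$vessels$mask$mask
  dice <- 2 * sum(got & truth) / (sum(got) + sum(truth))
  expect_gte(dice, 0.85)
})

test_that("punctate blobs are rejected by the shape filter", {
  px <- matrix(0, 64, 64)
  px[, 20:29] <- 1                      # tube
  px[40:45, 50:55] <- 1                 # compact blob
  vs <- segment_vessels(map_from(px), noise_model(0), smooth_sigma = 0)
  expect_true(all(vs$mask[, 20:29]))
  expect_false(any(vs$mask[40:45, 50:55]))
  keep_all <- segment_vessels(map_from(px), noise_model(0), smooth_sigma = 0,
                              min_shape_ratio = 0)
  expect_true(any(keep_all$mask[40:45, 50:55]))
})

test_that("tiles with proportional diameter and density correlate perfectly", {
  # three tile rows with band widths 4, 8, 12 px: local rho is proportional
  # to local diameter by construction
  m <- matrix(FALSE, 96, 96)
  m[, 14:17] <- TRUE    # tile row 1: width 4
  m[, 46:53] <- TRUE    # tile row 2: width 8
  m[, 76:87] <- TRUE    # tile row 3: width 12
  cc <- diameter_density_correlation(vessel_mask(m, 1), tile_px = 32)
  expect_identical(cc$n_tiles, 9L)
  expect_equal(cc$r, 1, tolerance = 1e-9)
  expect_lt(cc$p, 1e-6)
})

test_that("degenerate correlations are flagged, not silently zeroed", {
  # constant width everywhere -> zero diameter variance
  m <- matrix(FALSE, 96, 96)
  m[, c(14:19, 46:51)] <- TRUE
  m[1:40, 78:83] <- TRUE
  expect_warning(cc <- diameter_density_correlation(vessel_mask(m, 1), 32),
                 "constant")
  expect_true(is.na(cc$r))
  # fewer than 3 occupied tiles
  m2 <- matrix(FALSE, 96, 96); m2[1:20, 1:6] <- TRUE
  expect_error(diameter_density_correlation(vessel_mask(m2, 1), 96),
               "insufficient")
})

test_that("co-increasing tube radius and count give strong positive correlation", {
  m <- matrix(FALSE, 96, 96)
  m[, 10:13] <- TRUE                    # thin, single
  m[, c(36:43, 52:59)] <- TRUE          # medium, double
  m[, c(68:79, 84:95)] <- TRUE          # thick, double
  cc <- diameter_density_correlation(vessel_mask(m, 1), tile_px = 32)
  expect_gt(cc$r, 0.8)
})

test_that("hand-rolled Otsu agrees with the EBImage reference on [0,1] images", {
  set.seed(12)
  px <- c(rnorm(600, 0.25, 0.12), rnorm(400, 0.75, 0.12))
  px <- pmin(pmax(px, 0), 1)
  img <- EBImage::Image(matrix(px, 40, 25))
  ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  got <- pamclass:::.otsu_threshold(px)
  expect_equal(got, ref, tolerance = 0.05)
  # both cuts separate the two modes identically
  expect_identical(px > got, px > ref)
})
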