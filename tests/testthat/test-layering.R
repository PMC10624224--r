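test_that("surface depth is the first A-line extremum in micrometres", {
  # peak at axial sample 15 (0-based), dz = 7.5 -> 112.5 um
  a <- array(0, c(3, 3, 24))
  a[, , 16] <- 5
  v <- pa_volume(a, 5, 5, 7.5)
  surf <- extract_surface(v, noise_model(0.5))
  expect_true(all(surf$z_um == 112.5))
  expect_true(all(surf$valid))
})

test_that("all-zero A-lines are invalid; isolated gaps are neighbour-filled", {
  a <- array(0, c(5, 5, 10))
  a[, , 4] <- 3
  a[1, 1, ] <- 0  # corner column: only 3 neighbours, stays invalid
  a[3, 3, ] <- 0  # interior column: 8 valid neighbours, gets filled
  v <- pa_volume(a, 5, 5, 7.5)
  surf <- extract_surface(v, noise_model(0.5))
  expect_false(surf$valid[1, 1])
  expect_true(is.na(surf$z_um[1, 1]))
  expect_true(surf$valid[3, 3])
  expect_identical(surf$z_um[3, 3], 22.5)
  expect_identical(surf$filled, 1L)
})

test_that("an empty volume fails surface extraction loudly", {
  v <- pa_volume(array(0, c(4, 4, 6)), 5, 5, 7.5)
  expect_error(extract_surface(v, noise_model(0.1)), "50%")
})

test_that("noise-free phantom surface is recovered within one axial sample", {
  ph <- generate_phantom(small_spec("epidermal_mv", seed = 2, noise_sigma = 0))
  surf <- extract_surface(ph$volume, noise_model(0.01, "fixed"))
  expect_lte(max(abs(surf$z_um - ph$truth$surface_um)), 7.5)
})

test_that("flattening shifts columns by their surface depth", {
  # two-level tilted surface: half the columns one sample deeper
  a <- array(0, c(4, 4, 10))
  a[1:2, , 2] <- 5; a[1:2, , 3] <- 1
  a[3:4, , 3] <- 5; a[3:4, , 4] <- 1
  v <- pa_volume(a, 5, 5, 7.5)
  surf <- extract_surface(v, noise_model(0.5))
  fv <- flatten_to_surface(v, surf)
  expect_true(all(fv$flat[, , 1] == 5))  # surface lands at depth 0 everywhere
  expect_true(all(fv$flat[, , 2] == 1))
})

test_that("split_layers partitions depths into [0, Z) and [Z, max] exactly once", {
  v <- flat_surface_volume(nx = 4, ny = 4, nz = 8)
  surf <- extract_surface(v, noise_model(0.5))
  st <- split_layers(v, surf, Z = 15)   # 2 * dz
  expect_identical(dim(st$epidermis$amplitude)[3], 2L)
  expect_identical(dim(st$dermis$amplitude)[3], 6L)
  expect_identical(st$epidermis$d0_um, 0)
  expect_identical(st$dermis$d0_um, 15)
  # concatenating the layers reconstructs the flattened volume exactly
  recon <- array(c(st$epidermis$amplitude, st$dermis$amplitude), dim(st$flat))
  expect_identical(recon, st$flat)
  expect_error(split_layers(v, surf, Z = 10), "multiple")
  expect_error(split_layers(v, surf, Z = 300), "no dermal samples")
  expect_error(split_layers(v, surf, Z = 0), "positive")
})

test_that("phantom layer partition reconstructs the flattened volume", {
  ph <- generate_phantom(small_spec("mixed_m", seed = 4))
  va <- analyze_volume(ph$volume)
  st <- va$layers
  recon <- array(c(st$epidermis$amplitude, st$dermis$amplitude), dim(st$flat))
  expect_identical(recon, st$flat)
})

test_that("MAP collapses one axis by per-pixel maxima", {
  a <- array(0, c(3, 4, 5))
  a[2, 3, 4] <- 7
  m <- max_amplitude_projection(a, "XY")
  expect_identical(sum(m$pixels != 0), 1L)
  expect_identical(m$pixels[2, 3], 7)
  xz <- max_amplitude_projection(a, "XZ")
  expect_identical(dim(xz$pixels), c(3L, 5L))
  expect_identical(xz$pixels[2, 4], 7)
  cst <- max_amplitude_projection(array(2, c(3, 3, 3)), "XY")
  expect_true(all(cst$pixels == 2))
  expect_error(max_amplitude_projection(a, "YZ"))
})

test_that("MAP is invariant to permutations along the collapsed axis and idempotent", {
  set.seed(5)
  a <- array(runif(4 * 4 * 6), c(4, 4, 6))
  m1 <- max_amplitude_projection(a, "XY")
  m2 <- max_amplitude_projection(a[, , sample(6)], "XY")
  expect_identical(m1$pixels, m2$pixels)
  again <- max_amplitude_projection(array(m1$pixels, c(4, 4, 1)), "XY")
  expect_identical(again$pixels, m1$pixels)
})

test_that("dermal MAP support matches the projected vessels up to the PSF", {
  sp <- small_spec("epidermal_mv", seed = 1, noise_sigma = 0)
  sp$melanin_amplitude <- 0
  ph <- generate_phantom(sp)
  vm <- ph$truth$vessel_mask
  dim(vm) <- c(64 * 64, 96)
  proj <- matrix(rowSums(vm) > 0, 64, 64)
  full <- max_amplitude_projection(ph$volume$amplitude, "XY")
  nonzero <- full$pixels > 1e-6
  expect_true(all(nonzero[proj]))                 # contains the projection
  brush <- EBImage::makeBrush(9, "disc")          # PSF support ~2 px + margin
  dil <- as.matrix(EBImage::dilate(proj * 1, brush)) > 0
  expect_true(all(dil[nonzero]))                  # and no more than its dilation
})

test_that("boundary depth is found where tubular morphology appears", {
  ph <- generate_phantom(small_spec("epidermal_mv", seed = 1, noise_sigma = 0))
  no <- noise_model(0.02, "fixed")
  surf <- extract_surface(ph$volume, no)
  cand <- seq(30, 300, by = 7.5)
  b <- determine_boundary_z(ph$volume, surf, cand, no)
  expect_false(b$low_confidence)
  expect_lte(abs(b$Z_um - 165), 7.5)
})

test_that("vessel-free volumes raise the low-confidence flag", {
  sp <- small_spec("epidermal_m", seed = 1, noise_sigma = 0)
  sp$vessels <- list()
  ph <- generate_phantom(sp)
  no <- noise_model(0.02, "fixed")
  surf <- extract_surface(ph$volume, no)
  b <- determine_boundary_z(ph$volume, surf, seq(30, 300, 7.5), no)
  expect_true(b$low_confidence)
})

test_that("vessels shallower than every candidate select the first candidate", {
  sp <- phantom_spec(nx = 64, ny = 64, nz = 96,
                     epidermal_thickness_um = 30, melanin_max_depth_um = 30,
                     vessels = list(vessel_tube(120, 100, 30),
                                    vessel_tube(220, 100, 30)),
                     noise_sigma = 0)
  ph <- generate_phantom(sp)
  no <- noise_model(0.02, "fixed")
  surf <- extract_surface(ph$volume, no)
  cand <- seq(150, 300, by = 7.5)   # all below the tube tops
  b <- determine_boundary_z(ph$volume, surf, cand, no)
  expect_identical(b$Z_um, 150)
  expect_false(b$low_confidence)
})

test_that("boundary candidate lists are validated", {
  v <- flat_surface_volume()
  surf <- extract_surface(v, noise_model(0.5))
  expect_error(determine_boundary_z(v, surf, numeric(0), noise_model(0.5)), "empty")
  expect_error(determine_boundary_z(v, surf, c(30, 15), noise_model(0.5)), "ascending")
  expect_error(determine_boundary_z(v, surf, c(10, 20), noise_model(0.5)), "multiples")
})
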