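# Scaled-down phantom geometry for unit tests: 64 x 64 lateral grid
# (320 um field) with the same axial layout as the full presets.

small_tube <- function(y, r, amp = 1)
  vessel_tube(y_um = y, depth_um = 240, radius_um = r, amplitude = amp)

small_class_geometry <- list(
  epidermal_m = list(Z = 112.5, D = 112.5,
                     les = list(amp = 1.0, v = list(small_tube(80, 30), small_tube(240, 30))),
                     ctl = list(amp = 0.5, v = list(small_tube(160, 40)))),
  mixed_m = list(Z = 135, D = 165,
                 les = list(amp = 1.0, v = list(small_tube(80, 35), small_tube(240, 35))),
                 ctl = list(amp = 0.5, v = list(small_tube(160, 40)))),
  epidermal_mv = list(Z = 165, D = 165,
                      les = list(amp = 1.0, v = list(small_tube(80, 50), small_tube(240, 50))),
                      ctl = list(amp = 0.5, v = list(small_tube(160, 25)))),
  mixed_mv = list(Z = 135, D = 165,
                  les = list(amp = 1.0, v = list(small_tube(80, 50), small_tube(240, 50))),
                  ctl = list(amp = 0.5, v = list(small_tube(160, 25))))
)

small_spec <- function(name, seed = 1L, site = "lesional", noise_sigma = 0.05,
                       dot_count = 4L) {
  g <- small_class_geometry[[name]]
  s <- if (site == "lesional") g$les else g$ctl
  phantom_spec(nx = 64L, ny = 64L, nz = 96L,
               epidermal_thickness_um = g$Z,
               melanin_max_depth_um = if (site == "lesional") g$D else g$Z,
               melanin_amplitude = s$amp,
               dermal_dot_count = dot_count,
               vessels = s$v,
               noise_sigma = noise_sigma,
               seed = if (site == "lesional") seed else seed + 1L,
               label = if (site == "lesional") "lesional" else "non_lesional")
}

small_case <- function(name, seed = 1L, noise_sigma = 0.05) {
  list(lesional = generate_phantom(small_spec(name, seed, "lesional", noise_sigma)),
       control = generate_phantom(small_spec(name, seed, "control", noise_sigma)))
}

# constant-amplitude volume with a detectable surface at the first sample
flat_surface_volume <- function(nx = 4L, ny = 4L, nz = 8L, dz = 7.5,
                                peak = 2, body = 1) {
  a <- array(body, c(nx, ny, nz))
  a[, , 1L] <- peak
  pa_volume(a, 5, 5, dz)
}

expected_label <- c(epidermal_m = "Epidermal M", mixed_m = "Mixed M",
                    epidermal_mv = "Epidermal M+V", mixed_mv = "Mixed M+V")
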