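test_that("spectrum endpoints, dominance and hardening behave physically", {
  s80 <- make_spectrum(80)
  s140 <- make_spectrum(140)
  expect_equal(max(s80$energy_kev), 80)
  expect_equal(max(s140$energy_kev), 140)
  expect_equal(sum(s80$fluence), 1)
  expect_true(all(s80$fluence >= 0))
  mean_e <- function(s) sum(s$energy_kev * s$fluence)
  expect_gt(mean_e(s140), mean_e(s80))
  # prefiltering hardens the spectrum
  expect_gt(mean_e(make_spectrum(100, filtration_mm_al = 5)),
            mean_e(make_spectrum(100, filtration_mm_al = 0)))
  expect_error(make_spectrum(40), "60-150")
  expect_error(make_spectrum(80, n_bins = 5), "10 bins")
  expect_error(make_spectrum(80, e_min_kev = 90), "below minimum")
})

test_that("effective energy matches the fluence-weighted water attenuation", {
  m <- default_materials()
  s <- make_spectrum(120)
  e <- effective_energy(s)
  expect_equal(linear_attenuation(m$water, e), effective_mu(s, m$water),
               tolerance = 1e-8)
  expect_equal(effective_energy(mono_spectrum(73)), 73)
})

test_that("projection of an empty volume is a flat field", {
  vol <- raw_volume(array(0L, c(40, 40, 1)), 2, c("0" = "void"))
  sino <- project_polychromatic(vol, list(void = void_material()),
                                mono_spectrum(70, n0 = 1e4),
                                scan_geometry(96, 64))
  expect_equal(sino$values, matrix(1e4, 96, 64), tolerance = 1e-7)
})

test_that("monochromatic projection through an axis-aligned water slab is Beer-Lambert", {
  lab <- array(0L, c(160, 134, 1))
  lab[, 57:76, ] <- 1L   # 20 voxels x 2.5 mm = 5 cm water slab
  vol <- raw_volume(lab, 2.5, c("0" = "void", "1" = "water"))
  mats <- list(void = void_material(), water = default_materials()$water)
  s <- mono_spectrum(70, n0 = 1e6)
  geom <- scan_geometry(180, 256)
  sino <- project_polychromatic(vol, mats, s, geom)
  mu <- linear_attenuation(default_materials()$water, 70)
  # vertical rays (first angle) cross exactly 5 cm of water
  mid <- 120:136
  expect_equal(unname(sino$values[1, mid]) / 1e6,
               rep(exp(-mu * 5), length(mid)), tolerance = 1e-6)
  expect_error(project_polychromatic(vol, list(void = void_material()), s,
                                     geom), "unmapped label")
})

test_that("polychromatic water attenuation shows the beam-hardening signature", {
  # -ln(I/I0)/L strictly decreasing in L, against direct spectral integration
  m <- default_materials()
  s <- make_spectrum(80)
  mu_w <- linear_attenuation(m$water, s$energy_kev)
  L <- seq(2, 40, by = 2)
  p <- -log(as.numeric(exp(-outer(L, mu_w)) %*% s$fluence))
  expect_true(all(diff(p / L) < 0))
})

test_that("counting noise is Poisson, seeded, and leaves the caller's RNG alone", {
  vals <- matrix(50, 1, 1e4)
  sino <- structure(list(values = vals, angles = 0,
                         det_mm = seq_len(ncol(vals)), kind = "counts",
                         n0 = 50),
                    class = "sinogram")
  set.seed(99)
  before <- .Random.seed
  n1 <- add_counting_noise(sino, 7)
  expect_identical(.Random.seed, before)
  n2 <- add_counting_noise(sino, 7)
  expect_identical(n1$values, n2$values)
  n3 <- add_counting_noise(sino, 8)
  expect_false(identical(n1$values, n3$values))
  # moment oracle: mean of 1e4 draws within 3 sigma of lambda
  expect_lt(abs(mean(n1$values) - 50), 3 * sqrt(50 / 1e4))
  # zero counts stay zero
  zero <- sino; zero$values[] <- 0
  expect_true(all(add_counting_noise(zero, 1)$values == 0))
})

test_that("log normalization maps counts to line integrals with a starvation floor", {
  sino <- structure(list(values = matrix(c(1000, 1000 / exp(1), 0), 1),
                         angles = 0, det_mm = 1:3, kind = "counts",
                         n0 = 1000),
                    class = "sinogram")
  p <- log_normalize(sino, flat_field = 1000, starvation_floor = 1)
  expect_equal(as.numeric(p$values), c(0, 1, log(1000)))
  expect_equal(p$kind, "line_integral")
  expect_error(log_normalize(sino, flat_field = 0), "non-positive")
  expect_error(log_normalize(p), "counts sinogram")
})

test_that("water precorrection is the identity for matched monochromatic data", {
  m <- default_materials()
  s <- mono_spectrum(70)
  p <- matrix(seq(0, 8, length.out = 32), 2)
  sino <- structure(list(values = p, angles = c(0, 1), det_mm = 1:16,
                         kind = "line_integral", n0 = 1, spectrum = s),
                    class = "sinogram")
  out <- water_precorrect(sino, s, reference_energy_kev = 70)
  expect_equal(out$values, p, tolerance = 1e-9)
  expect_equal(out$values[1, 1], 0)   # p = 0 -> 0
  # monotone for polychromatic input
  s80 <- make_spectrum(80)
  sino$spectrum <- s80
  out2 <- water_precorrect(sino, s80)
  expect_true(all(diff(as.numeric(out2$values)[order(as.numeric(p))]) >= 0))
  expect_warning(
    water_precorrect(structure(list(values = matrix(25, 1, 1), angles = 0,
                                    det_mm = 1, kind = "line_integral",
                                    n0 = 1),
                               class = "sinogram"), s80),
    "calibration range")
})

test_that("water precorrection flattens the cupped water-box reconstruction", {
  m <- default_materials()
  vol <- water_box(100, 100, 2.5)
  s80 <- make_spectrum(80)
  geom <- scan_geometry(180, 192)
  sino <- log_normalize(project_polychromatic(vol, m, s80, geom))
  grid <- list(nx = 100, ny = 100, spacing_mm = 2.5)
  img_unc <- reconstruct_fbp(sino, grid)
  img_cor <- reconstruct_fbp(water_precorrect(sino, s80), grid)
  muw <- effective_mu(s80, m$water)
  d2 <- center_d2(100, 100, 2.5)
  cen <- d2 < 15^2; edge <- d2 > 90^2 & d2 < 110^2
  cup <- function(img) abs(mean(img[cen]) - mean(img[edge])) / muw * 1000
  expect_gt(cup(img_unc) / cup(img_cor), 5)
})

test_that("FBP is linear and recovers a known disk attenuation within 2%", {
  m <- default_materials()
  vol <- disk_volume(96, 2, 40)
  sino <- log_normalize(project_polychromatic(vol, m, mono_spectrum(70),
                                              scan_geometry(360, 256)))
  grid <- list(nx = 96, ny = 96, spacing_mm = 2)
  img <- reconstruct_fbp(sino, grid)
  mu_true <- linear_attenuation(m$ha_pellet, 70)
  d2 <- center_d2(96, 96, 2)
  expect_lt(abs(mean(img[d2 <= 30^2]) / mu_true - 1), 0.02)
  # linearity: zero in, zero out; scaling by c scales the image by c
  z <- sino; z$values[] <- 0
  expect_equal(reconstruct_fbp(z, grid), matrix(0, 96, 96))
  s3 <- sino; s3$values <- 3 * sino$values
  expect_equal(reconstruct_fbp(s3, grid), 3 * img, tolerance = 1e-12)
  few <- sino; few$values <- sino$values[1:45, ]; few$angles <- sino$angles[1:45]
  expect_error(reconstruct_fbp(few, grid), "90 angles")
  expect_error(reconstruct_fbp(sino, grid, "hann"), "unknown filter")
})

test_that("Hounsfield conversion pins water, air and double-water", {
  ct <- to_hounsfield(array(c(0.2, 0, 0.4, -0.1), c(4, 1, 1)), 0.2)
  expect_equal(as.numeric(ct$hu), c(0, -1000, 1000, -1042))  # floor clamp
  ct2 <- to_hounsfield(array(10, c(1, 1, 1)), 0.2, ceiling_hu = 3071)
  expect_equal(as.numeric(ct2$hu), 3071)
  expect_error(to_hounsfield(array(1, c(1, 1, 1)), 0), "> 0")
})

test_that("noiseless precorrected water scan reconstructs near 0 HU away from edges", {
  m <- default_materials()
  vol <- water_box(160, 134, 2.5)
  acq <- acquisition_params(noise = FALSE)
  ct <- dectlab:::simulate_scan_spectrum(vol, m, make_spectrum(80), acq, 1)
  d2 <- center_d2(160, 134, 2.5)
  expect_lt(max(abs(ct$hu[, , 1][d2 < 80^2])), 10)
})

test_that("scans are bit-identical under a fixed seed", {
  m <- default_materials()
  ph <- crop_slices(build_phantom(tiny_phantom_config()), 30:31)
  acq <- acquisition_params(n_angles = 96, n_det = 128)
  a <- simulate_scan(ph, m, 80, acq, seed = 5)
  b <- simulate_scan(ph, m, 80, acq, seed = 5)
  expect_identical(a$hu, b$hu)
  expect_equal(a$provenance$kvp, 80)
})

test_that("the titanium phantom shows more dark voxels at 80 kVp than at 140 kVp", {
  m <- default_materials()
  ph <- crop_slices(build_phantom(tiny_phantom_config()), 28:31)
  acq <- acquisition_params(n_angles = 120, n_det = 160)
  s80 <- simulate_scan(ph, m, 80, acq, seed = 11)
  s140 <- simulate_scan(ph, m, 140, acq, seed = 12)
  expect_gt(mean(s80$hu < -200), mean(s140$hu < -200))
})

test_that("dark-streak mass grows with the alloy attenuation at fixed seed", {
  m <- default_materials()
  acq <- acquisition_params(n_angles = 120, n_det = 160)
  dark <- sapply(c("titanium_alloy", "stainless_steel", "chrome_cobalt"),
                 function(alloy) {
    ph <- build_phantom(tiny_phantom_config(stem_material = alloy))
    ph <- crop_slices(ph, 28:29)
    ct <- simulate_scan(ph, m, 80, acq, seed = 21)
    mean(ct$hu < -200)
  })
  expect_true(all(diff(dark) > 0))  # Ti < steel < CoCr in LAC and in streaks
})

test_that("reconstructed noise vanishes as the tube fluence grows", {
  m <- default_materials()
  vol <- water_box(60, 60, 2.5)
  d2 <- center_d2(60, 60, 2.5)
  sds <- sapply(c(2e4, 2e5, 2e6), function(n0) {
    acq <- acquisition_params(n_angles = 96, n_det = 96, n0_ref = n0)
    ct <- simulate_scan(vol, m, 140, acq, seed = 3)
    sd(ct$hu[, , 1][d2 < 40^2])
  })
  expect_true(all(diff(sds) < 0))
  expect_lt(sds[3], sds[1] / 5)
})

test_that("metal-free scans reproduce the pellet attenuation contrast", {
  m <- default_materials()
  vol <- disk_volume(100, 2.5, 10)   # 20 mm pellet rod in water
  d2 <- center_d2(100, 100, 2.5)
  acq <- acquisition_params(noise = FALSE, n_angles = 180, n_det = 192)
  # monochromatic scan: pellet HU equals the analytic HU at that energy
  ct70 <- dectlab:::simulate_scan_spectrum(vol, m, mono_spectrum(70), acq, 1)
  analytic <- function(e) {
    1000 * (linear_attenuation(m$ha_pellet, e) -
              linear_attenuation(m$water, e)) / linear_attenuation(m$water, e)
  }
  expect_lt(abs(mean(ct70$hu[, , 1][d2 < 6^2]) - analytic(70)), 15)
  # polychromatic scan: in-object hardening lowers the contrast below the
  # entrance-spectrum prediction (toward the depth-hardened value)
  s80 <- make_spectrum(80)
  ct80 <- dectlab:::simulate_scan_spectrum(vol, m, s80, acq, 1)
  measured <- mean(ct80$hu[, , 1][d2 < 6^2])
  expect_lt(measured, analytic(effective_energy(s80)))
  expect_gt(measured, 0.5 * analytic(effective_energy(s80)))
})

test_that("CT volumes round-trip through NIfTI with provenance", {
  ct <- to_hounsfield(array(rnorm(64), c(4, 4, 4)), 0.2,
                      spacing_mm = c(2, 2, 2),
                      provenance = list(kind = "vms", kev = 70))
  path <- file.path(tempdir(), "ctvol")
  write_ct_volume(ct, path)
  back <- read_ct_volume(path)
  expect_equal(back$hu, ct$hu, tolerance = 1e-6)
  expect_equal(back$provenance$kev, 70)
  expect_equal(back$spacing_mm, c(2, 2, 2))
})
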