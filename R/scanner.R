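# Synthetic polychromatic CT acquisition: filtered-Kramers tube spectra,
# parallel-beam ray-driven projection through the labeled phantom,
# Poisson counting noise with a photon-starvation floor, water
# precorrection, and filtered back projection. This is the stand-in for the
# physical scanner: it preserves the artifact mechanisms under study (beam
# hardening, photon starvation) at desk scale; helical geometry, scatter and
# iterative reconstruction are deliberately out of scope.

#' Polychromatic tube spectrum (filtered Kramers model)
#'
#' Kramers bremsstrahlung as seen by an energy-integrating detector:
#' effective fluence ~ (kVp - E), attenuated by inherent aluminum filtration
#' and renormalized to unit total weight. Characteristic lines are omitted:
#' the analysis needs spectral hardening, not spectroscopic fidelity.
#'
#' @param kvp Tube peak kilovoltage, in the tube-realistic range 60-150.
#' @param n_bins Number of energy bins (>= 10).
#' @param filtration_mm_al Inherent aluminum filtration in mm (default 2.5).
#' @param n0 Photons per detector element at the air scan (total over bins).
#' @param e_min_kev Lowest retained bin energy (default 30, the lower edge of
#'   the packaged attenuation tables; softer photons are absorbed by the
#'   inherent filtration in any case).
#' @return A `spectrum` object: `kvp`, `energy_kev`, `fluence` (sums to 1),
#'   `n0`.
#' @export
make_spectrum <- function(kvp, n_bins = 24, filtration_mm_al = 6,
                          n0 = 2e7, e_min_kev = 30) {
  if (kvp < 60 || kvp > 150) stop("kvp must be in 60-150", call. = FALSE)
  if (n_bins < 10) stop("need at least 10 bins", call. = FALSE)
  if (kvp <= e_min_kev) stop("kvp below minimum bin energy", call. = FALSE)
  e <- seq(e_min_kev, kvp, length.out = n_bins)
  s <- kvp - e
  if (filtration_mm_al > 0) {
    s <- s * exp(-mass_attenuation("Al", e) * 2.699 * filtration_mm_al / 10)
  }
  s <- s / sum(s)
  structure(list(kvp = kvp, energy_kev = e, fluence = s, n0 = n0),
            class = "spectrum")
}

#' Monochromatic (single-bin) spectrum
#'
#' Degenerate spectrum used for calibration oracles and monochromatic
#' simulations.
#'
#' @param energy_kev Photon energy in keV.
#' @param n0 Photons per detector element at the air scan.
#' @export
mono_spectrum <- function(energy_kev, n0 = 2e7) {
  structure(list(kvp = energy_kev, energy_kev = energy_kev, fluence = 1,
                 n0 = n0),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %g kVp, %d bins [%g, %g] keV, n0 = %g\n",
              x$kvp, length(x$energy_kev), min(x$energy_kev),
              max(x$energy_kev), x$n0))
  invisible(x)
}

#' Fluence-weighted effective attenuation of a material under a spectrum
#'
#' @param spectrum A `spectrum`.
#' @param spec A `material_spec`.
#' @return Entrance-fluence-weighted linear attenuation, 1/cm.
#' @export
effective_mu <- function(spectrum, spec) {
  sum(spectrum$fluence * linear_attenuation(spec, spectrum$energy_kev))
}

#' Effective energy of a spectrum
#'
#' The monochromatic energy whose attenuation in the reference material
#' equals the fluence-weighted polychromatic attenuation at zero thickness.
#' Used as the default reference energy for water precorrection and for the
#' Hounsfield conversion of polychromatic reconstructions.
#'
#' @param spectrum A `spectrum`.
#' @param material Reference `material_spec`; water by default.
#' @export
effective_energy <- function(spectrum, material = NULL) {
  if (is.null(material)) material <- default_materials()$water
  if (length(spectrum$energy_kev) == 1L) return(spectrum$energy_kev)
  target <- effective_mu(spectrum, material)
  f <- function(e) linear_attenuation(material, e) - target
  stats::uniroot(f, range(spectrum$energy_kev), tol = 1e-10)$root
}

#' Parallel-beam scan geometry
#'
#' @param n_angles Projection angles, uniformly covering `[0, pi)`.
#' @param n_det Detector elements.
#' @param det_spacing_mm Detector pitch; if `NULL` it is derived at
#'   projection time so the detector row covers the grid diagonal.
#' @export
scan_geometry <- function(n_angles = 180, n_det = 256,
                          det_spacing_mm = NULL) {
  stopifnot(n_angles >= 1, n_det >= 8)
  structure(list(n_angles = n_angles, n_det = n_det,
                 det_spacing_mm = det_spacing_mm,
                 angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]),
            class = "scan_geometry")
}

geometry_detectors <- function(geom, nx, ny, spacing_mm) {
  pitch <- geom$det_spacing_mm
  if (is.null(pitch)) {
    half_diag <- sqrt((nx * spacing_mm)^2 + (ny * spacing_mm)^2) / 2
    pitch <- 2 * half_diag / geom$n_det
  }
  (seq_len(geom$n_det) - (geom$n_det + 1) / 2) * pitch
}

# per-label linear attenuation matrix (K labels x nE energies), 1/cm
label_mu_matrix <- function(vol, materials, energies) {
  labs <- sort(unique(c(0L, as.integer(names(vol$materials)))))
  mu <- matrix(0, length(labs), length(energies))
  for (i in seq_along(labs)) {
    mname <- vol$materials[[as.character(labs[i])]]
    spec <- materials[[mname]]
    if (is.null(spec)) stop("unmapped label material: ", mname, call. = FALSE)
    mu[i, ] <- linear_attenuation(spec, energies)
  }
  rownames(mu) <- as.character(labs)
  mu
}

#' Polychromatic forward projection of one phantom slice
#'
#' Parallel-beam projection on the label grid with a distance-driven
#' projector: for each view, every voxel's projected footprint (a top-hat of
#' width `spacing * (|cos| + |sin|)`) is intersected with the detector cells
#' it covers and the overlap fractions accumulate per-label path lengths per
#' detector. The splat is mass-conserving and a partition of unity across
#' the detector row, so uniform regions project without pitch/voxel moire
#' and axis-aligned slabs project exactly. Detected counts then follow the
#' spectrally integrated Beer-Lambert law
#' `N = n0 * sum_E S(E) exp(-sum_labels mu_label(E) L_label)`.
#'
#' @param vol A `labeled_volume`.
#' @param materials Named list of `material_spec` covering every label.
#' @param spectrum A `spectrum`.
#' @param geometry A [scan_geometry()].
#' @param slice z-index of the slice to project.
#' @return A `sinogram` (kind `"counts"`): `values` is `n_angles x n_det`.
#' @export
project_polychromatic <- function(vol, materials, spectrum,
                                  geometry = scan_geometry(), slice = 1L) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(spectrum, "spectrum"),
            inherits(geometry, "scan_geometry"))
  lab <- vol$labels[, , slice]
  sp <- vol$spacing_mm[1]
  nx <- nrow(lab); ny <- ncol(lab)
  mu <- label_mu_matrix(vol, materials, spectrum$energy_kev)
  lab_code <- match(as.integer(lab), as.integer(rownames(mu)))  # 1..K
  K <- nrow(mu)
  det <- geometry_detectors(geometry, nx, ny, sp)
  nd <- length(det)
  pitch <- if (nd > 1) det[2] - det[1] else sp
  # pixel-center coordinates relative to the grid center, mm
  px <- ((seq_len(nx) - (nx + 1) / 2)) * sp
  py <- ((seq_len(ny) - (ny + 1) / 2)) * sp
  PX <- rep(px, times = ny)
  PY <- rep(py, each = nx)
  edge0 <- det[1] - pitch / 2        # left edge of the first detector cell
  counts <- matrix(0, geometry$n_angles, nd)
  w <- spectrum$fluence
  code <- as.integer(lab_code)
  gbase <- nd * (code - 1L)
  for (ia in seq_along(geometry$angles)) {
    th <- geometry$angles[ia]
    wfoot <- sp * (abs(cos(th)) + abs(sin(th)))      # footprint width, mm
    t <- PX * cos(th) + PY * sin(th)
    a <- (t - wfoot / 2 - edge0) / pitch             # footprint in cell units
    b <- a + wfoot / pitch
    j1 <- floor(a)
    nspan <- ceiling(wfoot / pitch) + 1L
    Lvec <- numeric(nd * K)
    for (k in seq_len(nspan) - 1L) {
      j <- j1 + k                                    # 0-based cell index
      ov <- pmin(b, j + 1) - pmax(a, j)              # overlap, cell units
      keep <- ov > 0 & j >= 0L & j < nd
      if (!any(keep)) next
      sums <- rowsum(ov[keep], j[keep] + 1L + gbase[keep], reorder = FALSE)
      idx <- as.integer(rownames(sums))
      Lvec[idx] <- Lvec[idx] + sums
    }
    # overlap fractions (x pitch/wfoot) x voxel area / pitch, in cm
    L <- matrix(Lvec, nd, K) * (sp^2 / wfoot / 10)   # path lengths, cm
    A <- L %*% mu                                    # nd x nE line integrals
    counts[ia, ] <- as.numeric(exp(-A) %*% w) * spectrum$n0
  }
  structure(list(values = counts, angles = geometry$angles, det_mm = det,
                 kind = "counts", n0 = spectrum$n0, spectrum = spectrum),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d detectors (%s)\n",
              length(x$angles), length(x$det_mm), x$kind))
  invisible(x)
}

# run fn with a private RNG state so package randomness is reproducible and
# does not disturb the caller's stream
with_private_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

#' Poisson counting noise
#'
#' Independent Poisson draw per sinogram bin, reproducible under a fixed
#' seed. The mAs-scaled fluence (tube-current compensation between the 80 and
#' 140 kVp scans) is applied upstream through the spectrum's `n0`.
#'
#' @param sino A counts `sinogram`.
#' @param seed Integer seed.
#' @export
add_counting_noise <- function(sino, seed) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$kind != "counts") stop("need a counts sinogram", call. = FALSE)
  if (any(sino$values < 0)) stop("negative counts", call. = FALSE)
  out <- sino
  out$values[] <- with_private_seed(seed, function() {
    stats::rpois(length(sino$values), lambda = as.numeric(sino$values))
  })
  out$seed <- seed
  out
}

#' Log-normalize counts to line integrals
#'
#' `p = -ln(max(counts, floor) / flat)`. The starvation floor (default one
#' count) keeps rays that were fully absorbed behind metal finite -- the
#' mechanism that turns photon starvation into bright streaks.
#'
#' @param sino A counts `sinogram`.
#' @param flat_field Air-scan counts per detector (default the spectrum
#'   `n0`).
#' @param starvation_floor Minimum counts substituted before the log.
#' @export
log_normalize <- function(sino, flat_field = NULL, starvation_floor = 1) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$kind != "counts") stop("need a counts sinogram", call. = FALSE)
  if (is.null(flat_field)) flat_field <- sino$n0
  if (any(flat_field <= 0)) stop("non-positive flat field", call. = FALSE)
  out <- sino
  out$values <- -log(pmax(sino$values, starvation_floor) / flat_field)
  out$kind <- "line_integral"
  out
}

#' Water precorrection of polychromatic line integrals
#'
#' Maps each measured polychromatic line integral to the monochromatic
#' equivalent `mu_w(E_ref) * L` of the water thickness `L` that would have
#' produced it under this spectrum, using a calibration table computed by
#' direct spectral integration. Removes first-order (water) beam hardening:
#' a uniform water object reconstructs flat. Monochromatic spectra map to
#' the identity.
#'
#' @param sino A line-integral `sinogram`.
#' @param spectrum The acquisition `spectrum`.
#' @param water Water `material_spec` (default packaged water).
#' @param reference_energy_kev Reference energy; default the spectrum's
#'   [effective_energy()], which makes the correction an identity at zero
#'   thickness.
#' @param max_thickness_cm Calibration range (default 60 cm); line integrals
#'   beyond it are extrapolated linearly with a warning.
#' @param warn Warn on out-of-range extrapolation. Scans containing metal
#'   always exceed the water calibration range; the linear extension is the
#'   intended extended-scale behaviour there, so the scan driver disables
#'   the warning.
#' @export
water_precorrect <- function(sino, spectrum, water = NULL,
                             reference_energy_kev = NULL,
                             max_thickness_cm = 60, warn = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$kind != "line_integral") {
    stop("need a log-normalized sinogram", call. = FALSE)
  }
  if (is.null(water)) water <- default_materials()$water
  if (is.null(reference_energy_kev)) {
    reference_energy_kev <- effective_energy(spectrum, water)
  }
  mu_ref <- linear_attenuation(water, reference_energy_kev)
  mu_w <- linear_attenuation(water, spectrum$energy_kev)
  L <- seq(0, max_thickness_cm, length.out = 1024)
  p_cal <- -log(as.numeric(exp(-outer(L, mu_w)) %*% spectrum$fluence))
  p <- sino$values
  if (warn && any(p > max(p_cal))) {
    warning("line integrals beyond calibration range; extrapolating linearly")
  }
  # monotone calibration, linear extrapolation beyond either end
  slope_hi <- (L[length(L)] - L[length(L) - 1]) /
    (p_cal[length(p_cal)] - p_cal[length(p_cal) - 1])
  Lhat <- stats::approx(p_cal, L, xout = pmax(p, 0), rule = 2)$y
  over <- p > max(p_cal)
  if (any(over)) {
    Lhat[over] <- L[length(L)] + (p[over] - max(p_cal)) * slope_hi
  }
  out <- sino
  out$values <- array(mu_ref * Lhat, dim = dim(sino$values))
  out$reference_energy_kev <- reference_energy_kev
  out
}

# Ram-Lak spatial kernel frequency response with optional window, length m
fbp_filter_freq <- function(m, dt_cm, filter_name) {
  n <- m %/% 2
  h <- numeric(m)
  h[1] <- 1 / (4 * dt_cm^2)
  k <- seq_len(n)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2 * dt_cm^2)
  h[m + 1 - odd] <- -1 / (pi^2 * odd^2 * dt_cm^2)
  H <- Re(stats::fft(h))
  fr <- pmin(seq_len(m) - 1, m - (seq_len(m) - 1)) / m  # 0..0.5 cycles/sample
  win <- switch(filter_name,
    ramp = rep(1, m),
    `shepp-logan` = ifelse(fr == 0, 1, sin(pi * fr) / (pi * fr)),
    cosine = cos(pi * fr),
    stop("unknown filter: ", filter_name, call. = FALSE)
  )
  H * win
}

#' Filtered back projection (parallel beam)
#'
#' Classical FBP: each projection is convolved with the band-limited ramp
#' kernel (optionally windowed), then back-projected with linear
#' interpolation. Linear in the sinogram by construction.
#'
#' @param sino A line-integral `sinogram` with angles covering 180 degrees
#'   (at least 90 of them).
#' @param grid Reconstruction grid: list with `nx`, `ny`, `spacing_mm`
#'   (pixel centers mirror the phantom convention).
#' @param filter_name `"ramp"`, `"shepp-logan"` or `"cosine"`.
#' @return Matrix `nx x ny` of linear attenuation values, 1/cm.
#' @export
reconstruct_fbp <- function(sino, grid, filter_name = "ramp") {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$kind != "line_integral") {
    stop("need a log-normalized sinogram", call. = FALSE)
  }
  if (length(sino$angles) < 90) stop("need >= 90 angles over 180 degrees",
                                     call. = FALSE)
  p <- sino$values
  na <- nrow(p); nd <- ncol(p)
  dt_cm <- (sino$det_mm[2] - sino$det_mm[1]) / 10
  m <- 2^ceiling(log2(2 * nd))
  H <- fbp_filter_freq(m, dt_cm, filter_name)
  pad <- matrix(0, na, m)
  pad[, seq_len(nd)] <- p
  q <- t(apply(pad, 1, function(row) {
    Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / m
  }))[, seq_len(nd), drop = FALSE] * dt_cm
  nx <- grid$nx; ny <- grid$ny; sp <- grid$spacing_mm
  x <- (seq_len(nx) - (nx + 1) / 2) * sp
  y <- (seq_len(ny) - (ny + 1) / 2) * sp
  img <- matrix(0, nx, ny)
  t0 <- sino$det_mm[1]; dt_mm <- sino$det_mm[2] - sino$det_mm[1]
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  for (ia in seq_len(na)) {
    th <- sino$angles[ia]
    tt <- (X * cos(th) + Y * sin(th) - t0) / dt_mm + 1
    i0 <- floor(tt)
    frac <- tt - i0
    i0[i0 < 1 | i0 >= nd] <- NA
    v <- q[ia, i0] * (1 - frac) + q[ia, pmin(i0 + 1, nd)] * frac
    v[is.na(v)] <- 0
    img <- img + v
  }
  img * pi / na
}

#' Convert an attenuation image to Hounsfield units
#'
#' `HU = 1000 (mu - mu_w) / mu_w`, clamped below at the extended-scale floor
#' used for dark-artifact segmentation.
#'
#' @param mu_image Attenuation array (1/cm), 2-D or 3-D.
#' @param mu_water_effective Water attenuation of the provenance energy or
#'   spectrum, 1/cm (> 0).
#' @param spacing_mm Voxel spacing.
#' @param provenance List describing the origin, e.g.
#'   `list(kind = "polychromatic", kvp = 80)`.
#' @param floor_hu,ceiling_hu HU clamp (default floor -1042, no ceiling).
#' @param origin_mm Physical coordinate of the volume corner.
#' @return A `ct_volume`.
#' @export
to_hounsfield <- function(mu_image, mu_water_effective,
                          spacing_mm = c(1, 1, 1),
                          provenance = list(kind = "unknown"),
                          floor_hu = -1042, ceiling_hu = Inf,
                          origin_mm = c(0, 0, 0)) {
  if (mu_water_effective <= 0) stop("mu_water must be > 0", call. = FALSE)
  hu <- 1000 * (mu_image - mu_water_effective) / mu_water_effective
  hu <- pmax(hu, floor_hu)
  hu <- pmin(hu, ceiling_hu)
  if (is.matrix(hu)) hu <- array(hu, dim = c(dim(hu), 1L))
  structure(list(hu = hu, spacing_mm = rep(spacing_mm, length.out = 3),
                 provenance = provenance, origin_mm = origin_mm),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d @ %.3g mm, %s\n", d[1], d[2], d[3],
              x$spacing_mm[1], provenance_label(x$provenance)))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$hu), max(x$hu)))
  invisible(x)
}

provenance_label <- function(p) {
  if (!is.null(p$kvp)) sprintf("%gkVp", p$kvp)
  else if (!is.null(p$kev)) sprintf("%gkeV", p$kev)
  else p$kind %||% "unknown"
}

#' Acquisition parameter set for [simulate_scan()]
#'
#' Desk-scale defaults: 180 angles, 256 detectors, ramp filter, Poisson
#' noise on, water precorrection on, reference fluence 2e5 photons/detector
#' at 91 mAs (the 140 kVp tube-current-time product); other kVp stations are
#' scaled by their mAs, e.g. the 80 kVp scan at 265 mAs uses 265/91 x that
#' fluence, emulating the noise-matched dual-scan protocol.
#'
#' @param n_angles,n_det,filter_name Geometry and reconstruction filter.
#' @param noise Add Poisson counting noise?
#' @param precorrect Apply water precorrection?
#' @param n0_ref Air-scan photons per detector at `mas_ref`.
#' @param mas Named tube-current-time products per kVp station.
#' @param mas_ref Reference mAs for `n0_ref`.
#' @param n_bins,filtration_mm_al Spectrum model parameters.
#' @param starvation_floor Counts floor in the log step.
#' @param floor_hu,ceiling_hu Extended-HU clamp of the output volume.
#' @export
acquisition_params <- function(n_angles = 180, n_det = 256,
                               filter_name = "ramp", noise = TRUE,
                               precorrect = TRUE, n0_ref = 2e7,
                               mas = c("80" = 265, "140" = 91),
                               mas_ref = 91, n_bins = 24,
                               filtration_mm_al = 6,
                               starvation_floor = 1,
                               floor_hu = -1042, ceiling_hu = Inf) {
  list(n_angles = n_angles, n_det = n_det, filter_name = filter_name,
       noise = noise, precorrect = precorrect, n0_ref = n0_ref, mas = mas,
       mas_ref = mas_ref, n_bins = n_bins,
       filtration_mm_al = filtration_mm_al,
       starvation_floor = starvation_floor, floor_hu = floor_hu,
       ceiling_hu = ceiling_hu)
}

#' Simulate a polychromatic CT scan of a phantom
#'
#' Slice by slice: spectrum -> projection -> Poisson noise -> log-normalize
#' -> water precorrection -> FBP -> Hounsfield conversion. The effective
#' water attenuation used for the HU scale is the fluence-weighted water
#' attenuation of the spectrum, so noise-free water reconstructs near 0 HU.
#' Per-slice noise seeds are derived from the master seed by fixed offsets.
#'
#' @param phantom A `labeled_volume` (all of its z slices are scanned).
#' @param materials Named `material_spec` list covering every label.
#' @param kvp Tube voltage; its mAs scaling comes from `params$mas`.
#' @param params An [acquisition_params()] list.
#' @param seed Master seed for the counting noise.
#' @return A `ct_volume` tagged with polychromatic provenance.
#' @export
simulate_scan <- function(phantom, materials, kvp,
                          params = acquisition_params(), seed = 1L) {
  stopifnot(inherits(phantom, "labeled_volume"))
  mas_scale <- 1
  if (!is.null(params$mas) && as.character(kvp) %in% names(params$mas)) {
    mas_scale <- params$mas[[as.character(kvp)]] / params$mas_ref
  }
  spectrum <- make_spectrum(kvp, n_bins = params$n_bins,
                            filtration_mm_al = params$filtration_mm_al,
                            n0 = params$n0_ref * mas_scale)
  simulate_scan_spectrum(phantom, materials, spectrum, params, seed,
                         provenance = list(kind = "polychromatic",
                                           kvp = kvp, seed = seed))
}

# shared scan driver, also used with mono spectra in tests/oracles
simulate_scan_spectrum <- function(phantom, materials, spectrum,
                                   params = acquisition_params(),
                                   seed = 1L, provenance = NULL) {
  d <- dim(phantom$labels)
  geom <- scan_geometry(params$n_angles, params$n_det)
  grid <- list(nx = d[1], ny = d[2], spacing_mm = phantom$spacing_mm[1])
  water <- materials$water %||% default_materials()$water
  mu_w_eff <- effective_mu(spectrum, water)
  mu_stack <- array(0, dim = d)
  for (iz in seq_len(d[3])) {
    sino <- project_polychromatic(phantom, materials, spectrum, geom,
                                  slice = iz)
    if (params$noise) sino <- add_counting_noise(sino, seed + 101L * (iz - 1L))
    sino <- log_normalize(sino, starvation_floor = params$starvation_floor)
    if (params$precorrect && length(spectrum$energy_kev) > 1L) {
      sino <- water_precorrect(sino, spectrum, water = water, warn = FALSE)
    }
    mu_stack[, , iz] <- reconstruct_fbp(sino, grid, params$filter_name)
  }
  if (is.null(provenance)) {
    provenance <- list(kind = "monochromatic", kev = spectrum$energy_kev[1],
                       seed = seed)
  }
  to_hounsfield(mu_stack, mu_w_eff, spacing_mm = phantom$spacing_mm,
                provenance = provenance, floor_hu = params$floor_hu,
                ceiling_hu = params$ceiling_hu,
                origin_mm = phantom$origin_mm %||% c(0, 0, 0))
}

#' Write / read a CT volume as NIfTI with a JSON sidecar
#'
#' @param ct A `ct_volume`.
#' @param path Path without extension.
#' @export
write_ct_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- RNifti::asNifti(ct$hu, pixdim = ct$spacing_mm)
  RNifti::writeNifti(img, paste0(path, ".nii"))
  jsonlite::write_json(list(provenance = ct$provenance,
                            spacing_mm = ct$spacing_mm,
                            origin_mm = ct$origin_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c(".nii", ".json")))
}

#' @rdname write_ct_volume
#' @param path Path without extension (expects `<path>.nii` + `<path>.json`).
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(hu = array(as.numeric(img), dim = dim(img)),
                 spacing_mm = side$spacing_mm,
                 provenance = as.list(side$provenance),
                 origin_mm = side$origin_mm),
            class = "ct_volume")
}
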