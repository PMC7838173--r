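# Orchestration of the full three-alloy experiment: phantom -> dual-kVp
# polychromatic scans -> seven-energy VMS series -> artifact volumetry, ROI
# density/deviation tables, SNR and monochromatic-vs-polychromatic paired
# comparisons.

#' Experiment configuration
#'
#' Desk-scale defaults reproduce the study protocol: the full 400 x 335 x
#' 170 mm phantom at 2.1 mm voxels (about a 160 x 81 transverse grid), one
#' stem per alloy (titanium, chrome-cobalt, stainless steel), sequential
#' 80/140 kVp scans with 265/91 mAs fluence scaling, VMS synthesis at
#' 40/50/70/100/120/140/190 keV. The reconstructed slab spans the stem and
#' every pellet, and per-pellet ROIs follow the eight-slice protocol.
#'
#' @param phantom A [phantom_config()]; its `stem_material` is overridden
#'   per alloy.
#' @param alloys Character vector of stem material names.
#' @param kvp_pair Low/high tube voltages.
#' @param energies_kev VMS energy stations (sorted, unique).
#' @param thresholds An [artifact_thresholds()].
#' @param acquisition An [acquisition_params()].
#' @param slab_margin_mm Axial margin of the reconstructed slab beyond the
#'   stem/pellet extent.
#' @param roi_n_slices ROI slice count per pellet (8 in the protocol).
#' @param seed Master seed; every stochastic stage derives from it.
#' @export
experiment_config <- function(phantom = phantom_config(spacing_mm = 2.1),
                              alloys = c("titanium_alloy", "chrome_cobalt",
                                         "stainless_steel"),
                              kvp_pair = c(80, 140),
                              energies_kev = c(40, 50, 70, 100, 120, 140, 190),
                              thresholds = artifact_thresholds(),
                              acquisition = acquisition_params(),
                              slab_margin_mm = 10,
                              roi_n_slices = 8,
                              seed = 17) {
  stopifnot(length(kvp_pair) == 2, kvp_pair[1] < kvp_pair[2],
            length(alloys) >= 1, roi_n_slices >= 1)
  if (anyDuplicated(energies_kev) || is.unsorted(energies_kev)) {
    stop("energies must be sorted and unique", call. = FALSE)
  }
  structure(list(phantom = phantom, alloys = alloys, kvp_pair = kvp_pair,
                 energies_kev = energies_kev, thresholds = thresholds,
                 acquisition = acquisition,
                 slab_margin_mm = slab_margin_mm,
                 roi_n_slices = roi_n_slices,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full multi-alloy DECT experiment
#'
#' Deterministic under a fixed master seed. For each alloy: build the
#' phantom, scan at both kVp stations, decompose once and synthesize the VMS
#' series, then measure artifact volumes (prosthesis subtracted), per-pellet
#' ROI statistics, reference-pellet SNR, and the monochromatic-vs-spectral
#' paired comparisons.
#'
#' @param config An [experiment_config()].
#' @param materials Material list (default packaged materials).
#' @param keep_volumes Keep the HU volumes in the returned bundle (needed
#'   for [write_bundle()] volume export; tables are always kept).
#' @param verbose Emit per-stage progress messages.
#' @return An `experiment_bundle`: `artifacts`, `roi`, `snr_table`, `stats`
#'   data frames, per-alloy volumes (if kept), the config and a manifest.
#' @export
run_experiment <- function(config = experiment_config(),
                           materials = NULL, keep_volumes = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(materials)) materials <- default_materials()
  say <- function(...) if (verbose) message(sprintf(...))
  acq <- config$acquisition
  sp_low <- make_spectrum(config$kvp_pair[1], n_bins = acq$n_bins,
                          filtration_mm_al = acq$filtration_mm_al)
  sp_high <- make_spectrum(config$kvp_pair[2], n_bins = acq$n_bins,
                           filtration_mm_al = acq$filtration_mm_al)
  cal <- calibrate_basis(sp_low, sp_high, materials = materials)

  artifacts <- list(); roi <- list(); volumes <- list()
  for (ai in seq_along(config$alloys)) {
    alloy <- config$alloys[ai]
    say("[%s] building phantom", alloy)
    pcfg <- config$phantom
    pcfg$stem_material <- alloy
    ph_full <- build_phantom(pcfg)
    ph <- crop_slices(ph_full, stem_slab_slices(ph_full,
                                                config$slab_margin_mm))
    rm(ph_full)
    imask <- implant_mask(ph)
    seed_a <- config$seed + 10000L * (ai - 1L)
    say("[%s] scanning at %g kVp", alloy, config$kvp_pair[1])
    img_low <- simulate_scan(ph, materials, config$kvp_pair[1], acq, seed_a)
    say("[%s] scanning at %g kVp", alloy, config$kvp_pair[2])
    img_high <- simulate_scan(ph, materials, config$kvp_pair[2], acq,
                              seed_a + 5000L)
    say("[%s] VMS synthesis", alloy)
    vms <- vms_series(img_low, img_high, cal, config$energies_kev)
    vols <- c(stats::setNames(list(img_low, img_high),
                              sprintf("%gkVp", config$kvp_pair)),
              vms)
    say("[%s] quantification", alloy)
    rois <- lapply(1:6, function(k) {
      pellet_roi_mask(ph, k, n_slices = config$roi_n_slices)
    })
    for (vn in names(vols)) {
      v <- vols[[vn]]
      ar <- segment_artifacts(v, imask, config$thresholds)
      ar$alloy <- alloy
      ar$energy <- energy_of(v)
      ar$kind <- v$provenance$kind
      artifacts[[length(artifacts) + 1L]] <- ar
      for (k in 1:6) {
        rr <- roi_statistics(v, rois[[k]], pellet_id = k)
        rr$alloy <- alloy
        rr$energy <- energy_of(v)
        rr$kind <- v$provenance$kind
        roi[[length(roi) + 1L]] <- rr
      }
    }
    if (keep_volumes) volumes[[alloy]] <- vols
  }
  artifacts <- do.call(rbind, artifacts)
  roi <- do.call(rbind, roi)
  ref <- roi[roi$pellet == 1 & roi$sd_hu > 0, ]
  snr_table <- data.frame(alloy = ref$alloy, provenance = ref$provenance,
                          energy = ref$energy, kind = ref$kind,
                          snr = ref$mean_hu / ref$sd_hu)
  bundle <- structure(
    list(artifacts = artifacts, roi = roi, snr_table = snr_table,
         stats = NULL, volumes = volumes, config = config,
         manifest = list(config_md5 = config_hash(config),
                         seed = config$seed,
                         package_version =
                           as.character(utils::packageVersion("dectlab")))),
    class = "experiment_bundle"
  )
  bundle$stats <- compare_mono_vs_spectral(bundle)
  bundle
}

# numeric energy tag of a volume: keV for VMS/mono, kVp for polychromatic
energy_of <- function(v) {
  v$provenance$kev %||% v$provenance$kvp
}

#' Monochromatic-versus-polychromatic comparison table
#'
#' For each alloy, pairs the 70 keV VMS with the 80 kVp scan and the 140 keV
#' VMS with the 140 kVp scan: a paired t test on the six per-pellet density
#' deviations, plus the dark/bright artifact-volume differences
#' (monochromatic minus polychromatic).
#'
#' @param bundle An `experiment_bundle` containing those four provenances.
#' @return Data frame with one row per alloy x comparison.
#' @export
compare_mono_vs_spectral <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  pairs <- list(c("70keV", "80kVp"), c("140keV", "140kVp"))
  roi <- bundle$roi; art <- bundle$artifacts
  out <- list()
  for (alloy in unique(roi$alloy)) {
    for (pr in pairs) {
      sd_m <- roi$sd_hu[roi$alloy == alloy & roi$provenance == pr[1]]
      sd_p <- roi$sd_hu[roi$alloy == alloy & roi$provenance == pr[2]]
      if (length(sd_m) != 6 || length(sd_p) != 6) {
        stop("bundle is missing provenance ", paste(pr, collapse = "/"),
             call. = FALSE)
      }
      tt <- paired_t_test(sd_m, sd_p)
      am <- art[art$alloy == alloy & art$provenance == pr[1], ]
      ap <- art[art$alloy == alloy & art$provenance == pr[2], ]
      out[[length(out) + 1L]] <- data.frame(
        alloy = alloy, mono = pr[1], spectral = pr[2],
        t = tt$t, df = tt$df, p = tt$p,
        dark_diff_cm3 = am$dark_cm3 - ap$dark_cm3,
        bright_diff_cm3 = am$bright_cm3 - ap$bright_cm3)
    }
  }
  do.call(rbind, out)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d alloy(s), seed %d, config %s\n",
              length(unique(x$artifacts$alloy)), x$manifest$seed,
              substr(x$manifest$config_md5, 1, 8)))
  cat(sprintf("  %d artifact reports, %d ROI rows\n",
              nrow(x$artifacts), nrow(x$roi)))
  invisible(x)
}

#' @export
summary.experiment_bundle <- function(object, ...) {
  art <- object$artifacts
  vms <- art[art$kind == "vms", ]
  for (alloy in unique(art$alloy)) {
    a <- vms[vms$alloy == alloy, ]
    a <- a[order(a$energy), ]
    cat(sprintf("%s: dark %0.1f -> %0.1f cm^3 (40 -> %g keV, reduction %.1f%%)\n",
                alloy, a$dark_cm3[1], a$dark_cm3[nrow(a)],
                a$energy[nrow(a)],
                reduction_fraction(a$dark_cm3[1], a$dark_cm3[nrow(a)])))
  }
  invisible(object)
}

#' Artifact-volume-versus-energy curves
#'
#' Plots dark (solid) and bright (dashed) artifact volume against VMS energy
#' for every alloy in the bundle.
#'
#' @param x An `experiment_bundle`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.experiment_bundle <- function(x, ...) {
  art <- x$artifacts[x$artifacts$kind == "vms", ]
  alloys <- unique(art$alloy)
  en <- sort(unique(art$energy))
  dark <- sapply(alloys, function(a) {
    art$dark_cm3[art$alloy == a][order(art$energy[art$alloy == a])]
  })
  bright <- sapply(alloys, function(a) {
    art$bright_cm3[art$alloy == a][order(art$energy[art$alloy == a])]
  })
  graphics::matplot(en, dark, type = "b", pch = 16, lty = 1,
                    xlab = "VMS energy (keV)",
                    ylab = expression(volume ~ (cm^3)), ...)
  graphics::matlines(en, bright, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c(alloys, "dark", "bright"),
                   col = c(seq_along(alloys), 1, 1),
                   lty = c(rep(1, length(alloys)), 1, 2), bty = "n")
  invisible(x)
}

format_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 12, format = "g") else x
}

#' Write an experiment bundle to disk
#'
#' Tables as CSV with pinned floating-point formatting (so a fixed config
#' and seed reproduce every byte), a JSON summary with the manifest, and
#' optionally every HU volume as NIfTI + JSON sidecar.
#'
#' @param bundle An `experiment_bundle`.
#' @param dir Output directory (created if missing).
#' @param save_volumes Write NIfTI volumes too?
#' @export
write_bundle <- function(bundle, dir, save_volumes = FALSE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(artifacts = bundle$artifacts, roi = bundle$roi,
               snr = bundle$snr_table, stats = bundle$stats)
  for (nm in names(tabs)) {
    tb <- as.data.frame(lapply(tabs[[nm]], format_num))
    utils::write.csv(tb, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (save_volumes && length(bundle$volumes)) {
    for (alloy in names(bundle$volumes)) {
      ad <- file.path(dir, alloy)
      dir.create(ad, showWarnings = FALSE)
      for (vn in names(bundle$volumes[[alloy]])) {
        write_ct_volume(bundle$volumes[[alloy]][[vn]], file.path(ad, vn))
      }
    }
  }
  invisible(dir)
}
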