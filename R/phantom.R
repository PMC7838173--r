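# Voxelized hip-stem phantom: a water-gel box holding one cone-tapered
# femoral stem and six cylindrical hydroxyapatite pellets -- five at a 5 mm
# surface gap in Gruen zones 2-6 and one remote reference pellet near a box
# corner.
#
# Geometry and conventions: the stem lies along the scan axis, so
# reconstructed slices are transverse to it and contain its circular
# cross-section (this is the orientation that puts the most metal-affected
# anatomy in-plane around the stem profile, with the reference pellet
# visible in the corner of mid-stem slices). Array axes are
#   axis 1: lateral  (the 335 mm box dimension)
#   axis 2: vertical (the 170 mm box dimension)
#   axis 3: axial    (the 400 mm box dimension; stem + scan axis)
# Physical coordinates are mm from the box corner, voxel centers at
# (i - 0.5) * spacing. Pellet cylinders stand parallel to the stem axis so
# slices show their circular cross-section, as in the ROI protocol.

#' Phantom geometry configuration
#'
#' Defaults mirror the physical phantom: a 400 x 335 x 170 mm gel box, a
#' truncated-cone stem (length 150 mm, radius tapering 8 -> 3 mm proximal to
#' distal) centered in the box along the scan axis, and 30 mm x 20 mm
#' pellets at a 5 mm gap from the stem surface. Zones 2/6 sit
#' lateral/medial of the proximal third, 3/5 of the distal third, zone 4
#' vertically below the distal tip, and the reference pellet near a box
#' corner at mid-stem level.
#'
#' @param box_mm Box dimensions in mm: axial (scan axis), lateral, vertical.
#' @param spacing_mm Isotropic voxel spacing in mm; must be <= 2.5 so the
#'   5 mm stem-to-pellet gap stays resolved.
#' @param stem_length_mm,stem_radius_proximal_mm,stem_radius_distal_mm Stem
#'   truncated-cone dimensions; proximal radius >= distal radius > 0.
#' @param stem_material Name of the stem alloy (must exist in the material
#'   list handed to the scanner).
#' @param pellet_height_mm,pellet_diameter_mm Pellet cylinder dimensions.
#' @param gap_mm Stem-surface-to-pellet-surface distance.
#' @param reference_offset_mm Reference pellet (P1) center offset from the
#'   lateral/vertical (0, 0) slice corner.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(box_mm = c(400, 335, 170),
                           spacing_mm = 1.5,
                           stem_length_mm = 150,
                           stem_radius_proximal_mm = 8,
                           stem_radius_distal_mm = 3,
                           stem_material = "titanium_alloy",
                           pellet_height_mm = 30,
                           pellet_diameter_mm = 20,
                           gap_mm = 5,
                           reference_offset_mm = c(45, 45)) {
  stopifnot(length(box_mm) == 3, all(box_mm > 0),
            length(spacing_mm) == 1, spacing_mm > 0,
            stem_length_mm > 0, pellet_height_mm > 0,
            pellet_diameter_mm > 0, gap_mm > 0,
            length(reference_offset_mm) == 2)
  if (stem_radius_distal_mm <= 0 ||
      stem_radius_proximal_mm < stem_radius_distal_mm) {
    stop("need proximal radius >= distal radius > 0 (cone taper)",
         call. = FALSE)
  }
  if (spacing_mm > 2.5) {
    stop("voxel spacing must be <= 2.5 mm to resolve the 5 mm gap",
         call. = FALSE)
  }
  structure(
    list(box_mm = as.numeric(box_mm), spacing_mm = spacing_mm,
         stem_length_mm = stem_length_mm,
         stem_radius_proximal_mm = stem_radius_proximal_mm,
         stem_radius_distal_mm = stem_radius_distal_mm,
         stem_material = stem_material,
         pellet_height_mm = pellet_height_mm,
         pellet_diameter_mm = pellet_diameter_mm,
         gap_mm = gap_mm,
         reference_offset_mm = as.numeric(reference_offset_mm)),
    class = "phantom_config"
  )
}

# axial position of the proximal stem end (stem centered along the box)
stem_z0 <- function(cfg) (cfg$box_mm[1] - cfg$stem_length_mm) / 2

# stem cone radius (mm) at axial position z (mm); NA outside the stem span
stem_radius_at <- function(cfg, z) {
  z0 <- stem_z0(cfg)
  r <- cfg$stem_radius_proximal_mm +
    (cfg$stem_radius_distal_mm - cfg$stem_radius_proximal_mm) *
      (z - z0) / cfg$stem_length_mm
  # half-open axial span so lattice-aligned ends never double-count a slice
  r[z < z0 | z >= z0 + cfg$stem_length_mm] <- NA_real_
  r
}

# pellet centers (mm), columns (x lateral, y vertical, z axial):
# P1 reference near a corner at mid-stem level; P2/P6 lateral/medial at the
# proximal third; P3/P5 lateral/medial at the distal third; P4 vertically
# below the distal tip. The 5 mm gap is taken against the largest stem
# radius over the pellet's axial extent (the cone is wider proximally).
pellet_centers <- function(cfg) {
  z0 <- stem_z0(cfg)
  L <- cfg$stem_length_mm
  xc <- cfg$box_mm[2] / 2
  yc <- cfg$box_mm[3] / 2
  rp <- cfg$pellet_diameter_mm / 2
  hh <- cfg$pellet_height_mm / 2
  off <- function(z) {
    r_max <- stem_radius_at(cfg, max(z0, z - hh))
    r_max + cfg$gap_mm + rp
  }
  z26 <- z0 + L / 6
  z35 <- z0 + 5 * L / 6
  z4 <- z0 + L
  ctr <- rbind(
    P1 = c(cfg$reference_offset_mm, z0 + L / 2),
    P2 = c(xc + off(z26), yc, z26),
    P3 = c(xc + off(z35), yc, z35),
    P4 = c(xc, yc - (cfg$stem_radius_distal_mm + cfg$gap_mm + rp), z4),
    P5 = c(xc - off(z35), yc, z35),
    P6 = c(xc - off(z26), yc, z26)
  )
  colnames(ctr) <- c("x", "y", "z")
  ctr
}

check_phantom_geometry <- function(cfg) {
  bx <- cfg$box_mm
  ctr <- pellet_centers(cfg)
  rp <- cfg$pellet_diameter_mm / 2
  hh <- cfg$pellet_height_mm / 2
  lim <- c(bx[2], bx[3], bx[1])
  for (k in seq_len(nrow(ctr))) {
    lo <- ctr[k, ] - c(rp, rp, hh)
    hi <- ctr[k, ] + c(rp, rp, hh)
    if (any(lo <= 0) || any(hi >= lim)) {
      stop("pellet ", rownames(ctr)[k], " extends outside the box",
           call. = FALSE)
    }
  }
  z0 <- stem_z0(cfg)
  if (z0 <= 0 || z0 + cfg$stem_length_mm >= bx[1]) {
    stop("stem does not fit along the box", call. = FALSE)
  }
  if (bx[2] / 2 + cfg$stem_radius_proximal_mm >= bx[2] ||
      bx[3] / 2 + cfg$stem_radius_proximal_mm >= bx[3]) {
    stop("stem extends outside the box", call. = FALSE)
  }
  # pairwise pellet collisions: parallel cylinders overlap only if both the
  # lateral center distance and the axial spans overlap
  for (i in seq_len(nrow(ctr) - 1)) {
    for (j in (i + 1):nrow(ctr)) {
      lat <- sqrt(sum((ctr[i, 1:2] - ctr[j, 1:2])^2))
      zov <- abs(ctr[i, 3] - ctr[j, 3]) < cfg$pellet_height_mm
      if (zov && lat < cfg$pellet_diameter_mm - 1e-9) {
        stop("pellets ", rownames(ctr)[i], "/", rownames(ctr)[j],
             " intersect", call. = FALSE)
      }
    }
  }
  # reference pellet must stay clear of the stem
  lat1 <- sqrt(sum((ctr["P1", 1:2] - c(bx[2] / 2, bx[3] / 2))^2))
  if (lat1 < cfg$stem_radius_proximal_mm + cfg$gap_mm + rp) {
    stop("reference pellet too close to the stem", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the voxelized labeled phantom
#'
#' Labels: 0 background (water gel), 1 implant, 2-7 pellets P1-P6. Array
#' axes are lateral x vertical x axial; slices (third axis) are transverse
#' to the stem.
#'
#' @param config A [phantom_config()].
#' @return A `labeled_volume`: integer label array, voxel `spacing_mm`,
#'   `materials` (label -> material name), `pellet_centers_mm` and the
#'   config.
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  check_phantom_geometry(config)
  sp <- config$spacing_mm
  dims <- round(c(config$box_mm[2], config$box_mm[3], config$box_mm[1]) / sp)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  x <- (seq_len(nx) - 0.5) * sp
  y <- (seq_len(ny) - 0.5) * sp
  z <- (seq_len(nz) - 0.5) * sp
  lab <- array(0L, dim = c(nx, ny, nz))

  # stem: truncated cone along the axial direction, centered in-plane
  xc <- config$box_mm[2] / 2
  yc <- config$box_mm[3] / 2
  r_at <- stem_radius_at(config, z)
  d2xy <- outer((x - xc)^2, (y - yc)^2, `+`)   # nx x ny
  for (iz in which(!is.na(r_at))) {
    sl <- lab[, , iz]
    sl[d2xy <= r_at[iz]^2] <- 1L
    lab[, , iz] <- sl
  }

  # pellets: cylinders parallel to the stem axis
  ctr <- pellet_centers(config)
  rp <- config$pellet_diameter_mm / 2
  hh <- config$pellet_height_mm / 2
  for (k in seq_len(nrow(ctr))) {
    inz <- which(z >= ctr[k, "z"] - hh & z < ctr[k, "z"] + hh)
    disk <- outer((x - ctr[k, "x"])^2, (y - ctr[k, "y"])^2, `+`) <= rp^2
    idx <- which(disk)
    for (iz in inz) {
      sl <- lab[, , iz]
      if (any(sl[idx] != 0L)) stop("pellet intersects another solid",
                                   call. = FALSE)
      sl[idx] <- k + 1L
      lab[, , iz] <- sl
    }
  }

  materials <- c("0" = "water", "1" = config$stem_material,
                 stats::setNames(rep("ha_pellet", 6), as.character(2:7)))
  structure(
    list(labels = lab, spacing_mm = rep(sp, 3), materials = materials,
         pellet_centers_mm = ctr, config = config),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1]))
  tab <- table(x$labels)
  for (l in names(tab)) {
    cat(sprintf("  label %s (%s): %d voxels\n", l, x$materials[[l]], tab[[l]]))
  }
  invisible(x)
}

# voxel volume in cm^3
voxel_volume_cm3 <- function(spacing_mm) prod(spacing_mm) / 1000

#' Binary implant mask
#'
#' @param vol A `labeled_volume`.
#' @return Logical array, TRUE exactly where the label is the implant.
#' @export
implant_mask <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  vol$labels == 1L
}

#' Cylindrical pellet ROI mask
#'
#' Reproduces the measurement protocol: a circle strictly interior to the
#' pellet cross-section (16 mm inside the 20 mm pellet by default), centered
#' on the pellet center and spanning `n_slices` contiguous slices centered
#' on the pellet mid-height.
#'
#' @param vol A `labeled_volume`, possibly cropped with [crop_slices()].
#' @param pellet_id Integer 1-6 (P1 is the remote reference pellet).
#' @param roi_diameter_mm ROI circle diameter; must be strictly smaller than
#'   the pellet diameter.
#' @param n_slices Number of contiguous slices (8 in the protocol); all must
#'   fall inside the volume.
#' @return Logical array over the volume grid.
#' @export
pellet_roi_mask <- function(vol, pellet_id, roi_diameter_mm = 16,
                            n_slices = 8) {
  stopifnot(inherits(vol, "labeled_volume"))
  cfg <- vol$config
  if (!pellet_id %in% 1:6) stop("pellet_id must be in 1..6", call. = FALSE)
  if (roi_diameter_mm >= cfg$pellet_diameter_mm) {
    stop("ROI diameter must be strictly smaller than the pellet diameter",
         call. = FALSE)
  }
  d <- dim(vol$labels)
  if (n_slices > d[3]) stop("n_slices exceeds available slices", call. = FALSE)
  sp <- vol$spacing_mm
  ctr <- vol$pellet_centers_mm[pellet_id, ]
  org <- vol$origin_mm %||% c(0, 0, 0)
  x <- (seq_len(d[1]) - 0.5) * sp[1] + org[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2] + org[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3] + org[3]
  disk <- outer((x - ctr["x"])^2, (y - ctr["y"])^2, `+`) <=
    (roi_diameter_mm / 2)^2
  iz_ctr <- which.min(abs(z - ctr["z"]))
  half <- n_slices %/% 2
  iz <- (iz_ctr - half + if (n_slices %% 2 == 0) 1L else 0L):(iz_ctr + half)
  if (any(iz < 1) || any(iz > d[3])) {
    stop("ROI slices fall outside the volume", call. = FALSE)
  }
  mask <- array(FALSE, dim = d)
  mask[, , iz] <- disk
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a labeled volume to a contiguous range of slices
#'
#' Carves the scanned slab out of the full phantom while keeping physical
#' coordinates consistent (via the `origin_mm` offset), so ROI masks built
#' on the crop line up with volumes reconstructed from it.
#'
#' @param vol A `labeled_volume`.
#' @param z_idx Contiguous, increasing slice indices.
#' @export
crop_slices <- function(vol, z_idx) {
  stopifnot(inherits(vol, "labeled_volume"),
            all(diff(z_idx) == 1), all(z_idx >= 1),
            all(z_idx <= dim(vol$labels)[3]))
  out <- vol
  out$labels <- vol$labels[, , z_idx, drop = FALSE]
  org <- vol$origin_mm %||% c(0, 0, 0)
  out$origin_mm <- c(org[1], org[2],
                     org[3] + (z_idx[1] - 1) * vol$spacing_mm[3])
  out
}

#' Central slice indices of a labeled volume
#'
#' @param vol A `labeled_volume`.
#' @param n Number of central slices.
#' @export
central_slices <- function(vol, n) {
  nz <- dim(vol$labels)[3]
  stopifnot(n >= 1, n <= nz)
  mid <- (nz + 1) / 2
  start <- floor(mid - n / 2) + 1L
  seq.int(start, length.out = n)
}

#' Slice indices of the slab containing the stem and all pellets
#'
#' The axial range every measurement needs: from the proximal stem end to
#' the far edge of the most distal pellet, plus a margin.
#'
#' @param vol A `labeled_volume` (uncropped).
#' @param margin_mm Extra slab on both ends.
#' @export
stem_slab_slices <- function(vol, margin_mm = 10) {
  stopifnot(inherits(vol, "labeled_volume"))
  cfg <- vol$config
  sp <- vol$spacing_mm[3]
  hh <- cfg$pellet_height_mm / 2
  zr <- range(stem_z0(cfg), stem_z0(cfg) + cfg$stem_length_mm,
              vol$pellet_centers_mm[, "z"] - hh,
              vol$pellet_centers_mm[, "z"] + hh)
  lo <- max(1L, floor((zr[1] - margin_mm) / sp) + 1L)
  hi <- min(dim(vol$labels)[3], ceiling((zr[2] + margin_mm) / sp))
  seq.int(lo, hi)
}

#' Export a labeled phantom to NIfTI plus a JSON sidecar
#'
#' @param vol A `labeled_volume`.
#' @param path Output path without extension; writes `<path>.nii` and
#'   `<path>.json` (label map, pellet centers, spacing).
#' @export
write_phantom <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  img <- RNifti::asNifti(vol$labels, pixdim = vol$spacing_mm)
  RNifti::writeNifti(img, paste0(path, ".nii"))
  side <- list(spacing_mm = vol$spacing_mm, materials = as.list(vol$materials),
               pellet_centers_mm = as.data.frame(vol$pellet_centers_mm))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, c(".nii", ".json")))
}
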