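# Report every expectation rather than aborting the run at the default
# failure cap: the acceptance file asserts directional reproductions that
# are documented as not all attainable by this simulator.
options(testthat.progress.max_fails = Inf)

# Shared fixtures: a down-scaled phantom that keeps every geometric feature
# (cone taper, 5 mm gaps, six pellets, corner reference) and hand-built
# labeled volumes for projector/reconstruction oracles.

tiny_phantom_config <- function(spacing_mm = 2.5, ...) {
  phantom_config(box_mm = c(200, 170, 60), spacing_mm = spacing_mm,
                 stem_length_mm = 80, stem_radius_proximal_mm = 7,
                 stem_radius_distal_mm = 3,
                 reference_offset_mm = c(30, 30), ...)
}

# minimal labeled volume from a label array (no phantom config attached)
raw_volume <- function(labels, spacing_mm, materials) {
  structure(list(labels = labels, spacing_mm = rep(spacing_mm, 3),
                 materials = materials),
            class = "labeled_volume")
}

# centered disk of one material in a water background, single slice
disk_volume <- function(nx = 96, spacing_mm = 2, radius_mm = 40,
                        material = "ha_pellet", background = "water") {
  lab <- array(0L, c(nx, nx, 1))
  x <- (seq_len(nx) - 0.5) * spacing_mm
  ctr <- nx * spacing_mm / 2
  d2 <- outer((x - ctr)^2, (x - ctr)^2, `+`)
  lab[, , 1][d2 <= radius_mm^2] <- 1L
  raw_volume(lab, spacing_mm, c("0" = background, "1" = material))
}

# uniform water box filling the whole grid
water_box <- function(nx = 160, ny = 134, spacing_mm = 2.5) {
  raw_volume(array(0L, c(nx, ny, 1)), spacing_mm, c("0" = "water"))
}

# an effectively empty material (vacuum stand-in for projection tests)
void_material <- function() material_spec("void", 1e-9, c(H = 1))

# squared distance to a slice center, for region selection
center_d2 <- function(nx, ny, spacing_mm) {
  x <- (seq_len(nx) - 0.5) * spacing_mm - nx * spacing_mm / 2
  y <- (seq_len(ny) - 0.5) * spacing_mm - ny * spacing_mm / 2
  outer(x^2, y^2, `+`)
}
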