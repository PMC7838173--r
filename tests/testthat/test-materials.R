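test_that("mass attenuation reproduces the packaged tabulation exactly on grid points", {
  # independent re-read of the packaged table, bypassing the lookup path
  f <- system.file("extdata", "elements", "O.txt", package = "dectlab")
  tab <- read.table(f, col.names = c("e", "mu"))
  expect_identical(mass_attenuation("O", 80), tab$mu[tab$e == 80])
  for (e in tab$e) expect_identical(mass_attenuation("O", e),
                                    tab$mu[tab$e == e])
})

test_that("interpolation between grid points is log-log", {
  # geometric-mean identity at the log-midpoint of an adjacent grid pair
  f <- system.file("extdata", "elements", "Fe.txt", package = "dectlab")
  tab <- read.table(f, col.names = c("e", "mu"))
  a <- tab$mu[tab$e == 150]; b <- tab$mu[tab$e == 200]
  expect_equal(mass_attenuation("Fe", sqrt(150 * 200)), sqrt(a * b),
               tolerance = 1e-12)
})

test_that("mass attenuation rejects unknown elements and out-of-span energies", {
  expect_error(mass_attenuation("Xx", 80), "unknown element")
  expect_error(mass_attenuation("O", 20), "outside table span")
  expect_error(mass_attenuation("O", 250), "outside table span")
})

test_that("mass attenuation is positive and continuous over the span", {
  e <- seq(30, 200, by = 0.5)
  for (el in element_symbols()$symbol) {
    v <- mass_attenuation(el, e)
    expect_true(all(v > 0))
    expect_true(max(abs(diff(v)) / v[-1]) < 0.2)  # no jumps (no K-edges)
  }
})

test_that("material_spec validates composition and density", {
  expect_error(material_spec("m", 0, c(H = 1)), "positive")
  expect_error(material_spec("m", 1, c(H = 0.5)), "sum to 1")
  expect_error(material_spec("m", 1, c(H = 0.5, Zz = 0.5)), "unknown element")
  expect_error(material_spec("m", 1, c(H = 1.5, O = -0.5)), "in \\(0, 1\\]")
  expect_s3_class(material_spec("m", 1, c(H = 0.1119, O = 0.8881)),
                  "material_spec")
})

test_that("mixture rule: degenerate single-element material equals the element", {
  ti <- material_spec("ti", 4.5, c(Ti = 1))
  e <- c(40, 77, 190)
  expect_equal(mixture_mass_attenuation(ti, e), mass_attenuation("Ti", e))
})

test_that("mixture rule matches a brute-force hand summation for the pellet", {
  pellet <- default_materials()$ha_pellet
  e <- 70
  # independent oracle: manual log-log interpolation per element file
  manual <- 0
  for (el in names(pellet$composition)) {
    f <- system.file("extdata", "elements", paste0(el, ".txt"),
                     package = "dectlab")
    tab <- read.table(f, col.names = c("e", "mu"))
    i <- max(which(tab$e <= e))
    lmu <- log(tab$mu[i]) + (log(e) - log(tab$e[i])) /
      (log(tab$e[i + 1]) - log(tab$e[i])) * (log(tab$mu[i + 1]) - log(tab$mu[i]))
    manual <- manual + pellet$composition[[el]] * exp(lmu)
  }
  expect_equal(mixture_mass_attenuation(pellet, e), manual, tolerance = 1e-12)
})

test_that("mixture rule is linear: a mixture of mixtures equals the direct mixture", {
  m <- default_materials()
  w <- m$water$composition; p <- m$ha_pellet$composition
  lam <- 0.37
  comb <- c(lam * w, (1 - lam) * p)
  comb <- tapply(comb, names(comb), sum)
  direct <- material_spec("mix", 1, comb / sum(comb))
  e <- c(35, 60, 111, 190)
  expect_equal(mixture_mass_attenuation(direct, e),
               lam * mixture_mass_attenuation(material_spec("w", 1, w), e) +
                 (1 - lam) * mixture_mass_attenuation(material_spec("p", 1, p), e),
               tolerance = 1e-12)
})

test_that("linear attenuation is density times mass attenuation", {
  m <- default_materials()
  e <- c(40, 70, 150)
  expect_equal(linear_attenuation(m$water, e),
               mixture_mass_attenuation(m$water, e))  # unit density
  steel <- m$stainless_steel
  expect_equal(linear_attenuation(steel, e),
               steel$density_g_cm3 * mixture_mass_attenuation(steel, e))
})

test_that("alloy LAC ordering: titanium below steel and chrome-cobalt at all energies", {
  m <- default_materials()
  e <- 40:190
  ti <- linear_attenuation(m$titanium_alloy, e)
  fe <- linear_attenuation(m$stainless_steel, e)
  co <- linear_attenuation(m$chrome_cobalt, e)
  ha <- linear_attenuation(m$ha_pellet, e)
  expect_true(all(ti < fe))
  expect_true(all(ti < co))
  expect_true(all(ha < ti))
})

test_that("packaged LAC curves decrease strictly over 40-190 keV", {
  m <- default_materials()
  e <- seq(40, 190, by = 1)
  for (nm in names(m)) {
    expect_true(all(diff(linear_attenuation(m[[nm]], e)) < 0), label = nm)
  }
})

test_that("photoelectric dominance at 50 keV orders metals by dominant-element Z", {
  m <- default_materials()
  # dominant elements: Ti (Z 22) < Fe (Z 26) < Co (Z 27)
  v <- c(linear_attenuation(m$titanium_alloy, 50),
         linear_attenuation(m$stainless_steel, 50),
         linear_attenuation(m$chrome_cobalt, 50))
  expect_true(all(diff(v) > 0))
})

test_that("lac_curve preserves order and duplicates, one row per energy", {
  m <- default_materials()
  one <- lac_curve(m$water, 77)
  expect_equal(nrow(one), 1L)
  expect_equal(one$lac_cm1, linear_attenuation(m$water, 77))
  dup <- lac_curve(m$titanium_alloy, c(50, 50, 40))
  expect_equal(dup$energy_kev, c(50, 50, 40))
  expect_identical(dup$lac_cm1[1], dup$lac_cm1[2])
  expect_error(lac_curve(m$water, numeric(0)), "empty")
})

test_that("material files round-trip through YAML and JSON", {
  m <- default_materials()$ha_pellet
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = m$name, density_g_cm3 = m$density_g_cm3,
                        composition = as.list(m$composition)), fy)
  my <- read_material(fy)
  expect_equal(my$composition, m$composition)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = m$name, density_g_cm3 = m$density_g_cm3,
                            composition = as.list(m$composition)), fj,
                       auto_unbox = TRUE, digits = NA)
  mj <- read_material(fj)
  expect_equal(mj$density_g_cm3, m$density_g_cm3)
  expect_equal(mj$composition, m$composition)
})
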