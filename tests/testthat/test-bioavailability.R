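ref_profile <- list(nonheme_iron = 12, phytate = 990, calcium = 400,
                    vitamin_c = 50, polyphenols = 30, mfp = 100)

test_that("split_heme counts 40% of iron in heme-source foods as heme", {
  s <- split_heme(c(beef = 3, lentils = 5), c(beef = TRUE, lentils = FALSE))
  expect_equal(s$heme, 1.2)
  expect_equal(s$nonheme, 6.8)
  expect_equal(split_heme(c(a = 2), c(a = FALSE)), list(heme = 0, nonheme = 2))
  all_hsi <- split_heme(c(a = 4, b = 6), c(a = TRUE, b = TRUE))
  expect_equal(all_hsi$heme, 4)
  expect_equal(all_hsi$nonheme, 6)
  expect_error(split_heme(c(a = -1), TRUE), ">= 0")
})

test_that("each absorption algorithm reproduces an independent evaluation of
           the shipped coefficient file", {
  p <- load_absorption_params()
  with(ref_profile, {
    conway <- 9.64 + 0.045 * vitamin_c + 0.042 * mfp -
      0.0037 * phytate - 0.0016 * calcium
    rickard <- exp(2.162 + 0.094 * log1p(vitamin_c) + 0.135 * log1p(mfp) -
                     0.231 * log1p(phytate) - 0.067 * log1p(polyphenols) -
                     0.052 * log1p(calcium))
    armah <- exp(6.294 - 0.709 * log(21.7) + 0.119 * log(vitamin_c + 0.05) +
                   0.006 * mfp - 0.0003 * polyphenols -
                   0.247 * log(phytate + 0.05) - 0.137 * log(calcium + 0.05) -
                   0.083 * log(nonheme_iron + 0.05))
    expect_equal(nonheme_bioavailability(ref_profile, "conway", p), conway / 100)
    expect_equal(nonheme_bioavailability(ref_profile, "rickard", p), rickard / 100)
    expect_equal(nonheme_bioavailability(ref_profile, "armah", p), armah / 100)
  })
})

test_that("absorption algorithms share the contract: bounded, phytate never
           helps, vitamin C never hurts", {
  p <- load_absorption_params()
  set.seed(11)
  for (i in 1:20) {
    prof <- list(nonheme_iron = runif(1, 1, 30), phytate = runif(1, 0, 3000),
                 calcium = runif(1, 0, 1500), vitamin_c = runif(1, 0, 300),
                 polyphenols = runif(1, 0, 500), mfp = runif(1, 0, 400))
    for (alg in c("conway", "rickard", "armah")) {
      f0 <- nonheme_bioavailability(prof, alg, p)
      expect_gte(f0, 0.001)
      expect_lte(f0, 1)
      hi_phy <- prof; hi_phy$phytate <- prof$phytate * 2 + 100
      expect_lte(nonheme_bioavailability(hi_phy, alg, p), f0)
      hi_vc <- prof; hi_vc$vitamin_c <- prof$vitamin_c + 100
      expect_gte(nonheme_bioavailability(hi_vc, alg, p), f0)
    }
  }
  expect_error(nonheme_bioavailability(list(phytate = 1), "rickard", p),
               "missing covariate")
})

test_that("total bioavailable iron sums 25% of heme and the predicted
           non-heme fraction", {
  r <- total_bioavailable_iron(1.2, 10, 0.15)
  expect_equal(r$bioavailable_heme, 0.30)
  expect_equal(r$bioavailable_nonheme, 1.50)
  expect_equal(r$total_bioavailable, 1.80)
  expect_equal(r$percent_bioavailability, 1.80 / 11.2 * 100)

  expect_equal(total_bioavailable_iron(2, 5, 0)$total_bioavailable, 0.5)
  zero <- total_bioavailable_iron(0, 0, 0.2)
  expect_equal(zero$total_bioavailable, 0)
  expect_true(is.na(zero$percent_bioavailability))
  # never exceeds total intake
  expect_lte(total_bioavailable_iron(3, 7, 1)$total_bioavailable, 10)
  # percent invariant under uniform diet scaling at fixed fraction
  expect_equal(total_bioavailable_iron(2, 8, 0.1)$percent_bioavailability,
               total_bioavailable_iron(6, 24, 0.1)$percent_bioavailability)
})

test_that("absorbed zinc matches a brute-force root of the saturable binding
           equation and behaves at its limits", {
  p <- load_absorption_params()
  z <- p$zinc
  # independent oracle: solve TAZ * (KrP + U) = Amax * U with U = TDZ - TAZ
  taz_numeric <- function(zinc_mg, phytate_mg) {
    tdz <- zinc_mg / z$molar_mass_zinc
    tdp <- phytate_mg / z$molar_mass_phytate
    krp <- z$kr * (1 + tdp / z$kp)
    if (tdz == 0) return(0)
    f <- function(t) t * (krp + (tdz - t)) - z$amax * (tdz - t)
    stats::uniroot(f, c(0, min(z$amax, tdz)), tol = 1e-14)$root *
      z$molar_mass_zinc
  }
  for (case in list(c(9.8, 990), c(2, 0), c(15, 3000), c(0.5, 200))) {
    expect_equal(absorbed_zinc(case[1], case[2], p),
                 taz_numeric(case[1], case[2]), tolerance = 1e-9)
  }
  expect_equal(absorbed_zinc(0, 500, p), 0)
  # saturation: with no phytate and huge intake, absorption approaches Amax
  amax_mg <- z$amax * z$molar_mass_zinc
  expect_equal(absorbed_zinc(1e6, 0, p), amax_mg, tolerance = 1e-3)
  expect_lte(absorbed_zinc(1e6, 0, p), amax_mg)
})

test_that("TAZ is bounded, increasing in zinc and decreasing in phytate", {
  p <- load_absorption_params()
  amax_mg <- p$zinc$amax * p$zinc$molar_mass_zinc
  zn <- seq(0.5, 40, length.out = 12)
  taz_zn <- vapply(zn, absorbed_zinc, numeric(1), phytate_mg = 800, params = p)
  expect_true(all(diff(taz_zn) > 0))
  expect_true(all(taz_zn <= pmin(amax_mg, zn)))
  phy <- seq(0, 4000, length.out = 12)
  taz_phy <- vapply(phy, function(ph) absorbed_zinc(10, ph, p), numeric(1))
  expect_true(all(diff(taz_phy) < 0))
})

test_that("diet profiles and mineral adjustment match the generator's
           independent arithmetic", {
  w <- test_world()
  res <- test_pipeline()
  gt <- w$ground_truth$minerals |>
    dplyr::arrange(country, year)
  got <- res$minerals |> dplyr::arrange(country, year)
  for (k in c("heme_iron", "nonheme_iron", "mfp",
              "iron_absorption_fraction_conway",
              "iron_absorption_fraction_rickard",
              "iron_absorption_fraction_armah",
              "iron_bioavailable_conway", "iron_bioavailable_rickard",
              "iron_bioavailable_armah", "zinc_absorbed")) {
    expect_lt(max_rel_err(got[[k]], gt[[k]]), 1e-9)
  }
})
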