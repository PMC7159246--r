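noise_free_spatial <- function(centers = NULL, ...) {
  spatial_profile_params(center_intensity = centers, noise_sd = 0,
                         absorption_noise_sd = 0, ...)
}

test_that("spectral generator obeys its closed-form decay and background contracts", {
  prm <- noise_free_spatial()
  sp <- generate_spectral_profiles(prm, n_per_group = 2, seed = 1)
  expect_equal(nrow(sp), 4 * 2 * 7)  # 7 biopsies per tendon
  # controls emit background (0) only
  expect_equal(sp$fluorescence_au[sp$group %in% c("C", "Col")],
               rep(0, sum(sp$group %in% c("C", "Col"))))
  # treated: intensity ratio equals exp(-d/lambda) exactly
  gp <- sp[sp$group == "GP", ]
  base <- gp$fluorescence_au[gp$distance_mm == 0][1]
  for (d in c(3, 9, 15)) {
    got <- gp$fluorescence_au[gp$distance_mm == d][1] / base
    expect_equal(got, exp(-d / prm$decay_length[["GP"]]), tolerance = 1e-12)
  }
  # determinism
  sp2 <- generate_spectral_profiles(prm, n_per_group = 2, seed = 1)
  expect_identical(sp, sp2)
  expect_error(spatial_profile_params(decay_length = c(GP = -1, ColGP = 3)), "decay_length")
})

test_that("injection-site model returns the cell means with contrast inference", {
  centers <- c(C = 10, GP = 30, Col = 10, ColGP = 20)
  sp <- generate_spectral_profiles(noise_free_spatial(centers), n_per_group = 3, seed = 2)
  fit <- fit_injection_site_model(sp, "fluorescence")
  m <- setNames(fit$means$mean, fit$means$group)
  expect_equal(m[["C"]], 10, tolerance = 1e-12)
  expect_equal(m[["GP"]], 30, tolerance = 1e-12)
  expect_equal(m[["Col"]], 10, tolerance = 1e-12)
  expect_equal(m[["ColGP"]], 20, tolerance = 1e-12)
  # single group, constant response: mean c, SE 0
  one <- data.frame(specimen_id = "x", group = "GP", distance_mm = 0,
                    dry_weight_mg = 4, fluorescence_au = 7, absorption_au = 3)
  one <- one[rep(1, 5), ]
  f1 <- fit_injection_site_model(one, "fluorescence")
  expect_equal(f1$means$mean, 7)
  expect_equal(f1$means$se, 0)
  expect_error(fit_injection_site_model(sp[sp$distance_mm > 0, ]), "injection-site")
})

test_that("injection-site estimates stay within 3 SE of the truth almost always", {
  centers <- c(C = 0, GP = 30, Col = 0, ColGP = 20)
  prm <- spatial_profile_params(center_intensity = centers, noise_sd = 2)
  set.seed(123)
  hits <- replicate(200, {
    sp <- generate_spectral_profiles(prm, n_per_group = 9, seed = NULL)
    fit <- fit_injection_site_model(sp, "fluorescence")
    m <- setNames(fit$means$mean, fit$means$group)
    se <- setNames(fit$means$se, fit$means$group)
    abs(m[["GP"]] - 30) <= 3 * se[["GP"]]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("spatial dummy regression recovers exact cell-mean coefficients", {
  cells <- rbind(
    data.frame(group = "GP", distance_mm = c(0, 9, 15), y = c(10, 6.8, 3.1)),
    data.frame(group = "ColGP", distance_mm = c(0, 9, 15), y = c(5.5, 4.9, 3.1)))
  cells <- cells[rep(seq_len(nrow(cells)), each = 2), ]  # balanced, 2 per cell
  cells$specimen_id <- "s"
  cells$fluorescence_au <- cells$y
  cells$absorption_au <- cells$y
  cells$dry_weight_mg <- 4
  fit <- fit_spatial_model(cells, "fluorescence", distances = c(9, 15))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["beta0"]], 10, tolerance = 1e-10)
  expect_equal(est[["beta_ColGP"]], -4.5, tolerance = 1e-10)
  expect_equal(est[["beta_9mm_GP"]], -3.2, tolerance = 1e-10)
  expect_equal(est[["beta_15mm_GP"]], -6.9, tolerance = 1e-10)
  expect_equal(est[["beta_9mm_ColGP"]], -0.6, tolerance = 1e-10)
  expect_equal(est[["beta_15mm_ColGP"]], -2.4, tolerance = 1e-10)
  # percent drops from those coefficients
  expect_equal(percent_drop(fit, "GP", 9)$percent, -32, tolerance = 1e-10)
  expect_equal(percent_drop(fit, "GP", 0)$percent, 0)
  # all-equal responses collapse every coefficient except the baseline
  flat <- cells
  flat$fluorescence_au <- 4
  ffit <- fit_spatial_model(flat, "fluorescence", distances = c(9, 15))
  fe <- setNames(ffit$coefficients$estimate, ffit$coefficients$term)
  expect_equal(fe[["beta0"]], 4, tolerance = 1e-12)
  expect_equal(unname(fe[names(fe) != "beta0"]), rep(0, 5), tolerance = 1e-10)
})

test_that("balanced noisy fits equal independent cell-mean differences", {
  set.seed(5)
  sp <- generate_spectral_profiles(spatial_profile_params(), n_per_group = 9, seed = 6)
  treated <- sp[sp$group %in% c("GP", "ColGP"), ]
  fit <- fit_spatial_model(treated, "fluorescence", distances = c(3, 9, 15))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  cm <- function(g, d) mean(treated$fluorescence_au[treated$group == g &
                                                      treated$distance_mm == d])
  expect_equal(est[["beta0"]], cm("GP", 0), tolerance = 1e-10)
  expect_equal(est[["beta_ColGP"]], cm("ColGP", 0) - cm("GP", 0), tolerance = 1e-10)
  for (d in c(3, 9, 15)) {
    expect_equal(est[[sprintf("beta_%dmm_GP", d)]], cm("GP", d) - cm("GP", 0),
                 tolerance = 1e-10)
    expect_equal(est[[sprintf("beta_%dmm_ColGP", d)]], cm("ColGP", d) - cm("ColGP", 0),
                 tolerance = 1e-10)
  }
})

test_that("empty non-baseline cells give NA coefficients, empty baselines error", {
  sp <- generate_spectral_profiles(noise_free_spatial(), n_per_group = 2, seed = 3)
  treated <- sp[sp$group %in% c("GP", "ColGP"), ]
  drop9 <- treated[!(treated$group == "ColGP" & treated$distance_mm == 9), ]
  fit <- fit_spatial_model(drop9, "fluorescence", distances = c(9, 15))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_true(is.na(est[["beta_9mm_ColGP"]]))
  expect_false(is.na(est[["beta_9mm_GP"]]))
  nob <- treated[!(treated$group == "GP" & treated$distance_mm == 0), ]
  expect_error(fit_spatial_model(nob, "fluorescence"), "injection site")
  expect_error(fit_spatial_model(treated[treated$group == "GP", ], "fluorescence"),
               "treated groups")
})

test_that("noise-free percent drops equal the generator's closed form", {
  prm <- noise_free_spatial()
  sp <- generate_spectral_profiles(prm, n_per_group = 3, seed = 4)
  fit <- fit_spatial_model(sp, "fluorescence", distances = c(3, 9, 15))
  for (g in c("GP", "ColGP")) {
    lam <- prm$decay_length[[g]]
    for (d in c(3, 9, 15)) {
      expect_equal(percent_drop(fit, g, d)$percent, 100 * (exp(-d / lam) - 1),
                   tolerance = 1e-8)
    }
  }
})

test_that("fluorescence and absorption run through one code path", {
  sp <- generate_spectral_profiles(spatial_profile_params(), n_per_group = 4, seed = 9)
  sp$absorption_au <- sp$fluorescence_au
  f1 <- fit_spatial_model(sp, "fluorescence")
  f2 <- fit_spatial_model(sp, "absorption")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate)
  expect_equal(f1$coefficients$p, f2$coefficients$p)
})

test_that("the one-sample t-test against zero is calibrated and guarded", {
  expect_error(test_nonzero(c(5)), "n >= 2")
  expect_error(test_nonzero(c(5, 5, 5)), "zero variance")
  r <- test_nonzero(c(-1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(8)
  rej <- mean(replicate(500, test_nonzero(rnorm(10))$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
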