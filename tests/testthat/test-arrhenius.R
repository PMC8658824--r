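# build an mm_fit-like record quickly
mmf <- function(temperature, kcat, se = 1, valid = TRUE)
  structure(list(kcat = kcat, kcat_se = se, KM = 2e-4, KM_se = 1e-5,
                 Vmax = kcat * 1e-9, E0 = 1e-9, temperature_K = temperature,
                 n_points = 10, rss = 1e-18, converged = valid, valid = valid),
            class = "mm_fit")

line_fits <- function(slope, intercept, temps, se = 1) {
  structure(lapply(temps, function(Tk)
    mmf(Tk, exp(intercept + slope / Tk), se = se)), class = "mm_fits")
}

test_that("cut-off filtering keeps in-range valid fits and errors when < 3 remain", {
  fits <- structure(list(mmf(281, 100), mmf(285, 150), mmf(290, 200),
                         mmf(294, 260), mmf(298, 320)),
                    class = "mm_fits")
  kept <- suppressMessages(apply_temperature_cutoffs(fits, 283, 296))
  expect_equal(vapply(kept, `[[`, numeric(1), "temperature_K"),
               c(285, 290, 294))
  # cut-offs wider than the data are the identity
  all_kept <- apply_temperature_cutoffs(fits)
  expect_length(all_kept, 5)
  # a non-converged fit inside the range is removed
  fits[[3]]$valid <- FALSE
  kept2 <- suppressMessages(apply_temperature_cutoffs(fits, 283, 298.5))
  expect_equal(vapply(kept2, `[[`, numeric(1), "temperature_K"),
               c(285, 294, 298))
  expect_error(suppressMessages(apply_temperature_cutoffs(fits, 292, 296)),
               "insufficient")
})

test_that("noiseless Arrhenius points reproduce the generating line exactly", {
  fits <- line_fits(-7712, 32.06, seq(281, 298, by = 1.5))
  fit <- weighted_arrhenius_fit(fits)
  expect_equal(fit$slope, -7712, tolerance = 1e-9)
  expect_equal(fit$intercept, 32.06, tolerance = 1e-9)
})

test_that("weighted fit solves the weighted normal equations to 1e-10 relative", {
  set.seed(5)
  temps <- seq(280, 298, by = 2)
  fits <- structure(lapply(temps, function(Tk)
    mmf(Tk, exp(31 - 7500 / Tk) * exp(rnorm(1, 0, 0.05)),
        se = runif(1, 0.5, 20))), class = "mm_fits")
  fit <- weighted_arrhenius_fit(fits)
  ora <- wls_line_oracle(fit$points$inv_T, fit$points$ln_kcat,
                         fit$points$weight)
  expect_equal(fit$intercept, ora[1], tolerance = 1e-10)
  expect_equal(fit$slope, ora[2], tolerance = 1e-10)
})

test_that("equal weights reduce to ordinary least squares", {
  set.seed(6)
  temps <- seq(280, 298, by = 2)
  lnk <- 31 - 7500 / temps + rnorm(length(temps), 0, 0.1)
  fits <- structure(lapply(seq_along(temps), function(i)
    mmf(temps[i], exp(lnk[i]), se = 3)), class = "mm_fits")
  fit <- weighted_arrhenius_fit(fits)
  ols <- stats::lm(lnk ~ I(1 / temps))
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("a dominant weight pins the line to that point", {
  fits <- structure(list(mmf(280, exp(31 - 7500 / 280), se = 1e-4),
                         mmf(288, 60, se = 100), mmf(296, 200, se = 100)),
                    class = "mm_fits")
  fit <- weighted_arrhenius_fit(fits)
  pred <- fit$intercept + fit$slope / 280
  expect_equal(pred, 31 - 7500 / 280, tolerance = 1e-3)
})

test_that("non-positive kcat or degenerate design raises a domain error", {
  bad <- structure(list(mmf(280, -5), mmf(285, 10), mmf(290, 20)),
                   class = "mm_fits")
  expect_error(weighted_arrhenius_fit(bad), "kcat <= 0")
  flat <- structure(list(mmf(285, 10), mmf(285, 12), mmf(285, 14)),
                    class = "mm_fits")
  expect_error(weighted_arrhenius_fit(flat), "temperatures equal")
})

test_that("published global line gives the published activation parameters", {
  p <- activation_parameters(arrhenius_line(-7712, 32.06), T_ref = 287.5)
  expect_equal(p$Ea, 15.325, tolerance = 1e-3)
  expect_equal(p$dG, 13.818, tolerance = 1e-3)
  expect_equal(p$dH, 14.754, tolerance = 1e-3)
  expect_equal(p$TdS, 0.936, tolerance = 1e-3)
  expect_equal(p$A, exp(32.06))
  expect_equal(p$kcat_ref, exp(32.06 - 7712 / 287.5))
})

test_that("thermodynamic identities hold to machine precision", {
  set.seed(7)
  for (rep in 1:20) {
    slope <- runif(1, -12000, -4000); int <- runif(1, 20, 40)
    T_ref <- runif(1, 278, 310)
    p <- activation_parameters(arrhenius_line(slope, int), T_ref = T_ref)
    expect_equal(p$dH, p$Ea - thermo_constants()$R_kcal * T_ref)
    expect_equal(p$dG + p$TdS, p$dH)
  }
})

test_that("Ea ignores T_ref while dH falls by exactly R per kelvin of T_ref", {
  fit <- arrhenius_line(-8000, 30)
  p1 <- activation_parameters(fit, T_ref = 285)
  p2 <- activation_parameters(fit, T_ref = 295)
  expect_equal(p1$Ea, p2$Ea)
  expect_equal(p2$dH - p1$dH, -thermo_constants()$R_kcal * 10)
})

test_that("limit cases: zero slope, and Eyring identity dG = 0", {
  p <- activation_parameters(arrhenius_line(0, 5), T_ref = 300)
  expect_equal(p$Ea, 0)
  expect_equal(p$dH, -thermo_constants()$R_kcal * 300)
  # kcat equal to kB*T/h makes the activation free energy vanish
  kc <- thermo_constants()
  T_ref <- 298
  ln_k <- log(kc$kB * T_ref / kc$h)
  p2 <- activation_parameters(arrhenius_line(0, ln_k), T_ref = T_ref)
  expect_equal(p2$dG, 0, tolerance = 1e-10)
})

test_that("standard errors propagate from the coefficient covariance", {
  set.seed(8)
  temps <- seq(280, 298, by = 2)
  fits <- structure(lapply(temps, function(Tk)
    mmf(Tk, exp(32.06 - 7712 / Tk) * exp(rnorm(1, 0, 0.08)), se = 5)),
    class = "mm_fits")
  fit <- weighted_arrhenius_fit(fits)
  p <- activation_parameters(fit, T_ref = 287.5)
  R <- thermo_constants()$R_kcal
  expect_equal(p$Ea_se, R * sqrt(fit$covariance[2, 2]))
  expect_equal(p$dH_se, p$Ea_se)
  expect_equal(p$TdS_se, R * 287.5 * sqrt(fit$covariance[1, 1]))
  V <- fit$covariance
  var_lnk <- V[1, 1] + V[2, 2] / 287.5^2 + 2 * V[1, 2] / 287.5
  expect_equal(p$dG_se, R * 287.5 * sqrt(var_lnk))
  # confidence intervals are t-based with n - 2 degrees of freedom
  tc <- qt(0.975, df = fit$n - 2)
  expect_equal((p$ci$upper - p$ci$lower) / 2,
               tc * c(p$Ea_se, p$dG_se, p$dH_se, p$TdS_se))
})

test_that("Eyring extrapolation reconstructs turnover from dH and TdS", {
  # characterised at 294.5 K, evaluated back at the quoted temperature
  k_quoted <- eyring_kcat(dH = 16.3, TdS = -0.5, T_quoted = 294.5,
                          temperature = 294.5)
  kc <- thermo_constants()
  dG <- 16.3 - (-0.5)
  expect_equal(k_quoted,
               kc$kB * 294.5 / kc$h * exp(-dG / (kc$R_kcal * 294.5)))
  expect_error(eyring_kcat(dH = 16.3, TdS = -0.5, temperature = 300),
               "T_quoted")
})
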