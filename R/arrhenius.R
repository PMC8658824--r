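#' Filter Michaelis-Menten fits by temperature cut-offs and validity
#'
#' Keeps only valid, converged fits whose bin temperature lies within
#' `[t_min, t_max]`. Cut-offs let the experimenter eliminate bins where the
#' enzyme is no longer active (approaching unfolding) or where the substrate
#' behaves poorly (e.g. low solubility in the cold).
#'
#' @param fits An `mm_fits` list.
#' @param t_min,t_max Temperature window in kelvin (`t_min < t_max`);
#'   defaults keep everything.
#' @return The filtered `mm_fits` list. Errors if fewer than 3 fits survive,
#'   since the weighted Arrhenius line then has no spare degree of freedom.
#' @export
apply_temperature_cutoffs <- function(fits, t_min = -Inf, t_max = Inf) {
  stopifnot(t_min < t_max)
  keep <- vapply(fits, function(f)
    isTRUE(f$valid) && f$temperature_K >= t_min && f$temperature_K <= t_max,
    logical(1))
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " fit(s) removed by temperature cut-offs [",
            t_min, ", ", t_max, "] K or validity filter")
  if (sum(keep) < 3)
    stop("insufficient data: only ", sum(keep),
         " valid fit(s) survive cut-offs [", t_min, ", ", t_max,
         "] K; the Arrhenius fit needs at least 3")
  structure(fits[keep], class = "mm_fits")
}

#' Construct an Arrhenius line from known coefficients
#'
#' Builds an `arrhenius_fit` object directly from a slope (coefficient of
#' 1/T, in kelvin, equal to -Ea/R) and an intercept (ln A, with A in s^-1) —
#' useful for evaluating thermodynamic parameters from a published regression
#' line. The covariance defaults to zero (exact coefficients).
#'
#' @param slope Coefficient of 1/T (K).
#' @param intercept ln A (dimensionless, A in s^-1).
#' @param covariance 2x2 covariance matrix of (intercept, slope); default 0.
#' @param n Number of points behind the line (default 2, the minimum that
#'   defines a line).
#' @return An object of class `arrhenius_fit`.
#' @examples
#' activation_parameters(arrhenius_line(-7712, 32.06), T_ref = 287.5)
#' @export
arrhenius_line <- function(slope, intercept, covariance = matrix(0, 2, 2), n = 2L) {
  structure(list(slope = slope, intercept = intercept,
                 covariance = covariance, n = as.integer(n),
                 wrss = NA_real_, points = NULL),
            class = "arrhenius_fit")
}

#' Weighted Arrhenius fit of ln(kcat) against 1/T
#'
#' Regresses ln(kcat) on inverse temperature across temperature bins, with
#' weights 1/SE(kcat)^2 — the inverse squared standard error of each kcat
#' estimate, so precisely determined bins dominate. The slope equals -Ea/R
#' and the intercept ln A. The coefficient covariance is the
#' residual-variance-scaled inverse of the weighted normal matrix.
#'
#' The literal 1/SE(kcat)^2 weighting is the published convention even
#' though the response is on the log scale; `weights = "delta-log"` instead
#' uses (kcat/SE(kcat))^2, the delta-method weight for ln(kcat).
#'
#' @param fits An `mm_fits` list (already filtered via
#'   [apply_temperature_cutoffs()], or all valid).
#' @param weights `"kcat-se"` (default, 1/SE(kcat)^2) or `"delta-log"`
#'   ((kcat/SE(kcat))^2).
#' @return An object of class `arrhenius_fit`: `slope` (K), `intercept`,
#'   `covariance` (2x2, order intercept then slope), `n`, `wrss` (weighted
#'   residual sum of squares) and `points` (per-bin 1/T, ln kcat, weight).
#' @export
weighted_arrhenius_fit <- function(fits, weights = c("kcat-se", "delta-log")) {
  weights <- match.arg(weights)
  fits <- Filter(function(f) isTRUE(f$valid), fits)
  if (length(fits) < 3)
    stop("insufficient data: weighted Arrhenius fit needs >= 3 valid bins")
  kcat <- vapply(fits, `[[`, numeric(1), "kcat")
  se   <- vapply(fits, `[[`, numeric(1), "kcat_se")
  temp <- vapply(fits, `[[`, numeric(1), "temperature_K")
  if (any(kcat <= 0))
    stop("domain error: kcat <= 0 among inputs; ln(kcat) undefined")
  if (any(!is.finite(se) | se <= 0))
    stop("domain error: kcat standard errors must be positive and finite")
  if (length(unique(temp)) < 2)
    stop("singularity: all bin temperatures equal")
  w <- switch(weights, `kcat-se` = 1 / se^2, `delta-log` = (kcat / se)^2)
  inv_T <- 1 / temp
  ln_k <- log(kcat)
  # weighted least squares via QR of sqrt(w) X; a tight rank tolerance keeps
  # the solve exact even when one bin carries almost all the weight
  sw <- sqrt(w)
  X <- cbind(`(Intercept)` = 1, inv_T = inv_T)
  qd <- qr(X * sw, tol = 1e-14)
  if (qd$rank < 2) stop("singularity: weighted design matrix is rank-deficient")
  cf <- qr.coef(qd, ln_k * sw)
  resid <- ln_k - drop(X %*% cf)
  sigma2 <- sum(w * resid^2) / (length(ln_k) - 2)
  V <- matrix(NA_real_, 2, 2)
  V[qd$pivot, qd$pivot] <- chol2inv(qr.R(qd))
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(slope = unname(cf["inv_T"]), intercept = unname(cf["(Intercept)"]),
                 covariance = sigma2 * V, n = length(kcat),
                 wrss = sum(w * resid^2),
                 points = data.frame(inv_T = inv_T, ln_kcat = ln_k, weight = w,
                                     temperature_K = temp)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: ln(kcat) = %.4g + (%.6g) / T   [n = %d]\n",
              x$intercept, x$slope, x$n))
  invisible(x)
}

#' Activation thermodynamics from an Arrhenius line
#'
#' Converts the slope and intercept of a weighted Arrhenius fit into the
#' thermodynamic parameters of the activation barrier at a reference
#' temperature, with standard errors propagated from the coefficient
#' covariance by the delta method:
#' \itemize{
#'   \item Ea = -slope * R
#'   \item A = exp(intercept)
#'   \item kcat(T_ref) = exp(intercept + slope / T_ref)
#'   \item dG = R * T_ref * ln(kB * T_ref / (h * kcat(T_ref))), transmission
#'     coefficient kappa = 1
#'   \item dH = Ea - R * T_ref
#'   \item TdS = dH - dG
#' }
#' R is used in kcal units so every energy is in kcal/mol. The dG standard
#' error comes from the standard error of the fitted mean ln kcat at 1/T_ref;
#' the slope contribution to TdS cancels exactly, leaving TdS_se =
#' R * T_ref * SE(intercept).
#'
#' @param fit An `arrhenius_fit` (from [weighted_arrhenius_fit()] or
#'   [arrhenius_line()]).
#' @param T_ref Reference temperature (K). Default: the mean of the fitted
#'   bin temperatures, i.e. mid-range of the experiment.
#' @param conf_level Confidence level for the reported intervals (t
#'   distribution, n - 2 degrees of freedom); default 0.95.
#' @return An object of class `activation_parameters`: a list with `Ea`, `A`,
#'   `kcat_ref`, `dG`, `dH`, `TdS` (kcal/mol except `A`, `kcat_ref` in s^-1),
#'   matching `*_se` standard errors, `ci` (data.frame of confidence
#'   intervals when n > 2), `T_ref`, `kappa = 1`.
#' @examples
#' activation_parameters(arrhenius_line(-7712, 32.06), T_ref = 287.5)
#' @export
activation_parameters <- function(fit, T_ref = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (is.null(T_ref)) {
    if (is.null(fit$points))
      stop("T_ref must be given when the fit carries no point data")
    T_ref <- mean(fit$points$temperature_K)
  }
  stopifnot(T_ref > 0)
  R <- .const$R_kcal; kB <- .const$kB; h <- .const$h
  slope <- fit$slope; intercept <- fit$intercept
  V <- fit$covariance  # order: intercept, slope
  var_int <- V[1, 1]; var_slope <- V[2, 2]; cov_is <- V[1, 2]

  Ea <- -slope * R
  A <- exp(intercept)
  ln_k_ref <- intercept + slope / T_ref
  kcat_ref <- exp(ln_k_ref)
  if (!is.finite(A) || !is.finite(kcat_ref))
    stop("overflow: exp(", if (!is.finite(A)) "intercept" else "ln kcat(T_ref)",
         ") is not finite")
  dG <- R * T_ref * log(kB * T_ref / (h * kcat_ref))
  dH <- Ea - R * T_ref
  TdS <- dH - dG

  se_slope <- sqrt(var_slope)
  se_int <- sqrt(var_int)
  # Var(ln kcat(T_ref)) = Var(int) + Var(slope)/T^2 + 2 Cov/T
  var_lnk <- var_int + var_slope / T_ref^2 + 2 * cov_is / T_ref
  se_lnk <- sqrt(max(var_lnk, 0))
  Ea_se <- R * se_slope
  A_se <- A * se_int
  dG_se <- R * T_ref * se_lnk
  dH_se <- Ea_se
  # TdS = R*T_ref*(intercept - 1 - ln(kB*T_ref/h)): slope terms cancel
  TdS_se <- R * T_ref * se_int

  out <- list(Ea = Ea, A = A, kcat_ref = kcat_ref, dG = dG, dH = dH, TdS = TdS,
              Ea_se = Ea_se, A_se = A_se, dG_se = dG_se, dH_se = dH_se,
              TdS_se = TdS_se, T_ref = T_ref, kappa = 1, n = fit$n)
  if (fit$n > 2) {
    tc <- stats::qt(1 - (1 - conf_level) / 2, df = fit$n - 2)
    est <- c(Ea = Ea, dG = dG, dH = dH, TdS = TdS)
    se <- c(Ea = Ea_se, dG = dG_se, dH = dH_se, TdS = TdS_se)
    out$ci <- data.frame(parameter = names(est), estimate = unname(est),
                         lower = unname(est - tc * se),
                         upper = unname(est + tc * se))
  }
  class(out) <- "activation_parameters"
  out
}

#' @export
print.activation_parameters <- function(x, ...) {
  cat(sprintf("Activation parameters at T_ref = %.2f K (kappa = 1):\n", x$T_ref))
  cat(sprintf("  Ea   = %6.2f +/- %.2f kcal/mol\n", x$Ea, x$Ea_se))
  cat(sprintf("  dG++ = %6.2f +/- %.2f kcal/mol\n", x$dG, x$dG_se))
  cat(sprintf("  dH++ = %6.2f +/- %.2f kcal/mol\n", x$dH, x$dH_se))
  cat(sprintf("  TdS++= %6.2f +/- %.2f kcal/mol\n", x$TdS, x$TdS_se))
  cat(sprintf("  A    = %.3g s^-1, kcat(T_ref) = %.4g s^-1\n", x$A, x$kcat_ref))
  invisible(x)
}

#' Eyring rate from activation enthalpy and entropy
#'
#' Reconstructs kcat at a temperature from transition-state parameters:
#' k = kappa * (kB T / h) * exp(-(dH - T dS) / (R T)). Useful to extrapolate
#' a characterised enzyme's turnover to a temperature outside the measured
#' range.
#'
#' @param dH Activation enthalpy, kcal/mol.
#' @param dS Activation entropy, kcal/mol/K. Supply either `dS` or `TdS`.
#' @param TdS Entropic term T*dS (kcal/mol) quoted at `T_quoted`.
#' @param T_quoted Temperature (K) at which `TdS` is quoted.
#' @param temperature Temperature (K) at which to evaluate the rate.
#' @param kappa Transmission coefficient (default 1).
#' @return Rate constant in s^-1.
#' @examples
#' # psychrophilic amylase characterised at 294.5 K, extrapolated to 303.15 K
#' eyring_kcat(dH = 16.3, TdS = -0.5, T_quoted = 294.5, temperature = 303.15)
#' @export
eyring_kcat <- function(dH, dS = NULL, TdS = NULL, T_quoted = NULL,
                        temperature, kappa = 1) {
  if (is.null(dS)) {
    if (is.null(TdS) || is.null(T_quoted))
      stop("supply dS, or TdS together with T_quoted")
    dS <- TdS / T_quoted
  }
  R <- .const$R_kcal
  dG <- dH - temperature * dS
  kappa * (.const$kB * temperature / .const$h) * exp(-dG / (R * temperature))
}
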