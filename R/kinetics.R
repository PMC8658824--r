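#' Bin velocity points into equal-width temperature bins
#'
#' Partitions velocity points into `n_bins` equal-width temperature intervals
#' spanning `bounds` (default: the observed temperature range). Each point
#' falls in exactly one bin; the top bound is inclusive. Empty bins are
#' dropped with a message. Within each bin the representative temperature is
#' the arithmetic mean of the member temperatures.
#'
#' More bins mean less temperature variation within a bin but fewer
#' observations per Michaelis-Menten fit; the choice is the experimenter's,
#' driven by how many points were collected and how fast the rate changes.
#'
#' @param points A `velocity_points` data.frame from [rolling_velocity()].
#' @param n_bins Number of equal-width bins (>= 1).
#' @param bounds Optional length-2 numeric `[K, K]`; points outside are
#'   excluded before binning.
#'
#' @return A list of class `temperature_bins`; each element has fields
#'   `bin_index`, `temperature_mean`, `temperature_bounds` and `points`
#'   (the member rows).
#' @export
bin_by_temperature <- function(points, n_bins, bounds = NULL) {
  stopifnot(n_bins >= 1, nrow(points) > 0)
  temps <- points$temperature_K
  if (is.null(bounds)) bounds <- range(temps)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2] || n_bins == 1)
  keep <- temps >= bounds[1] & temps <= bounds[2]
  if (!any(keep))
    stop("no velocity points fall inside bounds [", bounds[1], ", ",
         bounds[2], "] K")
  pts <- points[keep, , drop = FALSE]
  if (bounds[1] == bounds[2]) bounds <- bounds + c(-0.5, 0.5)
  edges <- seq(bounds[1], bounds[2], length.out = n_bins + 1)
  idx <- findInterval(pts$temperature_K, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bins <- lapply(seq_len(n_bins), function(b) {
    member <- pts[idx == b, , drop = FALSE]
    if (nrow(member) == 0) return(NULL)
    list(bin_index = b,
         temperature_mean = mean(member$temperature_K),
         temperature_bounds = c(edges[b], edges[b + 1]),
         points = member)
  })
  empty <- vapply(bins, is.null, logical(1))
  if (any(empty))
    message(sum(empty), " empty temperature bin(s) dropped")
  structure(bins[!empty], class = "temperature_bins")
}

#' @export
print.temperature_bins <- function(x, ...) {
  cat(length(x), "temperature bin(s):\n")
  for (b in x)
    cat(sprintf("  bin %d: [%.2f, %.2f] K, mean %.2f K, %d points\n",
                b$bin_index, b$temperature_bounds[1], b$temperature_bounds[2],
                b$temperature_mean, nrow(b$points)))
  invisible(x)
}

#' Fit Michaelis-Menten parameters in one temperature bin
#'
#' Fits v = kcat * E0 * S / (KM + S) to the (substrate, velocity) pairs of a
#' bin by unweighted nonlinear least squares with the Levenberg-Marquardt
#' algorithm. Standard errors come from the linearised covariance
#' (residual-variance-scaled inverse of the Jacobian cross-product), as
#' reported by the fitter.
#'
#' The default starting values are kcat0 = max(v)/E0 and KM0 = median(S);
#' both work across the dynamic range seen in ramp assays. A fit that fails
#' to converge, or converges to non-positive kcat or KM, is flagged invalid
#' so that downstream Arrhenius fitting can exclude it — such bins typically
#' sit where the enzyme is no longer active.
#'
#' @param bin One element of a `temperature_bins` list (fields
#'   `temperature_mean` and `points`), or any list with a `points` data.frame
#'   holding `substrate_M` and `velocity_M_s`.
#' @param E0 Enzyme concentration (M).
#' @param initial_guess Optional numeric `c(kcat0, KM0)`.
#' @param min_points Minimum member velocities required (default 4); bins
#'   below it are returned as invalid with a warning.
#'
#' @return An object of class `mm_fit`: a list with `kcat`, `kcat_se`, `KM`,
#'   `KM_se`, `Vmax` (= kcat * E0), `E0`, `temperature_K`, `n_points`, `rss`,
#'   `converged`, `valid`.
#' @examples
#' S <- c(1000, 500, 250, 125, 62.5, 31.25) * 1e-6
#' v <- 100 * 1e-9 * S / (200e-6 + S)
#' bin <- list(temperature_mean = 287.5,
#'             points = data.frame(substrate_M = S, velocity_M_s = v))
#' fit_michaelis_menten(bin, E0 = 1e-9)
#' @export
fit_michaelis_menten <- function(bin, E0, initial_guess = NULL, min_points = 4) {
  stopifnot(E0 > 0)
  pts <- bin$points
  S <- pts$substrate_M
  v <- pts$velocity_M_s
  temperature <- if (!is.null(bin$temperature_mean)) bin$temperature_mean
                 else mean(pts$temperature_K)
  out <- list(kcat = NA_real_, kcat_se = NA_real_, KM = NA_real_,
              KM_se = NA_real_, Vmax = NA_real_, E0 = E0,
              temperature_K = temperature, n_points = length(v),
              rss = NA_real_, converged = FALSE, valid = FALSE)
  class(out) <- "mm_fit"
  if (length(v) < max(3, min_points) || length(unique(S)) < 2) {
    warning(sprintf(
      "bin at %.2f K skipped: %d point(s) over %d substrate level(s) (need >= %d over >= 2)",
      temperature, length(v), length(unique(S)), max(3, min_points)))
    return(out)
  }
  if (is.null(initial_guess))
    initial_guess <- c(kcat = max(v) / E0, KM = stats::median(S))
  names(initial_guess) <- c("kcat", "KM")
  if (initial_guess[["kcat"]] <= 0) initial_guess[["kcat"]] <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * E0 * S / (KM + S),
                      start = as.list(initial_guess),
                      data = list(v = v, S = S, E0 = E0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning(sprintf("bin at %.2f K: Michaelis-Menten fit failed to converge",
                    temperature))
    return(out)
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(kcat = NA_real_, KM = NA_real_))
  out$kcat <- est[["kcat"]]; out$KM <- est[["KM"]]
  out$kcat_se <- se[["kcat"]]; out$KM_se <- se[["KM"]]
  out$Vmax <- out$kcat * E0
  out$rss <- sum(stats::residuals(fit)^2)
  out$converged <- fit$convInfo$isConv
  out$valid <- out$converged && out$kcat > 0 && out$KM > 0
  if (out$converged && !out$valid)
    warning(sprintf("bin at %.2f K: non-physical fit (kcat = %.3g, KM = %.3g) excluded",
                    temperature, out$kcat, out$KM))
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit at %.2f K (%d points)%s\n",
              x$temperature_K, x$n_points,
              if (x$valid) "" else " [invalid]"))
  cat(sprintf("  kcat = %.4g +/- %.2g s^-1, KM = %.4g +/- %.2g M\n",
              x$kcat, x$kcat_se, x$KM, x$KM_se))
  invisible(x)
}

#' Fit Michaelis-Menten parameters in every temperature bin
#'
#' Convenience wrapper: applies [fit_michaelis_menten()] to each bin and
#' collects the results.
#'
#' @param bins A `temperature_bins` list from [bin_by_temperature()].
#' @param E0 Enzyme concentration (M).
#' @param ... Passed to [fit_michaelis_menten()].
#' @return A list of class `mm_fits` of `mm_fit` objects, one per bin.
#' @seealso [mm_fit_table()] for a tidy summary.
#' @export
fit_bins <- function(bins, E0, ...) {
  structure(lapply(bins, fit_michaelis_menten, E0 = E0, ...),
            class = "mm_fits")
}

#' Tabulate per-bin Michaelis-Menten fits
#'
#' @param fits An `mm_fits` list (or list of `mm_fit`).
#' @return A data.frame with one row per bin: `temperature_K`, `kcat`,
#'   `kcat_se`, `KM`, `KM_se`, `n_points`, `converged`, `valid`.
#' @export
mm_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(temperature_K = f$temperature_K, kcat = f$kcat,
               kcat_se = f$kcat_se, KM = f$KM, KM_se = f$KM_se,
               n_points = f$n_points, converged = f$converged,
               valid = f$valid)))
}
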