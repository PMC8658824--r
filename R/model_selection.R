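#' Corrected Akaike information criterion from a least-squares fit
#'
#' AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n - k - 1), the least-squares form of
#' the small-sample-corrected criterion. `k` counts the fitted coefficients
#' plus one for the residual variance.
#'
#' @param n Number of observations.
#' @param k Number of parameters (coefficients + 1 for the variance).
#' @param rss Residual sum of squares (> 0).
#' @return The scalar criterion.
#' @examples
#' aicc(8, 2, 2.0)  # 8*log(0.25) + 4 + 12/5
#' @export
aicc <- function(n, k, rss) {
  stopifnot(n > 0, k > 0)
  if (!is.finite(rss) || rss <= 0)
    stop("degenerate fit: rss must be positive and finite")
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 = ", n - k - 1, " (need > 0)")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike evidence weights
#'
#' Normalised model probabilities from a set of AICc values:
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2), where
#' Delta_i = AICc_i - min(AICc). Invariant to adding a constant to every
#' AICc value.
#'
#' @param aicc_values Numeric vector of >= 2 finite AICc values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(-37.99, -26.44, -13.36))
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 2)
  if (any(!is.finite(aicc_values))) stop("non-finite AICc value")
  d <- aicc_values - min(aicc_values)
  e <- exp(-d / 2)
  e / sum(e)
}

# weighted straight-line fit returning coefficients and weighted RSS
.wline <- function(x, y, w) {
  fit <- stats::lm(y ~ x, weights = w)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       wrss = sum(w * stats::residuals(fit)^2))
}

#' Compare one global Arrhenius line against per-dataset lines by AICc
#'
#' Given two or more datasets of Arrhenius points (1/T, ln kcat, weight) —
#' e.g. a temperature-gradient run and a classical stepwise run on the same
#' enzyme — fits (a) a single "global" line to the pooled points and (b) a
#' "separate" model giving each dataset its own line, and compares them with
#' AICc on the pooled weighted residual sum of squares. If the global model
#' wins, the datasets are statistically equivalent: one Arrhenius law
#' describes them all.
#'
#' Parameter counts follow the least-squares convention k = coefficients + 1
#' for the residual variance: k = 3 for the global line, k = 2d + 1 for d
#' separate lines. Each dataset's own line is also reported, with an AICc
#' computed on its own n — informative, but not likelihood-comparable to the
#' pooled models, so the Akaike weights are taken over the global and
#' separate models only.
#'
#' @param datasets A named list (>= 2) of data.frames with columns `inv_T`,
#'   `ln_kcat` and optionally `weight` (default 1). The `points` field of an
#'   [weighted_arrhenius_fit()] result has this shape.
#' @return An object of class `aicc_comparison`: `models` (data.frame with
#'   name, n, k, wrss, AICc, delta_AICc, weight, slope/intercept for
#'   single-line models), `preferred` (model name), `separate_coefficients`
#'   (per-dataset lines under the separate model) and `per_dataset`
#'   (individual own-n fits).
#' @export
compare_global_vs_separate <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  datasets <- lapply(datasets, function(d) {
    stopifnot(all(c("inv_T", "ln_kcat") %in% names(d)))
    if (is.null(d$weight)) d$weight <- rep(1, nrow(d))
    if (nrow(d) < 3) stop("each dataset needs >= 3 points")
    d
  })
  pooled <- do.call(rbind, lapply(names(datasets), function(nm)
    cbind(datasets[[nm]][c("inv_T", "ln_kcat", "weight")], dataset = nm)))
  n <- nrow(pooled)
  d <- length(datasets)

  glob <- .wline(pooled$inv_T, pooled$ln_kcat, pooled$weight)
  sep_fits <- lapply(datasets, function(dd) .wline(dd$inv_T, dd$ln_kcat, dd$weight))
  sep_wrss <- sum(vapply(sep_fits, `[[`, numeric(1), "wrss"))
  # guard against exactly-zero RSS on noiseless input
  eps <- 1e-300
  k_glob <- 3L; k_sep <- 2L * d + 1L
  aicc_glob <- aicc(n, k_glob, max(glob$wrss, eps))
  aicc_sep <- aicc(n, k_sep, max(sep_wrss, eps))
  w <- akaike_weights(c(aicc_glob, aicc_sep))
  models <- data.frame(
    name = c("global", "separate"),
    n = n, k = c(k_glob, k_sep),
    wrss = c(glob$wrss, sep_wrss),
    AICc = c(aicc_glob, aicc_sep),
    delta_AICc = c(aicc_glob, aicc_sep) - min(aicc_glob, aicc_sep),
    weight = w,
    slope = c(glob$slope, NA), intercept = c(glob$intercept, NA),
    stringsAsFactors = FALSE)
  per_dataset <- do.call(rbind, lapply(names(datasets), function(nm) {
    dd <- datasets[[nm]]; f <- sep_fits[[nm]]
    data.frame(name = nm, n = nrow(dd), k = 3L,
               wrss = f$wrss,
               AICc = if (nrow(dd) > 4) aicc(nrow(dd), 3L, max(f$wrss, eps)) else NA_real_,
               slope = f$slope, intercept = f$intercept,
               stringsAsFactors = FALSE)
  }))
  structure(list(models = models,
                 preferred = models$name[which.min(models$AICc)],
                 separate_coefficients = per_dataset[c("name", "slope", "intercept")],
                 per_dataset = per_dataset),
            class = "aicc_comparison")
}

#' @export
print.aicc_comparison <- function(x, ...) {
  cat("AICc model comparison (preferred:", x$preferred, ")\n")
  print(x$models[, c("name", "n", "k", "AICc", "delta_AICc", "weight")],
        row.names = FALSE)
  invisible(x)
}
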