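#' Rolling ordinary-least-squares reaction velocities
#'
#' Slides a window of `window` consecutive readings along each cuvette's
#' product-versus-time trace and reports the OLS slope of product
#' concentration on time as the instantaneous velocity for that window,
#' together with the window-mean temperature and window-mean substrate
#' concentration. Because each window needs `window` points, the first
#' `window - 1` positions of every trace produce no velocity, so the terminal
#' temperatures of a gradient are not represented.
#'
#' The default window of 4 points keeps the temperature change within a
#' window small on a 1-2 K/min ramp while leaving enough points for a stable
#' slope. Negative velocities (noise) are retained; filtering happens
#' downstream via temperature cut-offs and fit validity checks.
#'
#' @param traces A `cuvette_traces` data.frame from [to_concentrations()]
#'   (or a data.frame with columns `cuvette_id`, `time_s`, `temperature_K`,
#'   `product_M`, `substrate_M`).
#' @param window Number of consecutive points per window (>= 2, default 4).
#'
#' @return A data.frame of class `velocity_points` with columns `cuvette_id`,
#'   `time_mid_s`, `temperature_K`, `substrate_M`, `velocity_M_s`,
#'   `window_start`, `window_end` (indices into the cuvette's series).
#'   One row per contiguous window (stride 1): a cuvette with n points
#'   yields n - window + 1 rows.
#' @export
rolling_velocity <- function(traces, window = 4) {
  stopifnot(is.numeric(window), length(window) == 1)
  window <- as.integer(window)
  if (window < 2) stop("window must be >= 2")
  needed <- c("cuvette_id", "time_s", "temperature_K", "product_M", "substrate_M")
  stopifnot(all(needed %in% names(traces)))
  ids <- unique(traces$cuvette_id)
  pieces <- lapply(ids, function(id) {
    g <- traces[traces$cuvette_id == id, , drop = FALSE]
    g <- g[order(g$time_s), , drop = FALSE]
    n <- nrow(g)
    if (n < window)
      stop("cuvette '", id, "' has ", n, " points; window of ", window,
           " needs at least that many")
    k <- n - window + 1L
    v <- numeric(k); tm <- numeric(k); sm <- numeric(k); mid <- numeric(k)
    for (i in seq_len(k)) {
      idx <- i:(i + window - 1L)
      tt <- g$time_s[idx]
      if (stats::var(tt) == 0)
        stop("singular fit: zero time variance in window ", i,
             " of cuvette '", id, "'")
      fit <- stats::lm.fit(cbind(1, tt), g$product_M[idx])
      v[i]  <- fit$coefficients[2]
      tm[i] <- mean(g$temperature_K[idx])
      sm[i] <- mean(g$substrate_M[idx])
      mid[i] <- mean(tt)
    }
    data.frame(cuvette_id = id, time_mid_s = mid, temperature_K = tm,
               substrate_M = sm, velocity_M_s = v,
               window_start = seq_len(k), window_end = seq_len(k) + window - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("velocity_points", "data.frame")
  out
}
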