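# Independent oracles and small builders shared across tests.

# Two-pass least-squares slope: sum((t - tbar)(y - ybar)) / sum((t - tbar)^2).
# Deliberately coded from the textbook formula, independent of lm/lm.fit.
ols_slope_oracle <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  sum((t - tb) * (y - yb)) / sum((t - tb)^2)
}

# Exhaustive grid search for the Michaelis-Menten least-squares optimum,
# iteratively refined around the best cell until the grid spacing is below
# rel_tol of the current estimates.
grid_search_mm <- function(S, v, E0, kcat_range, KM_range, rel_tol = 1e-4) {
  rss <- function(kcat, KM) sum((v - kcat * E0 * S / (KM + S))^2)
  lo <- c(kcat_range[1], KM_range[1]); hi <- c(kcat_range[2], KM_range[2])
  best <- c(mean(kcat_range), mean(KM_range))
  repeat {
    ks <- seq(lo[1], hi[1], length.out = 41)
    ms <- seq(lo[2], hi[2], length.out = 41)
    g <- expand.grid(kcat = ks, KM = ms)
    r <- mapply(rss, g$kcat, g$KM)
    best <- unlist(g[which.min(r), ])
    dk <- ks[2] - ks[1]; dm <- ms[2] - ms[1]
    if (dk < rel_tol * best[1] && dm < rel_tol * best[2]) break
    lo <- c(max(best[1] - 2 * dk, 1e-12), max(best[2] - 2 * dm, 1e-15))
    hi <- c(best[1] + 2 * dk, best[2] + 2 * dm)
  }
  best
}

# Substrate remaining after time t at constant temperature, from the implicit
# integrated Michaelis-Menten relation KM ln(S0/S) + (S0 - S) = kcat E0 t,
# solved by root bracketing (independent of any ODE integrator).
integrated_mm_substrate <- function(t, S0, kcat, KM, E0) {
  vapply(t, function(tt) {
    f <- function(S) KM * log(S0 / S) + (S0 - S) - kcat * E0 * tt
    stats::uniroot(f, c(S0 * 1e-12, S0), tol = S0 * 1e-12)$root
  }, numeric(1))
}

# Weighted straight-line fit via explicit normal equations (oracle for the
# Arrhenius stage).
wls_line_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  unname(solve(A, b)[, 1]) # (intercept, slope)
}

# A minimal noiseless trace data.frame for velocity tests.
make_trace <- function(time, product, temperature = 300, S0 = 1e-3,
                       id = "cuv1") {
  structure(data.frame(cuvette_id = id, time_s = time,
                       temperature_K = rep_len(temperature, length(time)),
                       product_M = product, substrate_M = S0 - product,
                       S0 = S0, out_of_range = FALSE,
                       stringsAsFactors = FALSE),
            class = c("cuvette_traces", "data.frame"))
}

# Wrap (S, v) points as a pseudo temperature bin for fit_michaelis_menten.
make_bin <- function(S, v, temperature = 287.5) {
  list(bin_index = 1L, temperature_mean = temperature,
       temperature_bounds = temperature + c(-1, 1),
       points = data.frame(substrate_M = S, velocity_M_s = v))
}
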