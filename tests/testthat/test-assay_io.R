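test_that("parser normalises minutes and Celsius to seconds and kelvin", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,time,temperature,absorbance",
               "a,0.5,10,0.01", "a,1.0,10.5,0.02", "a,1.5,11,0.03"), path)
  r <- parse_instrument_csv(path, time_unit = "min")
  expect_equal(r$time_s, c(30, 60, 90))
  expect_equal(r$temperature_K, c(283.15, 283.65, 284.15))
})

test_that("kelvin/seconds input passes through unchanged (idempotent units)", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,time,temperature,absorbance",
               "a,30,283.15,0.01", "a,60,283.65,0.02"), path)
  r <- parse_instrument_csv(path)
  expect_equal(r$time_s, c(30, 60))
  expect_equal(r$temperature_K, c(283.15, 283.65))
})

test_that("interleaved cuvettes are grouped and time-sorted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,time,temperature,absorbance",
               "b,20,284,0.2", "a,10,283,0.1", "b,10,283,0.15",
               "a,20,284,0.12"), path)
  r <- parse_instrument_csv(path)
  expect_equal(r$cuvette_id, c("a", "a", "b", "b"))
  expect_equal(r$time_s, c(10, 20, 10, 20))
})

test_that("parser errors name the missing column, bad row, or duplicate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,minutes,temperature,absorbance", "a,1,10,0.1"), path)
  expect_error(parse_instrument_csv(path), "missing column 'time'")
  writeLines(c("sample,time,temperature,absorbance", "a,1,10,xyz"), path)
  expect_error(parse_instrument_csv(path), "row 1")
  writeLines(c("sample,time,temperature,absorbance",
               "a,1,10,0.1", "a,1,10.2,0.2"), path)
  expect_error(parse_instrument_csv(path), "duplicate")
})

test_that("Beer-Lambert conversion reproduces hand-computed concentrations", {
  # 0.178 AU at eps 17800 and 0.129 AU at eps 12900 both give 10 uM product
  cases <- list(list(eps = 17800, A = 0.178), list(eps = 12900, A = 0.129))
  for (cs in cases) {
    d <- assay_design(cs$eps, 1, E0 = 1e-9, S0 = c(a = 1e-3),
                      baseline = c(a = 0))
    r <- structure(data.frame(cuvette_id = "a", time_s = c(0, 10),
                              temperature_K = 283.15,
                              absorbance = c(cs$A, cs$A)),
                   class = c("assay_readings", "data.frame"))
    tr <- to_concentrations(r, d)
    expect_equal(tr$product_M, c(1e-5, 1e-5), tolerance = 1e-12)
    expect_equal(tr$substrate_M, 1e-3 - tr$product_M)
  }
})

test_that("baseline defaults to the first reading so product starts at zero", {
  d <- assay_design(17800, 1, E0 = 1e-9, S0 = c(a = 1e-3))
  r <- structure(data.frame(cuvette_id = "a", time_s = 0:2,
                            temperature_K = 283, absorbance = c(0.05, 0.05, 0.139)),
                 class = c("assay_readings", "data.frame"))
  tr <- to_concentrations(r, d)
  expect_equal(tr$product_M[1], 0)
  expect_equal(tr$product_M[2], 0)
  expect_equal(tr$product_M[3], (0.139 - 0.05) / 17800)
})

test_that("conversion is linear in net absorbance", {
  d <- assay_design(17800, 1, E0 = 1e-9, S0 = c(a = 1e-3), baseline = c(a = 0))
  mk <- function(A) structure(
    data.frame(cuvette_id = "a", time_s = seq_along(A), temperature_K = 283,
               absorbance = A),
    class = c("assay_readings", "data.frame"))
  A <- c(0.01, 0.05, 0.2)
  p1 <- to_concentrations(mk(A), d)$product_M
  p2 <- to_concentrations(mk(2 * A), d)$product_M
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("out-of-range product is flagged and retained, not dropped", {
  d <- assay_design(1000, 1, E0 = 1e-9, S0 = c(a = 1e-4), baseline = c(a = 0))
  r <- structure(data.frame(cuvette_id = "a", time_s = 0:2, temperature_K = 283,
                            absorbance = c(0, 0.05, 0.2)),
                 class = c("assay_readings", "data.frame"))
  expect_warning(tr <- to_concentrations(r, d), "flagged and retained")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$out_of_range, c(FALSE, FALSE, TRUE))
})

test_that("unknown cuvette id in the readings is a configuration error", {
  d <- assay_design(17800, 1, E0 = 1e-9, S0 = c(a = 1e-3))
  r <- structure(data.frame(cuvette_id = "zz", time_s = 0, temperature_K = 283,
                            absorbance = 0),
                 class = c("assay_readings", "data.frame"))
  expect_error(to_concentrations(r, d), "zz")
})

test_that("simulator CSV round-trips losslessly through the parser", {
  sim <- simulate_ramp(simulation_spec(noise_sd = 0.01, rng_seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_instrument_csv(sim$readings, path)
  back <- parse_instrument_csv(path)
  expect_equal(back$cuvette_id, sim$readings$cuvette_id)
  expect_equal(back$time_s, sim$readings$time_s, tolerance = 1e-6)
  expect_equal(back$temperature_K, sim$readings$temperature_K, tolerance = 1e-6)
  expect_equal(back$absorbance, sim$readings$absorbance, tolerance = 1e-6)
})
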