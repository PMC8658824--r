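#' Describe an assay: optics, enzyme and substrate concentrations
#'
#' Bundles the experimental constants needed to convert raw absorbance
#' readings into product/substrate concentrations: the chromophore extinction
#' coefficient, the cuvette path length, the enzyme concentration and the
#' initial substrate concentration loaded into each cuvette.
#'
#' @param extinction_coefficient Molar extinction coefficient of the product
#'   chromophore, in M^-1 cm^-1 (e.g. 17800 for para-nitrophenol at 405 nm).
#' @param path_length Optical path length in cm (default 1).
#' @param E0 Total enzyme concentration in M; assumed constant over the run.
#' @param S0 Named numeric vector of initial substrate concentrations (M),
#'   one element per cuvette id.
#' @param baseline Optional named numeric vector of baseline absorbances (AU)
#'   per cuvette. If `NULL` (default) the first reading of each cuvette is
#'   used, so product starts at zero.
#' @param ramp_rate Optional ramp rate in K/min (metadata only).
#' @param temperature_range Optional length-2 numeric, K (metadata only).
#'
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(17800, 1, E0 = 1e-9, S0 = c(cuv1 = 1e-3, cuv2 = 5e-4))
#' @export
assay_design <- function(extinction_coefficient, path_length = 1, E0,
                         S0, baseline = NULL, ramp_rate = NA_real_,
                         temperature_range = c(NA_real_, NA_real_)) {
  stopifnot(is.numeric(extinction_coefficient), length(extinction_coefficient) == 1,
            is.numeric(path_length), length(path_length) == 1,
            is.numeric(E0), length(E0) == 1, is.numeric(S0))
  if (extinction_coefficient <= 0) stop("extinction_coefficient must be > 0")
  if (path_length <= 0) stop("path_length must be > 0")
  if (E0 <= 0) stop("E0 must be > 0")
  if (is.null(names(S0)) || anyNA(names(S0)) || any(names(S0) == ""))
    stop("S0 must be a named vector (one initial concentration per cuvette id)")
  if (anyDuplicated(names(S0)))
    stop("duplicate cuvette ids in S0: ", paste(names(S0)[duplicated(names(S0))], collapse = ", "))
  if (any(S0 <= 0)) stop("all S0 must be > 0")
  if (!is.null(baseline) && is.null(names(baseline)))
    stop("baseline must be a named vector keyed by cuvette id")
  structure(
    list(extinction_coefficient = extinction_coefficient,
         path_length = path_length, E0 = E0, S0 = S0, baseline = baseline,
         ramp_rate = ramp_rate, temperature_range = temperature_range),
    class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design:\n")
  cat(sprintf("  epsilon = %g M^-1 cm^-1, path = %g cm, [E]0 = %g M\n",
              x$extinction_coefficient, x$path_length, x$E0))
  cat(sprintf("  %d cuvette(s), S0 = %s M\n", length(x$S0),
              paste(signif(x$S0, 4), collapse = ", ")))
  invisible(x)
}

# Convert instrument temperatures to kelvin. Values below `celsius_below`
# are taken as Celsius: no biological assay runs below 150 K.
.to_kelvin <- function(x, unit = c("auto", "K", "C"), celsius_below = 150) {
  unit <- match.arg(unit)
  if (unit == "K") return(x)
  if (unit == "C") return(x + 273.15)
  ifelse(x < celsius_below, x + 273.15, x)
}

.time_factor <- function(unit = c("s", "min", "h")) {
  switch(match.arg(unit), s = 1, min = 60, h = 3600)
}

#' Parse a long-form instrument CSV of a temperature-ramp assay
#'
#' Reads the long-form export of a temperature-controlled cuvette changer
#' (one row per reading: sample id, time, temperature, absorbance), maps the
#' columns, normalises time to seconds and temperature to kelvin, and returns
#' the readings grouped by cuvette and sorted by time.
#'
#' Temperatures below 150 K are interpreted as Celsius and shifted by 273.15
#' unless `temperature_unit` overrides the auto-detection; biological assays
#' never run below 150 K, so the heuristic is safe.
#'
#' @param path Path to the CSV file.
#' @param columns Named character or integer vector mapping the required
#'   fields `sample`, `time`, `temperature`, `absorbance` to column names (or
#'   positions) in the file. Default matches the long form written by the
#'   cuvette-changer software (and by [write_instrument_csv()]).
#' @param time_unit Unit of the time column: `"s"` (default), `"min"` or `"h"`.
#' @param temperature_unit `"auto"` (default), `"K"` or `"C"`.
#' @param sep,dec Field separator and decimal mark passed to the reader.
#'
#' @return A data.frame of class `assay_readings` with columns `cuvette_id`,
#'   `time_s`, `temperature_K`, `absorbance`, ordered by cuvette then time.
#' @seealso [to_concentrations()], [write_instrument_csv()]
#' @export
parse_instrument_csv <- function(path,
                                 columns = c(sample = "sample", time = "time",
                                             temperature = "temperature",
                                             absorbance = "absorbance"),
                                 time_unit = "s",
                                 temperature_unit = "auto",
                                 sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("parse error: no data rows in ", path)
  required <- c("sample", "time", "temperature", "absorbance")
  if (!all(required %in% names(columns)))
    stop("configuration error: column mapping must name ",
         paste(setdiff(required, names(columns)), collapse = ", "))
  pick <- function(field) {
    key <- columns[[field]]
    if (is.numeric(key)) {
      if (key > ncol(raw)) stop("configuration error: no column at position ",
                                key, " for field '", field, "'")
      return(raw[[key]])
    }
    if (!key %in% names(raw))
      stop("configuration error: missing column '", key, "' (field '", field, "')")
    raw[[key]]
  }
  as_num <- function(x, field) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop("parse error: non-numeric value in column '", field,
           "' at data row ", bad[1], " ('", x[bad[1]], "')")
    v
  }
  out <- data.frame(
    cuvette_id    = as.character(pick("sample")),
    time_s        = as_num(pick("time"), "time") * .time_factor(time_unit),
    temperature_K = .to_kelvin(as_num(pick("temperature"), "temperature"),
                               temperature_unit),
    absorbance    = as_num(pick("absorbance"), "absorbance"),
    stringsAsFactors = FALSE)
  if (any(out$time_s < 0)) stop("validation error: negative time values")
  if (any(out$temperature_K <= 0)) stop("validation error: non-positive kelvin temperature")
  out <- out[order(out$cuvette_id, out$time_s), , drop = FALSE]
  dup <- duplicated(out[, c("cuvette_id", "time_s")])
  if (any(dup))
    stop("validation error: duplicate (cuvette, time) reading: cuvette '",
         out$cuvette_id[dup][1], "' at t = ", out$time_s[dup][1], " s")
  rownames(out) <- NULL
  class(out) <- c("assay_readings", "data.frame")
  out
}

#' Write readings in the long-form instrument CSV dialect
#'
#' Inverse of [parse_instrument_csv()] under the default column mapping:
#' writes one row per reading with time in seconds and temperature in kelvin.
#'
#' @param readings An `assay_readings` data.frame (columns `cuvette_id`,
#'   `time_s`, `temperature_K`, `absorbance`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument_csv <- function(readings, path) {
  stopifnot(all(c("cuvette_id", "time_s", "temperature_K", "absorbance")
                %in% names(readings)))
  out <- data.frame(sample = readings$cuvette_id,
                    time = readings$time_s,
                    temperature = readings$temperature_K,
                    absorbance = readings$absorbance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert absorbance readings to product and substrate concentrations
#'
#' Applies Beer-Lambert: product = (A - baseline) / (epsilon * l), and
#' substrate = S0 - product for each cuvette. The baseline defaults to each
#' cuvette's first reading so product starts at zero. Product monotonicity is
#' not enforced (instrument noise is expected); readings whose product falls
#' outside [0, S0] by more than `tolerance * S0` are flagged and retained,
#' with a warning.
#'
#' @param readings An `assay_readings` data.frame from
#'   [parse_instrument_csv()] or [simulate_ramp()].
#' @param design An [assay_design()] object; every cuvette id in `readings`
#'   must have an `S0` entry.
#' @param tolerance Fraction of S0 by which product may exceed [0, S0]
#'   before being flagged (default 0.05).
#'
#' @return A data.frame of class `cuvette_traces` with columns `cuvette_id`,
#'   `time_s`, `temperature_K`, `product_M`, `substrate_M`, `S0`,
#'   `out_of_range`.
#' @examples
#' d <- assay_design(17800, 1, E0 = 1e-9, S0 = c(a = 1e-3))
#' r <- structure(data.frame(cuvette_id = "a", time_s = 0:2,
#'                           temperature_K = 283.15, absorbance = c(0, 0.089, 0.178)),
#'                class = c("assay_readings", "data.frame"))
#' to_concentrations(r, d)
#' @export
to_concentrations <- function(readings, design, tolerance = 0.05) {
  stopifnot(inherits(design, "assay_design"))
  ids <- unique(readings$cuvette_id)
  missing_ids <- setdiff(ids, names(design$S0))
  if (length(missing_ids))
    stop("no S0 in the assay design for cuvette(s): ",
         paste(missing_ids, collapse = ", "))
  el <- design$extinction_coefficient * design$path_length
  pieces <- lapply(ids, function(id) {
    g <- readings[readings$cuvette_id == id, , drop = FALSE]
    g <- g[order(g$time_s), , drop = FALSE]
    base <- if (!is.null(design$baseline) && id %in% names(design$baseline))
      design$baseline[[id]] else g$absorbance[1]
    s0 <- design$S0[[id]]
    product <- (g$absorbance - base) / el
    flagged <- product > s0 * (1 + tolerance) | product < -s0 * tolerance
    data.frame(cuvette_id = id, time_s = g$time_s,
               temperature_K = g$temperature_K,
               product_M = product, substrate_M = s0 - product,
               S0 = s0, out_of_range = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (any(out$out_of_range))
    warning(sum(out$out_of_range),
            " reading(s) give product outside [0, S0] beyond tolerance; ",
            "flagged and retained")
  rownames(out) <- NULL
  class(out) <- c("cuvette_traces", "data.frame")
  out
}
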