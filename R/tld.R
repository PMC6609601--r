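#' Calibration policy for TLD chip processing
#'
#' Bundles the constants of the chip-processing chain: the calibration
#' exposure the chips were irradiated with, the gamma-to-X-ray correction
#' factor (LiF chips are calibrated against gamma energy, which reads about
#' 1.25 times more sensitively than diagnostic X-rays, hence the 0.8
#' multiplier), and the relative-error tolerance used to screen chips.
#'
#' @param reference_dose Calibration exposure in µGy (default 5612.7).
#' @param gamma_correction Multiplicative correction in (0, 1\] (default 0.8).
#' @param screening_tolerance Proportional tolerance for chip screening
#'   (default 0.05, i.e. chips within ±5% are kept).
#' @return A list of class `ppd_policy`.
#' @export
calibration_policy <- function(reference_dose = 5612.7,
                               gamma_correction = 0.8,
                               screening_tolerance = 0.05) {
  if (gamma_correction <= 0 || gamma_correction > 1)
    stop("gamma_correction must be in (0, 1]")
  if (screening_tolerance <= 0)
    stop("screening_tolerance must be positive")
  if (reference_dose <= 0)
    stop("reference_dose must be positive")
  structure(list(reference_dose = reference_dose,
                 gamma_correction = gamma_correction,
                 screening_tolerance = screening_tolerance),
            class = "ppd_policy")
}

#' Read a chip-readings CSV
#'
#' Expected columns: `chip_id`, `site_id` (or `"background"`), `repeat_index`
#' (1-based exposure repetition), `raw_signal` (µGy-equivalent reader
#' output), `sensitivity_factor`, `is_background` (0/1).
#'
#' @param path CSV file.
#' @return Validated data frame of chip readings.
#' @export
read_chip_readings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_chip_readings(df)
}

validate_chip_readings <- function(df) {
  need <- c("chip_id", "site_id", "repeat_index", "raw_signal",
            "sensitivity_factor", "is_background")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("chip readings: missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$raw_signal < 0)) stop("chip readings: raw_signal must be >= 0")
  if (any(df$sensitivity_factor <= 0))
    stop("chip readings: sensitivity_factor must be > 0")
  df$is_background <- as.logical(df$is_background)
  df
}

#' Screen chips against their calibration exposure
#'
#' A chip is accepted when its calibration reading, relative to the
#' sensitivity-scaled reference dose, is within the screening tolerance:
#' `|reading / (reference_dose * sensitivity_factor) - 1| < tol`. Chips with
#' non-positive readings are rejected with a logged reason.
#'
#' @param calibration_readings Data frame with `chip_id`, `raw_signal`,
#'   `sensitivity_factor` (one calibration reading per chip).
#' @param policy A [calibration_policy()].
#' @return Character vector of accepted chip ids; rejected chips and their
#'   reasons are attached as attribute `"rejected"`.
#' @export
screen_chips <- function(calibration_readings, policy = calibration_policy()) {
  df <- calibration_readings
  if (!all(c("chip_id", "raw_signal", "sensitivity_factor") %in% names(df)))
    stop("calibration readings need chip_id, raw_signal, sensitivity_factor")
  rel_err <- df$raw_signal / (policy$reference_dose * df$sensitivity_factor) - 1
  bad_signal <- df$raw_signal <= 0
  ok <- !bad_signal & abs(rel_err) < policy$screening_tolerance
  rejected <- data.frame(chip_id = df$chip_id[!ok],
                         reason = ifelse(bad_signal[!ok],
                                         "non-positive calibration reading",
                                         sprintf("calibration error %.1f%% exceeds tolerance",
                                                 100 * abs(rel_err[!ok]))),
                         stringsAsFactors = FALSE)
  structure(df$chip_id[ok], rejected = rejected)
}

#' Net background-subtracted site signals, per repeat
#'
#' Per chip the reader output is corrected as
#' `raw_signal * gamma_correction / sensitivity_factor`; the mean of the
#' background chips, corrected the same way, is subtracted. Applying the
#' corrections identically to exposed and background chips makes the result
#' invariant to a constant added to every raw signal. Negative net signals
#' (statistically possible near background) are clamped to zero with a
#' warning. Chips at one site are averaged within each repeat.
#'
#' @param readings Chip readings (see [read_chip_readings()]): background
#'   rows flagged with `is_background`.
#' @param policy A [calibration_policy()].
#' @return Data frame `site_id`, `repeat_index`, `net_dose` (µGy),
#'   `n_chips`.
#' @export
net_site_signal <- function(readings, policy = calibration_policy()) {
  df <- validate_chip_readings(readings)
  bg <- df[df$is_background, , drop = FALSE]
  ex <- df[!df$is_background, , drop = FALSE]
  if (nrow(bg) == 0L)
    stop("no background chips: background subtraction is not configured")
  if (nrow(ex) == 0L) stop("no exposed chips")
  corr <- function(d) d$raw_signal * policy$gamma_correction / d$sensitivity_factor
  bg_level <- mean(corr(bg))
  net <- corr(ex) - bg_level
  if (any(net < 0)) {
    warning(sum(net < 0), " chip reading(s) below background; clamped to 0")
    net[net < 0] <- 0
  }
  agg <- aggregate(net, by = list(site_id = ex$site_id,
                                  repeat_index = ex$repeat_index), FUN = mean)
  n <- aggregate(net, by = list(site_id = ex$site_id,
                                repeat_index = ex$repeat_index), FUN = length)
  out <- data.frame(site_id = agg$site_id, repeat_index = agg$repeat_index,
                    net_dose = agg$x, n_chips = n$x,
                    stringsAsFactors = FALSE)
  out[order(out$site_id, out$repeat_index), , drop = FALSE]
}

#' Average site doses over exposure repeats
#'
#' @param per_repeat Output of [net_site_signal()]: every site must appear
#'   in every repeat.
#' @return Data frame `site_id`, `absorbed_dose` (µGy, mean over repeats),
#'   `sd` (0 for a single repeat), `n_repeats`, `n_chips`.
#' @export
average_repeats <- function(per_repeat) {
  reps <- sort(unique(per_repeat$repeat_index))
  sites <- unique(per_repeat$site_id)
  for (s in sites) {
    have <- per_repeat$repeat_index[per_repeat$site_id == s]
    miss <- setdiff(reps, have)
    if (length(miss))
      stop("site ", s, " missing from repeat(s) ", paste(miss, collapse = ", "))
  }
  m <- aggregate(net_dose ~ site_id, data = per_repeat, FUN = mean)
  s <- aggregate(net_dose ~ site_id, data = per_repeat,
                 FUN = function(x) if (length(x) > 1) sd(x) else 0)
  nch <- aggregate(n_chips ~ site_id, data = per_repeat, FUN = max)
  data.frame(site_id = m$site_id, absorbed_dose = m$net_dose,
             sd = s$net_dose, n_repeats = length(reps),
             n_chips = nch$n_chips, stringsAsFactors = FALSE)
}

#' Run the full TLD measurement-processing chain
#'
#' Composes (optional) chip screening, background subtraction and
#' gamma/sensitivity correction, repeat averaging, fraction-irradiated organ
#' integration and ICRP-103 weighting into one call, returning a per-stage
#' report.
#'
#' @param readings Chip readings data frame or CSV path.
#' @param policy A [calibration_policy()].
#' @param map A [site_map()].
#' @param table A [tissue_table()].
#' @param kvp Tube voltage (for the bone MEACR conversion).
#' @param remainder_rule Passed to [effective_dose()].
#' @param bone_rule,meacr_variant Passed to [organ_doses_from_sites()].
#' @param calibration Optional calibration readings for [screen_chips()];
#'   readings from rejected chips are dropped.
#' @return Object of class `ppd_tld`: list with `chips_used`,
#'   `chips_rejected`, `site_doses`, `organ_doses`, `effective`
#'   (a `ppd_effdose`), and the conventions used.
#' @export
run_tld_pipeline <- function(readings, policy = calibration_policy(),
                             map = site_map(), table = tissue_table(),
                             kvp = 66, remainder_rule = "mean_over_14",
                             bone_rule = "bone_fractions",
                             meacr_variant = "text",
                             calibration = NULL) {
  if (is.character(readings)) readings <- read_chip_readings(readings)
  readings <- validate_chip_readings(readings)
  rejected <- NULL
  if (!is.null(calibration)) {
    keep <- screen_chips(calibration, policy)
    rejected <- attr(keep, "rejected")
    readings <- readings[readings$chip_id %in% keep | readings$is_background, ,
                         drop = FALSE]
  }
  per_repeat <- net_site_signal(readings, policy)
  site_doses_df <- average_repeats(per_repeat)
  site_doses <- setNames(site_doses_df$absorbed_dose, site_doses_df$site_id)
  organ_doses <- organ_doses_from_sites(site_doses, table, map, kvp,
                                        bone_rule, meacr_variant)
  eff <- effective_dose(organ_doses, table, remainder_rule)
  structure(list(chips_used = unique(readings$chip_id[!readings$is_background]),
                 chips_rejected = rejected,
                 site_doses = site_doses_df,
                 organ_doses = organ_doses,
                 effective = eff,
                 kvp = kvp, remainder_rule = remainder_rule,
                 bone_rule = bone_rule),
            class = "ppd_tld")
}

#' @export
print.ppd_tld <- function(x, ...) {
  cat("TLD dosimetry pipeline:", length(x$chips_used), "exposed chips,",
      nrow(x$site_doses), "sites\n")
  cat("Site doses (uGy):\n")
  print(transform(x$site_doses, absorbed_dose = round(absorbed_dose, 3),
                  sd = round(sd, 3)), row.names = FALSE)
  print(x$effective)
  invisible(x)
}

#' Read a per-site dose table
#'
#' Reads a CSV of site-averaged absorbed doses (columns `site_id`,
#' `absorbed_dose_ugy`), the form in which supplementary per-site TLD doses
#' are published. The packaged file `synthetic_site_doses.csv` is a
#' synthetic example with plausible magnitudes, not measured data.
#'
#' @param path CSV file.
#' @return Named numeric vector site -> µGy.
#' @export
read_site_doses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "absorbed_dose_ugy") %in% names(df)))
    stop("site-dose table needs columns site_id, absorbed_dose_ugy")
  setNames(df$absorbed_dose_ugy, df$site_id)
}

#' Effective dose directly from site doses
#'
#' Shortcut for already-averaged site doses (e.g. a published per-site
#' table): applies the fraction-irradiated integration and ICRP-103
#' weighting only.
#'
#' @inheritParams run_tld_pipeline
#' @param site_doses Named numeric vector site -> µGy, or a CSV path for
#'   [read_site_doses()].
#' @return A `ppd_effdose`.
#' @export
effective_dose_from_site_doses <- function(site_doses, map = site_map(),
                                           table = tissue_table(), kvp = 66,
                                           remainder_rule = "mean_over_14",
                                           bone_rule = "bone_fractions",
                                           meacr_variant = "text") {
  if (is.character(site_doses)) site_doses <- read_site_doses(site_doses)
  organ <- organ_doses_from_sites(site_doses, table, map, kvp, bone_rule,
                                  meacr_variant)
  effective_dose(organ, table, remainder_rule)
}
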