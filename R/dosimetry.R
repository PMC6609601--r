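#' Bone-to-muscle mass energy-absorption coefficient ratio (MEACR)
#'
#' Dosimeter chips measure dose in a muscle-equivalent medium; converting a
#' bone-region reading into a bone-surface dose uses the empirical
#' bone/muscle mass energy-absorption coefficient ratio, a linear function
#' of the tube voltage. The default form is
#' `-0.0618 * (2/3 * kvp) + 6.9406`, decreasing with voltage as photon
#' energy rises and the photoelectric advantage of bone shrinks. A variant
#' with the positive sign is available as `variant = "footnote"` for
#' comparison with the alternative printed form of the fit.
#'
#' The formula is an empirical fit for diagnostic voltages; inputs outside
#' 40--120 kVp are refused rather than extrapolated.
#'
#' @param kvp Tube voltage in kVp, in \[40, 120\].
#' @param variant `"text"` (default, negative slope) or `"footnote"`.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' meacr(66)  # 4.2214
meacr <- function(kvp, variant = c("text", "footnote")) {
  variant <- match.arg(variant)
  if (!is.numeric(kvp) || any(!is.finite(kvp)))
    stop("kvp must be finite numeric")
  if (any(kvp < 40 | kvp > 120))
    stop("kvp outside the fitted range [40, 120]; refusing to extrapolate")
  slope <- if (variant == "text") -0.0618 else 0.0618
  slope * (2 / 3 * kvp) + 6.9406
}

#' Integrate site doses into one tissue's equivalent dose
#'
#' Combines absorbed doses measured at anatomic sites into the equivalent
#' dose of one tissue using the fraction-irradiated table: each sub-region's
#' dose is the mean over its mapped sites, and the tissue dose is the
#' fraction-weighted sum `sum(f_i * D_i)`. When the printed sub-region
#' fractions total more than the whole organ (the salivary gland lists each
#' fully-irradiated gland at 100%), the sum is normalized by the total,
#' which reduces to the mean over sub-regions. For the bone surface the
#' result is additionally multiplied by [meacr()] (rule
#' `"bone_fractions"`, the default); rule `"marrow_times_meacr"` instead
#' takes the literal bone-marrow dose times MEACR.
#'
#' Photons carry a radiation weighting factor of 1, so the returned
#' equivalent dose in µSv is numerically the absorbed dose in µGy.
#'
#' @param site_doses Named numeric vector of site absorbed doses (µGy),
#'   names matching `site_id` in the map.
#' @param tissue Tissue name (a `tissue` level of the table).
#' @param table A [tissue_table()].
#' @param map A [site_map()].
#' @param kvp Tube voltage, needed for the bone surface.
#' @param bone_rule `"bone_fractions"` or `"marrow_times_meacr"`.
#' @param meacr_variant Passed to [meacr()].
#' @return Equivalent dose in µSv.
#' @export
organ_dose_from_sites <- function(site_doses, tissue, table = tissue_table(),
                                  map = site_map(), kvp = 66,
                                  bone_rule = c("bone_fractions",
                                                "marrow_times_meacr"),
                                  meacr_variant = "text") {
  bone_rule <- match.arg(bone_rule)
  if (any(site_doses < 0)) stop("site doses must be non-negative")
  if (tissue == "bone" && bone_rule == "marrow_times_meacr") {
    marrow <- organ_dose_from_sites(site_doses, "bone_marrow", table, map,
                                    kvp, meacr_variant = meacr_variant)
    return(marrow * meacr(kvp, meacr_variant))
  }
  rows <- table[table$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown tissue: ", tissue)
  sub_dose <- vapply(rows$sub_region, function(sr) {
    sites <- map$site_id[map$tissue == tissue & map$sub_region == sr]
    if (length(sites) == 0L)
      stop("no mapped sites for ", tissue, "/", sr)
    missing <- setdiff(unique(sites), names(site_doses))
    if (length(missing))
      stop("missing site dose for site(s): ", paste(missing, collapse = ", "),
           " (tissue ", tissue, ", sub-region ", sr, ")")
    mean(site_doses[sites])
  }, numeric(1))
  dose <- sum(rows$fraction * sub_dose) / max(1, sum(rows$fraction))
  if (tissue == "bone") dose <- dose * meacr(kvp, meacr_variant)
  dose
}

#' Equivalent doses for all tissues of the table
#'
#' @inheritParams organ_dose_from_sites
#' @return Named numeric vector, tissue -> equivalent dose (µSv); an
#'   organ-dose set consumable by [effective_dose()].
#' @export
organ_doses_from_sites <- function(site_doses, table = tissue_table(),
                                   map = site_map(), kvp = 66,
                                   bone_rule = "bone_fractions",
                                   meacr_variant = "text") {
  tissues <- unique(table$tissue)
  doses <- vapply(tissues, organ_dose_from_sites, numeric(1),
                  site_doses = site_doses, table = table, map = map,
                  kvp = kvp, bone_rule = bone_rule,
                  meacr_variant = meacr_variant)
  names(doses) <- tissues
  doses
}

#' Collective dose of the ICRP remainder tissues
#'
#' The ICRP-103 remainder is a group of 14 tissues sharing one collective
#' weighting factor of 0.12, applied to their arithmetic mean dose. Four of
#' the 14 are measured in the head and neck (extrathoracic airways, lymph
#' nodes, muscles, oral mucosa). Under the default rule `"mean_over_14"` the
#' ten unmeasured tissues are taken as unirradiated, so the remainder dose
#' is the sum of the four divided by 14; `"mean_over_included"` divides by
#' the number measured instead. Both conventions are kept because published
#' site-dosimetry studies differ on the denominator.
#'
#' @param organ_doses Named numeric vector including the four remainder
#'   tissues (µSv).
#' @param rule `"mean_over_14"` (default) or `"mean_over_included"`.
#' @param table A [tissue_table()] (names the remainder tissues).
#' @return Remainder dose in µSv.
#' @export
remainder_dose <- function(organ_doses, rule = c("mean_over_14",
                                                 "mean_over_included"),
                           table = tissue_table()) {
  if (is.character(rule) && length(rule) == 1L &&
      !rule %in% c("mean_over_14", "mean_over_included"))
    stop("unknown remainder rule: ", rule)
  rule <- match.arg(rule)
  rem <- remainder_tissues(table)
  missing <- setdiff(rem, names(organ_doses))
  if (length(missing))
    stop("missing remainder tissue dose(s): ", paste(missing, collapse = ", "))
  denom <- if (rule == "mean_over_14") 14 else length(rem)
  sum(organ_doses[rem]) / denom
}

#' Effective dose from an organ-dose set
#'
#' Computes the ICRP-103 effective dose `E = sum(w_T * H_T)` over the named
#' head-and-neck tissues, plus the collective remainder term
#' `0.12 * remainder_dose(...)`. The result is linear in every input dose.
#'
#' @inheritParams remainder_dose
#' @param organ_doses Named numeric vector of tissue equivalent doses (µSv)
#'   covering all named tissues of the table and the four remainder tissues.
#' @return An object of class `ppd_effdose`: a list with `effective_dose`
#'   (µSv), `contributions` (tissue -> weighted µSv, summing to E),
#'   `organ_doses`, and the conventions used.
#' @export
#' @examples
#' tab <- tissue_table()
#' d <- setNames(rep(1, length(unique(tab$tissue))), unique(tab$tissue))
#' effective_dose(d)$effective_dose
effective_dose <- function(organ_doses, table = tissue_table(),
                           rule = "mean_over_14") {
  tissues <- unique(table$tissue)
  missing <- setdiff(tissues, names(organ_doses))
  if (length(missing))
    stop("missing tissue dose(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(organ_doses)) || any(organ_doses < 0))
    stop("organ doses must be finite and non-negative")
  rem <- remainder_tissues(table)
  named <- setdiff(tissues, rem)
  w <- vapply(named, function(t) table$w_t[table$tissue == t][1], numeric(1))
  contrib <- w * organ_doses[named]
  rdose <- remainder_dose(organ_doses, rule, table)
  denom <- if (identical(rule, "mean_over_14")) 14 else length(rem)
  rem_contrib <- 0.12 * organ_doses[rem] / denom
  contributions <- c(contrib, rem_contrib)
  structure(list(effective_dose = unname(sum(contributions)),
                 contributions = contributions,
                 organ_doses = organ_doses[tissues],
                 remainder_rule = if (identical(rule, "mean_over_14"))
                   "mean_over_14" else rule,
                 remainder_dose = rdose),
            class = "ppd_effdose")
}

#' Published reference effective doses for paediatric panoramic radiography
#'
#' The two published effective doses for the 5-year-old phantom under the
#' general exposure conditions: 3.850 µSv measured by thermoluminescent
#' dosimetry and 3.474 µSv from a whole-body Monte Carlo simulation code.
#' They serve as comparison values — e.g. for checking that the two
#' methods agree within the commonly quoted 10% bound — not as outputs of
#' this package.
#'
#' @return Named numeric vector `c(tld = 3.850, mc = 3.474)` in µSv.
#' @export
reference_effective_doses <- function() c(tld = 3.850, mc = 3.474)

#' @export
print.ppd_effdose <- function(x, ...) {
  cat("Effective dose:", format(x$effective_dose, digits = 4), "uSv",
      sprintf("(remainder rule: %s)\n", x$remainder_rule))
  df <- data.frame(tissue = names(x$organ_doses),
                   H_T_uSv = round(unname(x$organ_doses), 4),
                   contribution_uSv = round(unname(
                     x$contributions[names(x$organ_doses)]), 5))
  print(df, row.names = FALSE)
  invisible(x)
}
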