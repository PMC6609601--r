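#' Describe a synthetic TLD chip-measurement scenario
#'
#' Ground truth for a simulated measurement campaign: true absorbed dose at
#' each anatomic site, a common background dose accumulated by every chip,
#' a proportional (multiplicative Gaussian) reader-noise level, and the
#' spread of per-chip sensitivity factors. The default layout mirrors a
#' real campaign: 16 sites x 3 chips x 3 exposure repeats plus 3 background
#' chips.
#'
#' @param true_site_doses Named numeric vector site -> µGy (>= 0).
#' @param background Background dose per chip in µGy (default 0.2).
#' @param noise_sd Proportional reader noise standard deviation (default 0).
#' @param sens_sd Standard deviation of sensitivity factors around 1
#'   (default 0).
#' @param chips_per_site,n_repeats,n_background Layout (defaults 3/3/3).
#' @param seed Seed making the generated dataset reproducible.
#' @return List of class `ppd_chip_scenario`.
#' @export
chip_scenario <- function(true_site_doses, background = 0.2, noise_sd = 0,
                          sens_sd = 0, chips_per_site = 3, n_repeats = 3,
                          n_background = 3, seed = 1) {
  if (is.null(names(true_site_doses)) || any(!nzchar(names(true_site_doses))))
    stop("true_site_doses must be a named vector")
  if (any(true_site_doses < 0) || background < 0 || noise_sd < 0 ||
      sens_sd < 0)
    stop("doses, background and noise levels must be >= 0")
  structure(list(true_site_doses = true_site_doses, background = background,
                 noise_sd = noise_sd, sens_sd = sens_sd,
                 chips_per_site = chips_per_site, n_repeats = n_repeats,
                 n_background = n_background, seed = seed),
            class = "ppd_chip_scenario")
}

#' Generate a synthetic chip-reading dataset with known effective dose
#'
#' Emits chip readings as the TLD pipeline consumes them. Each exposed chip
#' records the true site dose plus background, divided by the gamma
#' correction (the reader reports gamma-equivalent signal), scaled by its
#' sensitivity factor and multiplicative Gaussian noise:
#' `raw = ((true + background) / gamma) * s * (1 + eps)`. Background chips
#' record the background dose the same way. The ground-truth effective dose
#' is computed by an independent direct weighted sum transcribed from the
#' dosimetry tables — not by the pipeline under test — so round-trip tests
#' compare two separate code paths.
#'
#' @param scenario A [chip_scenario()]; its sites must cover the map's.
#' @param map A [site_map()].
#' @param policy A [calibration_policy()] (supplies the gamma correction).
#' @param kvp Tube voltage assumed for the ground-truth bone conversion.
#' @param remainder_rule Remainder convention for the ground truth.
#' @return List: `readings` (chip data frame), `truth` (list with
#'   `site_doses`, `effective_dose` in µSv).
#' @export
gen_chip_dataset <- function(scenario, map = site_map(),
                             policy = calibration_policy(), kvp = 66,
                             remainder_rule = "mean_over_14") {
  sites <- map_sites(map)
  missing <- setdiff(sites, names(scenario$true_site_doses))
  if (length(missing))
    stop("scenario missing site(s) required by the map: ",
         paste(missing, collapse = ", "))
  set.seed(scenario$seed)
  doses <- scenario$true_site_doses[sites]
  rows <- list()
  for (s in sites) {
    for (ch in seq_len(scenario$chips_per_site)) {
      sens <- max(0.1, 1 + rnorm(1, 0, scenario$sens_sd))
      for (r in seq_len(scenario$n_repeats)) {
        eps <- if (scenario$noise_sd > 0) rnorm(1, 0, scenario$noise_sd) else 0
        raw <- (doses[[s]] + scenario$background) / policy$gamma_correction *
          sens * (1 + eps)
        rows[[length(rows) + 1L]] <- data.frame(
          chip_id = sprintf("%s_c%d", s, ch), site_id = s, repeat_index = r,
          raw_signal = max(0, raw), sensitivity_factor = sens,
          is_background = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  for (b in seq_len(scenario$n_background)) {
    sens <- max(0.1, 1 + rnorm(1, 0, scenario$sens_sd))
    eps <- if (scenario$noise_sd > 0) rnorm(1, 0, scenario$noise_sd) else 0
    raw <- scenario$background / policy$gamma_correction * sens * (1 + eps)
    rows[[length(rows) + 1L]] <- data.frame(
      chip_id = sprintf("bg_c%d", b), site_id = "background",
      repeat_index = 1L, raw_signal = max(0, raw),
      sensitivity_factor = sens, is_background = TRUE,
      stringsAsFactors = FALSE)
  }
  readings <- do.call(rbind, rows)
  truth_E <- direct_effective_dose(doses, kvp, remainder_rule)
  list(readings = readings,
       truth = list(site_doses = doses, effective_dose = truth_E))
}

# Independent ground-truth effective dose: a literal transcription of the
# fraction-irradiated table and ICRP-103 weights, written separately from
# the dosimetry pipeline so generator-based tests have a second route.
direct_effective_dose <- function(site_doses, kvp = 66,
                                  remainder_rule = "mean_over_14") {
  d <- site_doses
  calv <- mean(d[c("ant_calvarium", "left_calvarium", "right_calvarium")])
  ramus <- mean(d[c("right_ramus", "left_ramus")])
  cspine <- d[["cervical_spine"]]
  marrow <- 0.116 * calv + 0.011 * ramus + 0.027 * cspine
  bone <- (0.118 * calv + 0.013 * ramus + 0.034 * cspine) *
    (-0.0618 * (2 / 3 * kvp) + 6.9406)
  brain <- mean(d[c("midbrain_a", "midbrain_b", "pituitary")])
  oeso <- 0.10 * d[["oesophagus"]]
  saliv <- mean(c(mean(d[c("right_ramus", "left_ramus")]),
                  mean(d[c("right_ramus", "left_ramus")]),
                  d[["sublingual"]]))
  skin <- 0.05 * mean(d[c("right_eye", "left_eye", "back_of_neck")])
  thyroid <- mean(d[c("left_thyroid", "right_thyroid")])
  et <- mean(d[c("right_eye", "pituitary", "right_ramus", "left_ramus",
                 "right_ramus", "left_ramus", "sublingual", "oesophagus")])
  lymph <- 0.05 * mean(d[c("right_ramus", "left_ramus", "right_ramus",
                           "left_ramus", "sublingual", "left_thyroid",
                           "right_thyroid")])
  mucosa <- mean(d[c("right_ramus", "left_ramus", "right_ramus",
                     "left_ramus", "sublingual")])
  denom <- if (remainder_rule == "mean_over_14") 14 else 4
  0.12 * marrow + 0.01 * bone + 0.01 * brain + 0.04 * oeso + 0.01 * saliv +
    0.01 * skin + 0.04 * thyroid + 0.12 * (et + lymph + lymph + mucosa) / denom
}

#' Homogeneous-slab transport scenario with a closed-form oracle
#'
#' Builds a single-voxel slab of prescribed linear attenuation and
#' thickness together with its Beer-Lambert uncollided transmission
#' `exp(-mu * t)`, for validating the transport kernel against an analytic
#' value.
#'
#' @param mu Linear attenuation coefficient (1/cm), > 0.
#' @param thickness Slab thickness along the beam (cm), >= 0.
#' @return List: `grid`, `mu_lin`, `mu_compton` (zero: a pure absorber),
#'   `e_grid`, and `transmission` (the analytic oracle).
#' @export
#' @examples
#' gen_slab_scenario(1, 1)$transmission  # exp(-1)
gen_slab_scenario <- function(mu, thickness) {
  if (mu <= 0) stop("mu must be positive")
  if (thickness < 0) stop("thickness must be >= 0")
  t <- max(thickness, 1e-9)
  grid <- list(dims = c(1L, 1L, 1L), origin = c(0, 0, 0), voxel_cm = t,
               material = 0L, organ = 1L, n_organs = 1L)
  e_grid <- 5:150
  list(grid = grid,
       mu_lin = matrix(mu, nrow = 1, ncol = length(e_grid)),
       mu_compton = matrix(0, nrow = 1, ncol = length(e_grid)),
       e_grid = e_grid,
       transmission = exp(-mu * thickness))
}

#' Measure slab transmission with the Monte Carlo kernel
#'
#' Fires monoenergetic photons perpendicularly through a
#' [gen_slab_scenario()] slab and returns the uncollided exit fraction with
#' its binomial standard error.
#'
#' @param scenario A [gen_slab_scenario()].
#' @param n_histories Number of photons.
#' @param energy keV (default 60).
#' @param seed Optional seed.
#' @return List: `transmission`, `se`, `expected`.
#' @export
slab_transmission <- function(scenario, n_histories = 1e5, energy = 60,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_histories)
  t <- scenario$grid$voxel_cm
  src <- cbind(rep(-0.5, n), t / 2, t / 2)
  dir <- cbind(rep(1, n), 0, 0)
  res <- transport_photons(scenario$grid, scenario$mu_lin,
                           scenario$mu_compton, scenario$e_grid, src, dir,
                           rep(energy, n))
  p <- res$n_uncollided_exits / n
  list(transmission = p, se = sqrt(p * (1 - p) / n),
       expected = scenario$transmission)
}

#' Generate linear factor-response data
#'
#' Seeded fixture for the regression stage: `y = slope * x + intercept +
#' N(0, noise_sd)` over the given levels.
#'
#' @param slope,intercept Line parameters.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param levels Numeric x values (>= 3).
#' @param seed Seed.
#' @return Data frame `x`, `y`.
#' @export
gen_linear_response <- function(slope, intercept, noise_sd, levels,
                                seed = 1) {
  if (length(levels) < 3) stop("need at least 3 levels")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  y <- slope * levels + intercept +
    if (noise_sd > 0) rnorm(length(levels), 0, noise_sd) else 0
  data.frame(x = levels, y = y)
}
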