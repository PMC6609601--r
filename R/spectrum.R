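#' Packaged photon mass attenuation / energy-absorption coefficients
#'
#' Compact transcription of the standard photon-interaction compilations for
#' aluminum, dry air, water, average soft tissue and cortical bone over
#' 5--150 keV: mass attenuation coefficient and mass energy-absorption
#' coefficient (cm^2/g). Values between tabulated energies are obtained by
#' log-log interpolation ([mu_over_rho()]), the conventional treatment for
#' these smoothly power-law-like data.
#'
#' @param path CSV file; defaults to the packaged table.
#' @return Data frame `material`, `energy_kev`, `mu_rho_cm2_g`,
#'   `mu_en_rho_cm2_g`.
#' @export
attenuation_table <- function(path = ppd_extdata("attenuation_coefficients.csv")) {
  read.csv(path, stringsAsFactors = FALSE)
}

# nominal densities (g/cm^3) used to convert mass coefficients to linear ones
ppd_densities <- c(air = 0.001205, water = 1.0, soft_tissue = 1.06,
                   bone = 1.92, aluminum = 2.699, brain = 1.04)

#' Interpolated mass attenuation coefficient
#'
#' @param material One of `"aluminum"`, `"air"`, `"water"`, `"soft_tissue"`,
#'   `"bone"` (and `"brain"`, which uses soft-tissue coefficients).
#' @param energies keV, within 5--150.
#' @param quantity `"mu"` (attenuation) or `"mu_en"` (energy absorption).
#' @param table An [attenuation_table()].
#' @return Vector of cm^2/g.
#' @export
mu_over_rho <- function(material, energies, quantity = c("mu", "mu_en"),
                        table = attenuation_table()) {
  quantity <- match.arg(quantity)
  lookup <- if (material == "brain") "soft_tissue" else material
  tab <- table[table$material == lookup, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no attenuation data for material: ", material)
  if (any(energies < min(tab$energy_kev) | energies > max(tab$energy_kev)))
    stop("energies outside the tabulated 5-150 keV range")
  col <- if (quantity == "mu") tab$mu_rho_cm2_g else tab$mu_en_rho_cm2_g
  exp(approx(log(tab$energy_kev), log(col), xout = log(energies))$y)
}

#' Unfiltered Kramers-law bremsstrahlung spectrum
#'
#' Thin-target Kramers form: relative photon fluence per energy bin
#' proportional to `(kvp - E) / E`, truncated below a 5 keV floor (photons
#' below are locally absorbed), normalized to sum 1. Characteristic anode
#' lines and anode self-filtration are deliberately not modelled; see the
#' methods vignette for the scope of this approximation.
#'
#' @param kvp Peak tube voltage (keV endpoint).
#' @param grid keV bin centres; default 1-keV bins from 5 to `kvp`.
#' @return Object of class `ppd_spectrum`: list with `energies`, `weights`
#'   (non-negative, summing to 1), `kvp`, `filtration_mmAl`.
#' @export
kramers_spectrum <- function(kvp, grid = seq(5, kvp, by = 1)) {
  if (kvp <= 5) stop("kvp must exceed the 5 keV spectrum floor")
  if (length(grid) == 0L) stop("empty energy grid")
  if (kvp <= min(grid)) stop("kvp must exceed the grid minimum")
  grid <- grid[grid >= 5 & grid <= kvp]
  if (length(grid) == 0L) stop("no grid points between the 5 keV floor and kvp")
  w <- pmax(0, (kvp - grid) / grid)
  if (sum(w) <= 0) stop("degenerate spectrum: all weights zero")
  structure(list(energies = grid, weights = w / sum(w), kvp = kvp,
                 filtration_mmAl = 0), class = "ppd_spectrum")
}

#' Harden a spectrum with aluminum filtration
#'
#' Each bin is attenuated by `exp(-mu_Al(E) * t)` using the packaged
#' aluminum coefficients, then the spectrum is renormalized. Filtration
#' removes low-energy photons preferentially, so the mean energy increases
#' with thickness (beam hardening); successive applications compose
#' exponentially.
#'
#' @param spec A `ppd_spectrum`.
#' @param mmAl Aluminum thickness in mm, >= 0.
#' @return Filtered `ppd_spectrum` (with `filtration_mmAl` accumulated).
#' @export
apply_filtration <- function(spec, mmAl) {
  if (mmAl < 0) stop("filtration thickness must be >= 0")
  if (mmAl == 0) return(spec)
  mu <- mu_over_rho("aluminum", spec$energies) * ppd_densities[["aluminum"]]
  w <- spec$weights * exp(-mu * mmAl / 10)
  if (sum(w) <= 0) stop("filtration removed the entire spectrum")
  spec$weights <- w / sum(w)
  spec$filtration_mmAl <- spec$filtration_mmAl + mmAl
  spec
}

#' Filtered source spectrum for an exposure geometry
#'
#' Convenience wrapper: Kramers spectrum at the geometry's kVp, hardened by
#' its filtration.
#'
#' @param geom An [exposure_geometry()], or a kVp value.
#' @param filtration mmAl (ignored when `geom` is a geometry).
#' @return A `ppd_spectrum`.
#' @export
source_spectrum <- function(geom, filtration = 0) {
  if (inherits(geom, "ppd_geometry"))
    apply_filtration(kramers_spectrum(geom$kvp), geom$filtration)
  else
    apply_filtration(kramers_spectrum(geom), filtration)
}

#' Mean energy of a spectrum
#' @param spec A `ppd_spectrum`.
#' @return keV.
#' @export
mean_energy <- function(spec) sum(spec$energies * spec$weights)

#' @export
print.ppd_spectrum <- function(x, ...) {
  cat(sprintf("X-ray spectrum: %g kVp, %g mmAl; %d bins, mean energy %.2f keV\n",
              x$kvp, x$filtration_mmAl, length(x$energies), mean_energy(x)))
  invisible(x)
}

# mGy air kerma per source photon crossing the reference plane of given area
air_kerma_per_photon <- function(spec, area_cm2) {
  if (area_cm2 <= 0) stop("beam area must be positive")
  mu_en <- mu_over_rho("air", spec$energies, "mu_en")
  # keV -> J (1.602e-16), cm^2/g -> cm^2/kg (*1000), Gy -> mGy (*1000)
  sum(spec$weights * spec$energies * mu_en) * 1.602176634e-16 * 1e6 / area_cm2
}

#' Photon weight that reproduces a configured dose-area product
#'
#' Computes the air kerma at the reference plane implied by the spectrum per
#' source photon (via the packaged air mass energy-absorption coefficients)
#' and returns the number of physical photons each simulated history must
#' represent so that `n_histories` histories reproduce the configured DAP
#' over the beam area. Organ doses are therefore strictly proportional to
#' `dap` and independent of `n_histories` in expectation.
#'
#' @param spec A `ppd_spectrum`.
#' @param dap Dose-area product, mGy cm^2.
#' @param beam_area_at_reference cm^2 (> 0).
#' @param n_histories Number of simulated histories.
#' @return Photons per history (numeric scalar).
#' @export
dap_to_history_weight <- function(spec, dap, beam_area_at_reference,
                                  n_histories) {
  if (dap <= 0 || n_histories <= 0) stop("dap and n_histories must be > 0")
  kerma_pp <- air_kerma_per_photon(spec, beam_area_at_reference)
  n_photons <- dap / (kerma_pp * beam_area_at_reference)
  n_photons / n_histories
}
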