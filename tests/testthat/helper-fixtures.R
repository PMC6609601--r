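# shared fixtures: built in code, no stored data

uniform_site_doses <- function(value = 10, map = site_map()) {
  sites <- map_sites(map)
  setNames(rep(value, length(sites)), sites)
}

random_site_doses <- function(map = site_map()) {
  sites <- map_sites(map)
  setNames(runif(length(sites), 0, 100), sites)
}

random_organ_doses <- function(table = tissue_table()) {
  tissues <- unique(table$tissue)
  setNames(runif(length(tissues), 0, 50), tissues)
}

# brute-force ICRP-103 weighted sum written straight from the printed
# weighting factors, independent of effective_dose()'s implementation
brute_force_E <- function(d, denom = 14) {
  0.12 * d[["bone_marrow"]] + 0.01 * d[["bone"]] + 0.01 * d[["brain"]] +
    0.04 * d[["oesophagus"]] + 0.01 * d[["salivary_gland"]] +
    0.01 * d[["skin"]] + 0.04 * d[["thyroid"]] +
    0.12 * (d[["extrathoracic_airways"]] + d[["lymph_nodes"]] +
              d[["muscles"]] + d[["oral_mucosa"]]) / denom
}

# simple chip-reading rows for pipeline unit tests
chip_rows <- function(site_id, raw, sens = 1, rep_idx = 1, bg = FALSE) {
  data.frame(chip_id = paste0(site_id, "_", seq_along(raw)),
             site_id = site_id, repeat_index = rep_idx, raw_signal = raw,
             sensitivity_factor = sens, is_background = bg,
             stringsAsFactors = FALSE)
}

# one shared phantom for the Monte Carlo tests (construction is cheap but
# not free; tests that mutate nothing can share it)
shared_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- build_pediatric_phantom()
    ph
  }
})
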