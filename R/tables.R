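#' Fraction-irradiated and tissue-weighting table for the paediatric head and neck
#'
#' Loads the packaged table of head-and-neck tissues considered in paediatric
#' panoramic dosimetry: for each tissue, its sub-regions with the proportion
#' of the whole tissue irradiated during the examination, the ICRP-103 tissue
#' weighting factor `w_T`, and whether the tissue belongs to the ICRP
#' remainder group. Eleven tissues are covered: bone marrow, bone (surface),
#' brain, oesophagus, salivary gland, skin, thyroid, and the four measured
#' remainder tissues (extrathoracic airways, lymph nodes, muscles, oral
#' mucosa).
#'
#' The table ships as a human-editable CSV; it is validated on load
#' (fractions in \[0, 1\], `w_T` one of 0.12/0.04/0.01, all eleven tissues
#' present exactly once at the tissue level).
#'
#' @param path CSV file to read; defaults to the packaged table.
#' @return A data frame of class `ppd_tissue_table` with columns `tissue`,
#'   `sub_region`, `fraction` (proportion in \[0, 1\]), `w_t`,
#'   `is_remainder`.
#' @export
#' @examples
#' tab <- tissue_table()
#' sum(tab$fraction[tab$tissue == "bone_marrow"])  # 0.154
tissue_table <- function(path = ppd_extdata("tissue_fractions.csv")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "sub_region", "fraction_pct", "w_t", "is_remainder")
  if (!all(need %in% names(tab)))
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  tab$fraction <- tab$fraction_pct / 100
  tab$is_remainder <- as.logical(tab$is_remainder)
  if (any(tab$fraction < 0 | tab$fraction > 1))
    stop("tissue table: fractions must lie in [0, 1]")
  if (!all(tab$w_t %in% c(0.12, 0.04, 0.01)))
    stop("tissue table: weighting factors must be one of 0.12, 0.04, 0.01")
  w_by_tissue <- tapply(tab$w_t, tab$tissue, function(x) length(unique(x)))
  if (any(w_by_tissue != 1))
    stop("tissue table: a tissue must have a single weighting factor")
  expected <- c("bone_marrow", "bone", "brain", "oesophagus",
                "salivary_gland", "skin", "thyroid",
                "extrathoracic_airways", "lymph_nodes", "muscles",
                "oral_mucosa")
  if (!setequal(unique(tab$tissue), expected))
    stop("tissue table must contain exactly the eleven head/neck tissues")
  class(tab) <- c("ppd_tissue_table", "data.frame")
  tab
}

#' The four remainder tissues measured in the head and neck
#' @param table A [tissue_table()].
#' @return Character vector of remainder tissue names.
#' @export
remainder_tissues <- function(table = tissue_table()) {
  unique(table$tissue[table$is_remainder])
}

#' Map from anatomic dosimeter sites to organs and sub-regions
#'
#' Loads the packaged map of thermoluminescent dosimeter placements in the
#' 5-year-old anthropomorphic phantom: each row links one organ/tissue
#' sub-region to an anatomic site, the phantom slice-and-hole location, and
#' the three chip identifiers read at that site. One physical site may feed
#' several tissues (the ramus sites, for example, contribute to bone marrow,
#' bone, parotid and submandibular glands, and several remainder tissues).
#'
#' @param path CSV file to read; defaults to the packaged map.
#' @return A data frame of class `ppd_site_map` with columns `tissue`,
#'   `sub_region`, `site_label`, `site_id`, `slice_hole`, `chip_1..3`.
#' @export
site_map <- function(path = ppd_extdata("site_organ_map.csv")) {
  map <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "sub_region", "site_label", "site_id", "slice_hole",
            "chip_1", "chip_2", "chip_3")
  if (!all(need %in% names(map)))
    stop("site map must have columns: ", paste(need, collapse = ", "))
  # each site carries exactly 3 chip ids, consistently across rows
  chips <- unique(map[, c("site_id", "chip_1", "chip_2", "chip_3")])
  if (anyDuplicated(chips$site_id))
    stop("site map: a site_id must always carry the same chip triplet")
  if (any(!nzchar(chips$chip_1) | !nzchar(chips$chip_2) | !nzchar(chips$chip_3)))
    stop("site map: every site needs exactly 3 chip ids")
  class(map) <- c("ppd_site_map", "data.frame")
  map
}

#' Anatomic site identifiers of a site map
#' @param map A [site_map()].
#' @return Character vector of unique site ids.
#' @export
map_sites <- function(map = site_map()) unique(map$site_id)
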