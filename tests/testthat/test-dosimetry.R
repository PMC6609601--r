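test_that("MEACR follows the printed linear fit and decreases with voltage", {
  expect_equal(meacr(66), 4.2214, tolerance = 1e-12)
  expect_equal(meacr(57), 4.5922, tolerance = 1e-12)
  expect_equal(meacr(72), 3.9742, tolerance = 1e-12)
  kv <- seq(40, 120, by = 5)
  expect_true(all(diff(meacr(kv)) < 0))
  # footnote variant flips the slope sign
  expect_true(all(diff(meacr(kv, variant = "footnote")) > 0))
  expect_error(meacr(30), "range")
  expect_error(meacr(130), "range")
})

test_that("tissue table loads with the printed fraction totals and weights", {
  tab <- tissue_table()
  expect_equal(sum(tab$fraction[tab$tissue == "bone_marrow"]), 0.154)
  expect_equal(sum(tab$fraction[tab$tissue == "bone"]), 0.165)
  expect_length(unique(tab$tissue), 11)
  expect_setequal(remainder_tissues(tab),
                  c("extrathoracic_airways", "lymph_nodes", "muscles",
                    "oral_mucosa"))
  expect_true(all(tab$w_t %in% c(0.12, 0.04, 0.01)))
})

test_that("site map carries a consistent chip triplet per site", {
  map <- site_map()
  expect_length(map_sites(map), 16)
  # one physical site may feed several tissues
  ramus_tissues <- unique(map$tissue[map$site_id == "right_ramus"])
  expect_true(all(c("bone_marrow", "salivary_gland", "oral_mucosa") %in%
                    ramus_tissues))
})

test_that("organ dose integrates site doses by irradiated fraction", {
  d <- uniform_site_doses(10)
  expect_equal(organ_dose_from_sites(d, "bone_marrow"),
               10 * (0.116 + 0.011 + 0.027), tolerance = 1e-12)
  expect_equal(organ_dose_from_sites(uniform_site_doses(0), "bone_marrow"), 0)
  d5 <- uniform_site_doses(5)
  expect_equal(organ_dose_from_sites(d5, "brain"), 5, tolerance = 1e-12)
  # fully-irradiated multi-gland tissue reduces to the gland mean
  expect_equal(organ_dose_from_sites(d5, "salivary_gland"), 5,
               tolerance = 1e-12)
  # bone surface applies the MEACR conversion on top of its own fractions
  expect_equal(organ_dose_from_sites(d, "bone", kvp = 66),
               10 * 0.165 * meacr(66), tolerance = 1e-12)
  # literal reading: marrow value times MEACR
  expect_equal(organ_dose_from_sites(d, "bone", kvp = 66,
                                     bone_rule = "marrow_times_meacr"),
               10 * 0.154 * meacr(66), tolerance = 1e-12)
  d_missing <- d[setdiff(names(d), "cervical_spine")]
  expect_error(organ_dose_from_sites(d_missing, "bone_marrow"),
               "cervical_spine")
})

test_that("remainder dose honours both denominator conventions", {
  tab <- tissue_table()
  d <- setNames(rep(0, 11), unique(tab$tissue))
  d[remainder_tissues(tab)] <- 14
  expect_equal(remainder_dose(d, "mean_over_14"), 4.0)
  d[remainder_tissues(tab)] <- 4
  expect_equal(remainder_dose(d, "mean_over_included"), 4.0)
  d[remainder_tissues(tab)] <- 0
  expect_equal(remainder_dose(d, "mean_over_14"), 0)
  expect_equal(remainder_dose(d, "mean_over_included"), 0)
  expect_error(remainder_dose(d, "mean_over_7"), "unknown remainder rule")
})

test_that("effective dose is the ICRP-103 weighted sum", {
  tab <- tissue_table()
  tissues <- unique(tab$tissue)
  zero <- setNames(rep(0, 11), tissues)
  d <- zero; d["thyroid"] <- 1
  expect_equal(effective_dose(d)$effective_dose, 0.04, tolerance = 1e-12)
  d <- zero; d["brain"] <- 2
  expect_equal(effective_dose(d)$effective_dose, 0.02, tolerance = 1e-12)
  ones <- setNames(rep(1, 11), tissues)
  expect_equal(effective_dose(ones)$effective_dose,
               0.12 + 0.01 + 0.01 + 0.04 + 0.01 + 0.01 + 0.04 +
                 0.12 * 4 / 14, tolerance = 1e-12)
  res <- effective_dose(ones)
  expect_equal(sum(res$contributions), res$effective_dose,
               tolerance = 1e-9)
  expect_true(all(res$contributions >= 0))
  expect_error(effective_dose(ones[-1]), "missing tissue")
  neg <- ones; neg["skin"] <- -1
  expect_error(effective_dose(neg), "non-negative")
})

test_that("effective dose is linear and monotone in organ doses", {
  set.seed(42)
  for (i in 1:20) {
    d <- random_organ_doses()
    E <- effective_dose(d)$effective_dose
    k <- runif(1, 0, 5)
    expect_equal(effective_dose(k * d)$effective_dose, k * E,
                 tolerance = 1e-12)
    bump <- d
    t <- sample(names(d), 1)
    bump[t] <- bump[t] + runif(1, 0, 10)
    expect_gte(effective_dose(bump)$effective_dose, E)
  }
})

test_that("effective dose matches an independent brute-force weighted sum", {
  set.seed(7)
  for (i in 1:100) {
    d <- random_organ_doses()
    expect_equal(effective_dose(d)$effective_dose, brute_force_E(d),
                 tolerance = 1e-12)
    expect_equal(effective_dose(d, rule = "mean_over_included")$effective_dose,
                 brute_force_E(d, denom = 4), tolerance = 1e-12)
  }
})
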