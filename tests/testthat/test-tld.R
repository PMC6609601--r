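test_that("chip screening applies the relative-error tolerance", {
  pol <- calibration_policy()
  cal <- data.frame(chip_id = c("a", "b", "c", "d"),
                    raw_signal = pol$reference_dose * c(1, 1.06, 0.96, 0),
                    sensitivity_factor = 1)
  keep <- screen_chips(cal, pol)
  expect_setequal(as.character(keep), c("a", "c"))
  rej <- attr(keep, "rejected")
  expect_setequal(rej$chip_id, c("b", "d"))
  expect_match(rej$reason[rej$chip_id == "d"], "non-positive")
  # sensitivity-scaled reference: a chip reading high because it is more
  # sensitive is still accepted
  cal2 <- data.frame(chip_id = "e", raw_signal = pol$reference_dose * 1.2,
                     sensitivity_factor = 1.2)
  expect_equal(as.character(screen_chips(cal2, pol)), "e")
})

test_that("net site signal corrects, subtracts background and averages", {
  pol <- calibration_policy()
  bg0 <- chip_rows("background", 0, bg = TRUE)
  r <- rbind(chip_rows("s1", 10), bg0)
  out <- net_site_signal(r, pol)
  expect_equal(out$net_dose, 8.0, tolerance = 1e-12)  # 10 * 0.8
  # exact cancellation with the background level
  r2 <- rbind(chip_rows("s1", 5), chip_rows("background", 5, bg = TRUE))
  expect_equal(net_site_signal(r2, pol)$net_dose, 0, tolerance = 1e-12)
  # three chips average within a repeat (background 0)
  r3 <- rbind(chip_rows("s1", c(8, 10, 12) / pol$gamma_correction), bg0)
  expect_equal(net_site_signal(r3, pol)$net_dose, 10, tolerance = 1e-12)
  expect_equal(net_site_signal(r3, pol)$n_chips, 3)
  expect_error(net_site_signal(chip_rows("s1", 10), pol), "background")
  # sub-background readings clamp to zero with a warning
  r4 <- rbind(chip_rows("s1", 1), chip_rows("background", 5, bg = TRUE))
  expect_warning(out4 <- net_site_signal(r4, pol), "clamped")
  expect_equal(out4$net_dose, 0)
})

test_that("repeat averaging needs every site in every repeat", {
  pr <- data.frame(site_id = rep("s1", 3), repeat_index = 1:3,
                   net_dose = c(9, 10, 11), n_chips = 3)
  out <- average_repeats(pr)
  expect_equal(out$absorbed_dose, 10)
  expect_equal(out$sd, sd(c(9, 10, 11)))
  one <- pr[1, ]
  expect_equal(average_repeats(one)$sd, 0)
  expect_equal(average_repeats(transform(pr, net_dose = 0))$absorbed_dose, 0)
  bad <- rbind(pr, data.frame(site_id = "s2", repeat_index = 1,
                              net_dose = 1, n_chips = 3))
  expect_error(average_repeats(bad), "s2.*repeat|missing from repeat")
})

test_that("background invariance: a common raw offset cancels out", {
  pol <- calibration_policy()
  base <- rbind(chip_rows("s1", c(10, 12, 14)),
                chip_rows("s2", c(3, 4, 5)),
                chip_rows("background", c(1, 1, 1), bg = TRUE))
  shifted <- base
  shifted$raw_signal <- shifted$raw_signal + 7.3
  a <- net_site_signal(base, pol)
  b <- net_site_signal(shifted, pol)
  expect_equal(a$net_dose, b$net_dose, tolerance = 1e-12)
})

test_that("scaling every raw signal by k scales the effective dose by k", {
  ds <- gen_chip_dataset(chip_scenario(uniform_site_doses(20),
                                       background = 0.5, seed = 3))
  r1 <- run_tld_pipeline(ds$readings)
  scaled <- ds$readings
  scaled$raw_signal <- scaled$raw_signal * 2.5
  r2 <- run_tld_pipeline(scaled)
  expect_equal(r2$effective$effective_dose,
               2.5 * r1$effective$effective_dose, tolerance = 1e-12)
})

test_that("zero-noise synthetic chips round-trip exactly through the pipeline", {
  truth <- random_site_doses()
  set.seed(5)
  truth[] <- runif(length(truth), 0, 80)
  ds <- gen_chip_dataset(chip_scenario(truth, background = 0.4,
                                       sens_sd = 0.1, seed = 9))
  res <- run_tld_pipeline(ds$readings)
  rec <- setNames(res$site_doses$absorbed_dose, res$site_doses$site_id)
  expect_equal(rec[names(truth)], truth, tolerance = 1e-12)
  expect_equal(res$effective$effective_dose, ds$truth$effective_dose,
               tolerance = 1e-12)
})

test_that("all signals at background level give a zero effective dose", {
  ds <- gen_chip_dataset(chip_scenario(uniform_site_doses(0),
                                       background = 2, seed = 4))
  expect_equal(run_tld_pipeline(ds$readings)$effective$effective_dose, 0,
               tolerance = 1e-12)
})

test_that("site-dose error shrinks with more chips per site", {
  pol <- calibration_policy()
  err <- function(nchips, seed) {
    set.seed(seed)
    truth <- 100
    raw <- truth / pol$gamma_correction * (1 + rnorm(nchips, 0, 0.05))
    r <- rbind(chip_rows("s1", raw),
               chip_rows("background", 0, bg = TRUE))
    abs(net_site_signal(r, pol)$net_dose - truth)
  }
  seeds <- 1:200
  e3 <- mean(vapply(seeds, function(s) err(3, s), numeric(1)))
  e30 <- mean(vapply(seeds, function(s) err(30, s + 1000), numeric(1)))
  expect_lt(e30, e3)
})

test_that("the pipeline drops screened-out chips before averaging", {
  pol <- calibration_policy()
  ds <- gen_chip_dataset(chip_scenario(uniform_site_doses(10), seed = 2))
  chips <- unique(ds$readings$chip_id[!ds$readings$is_background])
  cal <- data.frame(chip_id = chips, raw_signal = pol$reference_dose,
                    sensitivity_factor = 1)
  bad <- chips[1]
  cal$raw_signal[cal$chip_id == bad] <- pol$reference_dose * 1.5
  res <- run_tld_pipeline(ds$readings, calibration = cal)
  expect_false(bad %in% res$chips_used)
  expect_true(bad %in% res$chips_rejected$chip_id)
  # remaining chips still reproduce the uniform truth (noise-free data)
  expect_equal(res$effective$effective_dose,
               ds$truth$effective_dose, tolerance = 1e-12)
})
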