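test_that("the one-factor-at-a-time design deduplicates onto the baseline", {
  d <- build_design()
  expect_equal(nrow(d), 36)
  expect_equal(sum(d$is_baseline), 1)
  # order-independence of the emitted configuration set
  sw <- factor_sweeps()
  d2 <- build_design(sw[rev(seq_len(nrow(sw))), ])
  key <- function(x) sort(apply(x[, c("rotation_angle", "vertical_angle",
                                      "frd", "beam_width", "beam_height",
                                      "filtration", "kvp")], 1, paste,
                                collapse = "|"))
  expect_identical(key(d), key(d2))
  # one factor, six levels, none at baseline -> 6 + shared baseline
  sw1 <- data.frame(factor = "frd", levels = I(list(c(10, 12, 14, 16, 18, 20))))
  expect_equal(nrow(build_design(sw1)), 7)
  # levels that include the baseline collapse onto it
  sw2 <- data.frame(factor = "frd", levels = I(list(c(25, 27, 29, 31, 33, 35))))
  expect_equal(nrow(build_design(sw2)), 6)
  dup <- rbind(sw1, sw1)
  expect_error(build_design(dup), "duplicate")
})

test_that("the packaged sweep levels are six evenly spaced values per factor", {
  sw <- factor_sweeps()
  expect_equal(nrow(sw), 7)
  expect_true(all(vapply(sw$levels, length, integer(1)) == 6))
  for (lv in sw$levels) {
    d <- diff(lv)
    expect_true(all(abs(d - d[1]) < 1e-9))
  }
})

test_that("simple linear regression recovers exact lines and flat responses", {
  f <- ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  rot <- seq(180, 240, by = 12)
  f2 <- ols(rot, 2 * rot + 1)
  expect_equal(f2$slope, 2, tolerance = 1e-10)
  expect_equal(f2$intercept, 1, tolerance = 1e-8)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
  f3 <- ols(rot, rep(3, 6))
  expect_equal(f3$slope, 0, tolerance = 1e-12)
  expect_equal(f3$r_squared, 0)
  expect_error(ols(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(ols(1:2, 1:2), "3 points")
})

test_that("ols agrees with hand-written normal equations on random data", {
  set.seed(31)
  for (i in 1:50) {
    x <- runif(8, -5, 5)
    y <- runif(8, -5, 5)
    f <- ols(x, y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    b <- sxy / sxx
    a <- mean(y) - b * mean(x)
    sse <- sum((y - a - b * x)^2)
    sst <- sum((y - mean(y))^2)
    expect_equal(f$slope, b, tolerance = 1e-10)
    expect_equal(f$intercept, a, tolerance = 1e-10)
    expect_equal(f$r_squared, 1 - sse / sst, tolerance = 1e-10)
    se_b <- sqrt(sse / (length(x) - 2) / sxx)
    p <- 2 * pt(abs(b / se_b), df = length(x) - 2, lower.tail = FALSE)
    expect_equal(f$p_value, p, tolerance = 1e-10)
  }
})

test_that("the report ranks factors by per-range impact with a name tie-break", {
  mk <- function(f, slope, span = 10) {
    x <- seq(0, span, length.out = 6)
    ols(x, slope * x + 1, factor_name = f)
  }
  rep <- sensitivity_report(list(mk("beam_height", 0.5), mk("frd", 0.01),
                                 mk("kvp", -0.2)))
  expect_equal(rep$factor, c("beam_height", "kvp", "frd"))
  expect_equal(rep$sign, c(1, -1, 1))
  expect_equal(rep$per_range_impact, c(5, -2, 0.1), tolerance = 1e-9)
  # equal magnitude: alphabetical factor order
  tie <- sensitivity_report(list(mk("kvp", 0.2), mk("beam_width", -0.2)))
  expect_equal(tie$factor, c("beam_width", "kvp"))
  flat <- sensitivity_report(list(mk("frd", 0), mk("kvp", 0)))
  expect_true(all(flat$coefficient == 0))
  expect_error(sensitivity_report(list()), "no regression")
})

test_that("a response driven by one factor ranks that factor first", {
  # synthetic engine: E depends only on beam height
  sw <- factor_sweeps()
  fits <- lapply(seq_len(nrow(sw)), function(i) {
    lv <- sw$levels[[i]]
    E <- if (sw$factor[i] == "beam_height") 0.5 * lv + 1 else rep(3, 6)
    ols(lv, E, factor_name = sw$factor[i])
  })
  rep <- sensitivity_report(fits)
  expect_equal(rep$factor[1], "beam_height")
  expect_true(all(rep$coefficient[rep$factor != "beam_height"] == 0))
})

test_that("noise-free linear fixtures are recovered exactly, noisy ones unbiasedly", {
  df <- gen_linear_response(1.7, -2, 0, levels = seq(0, 10, 2), seed = 1)
  f <- ols(df$x, df$y)
  expect_equal(f$slope, 1.7, tolerance = 1e-10)
  expect_equal(f$intercept, -2, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  slopes <- vapply(1:300, function(s) {
    d <- gen_linear_response(2, 1, 0.5, levels = seq(0, 10, 2), seed = s)
    ols(d$x, d$y)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2), 2.5 * se + 1e-12)
})

test_that("fitted signs agree with the rank correlation of the sweep points", {
  # internal consistency of the simulator-driven sweep at modest size
  sw <- factor_sweeps()
  run <- sensitivity_analysis(sw, n_histories = 4000, seed = 5,
                              phantom = shared_phantom())
  expect_equal(nrow(run$design), 36)
  for (f in names(run$fits)) {
    pts <- run$fits[[f]]$points
    rho <- suppressWarnings(cor(pts$x, pts$y, method = "spearman"))
    if (is.finite(rho) && abs(rho) > 0.5)
      expect_equal(sign(run$fits[[f]]$slope), sign(rho))
  }
})
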