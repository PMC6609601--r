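#' Six-level sweep values for the seven dose-determining factors
#'
#' Loads the packaged one-factor-at-a-time sweep table: for each of the
#' seven factors (rotation angle, vertical angle, FRD, beam width, beam
#' height, filtration, tube voltage) the six evenly-spaced input levels
#' spanning the manufacturer/regulatory range.
#'
#' @param path CSV file (columns `factor`, `v1..v6`); defaults to the
#'   packaged table.
#' @return Data frame with `factor` and a `levels` list-column of numeric
#'   length-6 vectors.
#' @export
factor_sweeps <- function(path = ppd_extdata("factor_levels.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("factor", paste0("v", 1:6))
  if (!all(need %in% names(df)))
    stop("sweep table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$factor)) stop("duplicate factor names in sweep table")
  lv <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, paste0("v", 1:6)]))
  for (i in seq_along(lv)) {
    d <- diff(lv[[i]])
    if (any(abs(d - d[1]) > 1e-9 * max(1, abs(d[1]))))
      stop("levels of factor ", df$factor[i], " are not evenly spaced")
  }
  data.frame(factor = df$factor, levels = I(lv), stringsAsFactors = FALSE)
}

ppd_factor_names <- c("rotation_angle", "vertical_angle", "frd",
                      "beam_width", "beam_height", "filtration", "kvp")

# per-factor tolerance for treating a level as identical to baseline;
# filtration gets 0.011 mmAl so that a 2.81 top level collapses onto a
# 2.8 mmAl baseline (the two printed forms of the same setting)
ppd_dedup_tol <- c(rotation_angle = 1e-9, vertical_angle = 1e-9, frd = 1e-9,
                   beam_width = 1e-9, beam_height = 1e-9,
                   filtration = 0.011, kvp = 1e-9)

#' Build the one-factor-at-a-time simulation design
#'
#' For each sweep factor and level, emits the baseline geometry with that
#' single field replaced; all configurations identical to the baseline
#' (within a per-field tolerance) collapse into one shared baseline run.
#' With the packaged seven sweeps and the default baseline the deduplicated
#' design has 36 entries.
#'
#' @param sweeps A [factor_sweeps()] table (or subset of it).
#' @param baseline An [exposure_geometry()].
#' @return Data frame of class `ppd_design`: columns `factor`, `level`, the
#'   seven geometry fields, and `is_baseline`. The shared baseline row has
#'   `factor = "baseline"`.
#' @export
#' @examples
#' nrow(build_design())  # 36
build_design <- function(sweeps = factor_sweeps(),
                         baseline = exposure_geometry()) {
  if (anyDuplicated(sweeps$factor)) stop("duplicate factor names")
  unknown <- setdiff(sweeps$factor, ppd_factor_names)
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  base_vals <- unlist(baseline[ppd_factor_names])
  rows <- list()
  used_baseline <- FALSE
  for (i in seq_len(nrow(sweeps))) {
    f <- sweeps$factor[i]
    for (lv in sweeps$levels[[i]]) {
      if (abs(lv - base_vals[[f]]) <= ppd_dedup_tol[[f]]) {
        used_baseline <- TRUE
        next
      }
      g <- base_vals
      g[[f]] <- lv
      rows[[length(rows) + 1L]] <- c(list(factor = f, level = lv),
                                     as.list(g), list(is_baseline = FALSE))
    }
  }
  rows[[length(rows) + 1L]] <- c(list(factor = "baseline", level = NA_real_),
                                 as.list(base_vals),
                                 list(is_baseline = TRUE))
  if (!used_baseline && nrow(sweeps) == length(ppd_factor_names))
    message("no sweep level coincides with the baseline; ",
            "the baseline run is added as an extra configuration")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(match(out$factor, c(ppd_factor_names, "baseline")),
                   out$level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppd_design", "data.frame")
  out
}

design_geometry <- function(design_row, baseline = exposure_geometry()) {
  exposure_geometry(rotation_angle = design_row$rotation_angle,
                    vertical_angle = design_row$vertical_angle,
                    frd = design_row$frd,
                    beam_width = design_row$beam_width,
                    beam_height = design_row$beam_height,
                    filtration = design_row$filtration,
                    kvp = design_row$kvp,
                    dap = baseline$dap,
                    reference_point = baseline$reference_point)
}

#' Run the Monte Carlo simulator over a design
#'
#' Executes one simulation per design row with a deterministic seed ladder
#' (`seed`, `seed + 1`, ...), so a sweep is reproducible from a single
#' seed.
#'
#' @param design A [build_design()] result.
#' @param baseline The baseline [exposure_geometry()] (supplies DAP and
#'   reference point).
#' @param n_histories Histories per configuration.
#' @param seed Base seed of the ladder.
#' @param phantom Optional shared phantom (built once by default).
#' @return The design with columns `effective_dose` (µSv) and `seed` added.
#' @export
run_design <- function(design, baseline = exposure_geometry(),
                       n_histories = 2e4, seed = 1, phantom = NULL) {
  if (is.null(phantom)) phantom <- build_pediatric_phantom()
  E <- numeric(nrow(design))
  seeds <- seed + seq_len(nrow(design)) - 1
  for (i in seq_len(nrow(design))) {
    g <- design_geometry(design[i, ], baseline)
    sim <- run_simulation(g, phantom = phantom, n_histories = n_histories,
                          seed = seeds[i])
    E[i] <- sim$effective$effective_dose
  }
  design$effective_dose <- E
  design$seed <- seeds
  design
}

#' Simple linear regression of effective dose on a factor
#'
#' Ordinary least squares (via [stats::lm()]) of the response on a single
#' factor's levels, reporting the regression coefficient (slope), the
#' intercept, the coefficient of determination R^2, and the two-sided
#' t-test p-value for the slope (classical t distribution, n - 2 degrees of
#' freedom; no multiple-testing correction is applied across factors).
#'
#' @param x Factor levels (>= 3 distinct design points).
#' @param y Effective doses (µSv).
#' @param factor_name Optional label carried into reports.
#' @return Object of class `ppd_ols`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `points` (data frame), `factor`.
#' @export
#' @examples
#' ols(0:2, c(0, 1, 2))  # slope 1, R^2 = 1
ols <- function(x, y, factor_name = NA_character_) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (var(x) == 0) stop("degenerate design: all x values equal")
  if (var(y) == 0)
    return(structure(list(factor = factor_name, slope = 0, intercept = y[1],
                          r_squared = 0, p_value = 1,
                          points = data.frame(x = x, y = y)),
                     class = "ppd_ols"))
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  slope <- unname(coef(fit)[2])
  p <- unname(sm$coefficients[2, 4])
  # an exact line gives a zero residual scale and an undefined t; report
  # the smallest representable positive p so p stays in (0, 1]
  if (!is.finite(p)) p <- .Machine$double.xmin
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  structure(list(factor = factor_name,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 p_value = p,
                 points = data.frame(x = x, y = y)),
            class = "ppd_ols")
}

#' @export
print.ppd_ols <- function(x, ...) {
  cat(sprintf("OLS%s: slope %.6g, intercept %.6g, R^2 %.4f, p %.4g (n = %d)\n",
              if (is.na(x$factor)) "" else paste0(" [", x$factor, "]"),
              x$slope, x$intercept, x$r_squared, x$p_value,
              nrow(x$points)))
  invisible(x)
}

#' Rank dose-determining factors by regression impact
#'
#' Summarizes per-factor regressions into a ranked table. Raw regression
#' coefficients carry the factor's units (µSv per degree, per cm, per mmAl,
#' per kVp), so the table also reports a per-range impact — coefficient
#' times the swept level span — which is unit-free across factors; ranking
#' uses its absolute value, with ties broken by factor name order.
#'
#' @param results List of `ppd_ols` objects (one per factor, with
#'   `factor` set).
#' @return Data frame of class `ppd_sensitivity`, ranked by
#'   `abs(per_range_impact)` descending: `factor`, `coefficient`,
#'   `intercept`, `r_squared`, `p_value`, `sign`, `per_unit_impact`,
#'   `per_range_impact`, `level_span`.
#' @export
sensitivity_report <- function(results) {
  if (length(results) == 0) stop("no regression results supplied")
  rows <- lapply(results, function(r) {
    span <- diff(range(r$points$x))
    data.frame(factor = r$factor, coefficient = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               p_value = r$p_value, sign = sign(r$slope),
               per_unit_impact = r$slope,
               per_range_impact = r$slope * span,
               level_span = span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$per_range_impact), out$factor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppd_sensitivity", "data.frame")
  out
}

#' One-factor-at-a-time sensitivity analysis, end to end
#'
#' Builds the deduplicated design, runs the Monte Carlo simulator over it,
#' regresses effective dose on each factor's six levels (the shared
#' baseline run supplies the baseline level of every factor), and returns
#' the ranked report.
#'
#' @inheritParams run_design
#' @param sweeps A [factor_sweeps()] table.
#' @return List of class `ppd_sensitivity_run`: `design` (with doses),
#'   `fits` (per-factor `ppd_ols`), `report` (a `ppd_sensitivity`).
#' @export
sensitivity_analysis <- function(sweeps = factor_sweeps(),
                                 baseline = exposure_geometry(),
                                 n_histories = 2e4, seed = 1,
                                 phantom = NULL) {
  design <- build_design(sweeps, baseline)
  design <- run_design(design, baseline, n_histories, seed, phantom)
  base_E <- design$effective_dose[design$is_baseline]
  base_vals <- unlist(baseline[ppd_factor_names])
  fits <- lapply(sweeps$factor, function(f) {
    sub <- design[design$factor == f, , drop = FALSE]
    x <- sub$level
    y <- sub$effective_dose
    # levels that collapsed onto the shared baseline run re-enter here
    lv <- sweeps$levels[[which(sweeps$factor == f)]]
    collapsed <- lv[abs(lv - base_vals[[f]]) <= ppd_dedup_tol[[f]]]
    if (length(collapsed)) {
      x <- c(x, collapsed)
      y <- c(y, rep(base_E, length(collapsed)))
    }
    ord <- order(x)
    ols(x[ord], y[ord], factor_name = f)
  })
  names(fits) <- sweeps$factor
  structure(list(design = design, fits = fits,
                 report = sensitivity_report(fits)),
            class = "ppd_sensitivity_run")
}

#' @export
print.ppd_sensitivity_run <- function(x, ...) {
  cat("One-factor-at-a-time sensitivity analysis,",
      nrow(x$design), "simulations\n")
  rep <- x$report
  rep$coefficient <- signif(rep$coefficient, 4)
  rep$r_squared <- round(rep$r_squared, 4)
  rep$p_value <- signif(rep$p_value, 3)
  rep$per_range_impact <- signif(rep$per_range_impact, 4)
  print(as.data.frame(rep)[, c("factor", "coefficient", "r_squared",
                               "p_value", "per_range_impact")],
        row.names = FALSE)
  invisible(x)
}

#' Plot factor-response curves of a sensitivity run
#'
#' One panel per factor: the six (level, effective dose) points and the
#' fitted regression line.
#'
#' @param x A `ppd_sensitivity_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ppd_sensitivity_run <- function(x, ...) {
  fits <- x$fits
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(fits)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (f in names(fits)) {
    p <- fits[[f]]$points
    graphics::plot(p$x, p$y, xlab = f, ylab = "effective dose (uSv)",
                   main = f, pch = 19, ...)
    graphics::abline(fits[[f]]$intercept, fits[[f]]$slope, col = 2)
  }
  invisible(x)
}
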