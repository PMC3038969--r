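#' Pearson correlation and ordinary least-squares regression
#'
#' One comparison as used throughout the cohort analysis: OLS slope and
#' intercept of `y` on `x`, Pearson's r, and the two-sided p value from the
#' t transform of r with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite, `x`
#'   non-constant.
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `n`.
#' @export
pearson_and_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 paired observations are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) < 1e-15) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  if (stats::sd(y) < 1e-15) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 pearson_r = r, p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g  (r = %.3f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Inter-observer coefficient of variation
#'
#' `100 * SD(a - b) / mean(c(a, b))`: the sample standard deviation of the
#' paired differences between two measurement series divided by the grand
#' mean of all measurements, as a percentage.
#'
#' @param series_a,series_b Paired measurement series, equal length,
#'   `n >= 2`.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(series_a, series_b) {
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) stop("the two series must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  gm <- mean(c(a, b))
  if (abs(gm) < 1e-15) stop("grand mean is zero; CoV undefined")
  100 * stats::sd(a - b) / gm
}

#' Mean and SD of paired differences
#'
#' @param x,y Paired series, equal length, `n >= 2`.
#' @return List with `mean_diff` and `sd_diff` of `x - y`.
#' @export
paired_difference_summary <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  d <- x - y
  list(mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Per-group mean and SD
#'
#' @param values Numeric vector.
#' @param group Grouping labels, one per value.
#' @return Data frame with `group`, `n`, `mean`, `sd` (`sd` is `NA` for
#'   singleton groups).
#' @export
group_summary <- function(values, group) {
  values <- as.numeric(values)
  if (length(values) != length(group)) stop("one group label per value is required")
  if (anyNA(group)) stop("group labels must not be missing")
  g <- factor(group)
  out <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_)))
  rownames(out) <- NULL
  out
}

#' Age-group labels for cohort summaries
#'
#' @param age Ages in years.
#' @param split Split age (default 50): groups are `<= split` and
#'   `> split`.
#' @return Factor with levels `"<=50"`-style labels.
#' @export
age_groups <- function(age, split = 50) {
  factor(ifelse(age <= split, paste0("<=", split), paste0(">", split)),
         levels = c(paste0("<=", split), paste0(">", split)))
}

#' Bramwell-Hill consistency analysis of a cohort
#'
#' Reproduces the cohort-level statistical analysis: linear regressions of
#' the local distensibility indices (converted to Pa^-1) on
#' `1 / Arch_PWV^2`, of the local theoretical PWV indices on `Arch_PWV`, and
#' of `Arch_PWV` on the tonometric `CF_PWV`; the theoretical Bramwell-Hill
#' slope `1 / rho` (SI) with the measured-to-theoretical slope ratio;
#' inter-observer coefficients of variation for arch length, transit time
#' and `Arch_PWV` when second-operator measurements are present; and
#' age-group PWV summaries.
#'
#' @param cohort Data frame with one row per subject; recognized columns:
#'   `age`, `arch_pwv`, `aa_distc`, `aa_distb`, `aa_pwvc`, `aa_pwvb`,
#'   `cf_pwv`, and optionally `arch_length`, `transit_time`,
#'   `arch_length_op2`, `transit_time_op2`, `arch_pwv_op2`. Comparisons with
#'   missing inputs are skipped.
#' @param rho Blood density, kg m^-3.
#' @param age_split Age split for the group summaries, years.
#' @return An object of class `consistency_report`: `regressions` (named
#'   list of [pearson_and_regression()] results), `theoretical_slope`
#'   (Pa^-1 per (m/s)^-2), `slope_ratio`, `cov` (named numeric, percent),
#'   `group_summaries` (named list of data frames), `n`.
#' @export
bramwell_hill_consistency <- function(cohort, rho = DEFAULT_BLOOD_DENSITY,
                                      age_split = 50) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) < 3L) stop("a cohort analysis needs at least 3 subjects")
  if (is.null(cohort$arch_pwv)) stop("cohort must contain an arch_pwv column")
  ok_col <- function(nm) !is.null(cohort[[nm]]) && sum(is.finite(cohort[[nm]])) >= 3L

  inv_pwv2 <- 1 / cohort$arch_pwv^2
  regressions <- list()
  run <- function(nm, x, y) {
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) >= 3L) regressions[[nm]] <<- pearson_and_regression(x[keep], y[keep])
    else message("comparison '", nm, "' skipped: fewer than 3 complete pairs")
  }
  if (ok_col("aa_distc"))
    run("aa_distc_vs_inv_arch_pwv2", inv_pwv2, cohort$aa_distc / MMHG_TO_PA)
  if (ok_col("aa_distb"))
    run("aa_distb_vs_inv_arch_pwv2", inv_pwv2, cohort$aa_distb / MMHG_TO_PA)
  if (ok_col("aa_pwvc"))
    run("aa_pwvc_vs_arch_pwv", cohort$arch_pwv, cohort$aa_pwvc)
  if (ok_col("aa_pwvb"))
    run("aa_pwvb_vs_arch_pwv", cohort$arch_pwv, cohort$aa_pwvb)
  if (ok_col("cf_pwv"))
    run("arch_pwv_vs_cf_pwv", cohort$cf_pwv, cohort$arch_pwv)

  theoretical_slope <- 1 / rho
  slope_ratio <- if (!is.null(regressions$aa_distc_vs_inv_arch_pwv2))
    regressions$aa_distc_vs_inv_arch_pwv2$slope / theoretical_slope
  else NA_real_

  cov <- c()
  if (ok_col("arch_length") && ok_col("arch_length_op2"))
    cov["arch_length"] <- coefficient_of_variation(cohort$arch_length,
                                                   cohort$arch_length_op2)
  if (ok_col("transit_time") && ok_col("transit_time_op2"))
    cov["transit_time"] <- coefficient_of_variation(cohort$transit_time,
                                                    cohort$transit_time_op2)
  if (ok_col("arch_pwv") && ok_col("arch_pwv_op2"))
    cov["arch_pwv"] <- coefficient_of_variation(cohort$arch_pwv,
                                                cohort$arch_pwv_op2)

  group_summaries <- list()
  if (!is.null(cohort$age)) {
    grp <- age_groups(cohort$age, age_split)
    for (nm in intersect(c("arch_pwv", "aa_pwvc", "aa_pwvb"), names(cohort)))
      group_summaries[[nm]] <- group_summary(cohort[[nm]], grp)
  }

  structure(list(regressions = regressions,
                 theoretical_slope = theoretical_slope,
                 slope_ratio = slope_ratio,
                 cov = cov,
                 group_summaries = group_summaries,
                 n = nrow(cohort)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Bramwell-Hill consistency report (n = %d)\n", x$n))
  cat(sprintf("  theoretical slope 1/rho = %.3g Pa^-1 (m/s)^2\n",
              x$theoretical_slope))
  if (is.finite(x$slope_ratio))
    cat(sprintf("  measured/theoretical distensibility slope ratio = %.3f\n",
                x$slope_ratio))
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    cat(sprintf("  %-28s r = %.3f (p = %.2g), slope = %.4g, n = %d\n",
                nm, r$pearson_r, r$p_value, r$slope, r$n))
  }
  if (length(x$cov))
    cat("  CoV (%):", paste(sprintf("%s %.2f", names(x$cov), x$cov),
                            collapse = ", "), "\n")
  invisible(x)
}
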