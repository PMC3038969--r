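#' Pipeline configuration
#'
#' Tunables of the end-to-end analysis, with the package defaults.
#'
#' @param blood_density Blood density for the Bramwell-Hill transforms,
#'   kg m^-3.
#' @param onset_fraction Flow-onset threshold on the normalized velocity.
#' @param transit_search_max Largest transit-time shift searched, ms.
#' @param quadrature_tol Arc-length quadrature tolerance, mm.
#' @param clip_tol Plane-clipping distance tolerance, mm.
#' @param age_split Age split for group summaries, years.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(blood_density = DEFAULT_BLOOD_DENSITY,
                            onset_fraction = 0.05,
                            transit_search_max = 100L,
                            quadrature_tol = 1e-3,
                            clip_tol = 1e-6,
                            age_split = 50) {
  if (quadrature_tol <= 0 || clip_tol <= 0) stop("tolerances must be positive")
  if (transit_search_max < 1L) stop("transit_search_max must be >= 1 ms")
  structure(list(blood_density = blood_density,
                 onset_fraction = onset_fraction,
                 transit_search_max = as.integer(transit_search_max),
                 quadrature_tol = quadrature_tol,
                 clip_tol = clip_tol,
                 age_split = age_split),
            class = "pipeline_config")
}

# ---- readers / writers ------------------------------------------------------

read_table_checked <- function(path, required, label, optional = character()) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(label, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra))
    warning(label, " file ", path, " has unknown column(s) (ignored): ",
            paste(extra, collapse = ", "))
  df
}

check_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !(is.na(df[[col]]) | df[[col]] == ""))
  if (length(bad))
    stop("non-numeric value(s) in column '", col, "' of ", path,
         " at data row(s): ", paste(bad, collapse = ", "))
  v
}

read_meta_rr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 5L)
  m <- regmatches(lines, regexpr("rr_interval_ms\\s*=\\s*[0-9.]+", lines))
  m <- unlist(m)
  if (!length(m))
    stop("no '# rr_interval_ms=<value>' metadata line found in ", path)
  as.numeric(sub(".*=\\s*", "", m[1L]))
}

#' Read a velocity waveform CSV
#'
#' Expected format: a metadata comment line `# rr_interval_ms=<value>`
#' followed by a header `time_ms,velocity_cm_s`. Unknown extra columns are
#' accepted with a warning; non-increasing times, missing columns and
#' non-numeric cells are rejected.
#'
#' @param path CSV file path.
#' @return A [velocity_waveform()].
#' @export
read_waveform_csv <- function(path) {
  rr <- read_meta_rr(path)
  df <- read_table_checked(path, c("time_ms", "velocity_cm_s"), "waveform")
  times <- check_numeric_col(df, "time_ms", path)
  vel <- check_numeric_col(df, "velocity_cm_s", path)
  if (any(diff(times) <= 0))
    stop("times in ", path, " must be strictly increasing (rows shuffled?)")
  velocity_waveform(times, vel, rr)
}

#' Write a velocity waveform CSV
#'
#' @param w A [velocity_waveform()].
#' @param path Output path.
#' @export
write_waveform_csv <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rr_interval_ms=%.10g", w$rr_interval), con)
  utils::write.csv(data.frame(time_ms = w$times, velocity_cm_s = w$velocities),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a lumen-area curve CSV
#'
#' Format: `# rr_interval_ms=<value>` metadata line, header
#' `time_ms,area_mm2`.
#'
#' @param path CSV file path.
#' @return An [area_curve()].
#' @export
read_area_csv <- function(path) {
  rr <- read_meta_rr(path)
  df <- read_table_checked(path, c("time_ms", "area_mm2"), "area")
  times <- check_numeric_col(df, "time_ms", path)
  areas <- check_numeric_col(df, "area_mm2", path)
  if (any(diff(times) <= 0))
    stop("times in ", path, " must be strictly increasing")
  area_curve(times, areas, rr)
}

#' Write a lumen-area curve CSV
#' @param a An [area_curve()].
#' @param path Output path.
#' @export
write_area_csv <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rr_interval_ms=%.10g", a$rr_interval), con)
  utils::write.csv(data.frame(time_ms = a$times, area_mm2 = a$areas),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read centerline markers CSV
#'
#' Header `x_mm,y_mm,z_mm,segment`, with segment labels `ascending`,
#' `arch_top`, `descending` in curve order.
#'
#' @param path CSV file path.
#' @return A [centerline_markers()].
#' @export
read_markers_csv <- function(path) {
  df <- read_table_checked(path, c("x_mm", "y_mm", "z_mm", "segment"),
                           "markers")
  pts <- cbind(check_numeric_col(df, "x_mm", path),
               check_numeric_col(df, "y_mm", path),
               check_numeric_col(df, "z_mm", path))
  centerline_markers(pts, df$segment)
}

#' Write centerline markers CSV
#' @param m A [centerline_markers()].
#' @param path Output path.
#' @export
write_markers_csv <- function(m, path) {
  utils::write.csv(data.frame(x_mm = m$points[, 1L], y_mm = m$points[, 2L],
                              z_mm = m$points[, 3L], segment = m$segment),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a slice plane CSV
#'
#' Single-row CSV with columns `origin_x_mm,origin_y_mm,origin_z_mm,
#' normal_x,normal_y,normal_z`.
#'
#' @param path CSV file path.
#' @return A [slice_plane()].
#' @export
read_plane_csv <- function(path) {
  cols <- c("origin_x_mm", "origin_y_mm", "origin_z_mm",
            "normal_x", "normal_y", "normal_z")
  df <- read_table_checked(path, cols, "plane")
  if (nrow(df) != 1L) stop("plane file ", path, " must contain exactly one row")
  slice_plane(as.numeric(df[1L, cols[1:3]]), as.numeric(df[1L, cols[4:6]]))
}

#' Write a slice plane CSV
#' @param p A [slice_plane()].
#' @param path Output path.
#' @export
write_plane_csv <- function(p, path) {
  utils::write.csv(data.frame(origin_x_mm = p$origin[1L],
                              origin_y_mm = p$origin[2L],
                              origin_z_mm = p$origin[3L],
                              normal_x = p$normal[1L],
                              normal_y = p$normal[2L],
                              normal_z = p$normal[3L]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pressures CSV
#'
#' Single-row CSV with columns `brachial_systolic_mmHg`,
#' `brachial_diastolic_mmHg`, and optionally `brachial_mean_mmHg`,
#' `carotid_pp_mmHg`, `cf_pwv_m_s`, `age_years`. A sibling
#' `carotid_waveform.csv` (header `time_ms,pressure_au`), if given, supplies
#' the raw tonometric waveform.
#'
#' @param path CSV file path.
#' @param carotid_waveform_path Optional raw carotid waveform CSV.
#' @return List with a [pressure_record()] plus `cf_pwv` and `age`
#'   (`NA` when absent).
#' @export
read_pressures_csv <- function(path, carotid_waveform_path = NULL) {
  df <- read_table_checked(path,
                           c("brachial_systolic_mmHg", "brachial_diastolic_mmHg"),
                           "pressures",
                           optional = c("brachial_mean_mmHg", "carotid_pp_mmHg",
                                        "cf_pwv_m_s", "age_years"))
  if (nrow(df) != 1L) stop("pressures file ", path, " must contain exactly one row")
  getnum <- function(nm) {
    if (is.null(df[[nm]]) || is.na(df[[nm]]) || df[[nm]] == "") NULL
    else as.numeric(df[[nm]])
  }
  raw <- NULL
  if (!is.null(carotid_waveform_path) && file.exists(carotid_waveform_path)) {
    wdf <- read_table_checked(carotid_waveform_path,
                              c("time_ms", "pressure_au"), "carotid waveform")
    raw <- check_numeric_col(wdf, "pressure_au", carotid_waveform_path)
  }
  pr <- pressure_record(as.numeric(df$brachial_systolic_mmHg),
                        as.numeric(df$brachial_diastolic_mmHg),
                        brachial_mean = getnum("brachial_mean_mmHg"),
                        carotid_raw = raw,
                        carotid_pp = getnum("carotid_pp_mmHg"))
  list(pressures = pr,
       cf_pwv = if (is.null(getnum("cf_pwv_m_s"))) NA_real_ else getnum("cf_pwv_m_s"),
       age = if (is.null(getnum("age_years"))) NA_real_ else getnum("age_years"))
}

# ---- per-subject analysis ---------------------------------------------------

#' Compute all stiffness indices for one subject
#'
#' Orchestrates the full per-subject pipeline: transit time from the
#' waveform pair, centerline fit + plane clipping + arc length from the
#' markers, strain from the area curve, carotid/brachial distensibility and
#' Bramwell-Hill theoretical PWV, and the regional arch PWV. Carotid-based
#' indices are `NA` when no carotid pressure input is available.
#'
#' @param ascending,descending [velocity_waveform()] pair.
#' @param area An [area_curve()].
#' @param markers A [centerline_markers()] object.
#' @param plane A [slice_plane()].
#' @param pressures A [pressure_record()].
#' @param cf_pwv Optional external carotid-femoral PWV, m/s.
#' @param age Optional age, years.
#' @param config A [pipeline_config()].
#' @return A list of indices and audit intermediates: `transit_time_ms`,
#'   `boundary_flag`, `error_profile`, `u_asc`, `u_desc`, `arch_length_mm`,
#'   `strain`, `Ss`, `Sd`, `carotid_pp`, `brachial_pp`, `aa_distc`,
#'   `aa_distb` (mmHg^-1), `aa_pwvc`, `aa_pwvb`, `arch_pwv` (m/s),
#'   `cf_pwv`, `age`.
#' @export
analyze_subject <- function(ascending, descending, area, markers, plane,
                            pressures, cf_pwv = NA_real_, age = NA_real_,
                            config = pipeline_config()) {
  tt <- estimate_transit_time(ascending, descending,
                              onset_fraction = config$onset_fraction,
                              k_max = config$transit_search_max)
  curve <- fit_centerline(markers)
  uu <- clip_to_plane(curve, plane, tol = config$clip_tol)
  len <- arc_length(curve, uu[["u_asc"]], uu[["u_desc"]],
                    tol = config$quadrature_tol)
  st <- compute_strain(area)
  bpp <- pressures$brachial_pp
  cpp <- pressures$carotid_pp
  aa_distb <- compute_distensibility(st$strain, bpp)
  aa_pwvb <- if (st$strain > 0)
    pwv_from_distensibility(aa_distb, config$blood_density) else NA_real_
  if (is.finite(cpp)) {
    aa_distc <- compute_distensibility(st$strain, cpp)
    aa_pwvc <- if (st$strain > 0)
      pwv_from_distensibility(aa_distc, config$blood_density) else NA_real_
  } else {
    aa_distc <- NA_real_; aa_pwvc <- NA_real_
  }
  arch_pwv <- compute_arch_pwv(len, tt$delta_t, tt$boundary_flag)
  list(transit_time_ms = tt$delta_t,
       boundary_flag = tt$boundary_flag,
       error_profile = tt$error_profile,
       u_asc = uu[["u_asc"]], u_desc = uu[["u_desc"]],
       arch_length_mm = len,
       strain = st$strain, Ss = st$Ss, Sd = st$Sd,
       carotid_pp = cpp, brachial_pp = bpp,
       aa_distc = aa_distc, aa_distb = aa_distb,
       aa_pwvc = aa_pwvc, aa_pwvb = aa_pwvb,
       arch_pwv = arch_pwv,
       cf_pwv = cf_pwv, age = age)
}

#' Analyze every subject of a synthetic cohort in memory
#'
#' Runs [analyze_subject()] on each generated subject, including the
#' second-operator marker picks and waveform replicate, and returns the
#' cohort table expected by [bramwell_hill_consistency()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [pipeline_config()].
#' @return Data frame, one row per subject.
#' @export
analyze_synthetic_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    res <- analyze_subject(s$ascending, s$descending, s$area, s$markers,
                           s$plane, s$pressures, s$cf_pwv, s$age, config)
    curve2 <- fit_centerline(s$markers_op2)
    uu2 <- clip_to_plane(curve2, s$plane, tol = config$clip_tol)
    len2 <- arc_length(curve2, uu2[["u_asc"]], uu2[["u_desc"]],
                       tol = config$quadrature_tol)
    tt2 <- estimate_transit_time(s$ascending_op2, s$descending_op2,
                                 onset_fraction = config$onset_fraction,
                                 k_max = config$transit_search_max)
    data.frame(subject_id = s$subject_id, age = s$age,
               transit_time = res$transit_time_ms,
               arch_length = res$arch_length_mm,
               strain = res$strain,
               carotid_pp = res$carotid_pp, brachial_pp = res$brachial_pp,
               aa_distc = res$aa_distc, aa_distb = res$aa_distb,
               aa_pwvc = res$aa_pwvc, aa_pwvb = res$aa_pwvb,
               arch_pwv = res$arch_pwv, cf_pwv = res$cf_pwv,
               transit_time_op2 = tt2$delta_t,
               arch_length_op2 = len2,
               arch_pwv_op2 = compute_arch_pwv(len2, tt2$delta_t,
                                               tt2$boundary_flag))
  })
  do.call(rbind, rows)
}

# ---- on-disk cohort layout --------------------------------------------------

subject_files <- c(ascending = "asc_velocity.csv",
                   descending = "desc_velocity.csv",
                   area = "area.csv",
                   markers = "markers.csv",
                   plane = "plane.csv",
                   pressures = "pressures.csv")

#' Write a synthetic cohort to a directory of per-subject CSV files
#'
#' One sub-directory per subject with `asc_velocity.csv`,
#' `desc_velocity.csv` (plus `_op2` replicates), `area.csv`, `markers.csv`,
#' `markers_op2.csv`, `plane.csv`, `pressures.csv` and
#' `carotid_waveform.csv`; a cohort-level `truth.csv` and the generator
#' parameters echoed to `config.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_waveform_csv(s$ascending, file.path(sd, "asc_velocity.csv"))
    write_waveform_csv(s$descending, file.path(sd, "desc_velocity.csv"))
    write_waveform_csv(s$ascending_op2, file.path(sd, "asc_velocity_op2.csv"))
    write_waveform_csv(s$descending_op2, file.path(sd, "desc_velocity_op2.csv"))
    write_area_csv(s$area, file.path(sd, "area.csv"))
    write_markers_csv(s$markers, file.path(sd, "markers.csv"))
    write_markers_csv(s$markers_op2, file.path(sd, "markers_op2.csv"))
    write_plane_csv(s$plane, file.path(sd, "plane.csv"))
    utils::write.csv(data.frame(
      brachial_systolic_mmHg = s$pressures$brachial_systolic,
      brachial_diastolic_mmHg = s$pressures$brachial_diastolic,
      brachial_mean_mmHg = s$pressures$brachial_mean,
      cf_pwv_m_s = s$cf_pwv,
      age_years = s$age), file.path(sd, "pressures.csv"),
      row.names = FALSE, quote = FALSE)
    nw <- length(s$pressures$carotid_raw)
    utils::write.csv(data.frame(
      time_ms = seq(0, cohort$params$rr_interval,
                    length.out = nw + 1L)[seq_len(nw)],
      pressure_au = s$pressures$carotid_raw),
      file.path(sd, "carotid_waveform.csv"), row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cohort$params), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the per-subject pipeline on a subject directory
#'
#' Reads the subject's CSV inputs (see [write_cohort()] for the layout),
#' computes all indices and optionally writes an audit JSON report with
#' every intermediate.
#'
#' @param subject_dir Directory holding the subject's CSV files.
#' @param config A [pipeline_config()].
#' @param report_path Optional path for the JSON report.
#' @return The [analyze_subject()] result (with `subject_id` added).
#' @export
run_subject <- function(subject_dir, config = pipeline_config(),
                        report_path = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for ", subject_dir, ": ",
           conditionMessage(e), call. = FALSE))
  }
  asc <- stage("read ascending waveform",
               read_waveform_csv(file.path(subject_dir, subject_files[["ascending"]])))
  desc <- stage("read descending waveform",
                read_waveform_csv(file.path(subject_dir, subject_files[["descending"]])))
  area <- stage("read area curve",
                read_area_csv(file.path(subject_dir, subject_files[["area"]])))
  markers <- stage("read markers",
                   read_markers_csv(file.path(subject_dir, subject_files[["markers"]])))
  plane <- stage("read plane",
                 read_plane_csv(file.path(subject_dir, subject_files[["plane"]])))
  pres <- stage("read pressures",
                read_pressures_csv(file.path(subject_dir, subject_files[["pressures"]]),
                                   file.path(subject_dir, "carotid_waveform.csv")))
  res <- stage("analysis",
               analyze_subject(asc, desc, area, markers, plane,
                               pres$pressures, pres$cf_pwv, pres$age, config))
  res$subject_id <- basename(subject_dir)
  # second-operator measurements when the replicate files are present
  m2 <- file.path(subject_dir, "markers_op2.csv")
  a2 <- file.path(subject_dir, "asc_velocity_op2.csv")
  d2 <- file.path(subject_dir, "desc_velocity_op2.csv")
  if (file.exists(m2)) {
    curve2 <- fit_centerline(read_markers_csv(m2))
    uu2 <- clip_to_plane(curve2, plane, tol = config$clip_tol)
    res$arch_length_op2 <- arc_length(curve2, uu2[["u_asc"]], uu2[["u_desc"]],
                                      tol = config$quadrature_tol)
  }
  if (file.exists(a2) && file.exists(d2)) {
    tt2 <- estimate_transit_time(read_waveform_csv(a2), read_waveform_csv(d2),
                                 onset_fraction = config$onset_fraction,
                                 k_max = config$transit_search_max)
    res$transit_time_op2 <- tt2$delta_t
    if (!is.null(res$arch_length_op2))
      res$arch_pwv_op2 <- compute_arch_pwv(res$arch_length_op2, tt2$delta_t,
                                           tt2$boundary_flag)
  }
  if (!is.null(report_path))
    jsonlite::write_json(res, report_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  res
}

#' Run the cohort pipeline on a directory of subjects
#'
#' Each sub-directory containing an `asc_velocity.csv` is treated as one
#' subject. Subjects whose analysis fails are skipped with a warning (the
#' cohort size is decremented); at least 3 complete subjects are required.
#' Writes `cohort.csv` (one row per subject) and `consistency_report.json`
#' to `out_dir` when given, plus scatter plots of the four Bramwell-Hill
#' regression comparisons when `make_plots` is `TRUE`.
#'
#' @param dir Cohort directory.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param make_plots Write regression scatter plots (PNG) to `out_dir`.
#' @return List with `cohort` (data frame) and `report`
#'   ([bramwell_hill_consistency()] result).
#' @export
run_cohort <- function(dir, config = pipeline_config(), out_dir = NULL,
                       make_plots = FALSE) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  subdirs <- list.dirs(dir, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, subject_files[["ascending"]]))]
  if (!length(subdirs)) stop("no subject directories found in ", dir)
  rows <- list()
  for (sd in subdirs) {
    rec <- tryCatch(run_subject(sd, config), error = function(e) {
      warning("subject ", basename(sd), " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = rec$subject_id, age = rec$age,
      transit_time = rec$transit_time_ms, arch_length = rec$arch_length_mm,
      strain = rec$strain, carotid_pp = rec$carotid_pp,
      brachial_pp = rec$brachial_pp,
      aa_distc = rec$aa_distc, aa_distb = rec$aa_distb,
      aa_pwvc = rec$aa_pwvc, aa_pwvb = rec$aa_pwvb,
      arch_pwv = rec$arch_pwv, cf_pwv = rec$cf_pwv,
      arch_length_op2 = if (is.null(rec$arch_length_op2)) NA_real_ else rec$arch_length_op2,
      transit_time_op2 = if (is.null(rec$transit_time_op2)) NA_real_ else rec$transit_time_op2,
      arch_pwv_op2 = if (is.null(rec$arch_pwv_op2)) NA_real_ else rec$arch_pwv_op2)
  }
  if (length(rows) < 3L)
    stop("fewer than 3 subjects analyzed successfully (", length(rows), ")")
  cohort <- do.call(rbind, rows)
  report <- bramwell_hill_consistency(cohort, rho = config$blood_density,
                                      age_split = config$age_split)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(regressions = lapply(report$regressions, unclass),
           theoretical_slope = report$theoretical_slope,
           slope_ratio = report$slope_ratio,
           cov = as.list(report$cov),
           group_summaries = report$group_summaries,
           n = report$n),
      file.path(out_dir, "consistency_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    if (make_plots) plot_consistency(cohort, report, out_dir)
  }
  list(cohort = cohort, report = report)
}

# Scatter plots of the regression comparisons (base graphics, one PNG each).
plot_consistency <- function(cohort, report, out_dir) {
  specs <- list(
    c("aa_distc_vs_inv_arch_pwv2", "1/Arch_PWV^2 (s^2/m^2)", "AA_Distc (Pa^-1)"),
    c("aa_distb_vs_inv_arch_pwv2", "1/Arch_PWV^2 (s^2/m^2)", "AA_Distb (Pa^-1)"),
    c("aa_pwvc_vs_arch_pwv", "Arch_PWV (m/s)", "AA_PWVc (m/s)"),
    c("aa_pwvb_vs_arch_pwv", "Arch_PWV (m/s)", "AA_PWVb (m/s)"),
    c("arch_pwv_vs_cf_pwv", "CF_PWV (m/s)", "Arch_PWV (m/s)"))
  xy <- list(
    aa_distc_vs_inv_arch_pwv2 = cbind(1 / cohort$arch_pwv^2,
                                      cohort$aa_distc / MMHG_TO_PA),
    aa_distb_vs_inv_arch_pwv2 = cbind(1 / cohort$arch_pwv^2,
                                      cohort$aa_distb / MMHG_TO_PA),
    aa_pwvc_vs_arch_pwv = cbind(cohort$arch_pwv, cohort$aa_pwvc),
    aa_pwvb_vs_arch_pwv = cbind(cohort$arch_pwv, cohort$aa_pwvb),
    arch_pwv_vs_cf_pwv = cbind(cohort$cf_pwv, cohort$arch_pwv))
  for (sp in specs) {
    nm <- sp[1L]
    reg <- report$regressions[[nm]]
    if (is.null(reg)) next
    grDevices::png(file.path(out_dir, paste0(nm, ".png")), 600, 600)
    graphics::plot(xy[[nm]][, 1L], xy[[nm]][, 2L], pch = 19,
                   xlab = sp[2L], ylab = sp[3L],
                   main = sprintf("%s (r = %.2f)", nm, reg$pearson_r))
    graphics::abline(reg$intercept, reg$slope, col = "red")
    grDevices::dev.off()
  }
  invisible(NULL)
}
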