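zero_noise_dir <- local({
  dir <- file.path(tempdir(), "aortastiff-zero-noise")
  if (!dir.exists(dir)) {
    co <- generate_cohort(noise_free(synth_params(n_subjects = 5, seed = 21)))
    write_cohort(co, dir)
  }
  dir
})

test_that("waveform CSVs round-trip bit-identically", {
  pr <- test_pair(20)
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(pr$asc, path)
  back <- read_waveform_csv(path)
  expect_identical(back$times, pr$asc$times)
  expect_identical(back$rr_interval, pr$asc$rr_interval)
  expect_equal(back$velocities, pr$asc$velocities, tolerance = 1e-12)
  # a second write of the re-read object is content-identical
  path2 <- tempfile(fileext = ".csv")
  write_waveform_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("waveform reader validates structure and tolerates unknown columns", {
  pr <- test_pair(20)
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(pr$asc, path)
  lines <- readLines(path)
  # shuffled rows -> non-increasing times -> rejected
  shuffled <- c(lines[1:2], rev(lines[-(1:2)]))
  path_s <- tempfile(fileext = ".csv"); writeLines(shuffled, path_s)
  expect_error(read_waveform_csv(path_s), "increasing")
  # missing metadata line
  path_m <- tempfile(fileext = ".csv"); writeLines(lines[-1], path_m)
  expect_error(read_waveform_csv(path_m), "rr_interval_ms")
  # extra unknown column -> warning, still read
  df <- utils::read.csv(path, comment.char = "#")
  df$note <- "x"
  path_e <- tempfile(fileext = ".csv")
  writeLines(lines[1], path_e)
  suppressWarnings(utils::write.table(df, path_e, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  expect_warning(w <- read_waveform_csv(path_e), "unknown column")
  expect_equal(w$velocities, pr$asc$velocities, tolerance = 1e-12)
  # non-numeric cell -> rejected with the row number
  bad <- lines; bad[5] <- sub(",", ",abc", bad[5])
  path_b <- tempfile(fileext = ".csv"); writeLines(bad, path_b)
  expect_error(read_waveform_csv(path_b), "non-numeric.*row")
  # missing column -> named in the error
  nov <- sub("velocity_cm_s", "vel", lines)
  path_n <- tempfile(fileext = ".csv"); writeLines(nov, path_n)
  expect_error(read_waveform_csv(path_n), "velocity_cm_s")
})

test_that("marker CSVs validate segment labels and ordering", {
  g <- generate_arch_markers(25, 50, params = noise_free(synth_params()))
  path <- tempfile(fileext = ".csv")
  write_markers_csv(g$markers, path)
  back <- read_markers_csv(path)
  expect_equal(back$points, g$markers$points, tolerance = 1e-12)
  expect_identical(back$segment, g$markers$segment)
  df <- utils::read.csv(path)
  df$segment[df$segment == "arch_top"] <- "descending"
  path_o <- tempfile(fileext = ".csv")
  utils::write.csv(df, path_o, row.names = FALSE, quote = FALSE)
  expect_error(read_markers_csv(path_o), "ascending -> arch_top")
  df2 <- utils::read.csv(path)[1:3, ]
  path_3 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, path_3, row.names = FALSE, quote = FALSE)
  expect_error(read_markers_csv(path_3), "4 markers")
  df3 <- utils::read.csv(path)
  df3$segment[2] <- "arch"
  path_u <- tempfile(fileext = ".csv")
  utils::write.csv(df3, path_u, row.names = FALSE, quote = FALSE)
  expect_error(read_markers_csv(path_u), "segment labels")
})

test_that("area, plane and pressure files round-trip", {
  a <- generate_area_curve(430, 0.22, 900, noise_free(synth_params()))
  pa <- tempfile(fileext = ".csv")
  write_area_csv(a, pa)
  expect_equal(read_area_csv(pa)$areas, a$areas, tolerance = 1e-12)
  p <- slice_plane(c(1, 2, 3), c(0, 1 / sqrt(2), 1 / sqrt(2)))
  pp <- tempfile(fileext = ".csv")
  write_plane_csv(p, pp)
  back <- read_plane_csv(pp)
  expect_equal(back$origin, p$origin)
  expect_equal(back$normal, p$normal, tolerance = 1e-12)
})

test_that("a zero-noise subject analyzed from disk matches the ground truth", {
  truth <- utils::read.csv(file.path(zero_noise_dir, "truth.csv"))
  rec <- run_subject(file.path(zero_noise_dir, "subj_001"))
  tr <- truth[truth$subject_id == "subj_001", ]
  expect_lte(abs(rec$transit_time_ms - tr$true_transit_time_ms), 1)
  expect_equal(rec$arch_length_mm, tr$true_arch_length_mm, tolerance = 5e-3)
  expect_equal(rec$strain, tr$true_strain, tolerance = 1e-6)
  expect_equal(rec$aa_distc, tr$true_distensibility, tolerance = 1e-5)
  # arch PWV agrees with the true PWV up to the 1 ms transit quantization
  expect_equal(rec$arch_pwv, tr$true_pwv,
               tolerance = 1.5 / tr$true_transit_time_ms + 5e-3)
  # second-operator replicates are picked up
  expect_false(is.null(rec$arch_length_op2))
  expect_false(is.null(rec$transit_time_op2))
})

test_that("subject reports are deterministic and audit-complete", {
  r1 <- tempfile(fileext = ".json"); r2 <- tempfile(fileext = ".json")
  run_subject(file.path(zero_noise_dir, "subj_002"), report_path = r1)
  run_subject(file.path(zero_noise_dir, "subj_002"), report_path = r2)
  expect_identical(readLines(r1), readLines(r2))
  rep <- jsonlite::read_json(r1)
  for (field in c("transit_time_ms", "error_profile", "u_asc", "u_desc",
                  "arch_length_mm", "Ss", "Sd", "carotid_pp", "arch_pwv"))
    expect_false(is.null(rep[[field]]))
  expect_length(rep$error_profile, 101L)
})

test_that("missing carotid inputs degrade to brachial-only indices", {
  src <- file.path(zero_noise_dir, "subj_003")
  dst <- file.path(tempdir(), "subj-nocarotid")
  unlink(dst, recursive = TRUE); dir.create(dst)
  file.copy(list.files(src, full.names = TRUE), dst)
  file.remove(file.path(dst, "carotid_waveform.csv"))
  rec <- run_subject(dst)
  expect_true(is.na(rec$aa_distc))
  expect_true(is.na(rec$aa_pwvc))
  expect_false(is.na(rec$aa_distb))
  expect_false(is.na(rec$aa_pwvb))
})

test_that("stage failures carry the stage name", {
  dst <- file.path(tempdir(), "subj-broken")
  unlink(dst, recursive = TRUE); dir.create(dst)
  file.copy(list.files(file.path(zero_noise_dir, "subj_004"), full.names = TRUE), dst)
  file.remove(file.path(dst, "area.csv"))
  expect_error(run_subject(dst), "read area curve")
})

test_that("the cohort runner aggregates subjects and skips corrupt ones", {
  out <- file.path(tempdir(), "cohort-out")
  res <- run_cohort(zero_noise_dir, out_dir = out)
  expect_equal(nrow(res$cohort), 5L)
  expect_s3_class(res$report, "consistency_report")
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "consistency_report.json")))
  # corrupt one subject: it is skipped with a warning, n decremented
  broken <- file.path(tempdir(), "cohort-broken")
  unlink(broken, recursive = TRUE)
  dir.create(broken)
  file.copy(list.files(zero_noise_dir, full.names = TRUE), broken,
            recursive = TRUE)
  file.remove(file.path(broken, "subj_005", "markers.csv"))
  expect_warning(res2 <- run_cohort(broken), "skipped")
  expect_equal(nrow(res2$cohort), 4L)
  # an empty directory is an error
  empty <- file.path(tempdir(), "cohort-empty")
  unlink(empty, recursive = TRUE); dir.create(empty)
  expect_error(run_cohort(empty), "no subject directories")
})

test_that("cohort plots are written on request", {
  out <- file.path(tempdir(), "cohort-plots")
  unlink(out, recursive = TRUE)
  run_cohort(zero_noise_dir, out_dir = out, make_plots = TRUE)
  expect_true(file.exists(file.path(out, "aa_distc_vs_inv_arch_pwv2.png")))
  expect_true(file.exists(file.path(out, "arch_pwv_vs_cf_pwv.png")))
})
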