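# Trial data model, trial-table dialect, C3D ingest, marker validation.

test_that("trial_recording enforces its invariants", {
  expect_s3_class(make_trial(MP_R = c(0, 200, 0), TROCHANTER_R = c(0, 0, 0)),
                  "trial_recording")
  expect_error(make_trial(BOGUS = c(0, 0, 0)), class = "reachcomp_marker_error")
  expect_error(
    trial_recording(list(MP_R = matrix(0, 3, 3), C7 = matrix(0, 5, 3)),
                    60, "forward_reach", "right"),
    class = "reachcomp_format_error")
  expect_error(
    trial_recording(list(MP_R = matrix(0, 1, 3)), 60, "forward_reach", "right"),
    class = "reachcomp_format_error")
  expect_error(
    trial_recording(list(MP_R = matrix(0, 3, 3)), 0, "forward_reach", "right"),
    class = "reachcomp_format_error")
})

test_that("marker vocabulary has 10 names in L/R pairs", {
  nm <- marker_names()
  expect_length(nm, 10)
  sided <- grep("_[LR]$", nm, value = TRUE)
  expect_length(sided, 8)
  lefts <- sub("_L$", "", grep("_L$", sided, value = TRUE))
  rights <- sub("_R$", "", grep("_R$", sided, value = TRUE))
  expect_setequal(lefts, rights)
})

test_that("trial table read-back reproduces a hand-written file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#task=forward_reach", "#side=right", "#sampling_rate=60",
    "time\tMP_R_x\tMP_R_y\tMP_R_z",
    "0\t0\t200\t0",
    sprintf("%.10f\t0\t250\t0", 1 / 60),
    sprintf("%.10f\t0\t300\t0", 2 / 60)), f)
  tr <- read_trial_table(f)
  expect_equal(unname(tr$positions$MP_R[, "Y"]), c(200, 250, 300))
  expect_equal(tr$task, "forward_reach")
  expect_equal(tr$sampling_rate, 60)
})

test_that("write/read round-trip is lossless, nan-preserving and deterministic", {
  set.seed(42)
  mp <- matrix(rnorm(30, 200, 50), 10, 3)
  mp[4, 2] <- NaN
  tr <- make_trial(MP_R = mp, C7 = c(0, 1 / 3, 450), TROCHANTER_R = c(0, 0, 0),
                   n = 10, uel = 717)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tr, f1)
  back <- read_trial_table(f1, max_gap_s = 0)   # keep the NaN intact
  for (mk in names(tr$positions)) {
    expect_equal(back$positions[[mk]], tr$positions[[mk]], tolerance = 1e-9)
  }
  expect_true(is.nan(back$positions$MP_R[4, 2]))
  expect_equal(back$upper_extremity_length, 717)
  write_trial_table(tr, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("trial table error paths name the offender", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#side=right", "#sampling_rate=60",
               "time\tMP_R_x\tMP_R_y\tMP_R_z", "0\t0\t0\t0", "0.0166667\t0\t0\t0"), f)
  expect_error(read_trial_table(f), "task", class = "reachcomp_format_error")

  writeLines(c("#task=forward_reach", "#side=right", "#sampling_rate=60",
               "time\tMP_R_x\tMP_R_y\tMP_R_z", "0\t0\toops\t0",
               "0.0166667\t0\t0\t0"), f)
  err <- tryCatch(read_trial_table(f), error = identity)
  expect_s3_class(err, "reachcomp_parse_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "MP_R_y")

  writeLines(c("#task=forward_reach", "#side=right", "#sampling_rate=60",
               "time\tMP_R_x\tMP_R_x\tMP_R_z", "0\t0\t0\t0", "0.0166667\t0\t0\t0"), f)
  expect_error(read_trial_table(f), "duplicate", class = "reachcomp_format_error")

  writeLines(c("#task=forward_reach", "#side=right", "#sampling_rate=60",
               "time\tMP_R_x\tMP_R_y\tMP_R_z", "0\t0\t0\t0", "0.5\t0\t0\t0"), f)
  expect_error(read_trial_table(f), "spacing", class = "reachcomp_format_error")
})

test_that("short gaps are interpolated at read time and flagged; long gaps kept", {
  mp <- ramp(c(0, 0, 0), c(0, 90, 0), 46)
  mp[10:12, 2] <- NaN     # 3 frames = 0.05 s: interpolate
  mp[20:40, 2] <- NaN     # 21 frames = 0.35 s: keep
  tr <- make_trial(MP_R = mp, TROCHANTER_R = c(0, 0, 0), n = 46)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tr, f)
  back <- read_trial_table(f)
  expect_equal(unname(back$positions$MP_R[10:12, 2]), c(18, 20, 22),
               tolerance = 1e-6)
  expect_true(all(is.nan(back$positions$MP_R[20:40, 2])))
  expect_true(any(grepl("MP_R.Y", back$provenance$interpolated)))
})

test_that("validate_marker_set reports missing and gappy required markers", {
  ok <- make_trial(MP_R = c(0, 1, 0), ACROMION_R = c(0, 0, 0), C7 = c(0, 0, 0),
                   TROCHANTER_R = c(0, 0, 0))
  expect_identical(nrow(validate_marker_set(ok)), 0L)

  htm <- make_trial(MP_R = c(0, 1, 0), ACROMION_R = c(0, 0, 0), C7 = c(0, 0, 0),
                    TROCHANTER_R = c(0, 0, 0), EPICONDYLE_R = c(0, 0, 0),
                    task = "hand_to_mouth")
  d <- validate_marker_set(htm)
  expect_identical(d$marker, "CHIN")
  expect_identical(d$problem, "missing")

  c7 <- matrix(0, 10, 3); c7[1:5, 3] <- NaN
  gappy <- make_trial(MP_R = c(0, 1, 0), ACROMION_R = c(0, 0, 0), C7 = c7,
                      TROCHANTER_R = c(0, 0, 0))
  d <- validate_marker_set(gappy)
  expect_identical(d$marker, "C7")
  expect_match(d$problem, "gap fraction 50")
  expect_equal(d$nan_fraction, 0.5)
})

test_that("C3D round-trip through the internal writer preserves positions", {
  set.seed(7)
  pts <- list(RFIN = matrix(rnorm(15, 300, 40), 5, 3),
              RSHO = matrix(rnorm(15, 100, 10), 5, 3),
              C7 = matrix(rnorm(15, 0, 5), 5, 3),
              RGT = matrix(rnorm(15, -50, 5), 5, 3))
  f <- withr::local_tempfile(fileext = ".c3d")
  reachcomp:::write_c3d_minimal(pts, f, rate = 60, units = "mm")
  tr <- ingest_c3d(f, c(RFIN = "MP_R", RSHO = "ACROMION_R",
                        C7 = "C7", RGT = "TROCHANTER_R"))
  expect_equal(tr$sampling_rate, 60)
  expect_equal(unname(tr$positions$MP_R), unname(pts$RFIN), tolerance = 1e-4)
  expect_equal(unname(tr$positions$C7), unname(pts$C7), tolerance = 1e-4)

  # and through the trial-table dialect, to 1e-6 mm
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tr, tsv)
  back <- read_trial_table(tsv)
  expect_equal(back$positions$MP_R, tr$positions$MP_R, tolerance = 1e-6)
})

test_that("C3D ingest converts metres and permutes axes", {
  pts <- list(RFIN = matrix(c(0.1, 0.2, 0.3), 3, 3, byrow = TRUE),
              RSHO = matrix(0, 3, 3), C7 = matrix(0, 3, 3),
              RGT = matrix(0, 3, 3))
  f <- withr::local_tempfile(fileext = ".c3d")
  reachcomp:::write_c3d_minimal(pts, f, rate = 100, units = "m")
  mm <- c(RFIN = "MP_R", RSHO = "ACROMION_R", C7 = "C7", RGT = "TROCHANTER_R")
  tr <- ingest_c3d(f, mm)
  expect_equal(unname(tr$positions$MP_R[1, ]), c(100, 200, 300), tolerance = 1e-4)
  expect_equal(tr$sampling_rate, 100)

  # lab axes Z-up unchanged, but forward along -X, lateral along +Y
  tr2 <- ingest_c3d(f, mm, axes = c(lateral = "+Y", forward = "-X", up = "+Z"))
  expect_equal(unname(tr2$positions$MP_R[1, ]), c(200, -100, 300), tolerance = 1e-4)
})

test_that("C3D ingest error paths: unmapped marker, bad units", {
  pts <- list(RFIN = matrix(0, 3, 3), RSHO = matrix(0, 3, 3))
  f <- withr::local_tempfile(fileext = ".c3d")
  reachcomp:::write_c3d_minimal(pts, f)
  err <- tryCatch(
    ingest_c3d(f, c(RFIN = "MP_R", RSHO = "ACROMION_R")), error = identity)
  expect_s3_class(err, "reachcomp_mapping_error")
  expect_match(conditionMessage(err), "C7")
  expect_match(conditionMessage(err), "RFIN")  # lists candidate labels

  reachcomp:::write_c3d_minimal(pts, f, units = "in")
  expect_error(ingest_c3d(f, c(RFIN = "MP_R", RSHO = "ACROMION_R")),
               class = "reachcomp_unit_error")
})

test_that("subject_record rejects Fugl-Meyer scores for healthy subjects", {
  expect_error(subject_record("H1", "healthy", fma_total = 60),
               class = "reachcomp_format_error")
  s <- subject_record("S1", "stroke", fma_total = 52, affected_side = "left")
  expect_identical(s$group, "stroke")
})
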