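# DICOM Part-10 codec and RT Plan / RT Dose readers and writers

test_that("plan files survive read-write-read on all modeled fields", {
  plan <- make_synthetic_plan(3, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f1)
  p1 <- read_rtplan(f1)
  write_rtplan(p1, f2)
  p2 <- read_rtplan(f2)
  expect_identical(p1, p2)
  # byte-level fixpoint after one quantization pass
  f3 <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(p2, f3)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))
  # modeled fields identical to the source (positions on the 0.01 cm grid)
  expect_equal(p1$dialect, plan$dialect)
  expect_equal(vapply(p1$beams, `[[`, 0, "gantry_angle"),
               vapply(plan$beams, `[[`, 0, "gantry_angle"))
  expect_equal(vapply(p1$beams, `[[`, 0, "mu"),
               vapply(plan$beams, `[[`, 0, "mu"))
  expect_equal(p1$beams[[2]]$control_points[[1]]$bank_a,
               plan$beams[[2]]$control_points[[1]]$bank_a, tolerance = 1e-9)
})

test_that("dialect is auto-detected and conflicts are errors, never guesses", {
  plan <- open_plan()
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  expect_identical(read_rtplan(f)$dialect, "monaco")
  ecl <- convert_plan(plan)
  fe <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(ecl, fe)
  expect_identical(read_rtplan(fe)$dialect, "eclipse")

  # corrupt the SAD so MLC tag and SAD disagree
  ds <- imucheck:::dcm_read_file(f)
  beam_ds <- imucheck:::dcm_get(ds, "BeamSequence")[[1]]
  beam_ds[["300A00B4"]]$value <- 1000
  ds[["300A00B0"]]$value[[1]] <- beam_ds
  fbad <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(fbad, ds, imucheck:::.UID_RTPLAN, "1.2.3")
  expect_error(read_rtplan(fbad), "dialect detection conflict")

  # drop the MLC item entirely
  ds2 <- imucheck:::dcm_read_file(f)
  beam_ds2 <- imucheck:::dcm_get(ds2, "BeamSequence")[[1]]
  bld <- beam_ds2[["300A00B6"]]$value
  beam_ds2[["300A00B6"]]$value <-
    Filter(function(it) !imucheck:::dcm_get(it, "RTBeamLimitingDeviceType") %in%
             c("MLCX", "MLCY"), bld)
  ds2[["300A00B0"]]$value[[1]] <- beam_ds2
  fbad2 <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(fbad2, ds2, imucheck:::.UID_RTPLAN, "1.2.4")
  expect_error(read_rtplan(fbad2), "missing MLC sequence")
})

test_that("eclipse plans carry MLCX plus X jaws; monaco plans carry MLCY and no X jaws", {
  plan <- open_plan()
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  ds <- imucheck:::dcm_read_file(f)
  cp <- imucheck:::dcm_get(imucheck:::dcm_get(
    imucheck:::dcm_get(ds, "BeamSequence")[[1]], "ControlPointSequence")[[1]],
    "BeamLimitingDevicePositionSequence")
  types <- vapply(cp, function(it)
    imucheck:::dcm_get(it, "RTBeamLimitingDeviceType"), "")
  expect_true("MLCY" %in% types)
  expect_false(any(c("MLCX", "ASYMX", "X") %in% types))

  fe <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(convert_plan(plan), fe)
  dse <- imucheck:::dcm_read_file(fe)
  cpe <- imucheck:::dcm_get(imucheck:::dcm_get(
    imucheck:::dcm_get(dse, "BeamSequence")[[1]], "ControlPointSequence")[[1]],
    "BeamLimitingDevicePositionSequence")
  typese <- vapply(cpe, function(it)
    imucheck:::dcm_get(it, "RTBeamLimitingDeviceType"), "")
  expect_true(all(c("MLCX", "ASYMX", "ASYMY") %in% typese))
  expect_false("MLCY" %in% typese)
})

test_that("dose grids round-trip within storage quantization and scaling applies", {
  set.seed(4)
  vals <- array(stats::runif(18 * 14 * 9, 0, 6), dim = c(18, 14, 9))
  g <- dose_grid(vals, origin = c(-17, -13, -8), spacing = c(2, 2, 2),
                 source_engine = "toy", beam_number = 7L)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, f)
  g2 <- read_rtdose(f)
  expect_lt(max(abs(g2$values - vals)), max(vals) * 5e-10)
  expect_identical(g2$beam_number, 7L)
  expect_identical(g2$summation, "beam")

  # scaling definition: stored integer 2500 with scaling 1e-3 reads as 2.5 Gy
  ds <- imucheck:::dcm_read_file(f)
  ds[["3004000E"]]$value <- 1e-3
  ds[["7FE00010"]]$value <- writeBin(rep(2500L, 18 * 14 * 9), raw(),
                                     size = 4L, endian = "little")
  fs <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(fs, ds, imucheck:::.UID_RTDOSE, "1.2.5")
  expect_equal(max(read_rtdose(fs)$values), 2.5)
  expect_equal(min(read_rtdose(fs)$values), 2.5)
})

test_that("malformed dose files are rejected", {
  g <- uniform_grid()
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, f)
  # non-uniform slice spacing
  ds <- imucheck:::dcm_read_file(f)
  ds[["3004000C"]]$value <- c(0, 5, 11, 15, 20, 25, 30, 35, 40, 45, 50, 55)
  f1 <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(f1, ds, imucheck:::.UID_RTDOSE, "1.2.6")
  expect_error(read_rtdose(f1), "non-uniform")
  # missing scaling
  ds2 <- imucheck:::dcm_read_file(f)
  ds2[["3004000E"]] <- NULL
  f2 <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(f2, ds2, imucheck:::.UID_RTDOSE, "1.2.7")
  expect_error(read_rtdose(f2), "DoseGridScaling")
  # empty grid
  ds3 <- imucheck:::dcm_read_file(f)
  ds3[["00280008"]]$value <- 0L
  f3 <- withr::local_tempfile(fileext = ".dcm")
  imucheck:::dcm_write_file(f3, ds3, imucheck:::.UID_RTDOSE, "1.2.8")
  expect_error(read_rtdose(f3))
})

test_that("written files are readable by an independent DICOM implementation", {
  plan <- make_synthetic_plan(2, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  script <- sprintf(
    "import pydicom,sys;d=pydicom.dcmread(r'%s');b=d.BeamSequence[0];\nassert d.Modality=='RTPLAN' and float(b.SourceAxisDistance)==1435.0;\nassert abs(float(b.ControlPointSequence[0].GantryAngle)-%f)<1e-6;\nprint('ok')", f, plan$beams[[1]]$gantry_angle)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(tail(out, 1), "ok")
})
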