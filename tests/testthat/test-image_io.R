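test_that("TIFF stack round-trips exactly (8- and 16-bit)", {
  frames <- array(0L, dim = c(3, 2, 2))
  frames[1, , ] <- matrix(c(0L, 2L, 4L, 6L), 2, 2, byrow = TRUE)
  frames[2, , ] <- matrix(c(10L, 20L, 30L, 40L), 2, 2, byrow = TRUE)
  frames[3, , ] <- matrix(c(255L, 0L, 128L, 7L), 2, 2, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_tiff_stack(frames, path, bit_depth = 8)
  got <- read_tiff_stack(path)
  expect_identical(got$frames, frames)
  expect_identical(got$bit_depth, 8L)

  f16 <- array(sample.int(65536, 24) - 1L, dim = c(2, 3, 4))
  p16 <- withr::local_tempfile(fileext = ".tiff")
  write_tiff_stack(f16, p16, bit_depth = 16)
  expect_identical(read_tiff_stack(p16)$frames, f16)
})

test_that("frame-stack I/O enforces its invariants", {
  one <- array(1L, dim = c(1, 2, 2))
  p <- withr::local_tempfile(fileext = ".tiff")
  write_tiff_stack(one, p)
  expect_error(read_frame_stack(p, frame_rate = 25), class = "pq_invalid_input")

  two <- array(1L, dim = c(2, 2, 2))
  p2 <- withr::local_tempfile(fileext = ".tiff")
  write_tiff_stack(two, p2)
  expect_error(read_frame_stack(p2), class = "pq_config_error") # no frame rate
  st <- read_frame_stack(p2, frame_rate = 25)
  expect_s3_class(st, "frame_stack")

  # sidecar metadata supplies the frame rate after write_frame_stack
  p3 <- withr::local_tempfile(fileext = ".tiff")
  write_frame_stack(frame_stack(two, frame_rate = 10, origin_timestamp = 1.5), p3)
  st3 <- read_frame_stack(p3)
  expect_equal(st3$frame_rate, 10)
  expect_equal(st3$origin_timestamp, 1.5)
})

test_that("perfquant reads tifffile output and vice versa (oracle cross-check)", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  td <- withr::local_tempdir()
  ours <- file.path(td, "ours.tiff"); theirs <- file.path(td, "theirs.tiff")
  rgb <- file.path(td, "rgb.tiff"); dump <- file.path(td, "dump.csv")
  frames <- array(sample.int(256, 3 * 4 * 5) - 1L, dim = c(3, 4, 5))
  write_tiff_stack(frames, ours)
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s)\n",
    "np.savetxt(%s, a.reshape(a.shape[0], -1).astype(int), fmt='%%d', delimiter=',')\n",
    "rng = np.random.default_rng(1)\n",
    "b = rng.integers(0, 255, size=(2, 6, 5), dtype=np.uint8)\n",
    "tifffile.imwrite(%s, b, photometric='minisblack')\n",
    "c = rng.integers(0, 255, size=(4, 4, 3), dtype=np.uint8)\n",
    "tifffile.imwrite(%s, c, photometric='rgb')\n",
    "np.save(%s, b)\n"),
    shQuote(ours), shQuote(dump), shQuote(theirs), shQuote(rgb),
    shQuote(file.path(td, "b.npy")))
  writeLines(script, file.path(td, "x.py"))
  expect_equal(system2(py, file.path(td, "x.py")), 0L)
  # tifffile read our file: rows of dump are frames, row-major H*W
  a <- as.matrix(utils::read.csv(dump, header = FALSE))
  for (t in 1:3)
    expect_identical(unname(a[t, ]), as.vector(t(frames[t, , ])))
  # we read tifffile's multi-page grayscale file
  got <- read_tiff_stack(theirs)
  expect_identical(dim(got$frames), c(2L, 6L, 5L))
  # and reject RGB with a classed error
  expect_error(read_tiff_stack(rgb), class = "pq_unsupported_format")
})

test_that("ROI mean extraction matches hand arithmetic", {
  frames <- array(0L, dim = c(2, 2, 2))
  frames[1, , ] <- matrix(c(0L, 2L, 4L, 6L), 2, 2, byrow = TRUE)
  frames[2, , ] <- 5L
  st <- frame_stack(frames, frame_rate = 1, origin_timestamp = 0)
  roi <- roi_definition("R", rect = c(0L, 0L, 2L, 2L))
  cv <- extract_roi_curve(st, roi, injection_time = 0.5)
  expect_equal(cv$intensities, c(3, 5))
  expect_equal(cv$times, c(0, 1))
  # out-of-bounds mask is an error
  bad <- roi_definition("B", rect = c(0L, 0L, 3L, 2L))
  expect_error(extract_roi_curve(st, bad, 0.5), class = "pq_invalid_input")
})

test_that("mean extraction is permutation-invariant within the mask", {
  set.seed(11)
  frames <- array(sample.int(200, 4 * 6 * 6, replace = TRUE), dim = c(4, 6, 6))
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:4] <- TRUE
  idx <- which(mask)
  shuffled <- frames
  perm <- sample(idx)
  fm <- frames; dim(fm) <- c(4, 36)
  sm <- shuffled; dim(sm) <- c(4, 36)
  sm[, idx] <- fm[, perm]
  dim(sm) <- c(4, 6, 6)
  st1 <- frame_stack(frames, 25); st2 <- frame_stack(sm, 25)
  roi <- roi_definition("R", mask = mask)
  expect_equal(extract_roi_curve(st1, roi, 0.05)$intensities,
               extract_roi_curve(st2, roi, 0.05)$intensities)
})

test_that("noiseless rendered stack returns the generating curve exactly", {
  acq <- acquisition_config(noise_sd = 0, duration = 30, seed = 1)
  cvs <- list(D1 = simulate_curve(roi_perfusion_spec("D1", 0.6, 4), 1, acq),
              D3 = simulate_curve(roi_perfusion_spec("D3"), 1, acq))
  geom <- list(D1 = c(0L, 0L, 4L, 4L), D3 = c(0L, 6L, 4L, 10L))
  fs <- simulate_frame_stack(cvs, geom, canvas = c(6L, 12L))
  for (rn in names(cvs)) {
    got <- extract_roi_curve(fs$stack, fs$rois[[rn]], acq$injection_time)
    expect_equal(got$intensities, cvs[[rn]]$intensities)
    expect_equal(got$times, cvs[[rn]]$times)
  }
  expect_error(
    simulate_frame_stack(cvs, list(D1 = c(0L, 0L, 4L, 4L), D3 = c(2L, 2L, 6L, 6L)),
                         canvas = c(6L, 12L)),
    class = "pq_config_error")
})

test_that("curve CSV round-trips at full precision with metadata", {
  cv <- make_random_curve(3)$curve
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- read_curve_csv(path)
  expect_identical(back$intensities, cv$intensities)
  expect_identical(back$times, cv$times)
  expect_identical(back$injection_time, cv$injection_time)
  expect_identical(back$roi_name, cv$roi_name)
})

test_that("malformed curve CSVs fail with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,intensity", "0,1", "0.04,2,9"), path)
  expect_error(read_curve_csv(path, injection_time = 0.01), "row 3",
               class = "pq_parse_error")
  writeLines(c("time_s,intensity", "0,1", "0.04,abc"), path)
  expect_error(read_curve_csv(path, injection_time = 0.01), "row 3",
               class = "pq_parse_error")
})

test_that("ROI JSON round-trips and enforces a single reference", {
  rois <- list(D1 = roi_definition("D1", rect = c(0L, 0L, 2L, 2L)),
               D3 = roi_definition("D3", rect = c(0L, 3L, 2L, 5L), is_reference = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_json(rois, path)
  back <- read_roi_json(path)
  expect_equal(back$D3$rect, c(0L, 3L, 2L, 5L))
  expect_true(back$D3$is_reference)
  rois$D3$is_reference <- FALSE
  write_roi_json(rois, path)
  expect_error(read_roi_json(path), class = "pq_invalid_input")
})
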