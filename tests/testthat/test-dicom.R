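small_phantom <- function(seed = 40) generate_phantom(phantom_spec(seed = seed, n_slices = 3))

test_that("DICOM series round-trips voxels and geometry exactly", {
  ph <- small_phantom()
  d <- file.path(tempdir(), "dcm_rt")
  unlink(d, recursive = TRUE)
  write_dicom_series(ph$volume, d)
  back <- read_lge_series(d)
  expect_true(all(back$data == ph$volume$data))
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-12)
  expect_equal(back$origin, ph$volume$origin, tolerance = 1e-12)
  expect_equal(back$orientation, ph$volume$orientation, ignore_attr = TRUE)
})

test_that("NIfTI and DICOM paths agree on the affine geometry", {
  ph <- small_phantom(41)
  d <- file.path(tempdir(), "dcm_nifti"); unlink(d, recursive = TRUE)
  write_dicom_series(ph$volume, d)
  nf <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$volume, nf)
  a <- read_lge_series(d)
  b <- read_lge_series(nf)
  expect_true(all(a$data == b$data))
  expect_lt(max(abs(a$origin - b$origin)), 1e-4)
  expect_lt(max(abs(a$spacing - b$spacing)), 1e-4)
  expect_lt(max(abs(a$orientation - b$orientation)), 1e-4)
})

test_that("reader rejects empty directories and inconsistent series", {
  d <- file.path(tempdir(), "empty_dir"); dir.create(d, showWarnings = FALSE)
  expect_error(read_lge_series(d), "no DICOM files")
  expect_error(read_lge_series(file.path(tempdir(), "no_such_thing")), "does not exist")

  # two slices with different orientations must be refused, naming the file
  d2 <- file.path(tempdir(), "mixed"); unlink(d2, recursive = TRUE); dir.create(d2)
  px <- matrix(1L, 8, 8)
  cartoplan:::dicom_write_slice(file.path(d2, "a.dcm"), px, c(0, 0, 0), c(1, 1),
                                orientation = c(1, 0, 0, 0, 1, 0), slice_thickness = 5,
                                instance_number = 1, series_uid = "1.2.3", study_uid = "1.2")
  cartoplan:::dicom_write_slice(file.path(d2, "b.dcm"), px, c(0, 0, 5), c(1, 1),
                                orientation = c(0, 1, 0, 1, 0, 0), slice_thickness = 5,
                                instance_number = 2, series_uid = "1.2.3", study_uid = "1.2")
  expect_error(read_lge_series(d2), "b\\.dcm.*orientation")
})

test_that("treatment datasets: one series and sidecar per target, markers in place", {
  ph <- small_phantom(42)
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  plan <- assign_targets(map, planner_config(
    n_targets = 8, sector_split = c(septal = 4, anterior = 4),
    septal_direction = ph$truth$septal_direction))
  out <- file.path(tempdir(), "treat"); unlink(out, recursive = TRUE)
  res <- write_treatment_datasets(plan, map, geometry, out, config_hash = "abc")
  expect_length(res$series_dirs, nrow(plan$targets))
  expect_length(res$sidecars, nrow(plan$targets))
  expect_true(all(file.exists(res$sidecars)))

  # sidecar is the loss-free authority on coordinates
  sc <- jsonlite::fromJSON(res$sidecars[[3]])
  expect_equal(unlist(sc$position_mm),
               as.numeric(plan$targets[3, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sc$needle_depth_mm, plan$targets$needle_depth[3], tolerance = 1e-9)
  expect_equal(sc$sector, plan$targets$sector[3])

  # voxelised sphere centre of mass sits within half a voxel of the target
  vol <- read_lge_series(res$series_dirs[[3]])
  idx <- which(vol$data == max(vol$data), arr.ind = TRUE)
  A <- vol$orientation %*% diag(vol$spacing)
  mm <- t(A %*% t(idx - 1)) + rep(vol$origin, each = nrow(idx))
  com <- colMeans(mm)
  expect_lt(sqrt(sum((com - unlist(sc$position_mm))^2)), max(vol$spacing) / 2)

  # a target outside the volume is refused
  plan_bad <- plan
  plan_bad$targets$x[1] <- 1e4
  expect_error(write_treatment_datasets(plan_bad, map, geometry,
                                        file.path(tempdir(), "treat_bad")),
               "outside")
})

test_that("written files are readable by an independent DICOM implementation", {
  ph <- small_phantom(43)
  d <- file.path(tempdir(), "dcm_py"); unlink(d, recursive = TRUE)
  write_dicom_series(ph$volume, d)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.Rows, ds.Columns)",
    "print('\\\\'.join(str(v) for v in ds.PixelSpacing))",
    "print('\\\\'.join(str(v) for v in ds.ImagePositionPatient))",
    "print(int(ds.pixel_array.sum()))",
    sep = "\n")
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  out <- system2("python", c(sf, file.path(d, "slice_002.dcm")), stdout = TRUE)
  expect_equal(as.integer(strsplit(out[1], " ")[[1]]),
               c(ph$volume$dim[2], ph$volume$dim[1]))
  expect_equal(as.numeric(strsplit(out[2], "\\\\")[[1]]),
               ph$volume$spacing[c(2, 1)], tolerance = 1e-9)
  ipp <- ph$volume$origin + c(0, 0, ph$volume$spacing[3])
  expect_equal(as.numeric(strsplit(out[3], "\\\\")[[1]]), ipp, tolerance = 1e-9)
  expect_equal(as.numeric(out[4]), sum(ph$volume$data[, , 2]))
})
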