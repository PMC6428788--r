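# Minimal DICOM Part-10 I/O: explicit-VR little-endian, single-frame,
# uncompressed 16-bit monochrome secondary-capture objects. This covers
# exactly what the pipeline needs — writing geometry-faithful volumes
# and per-target treatment datasets and reading them (and comparable
# single-frame series) back. Patient coordinates are DICOM LPS
# millimetres throughout the package.

SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLEMENTATION_UID <- "2.25.842203766502972964"

#' @keywords internal
new_uid <- function() {
  paste0("2.25.", paste(sample(0:9, 24, replace = TRUE), collapse = ""))
}

# --- encoding ----------------------------------------------------------

#' @keywords internal
enc_element <- function(group, element, vr, value) {
  pad_str <- function(s, pad = " ") {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(pad))
    r
  }
  body <- switch(vr,
    UI = { r <- charToRaw(value); if (length(r) %% 2 == 1) c(r, as.raw(0)) else r },
    CS = , LO = , PN = , SH = , DA = , TM = , IS = , DS = pad_str(as.character(value)),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OB = as.raw(value),
    OW = value,  # already raw
    stop("unsupported VR: ", vr))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    if (length(body) > 65534) stop("element too long for short VR form")
    c(head, writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

#' @keywords internal
ds_string <- function(x) paste(vapply(x, function(v) format(v, digits = 12, scientific = FALSE, trim = TRUE), ""), collapse = "\\")

# Write one single-frame slice. `pixels` is an integer matrix indexed
# [column (x), row (y)]; values must be in [0, 32767].
#' @keywords internal
dicom_write_slice <- function(path, pixels, position, pixel_spacing,
                              orientation = c(1, 0, 0, 0, 1, 0),
                              slice_thickness, instance_number,
                              series_uid, study_uid, sop_uid = new_uid(),
                              series_description = "cartoplan",
                              series_number = 1,
                              patient_name = "PHANTOM^LV", patient_id = "CARTOPLAN") {
  pixels <- round(pixels)
  if (min(pixels) < 0 || max(pixels) > 32767)
    stop("pixel values must fit in [0, 32767]")
  ncol_img <- nrow(pixels)   # x = columns of the DICOM image
  nrow_img <- ncol(pixels)   # y = rows
  # DICOM stores rows top to bottom, columns left to right: with the
  # [x, y] layout the column index varies fastest, which is exactly
  # R's column-major order of `pixels`.
  pixel_raw <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")

  meta <- c(enc_element(0x0002, 0x0001, "OB", c(0, 1)),
            enc_element(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
            enc_element(0x0002, 0x0003, "UI", sop_uid),
            enc_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
            enc_element(0x0002, 0x0012, "UI", IMPLEMENTATION_UID))
  meta <- c(enc_element(0x0002, 0x0000, "UL", length(meta)), meta)

  body <- c(enc_element(0x0008, 0x0008, "CS", "DERIVED\\SECONDARY"),
            enc_element(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
            enc_element(0x0008, 0x0018, "UI", sop_uid),
            enc_element(0x0008, 0x0060, "CS", "OT"),
            enc_element(0x0008, 0x103E, "LO", series_description),
            enc_element(0x0010, 0x0010, "PN", patient_name),
            enc_element(0x0010, 0x0020, "LO", patient_id),
            enc_element(0x0018, 0x0050, "DS", ds_string(slice_thickness)),
            enc_element(0x0020, 0x000D, "UI", study_uid),
            enc_element(0x0020, 0x000E, "UI", series_uid),
            enc_element(0x0020, 0x0011, "IS", as.character(series_number)),
            enc_element(0x0020, 0x0013, "IS", as.character(instance_number)),
            enc_element(0x0020, 0x0032, "DS", ds_string(position)),
            enc_element(0x0020, 0x0037, "DS", ds_string(orientation)),
            enc_element(0x0028, 0x0002, "US", 1),
            enc_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
            enc_element(0x0028, 0x0010, "US", nrow_img),
            enc_element(0x0028, 0x0011, "US", ncol_img),
            enc_element(0x0028, 0x0030, "DS", ds_string(c(pixel_spacing[2], pixel_spacing[1]))),
            enc_element(0x0028, 0x0100, "US", 16),
            enc_element(0x0028, 0x0101, "US", 16),
            enc_element(0x0028, 0x0102, "US", 15),
            enc_element(0x0028, 0x0103, "US", 0),
            enc_element(0x7FE0, 0x0010, "OW", pixel_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# --- decoding ----------------------------------------------------------

# Parse one explicit-VR little-endian Part-10 file into a tag list.
#' @keywords internal
dicom_read_file <- function(path) {
  r <- readBin(path, raw(), file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM Part-10 file", path))
  pos <- 133L
  u16 <- function(i) readBin(r[i:(i + 1)], "integer", size = 2, endian = "little", signed = FALSE)
  u32 <- function(i) readBin(r[i:(i + 3)], "integer", size = 4, endian = "little")
  tags <- list()
  ts <- NULL
  while (pos + 7 <= length(r)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6); vstart <- pos + 8L
    }
    val_raw <- if (len > 0) r[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- list(vr = vr, raw = val_raw)
    if (key == "0002,0010") ts <- trimws(rawToChar(val_raw))
    pos <- vstart + len
  }
  if (!identical(ts, TRANSFER_SYNTAX_EXPLICIT_LE))
    stop(sprintf("%s: unsupported transfer syntax '%s'", path, ts %||% "missing"))
  tags
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
tag_string <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  r <- t$raw
  while (length(r) && r[length(r)] %in% as.raw(c(0L, 32L))) r <- r[-length(r)]
  trimws(rawToChar(r))
}

#' @keywords internal
tag_numeric <- function(tags, key) {
  s <- tag_string(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' @keywords internal
tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$raw, "integer", n = length(t$raw) / 2, size = 2,
          endian = "little", signed = FALSE)
}

#' Read an LGE volume from a DICOM directory or NIfTI file
#'
#' Accepts either a directory of single-frame DICOM files (explicit-VR
#' little endian) or a NIfTI file. Slices are sorted by the projection
#' of their position onto the slice normal; all files must share the
#' image orientation and carry pixel spacing, otherwise an error names
#' the offending file. NIfTI input is converted from its RAS convention
#' to the package's DICOM LPS patient space at the boundary.
#'
#' @param path directory of `.dcm` files, or a `.nii` / `.nii.gz` file.
#' @return An `lge_volume`: `data` (array `[x, y, z]`), `spacing` (mm),
#'   `origin` (mm, centre of voxel `[0, 0, 0]`), `orientation` (3x3
#'   direction cosines), `dim`.
#' @export
read_lge_series <- function(path) {
  if (dir.exists(path)) return(read_dicom_dir(path))
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  lps <- diag(c(-1, -1, 1, 1)) %*% aff
  sp <- sqrt(colSums(lps[1:3, 1:3]^2))
  orientation <- sweep(lps[1:3, 1:3], 2, sp, "/")
  dat <- array(as.numeric(img), dim(img))
  structure(list(data = dat, spacing = as.numeric(sp),
                 origin = as.numeric(lps[1:3, 4]),
                 orientation = orientation, dim = dim(dat)),
            class = "lge_volume")
}

#' @keywords internal
read_dicom_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no DICOM files found in '%s'", path))
  parsed <- lapply(files, dicom_read_file)
  iop <- NULL
  slices <- vector("list", length(files))
  for (i in seq_along(files)) {
    tg <- parsed[[i]]
    this_iop <- tag_numeric(tg, "0020,0037")
    ps <- tag_numeric(tg, "0028,0030")
    ipp <- tag_numeric(tg, "0020,0032")
    if (is.null(ps)) stop(sprintf("%s: missing PixelSpacing", files[i]))
    if (is.null(ipp)) stop(sprintf("%s: missing ImagePositionPatient", files[i]))
    if (is.null(this_iop)) stop(sprintf("%s: missing ImageOrientationPatient", files[i]))
    if (is.null(iop)) iop <- this_iop
    else if (max(abs(iop - this_iop)) > 1e-6)
      stop(sprintf("%s: image orientation differs from the rest of the series", files[i]))
    rows <- tag_us(tg, "0028,0010"); cols <- tag_us(tg, "0028,0011")
    pix <- readBin(tg[["7fe0,0010"]]$raw, "integer", n = rows * cols,
                   size = 2, endian = "little", signed = FALSE)
    slices[[i]] <- list(ipp = ipp, ps = ps,
                        mat = matrix(pix, nrow = cols, ncol = rows))  # [x, y]
  }
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  dz <- if (length(zpos) > 1) stats::median(diff(zpos)) else
    tag_numeric(parsed[[1]], "0018,0050") %||% 1
  nx <- nrow(slices[[1]]$mat); ny <- ncol(slices[[1]]$mat)
  dat <- array(0, c(nx, ny, length(slices)))
  for (i in seq_along(slices)) dat[, , i] <- slices[[i]]$mat
  sp <- c(slices[[1]]$ps[2], slices[[1]]$ps[1], dz)
  structure(list(data = dat, spacing = sp, origin = slices[[1]]$ipp,
                 orientation = cbind(rdir, cdir, normal), dim = dim(dat)),
            class = "lge_volume")
}

#' Write a volume as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per slice, carrying
#' the full voxel geometry (position, orientation, spacing). Intensities
#' must be integers in `[0, 32767]`; the phantom generates integer
#' magnitudes, so its volumes round-trip bit for bit.
#'
#' @param volume an `lge_volume`.
#' @param dir output directory (created).
#' @param series_description free-text series label.
#' @param series_number integer series number.
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(volume, dir, series_description = "cartoplan",
                               series_number = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study_uid <- new_uid(); series_uid <- new_uid()
  iop <- c(volume$orientation[, 1], volume$orientation[, 2])
  files <- character(volume$dim[3])
  for (k in seq_len(volume$dim[3])) {
    pos <- volume$origin + volume$orientation[, 3] * volume$spacing[3] * (k - 1)
    files[k] <- file.path(dir, sprintf("slice_%03d.dcm", k))
    dicom_write_slice(files[k], volume$data[, , k], pos,
                      pixel_spacing = volume$spacing[1:2], orientation = iop,
                      slice_thickness = volume$spacing[3], instance_number = k,
                      series_uid = series_uid, study_uid = study_uid,
                      series_description = series_description,
                      series_number = series_number)
  }
  invisible(files)
}

#' Export per-target DICOM treatment datasets
#'
#' The deliverable of the planning stage: one DICOM series per
#' injection target, sharing the voxel geometry of the base LGE volume.
#' In each series the target is voxelised as a filled sphere at maximal
#' intensity and a subsampled endocardial point cloud is burnt in at
#' unit intensity, so any DICOM viewer displays the target against the
#' anatomy used for registration. A JSON sidecar per target is the
#' loss-free authority: it carries the exact millimetre coordinates,
#' sector, needle depth and provenance (configuration hash, creation
#' time).
#'
#' @param plan a `target_plan`.
#' @param map the `endo_map` the plan was made on.
#' @param geometry voxel geometry of the base volume (`dim`, `spacing`,
#'   `origin`, `orientation`).
#' @param out_dir output directory.
#' @param sphere_radius target marker radius, mm.
#' @param endo_stride keep every `endo_stride`-th endocardial vertex.
#' @param marker_intensity voxel value of the target sphere.
#' @param config_hash provenance string stored in the sidecars.
#' @return Invisibly, a list with `series_dirs` and `sidecars`.
#' @export
write_treatment_datasets <- function(plan, map, geometry, out_dir,
                                     sphere_radius = 2, endo_stride = 4,
                                     marker_intensity = 1000,
                                     config_hash = "unspecified") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  endo_pts <- map$vertices[seq(1, nrow(map$vertices), by = endo_stride), , drop = FALSE]
  endo_ijk <- mm_to_voxel(geometry, endo_pts)
  nt <- nrow(plan$targets)
  series_dirs <- character(nt); sidecars <- character(nt)
  for (ti in seq_len(nt)) {
    tgt <- plan$targets[ti, ]
    tpos <- c(tgt$x, tgt$y, tgt$z)
    ijk <- mm_to_voxel(geometry, matrix(tpos, 1))
    if (any(ijk < 1) || any(ijk > geometry$dim))
      stop(sprintf("target %d lies outside the base volume", ti))
    dat <- array(0L, geometry$dim)
    okp <- endo_ijk[, 1] >= 1 & endo_ijk[, 1] <= geometry$dim[1] &
           endo_ijk[, 2] >= 1 & endo_ijk[, 2] <= geometry$dim[2] &
           endo_ijk[, 3] >= 1 & endo_ijk[, 3] <= geometry$dim[3]
    dat[endo_ijk[okp, , drop = FALSE]] <- 1L
    dat <- burn_sphere(dat, geometry, tpos, sphere_radius, marker_intensity)
    vol <- structure(list(data = dat, spacing = geometry$spacing,
                          origin = geometry$origin, orientation = geometry$orientation,
                          dim = geometry$dim), class = "lge_volume")
    series_dirs[ti] <- file.path(out_dir, sprintf("target_%02d", ti))
    write_dicom_series(vol, series_dirs[ti],
                       series_description = sprintf("treatment target %02d (%s)", ti, tgt$sector),
                       series_number = ti)
    sidecars[ti] <- file.path(out_dir, sprintf("target_%02d.json", ti))
    jsonlite::write_json(list(target_index = ti,
                              position_mm = tpos,
                              sector = tgt$sector,
                              needle_depth_mm = tgt$needle_depth,
                              wall_thickness_mm = tgt$wall_thickness,
                              transmurality_pct = tgt$transmurality,
                              slice_index = tgt$slice_index,
                              provenance = list(config_hash = config_hash,
                                                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                         sidecars[ti], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(series_dirs = series_dirs, sidecars = sidecars))
}

# Voxelise a filled sphere; only the grid neighbourhood is scanned.
#' @keywords internal
burn_sphere <- function(dat, geometry, center, radius, value) {
  ctr <- mm_to_voxel(geometry, matrix(center, 1))
  rad_vox <- ceiling(radius / geometry$spacing) + 1
  rng <- lapply(1:3, function(d) max(1, ctr[d] - rad_vox[d]):min(geometry$dim[d], ctr[d] + rad_vox[d]))
  A <- geometry$orientation %*% diag(geometry$spacing)
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- t(A %*% t(grid - 1)) + rep(geometry$origin, each = nrow(grid))
  inside <- rowSums((mm - rep(center, each = nrow(grid)))^2) <= radius^2
  dat[grid[inside, , drop = FALSE]] <- as.integer(value)
  dat
}
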