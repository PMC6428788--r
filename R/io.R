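# NIfTI and ascii-PLY helpers. NIfTI files use the RAS convention; the
# package works in DICOM LPS patient millimetres, so the first two axes
# of the affine are negated at the boundary in both directions.

#' Write a volume as NIfTI
#'
#' @param volume an `lge_volume` (LPS geometry).
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(c(-1, -1, 1)) %*% (volume$orientation %*% diag(volume$spacing))
  aff[1:3, 4] <- c(-1, -1, 1) * volume$origin
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write an ascii PLY file
#'
#' Minimal ascii PLY support for surface meshes with optional per-vertex
#' scalar properties (beyond x/y/z) and for bare point clouds.
#'
#' @param vertices n x 3 matrix (mm).
#' @param path file path.
#' @param faces optional m x 3 matrix of 1-based triangle indices.
#' @param vertex_props optional data frame of extra per-vertex scalars.
#' @return `read_ply` returns a list with `vertices`, `faces` (NULL when
#'   absent) and `vertex_props`.
#' @export
write_ply <- function(vertices, path, faces = NULL, vertex_props = NULL) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  props <- c("x", "y", "z")
  tab <- as.data.frame(vertices)
  names(tab) <- props
  if (!is.null(vertex_props)) {
    stopifnot(nrow(vertex_props) == n)
    tab <- cbind(tab, vertex_props)
    props <- c(props, names(vertex_props))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
           sprintf("property float %s", props))
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  writeLines(do.call(paste, c(lapply(tab, format, digits = 9, trim = TRUE,
                                     scientific = FALSE))), con)
  if (!is.null(faces))
    writeLines(paste(3, faces[, 1] - 1, faces[, 2] - 1, faces[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ascii PLY is supported")
  endh <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  vlines <- grep("^property (float|double) ", hdr, value = TRUE)
  props <- sub("^property (float|double) ", "", vlines)
  vdat <- utils::read.table(text = lines[endh + seq_len(nv)], col.names = props)
  faces <- NULL
  if (nf > 0) {
    fdat <- utils::read.table(text = lines[endh + nv + seq_len(nf)])
    faces <- as.matrix(fdat[, 2:4]) + 1L
  }
  extra <- setdiff(props, c("x", "y", "z"))
  list(vertices = as.matrix(vdat[, c("x", "y", "z")]),
       faces = faces,
       vertex_props = if (length(extra)) vdat[, extra, drop = FALSE] else NULL)
}

#' Write a point cloud as CSV
#'
#' @param points n x 3 matrix.
#' @param path file path.
#' @export
write_cloud_csv <- function(points, path) {
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2], z = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) as.matrix(utils::read.csv(path)[, c("x", "y", "z")])
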