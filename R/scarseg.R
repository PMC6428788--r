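#' Full-width-at-half-maximum infarct segmentation
#'
#' Segments hyperenhanced (infarcted) myocardium within a myocardial
#' mask by the FWHM rule: a voxel is scar when its intensity reaches
#' half-maximal enhancement. The half-maximum is referenced to the
#' myocardial minimum by default, `T = I_min + 0.5 (I_max - I_min)`,
#' computed per slice; this is the common published variant and is
#' invariant to global intensity scaling and offset. `reference = "max"`
#' switches to the plain `T = 0.5 I_max` rule, and `scope = "volume"`
#' pools all myocardial voxels into a single threshold. Connected scar
#' components (8-connected, in-plane) smaller than `min_component_px`
#' pixels are discarded as noise.
#'
#' A slice whose myocardial intensities are constant carries no
#' enhancement information: it yields an empty scar mask with a warning,
#' not an error.
#'
#' @param intensities numeric array (2-D slice or 3-D volume), a.u.; an
#'   `lge_volume` is also accepted.
#' @param myo_mask logical array of the same shape; myocardium between
#'   the endo- and epicardial contours.
#' @param min_component_px minimum connected-component size kept, pixels.
#' @param reference `"min"` (half of the min-to-max range above the
#'   minimum, default) or `"max"` (half of the maximum).
#' @param scope `"slice"` (threshold per slice, default) or `"volume"`.
#' @return Object of class `scar_seg`: logical `scar_mask` (same shape as
#'   input) and numeric `threshold_used` per slice (NA where the slice
#'   has no myocardium).
#' @examples
#' img <- matrix(c(10, 10, 100, 90, 10), 1)
#' fwhm_segment(img, matrix(TRUE, 1, 5), min_component_px = 1)$threshold_used
#' @export
fwhm_segment <- function(intensities, myo_mask, min_component_px = 5,
                         reference = c("min", "max"), scope = c("slice", "volume")) {
  reference <- match.arg(reference)
  scope <- match.arg(scope)
  if (inherits(intensities, "lge_volume")) intensities <- intensities$data
  two_d <- length(dim(intensities)) < 3 || is.null(dim(intensities))
  if (is.null(dim(intensities))) intensities <- matrix(intensities, 1)
  if (two_d) {
    intensities <- array(intensities, c(dim(intensities), 1))
    myo_mask <- array(as.logical(myo_mask), dim(intensities))
  }
  stopifnot(all(dim(myo_mask) == dim(intensities)))
  myo_mask <- array(as.logical(myo_mask), dim(intensities))
  nz <- dim(intensities)[3]
  if (sum(myo_mask) < 1) stop("myocardial mask is empty")

  thr <- rep(NA_real_, nz)
  scar <- array(FALSE, dim(intensities))
  if (scope == "volume") {
    vals <- intensities[myo_mask]
    thr_vol <- fwhm_threshold(vals, reference)
  }
  for (k in seq_len(nz)) {
    m <- myo_mask[, , k]
    if (!any(m)) next
    vals <- intensities[, , k][m]
    tk <- if (scope == "volume") thr_vol else fwhm_threshold(vals, reference)
    if (is.na(tk)) {
      warning(sprintf("slice %d: uniform myocardial intensities, empty scar mask", k - 1))
      thr[k] <- max(vals)  # degenerate: threshold above every voxel
      next
    }
    thr[k] <- tk
    sk <- m & intensities[, , k] >= tk
    scar[, , k] <- prune_small_components(sk, min_component_px)
  }
  out_mask <- if (two_d) scar[, , 1] else scar
  structure(list(scar_mask = out_mask, threshold_used = thr,
                 reference = reference, scope = scope,
                 min_component_px = min_component_px),
            class = "scar_seg")
}

#' @keywords internal
fwhm_threshold <- function(vals, reference) {
  imin <- min(vals); imax <- max(vals)
  if (imax - imin < .Machine$double.eps * max(1, abs(imax))) return(NA_real_)
  if (reference == "min") imin + 0.5 * (imax - imin) else 0.5 * imax
}

# Drop 8-connected components smaller than min_px from a logical matrix.
#' @keywords internal
prune_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim(mask))
}

#' @export
print.scar_seg <- function(x, ...) {
  cat(sprintf("scar_seg (FWHM, %s-referenced, per-%s): %d scar voxels, %d slices\n",
              x$reference, x$scope, sum(x$scar_mask),
              length(x$threshold_used)))
  invisible(x)
}
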