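# Two-stage rigid registration of the planning geometry (MRI space) to
# an interventional epicardial point cloud: a coarse centroid +
# principal-axes initialisation standing in for the workstation's
# anatomy-based pre-alignment, then trimmed iterative closest point on
# the epicardial surface.

#' Coarse rigid alignment by centroids and principal axes
#'
#' Aligns the source cloud to the target cloud by matching centroids and
#' the principal axes of the two point distributions. The axes leave a
#' four-fold proper sign ambiguity; the combination minimising the
#' symmetric nearest-neighbour RMS is kept. A degenerate (rank < 3)
#' distribution falls back to a centroid-only translation with a
#' warning.
#'
#' @param source,target n x 3 point matrices (mm), at least 10 points
#'   each.
#' @return A [rigid_transform()] mapping source into target space.
#' @export
coarse_align <- function(source, target) {
  source <- as_points(source); target <- as_points(target)
  if (nrow(source) < 10 || nrow(target) < 10)
    stop("need at least 10 points in each cloud")
  cs <- colMeans(source); ct <- colMeans(target)
  es <- eigen(stats::cov(source), symmetric = TRUE)
  et <- eigen(stats::cov(target), symmetric = TRUE)
  if (min(es$values) < 1e-8 * max(es$values) ||
      min(et$values) < 1e-8 * max(et$values)) {
    warning("degenerate point distribution; returning centroid-only alignment")
    return(rigid_transform(diag(3), ct - cs))
  }
  Vs <- fix_handedness(es$vectors)
  Vt <- fix_handedness(et$vectors)
  sign_sets <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL; best_rms <- Inf
  ssub <- subsample_rows(source, 400)
  tsub <- subsample_rows(target, 400)
  for (sg in sign_sets) {
    R <- Vt %*% diag(sg) %*% t(Vs)
    tf <- rigid_transform(R, ct - as.numeric(R %*% cs))
    moved <- transform_points(tf, ssub)
    rms <- sqrt((mean(nn_dist2(moved, tsub)) + mean(nn_dist2(tsub, moved))) / 2)
    if (rms < best_rms) { best_rms <- rms; best <- tf }
  }
  best
}

#' @keywords internal
fix_handedness <- function(V) { if (det(V) < 0) V[, 3] <- -V[, 3]; V }

#' @keywords internal
as_points <- function(x) {
  if (inherits(x, "ra_cloud")) x <- x$points
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3)
  m
}

# deterministic thinning (every k-th row) for RMS scoring
#' @keywords internal
subsample_rows <- function(x, n) {
  if (nrow(x) <= n) return(x)
  x[seq(1, nrow(x), length.out = n), , drop = FALSE]
}

# Squared distance from each row of a to its nearest neighbour in b,
# chunked to bound memory.
#' @keywords internal
nn_dist2 <- function(a, b, chunk = 2000L) {
  bb <- rowSums(b^2)
  out <- numeric(nrow(a))
  idx <- integer(nrow(a))
  for (st in seq(1, nrow(a), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(a))
    aa <- a[st:en, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * tcrossprod(aa, b)
    j <- max.col(-d2, ties.method = "first")
    idx[st:en] <- j
    # recompute the winning distances by direct differencing: the
    # expanded form cancels catastrophically near zero
    out[st:en] <- rowSums((aa - b[j, , drop = FALSE])^2)
  }
  attr(out, "index") <- idx
  out
}

#' Trimmed iterative closest point refinement
#'
#' Refines an initial rigid transform by point-to-point ICP: at each
#' iteration, source points (moved by the current transform) are matched
#' to their nearest target points, the worst `trim_fraction` of matches
#' by distance are discarded (robustness against partial overlap of the
#' interventional reconstruction), and the optimal rigid fit for the
#' kept pairs is computed in closed form from the SVD of the
#' cross-covariance. Iteration stops when the trimmed RMS improves by
#' less than `tol` or after `max_iter` iterations.
#'
#' @param source,target n x 3 point matrices (mm).
#' @param init initial [rigid_transform()] (e.g. from [coarse_align()]).
#' @param max_iter iteration cap.
#' @param tol RMS improvement threshold, mm.
#' @param trim_fraction fraction of worst correspondences discarded per
#'   iteration; 0 gives classic untrimmed ICP.
#' @return List: `transform` (composed with `init`), `rms` (final
#'   trimmed RMS, mm), `iterations`, and the per-iteration `rms_trace`.
#' @export
icp_refine <- function(source, target, init = rigid_transform(),
                       max_iter = 100, tol = 1e-4, trim_fraction = 0.2) {
  source <- as_points(source); target <- as_points(target)
  if (!all(is.finite(source)) || !all(is.finite(target)))
    stop("point clouds contain non-finite coordinates")
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must be in [0, 1)")
  tf <- init
  n_keep <- max(3L, floor((1 - trim_fraction) * nrow(source)))
  prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    moved <- transform_points(tf, source)
    d2 <- nn_dist2(moved, target)
    jj <- attr(d2, "index")
    keep <- order(d2)[seq_len(n_keep)]
    p <- source[keep, , drop = FALSE]
    q <- target[jj[keep], , drop = FALSE]
    rms <- sqrt(mean(d2[keep]))
    trace <- c(trace, rms)
    if (prev - rms < tol && it > 1) break
    prev <- rms
    tf <- kabsch_fit(p, q)
  }
  list(transform = tf, rms = rms, iterations = it, rms_trace = trace)
}

# Closed-form least-squares rigid fit R p + t ~ q (Kabsch/Umeyama).
#' @keywords internal
kabsch_fit <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  sv <- svd(H)
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, qc - as.numeric(R %*% pc))
}

#' Two-stage registration to an interventional surface
#'
#' Runs [coarse_align()] followed by [icp_refine()], mirroring the
#' interventional workflow of a rough anatomy-based fusion refined on
#' the epicardial contour. The ventricular surface is close to a
#' surface of revolution, so the ICP cost is shallow along rotations
#' about the long axis and point-to-point ICP can settle a few degrees
#' off; by default a multi-start sweep probes small rotations about the
#' target's principal axes with short trimmed-ICP runs on subsampled
#' clouds and full refinement starts from the basin with the lowest
#' trimmed RMS.
#'
#' @inheritParams icp_refine
#' @param multistart probe perturbed starts before the full refinement.
#' @param denoise_k smooth the target cloud by replacing each point with
#'   the mean of its `denoise_k` nearest neighbours before matching
#'   (standard surface denoising; the angiographic reconstruction is the
#'   noisy side). 0 disables.
#' @param ... passed to [icp_refine()].
#' @return As [icp_refine()], plus `coarse` (the initial transform).
#' @export
register_to_ra <- function(source, target, multistart = TRUE, denoise_k = 6, ...) {
  source <- as_points(source); target <- as_points(target)
  if (denoise_k > 0) target <- knn_smooth(target, denoise_k)
  coarse <- init <- coarse_align(source, target)
  dots <- list(...)
  trim <- dots$trim_fraction %||% 0.2
  if (multistart) {
    ctr <- colMeans(target)
    axes <- eigen(stats::cov(target), symmetric = TRUE)$vectors
    ssub <- subsample_rows(source, 800)
    tsub <- subsample_rows(target, 1000)
    cands <- list(init)
    for (ax in 1:3) for (ang in c(-8, -5, -2.5, 2.5, 5, 8)) {
      R <- rotation_axis_angle(axes[, ax], ang)
      pert <- rigid_transform(R, ctr - as.numeric(R %*% ctr))
      cands[[length(cands) + 1]] <- compose_transforms(pert, init)
    }
    probes <- lapply(cands, function(tf)
      icp_refine(ssub, tsub, init = tf, max_iter = 20, tol = 1e-3,
                 trim_fraction = trim))
    # fully refine the few most promising basins; keep the best by RMS
    top <- order(vapply(probes, `[[`, numeric(1), "rms"))[1:3]
    runs <- lapply(top, function(i)
      icp_refine(source, target, init = probes[[i]]$transform, ...))
    out <- runs[[which.min(vapply(runs, `[[`, numeric(1), "rms"))]]
    out$coarse <- coarse
    return(out)
  }
  out <- icp_refine(source, target, init = init, ...)
  out$coarse <- coarse
  out
}

# Replace each point by the mean of its k nearest neighbours (self
# included), chunked to bound memory.
#' @keywords internal
knn_smooth <- function(p, k = 6, chunk = 1500L) {
  n <- nrow(p)
  k <- min(k, n)
  out <- matrix(0, n, 3)
  pp <- rowSums(p^2)
  for (st in seq(1, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    d2 <- outer(pp[st:en], pp, "+") - 2 * tcrossprod(p[st:en, , drop = FALSE], p)
    for (i in seq_len(en - st + 1L)) {
      nb <- order(d2[i, ])[seq_len(k)]
      out[st + i - 1L, ] <- colMeans(p[nb, , drop = FALSE])
    }
  }
  out
}

# Rodrigues rotation about a unit axis, angle in degrees.
#' @keywords internal
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
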