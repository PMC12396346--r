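#' Three-dimensional image stack
#'
#' A confocal stack stored as a (z, y, x) array of non-negative
#' intensities with an anisotropic physical voxel size in micrometers
#' (confocal stacks typically have coarser z steps, e.g. 0.15 um z against
#' 0.1 um in-plane).
#'
#' @param intensities numeric 3D array indexed (z, y, x).
#' @param voxel_size numeric length-3 `(dz, dy, dx)` in micrometers, all
#'   positive.
#' @param channel channel label, e.g. `"presynaptic"`.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(intensities, voxel_size, channel = "unnamed") {
  assert_that(is.array(intensities) && length(dim(intensities)) == 3,
              "intensities must be a 3D (z, y, x) array")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be three positive numbers (dz, dy, dx)")
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("ImageStack '%s': %d x %d x %d (z,y,x), voxel %s um\n",
              x$channel, d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Channel-labeled puncta coordinates
#'
#' Point set of detected or simulated puncta in physical micrometer
#' coordinates.
#'
#' @param coords numeric matrix with columns `x_um`, `y_um`, `z_um`.
#' @param channel channel label, e.g. `"presynaptic"` (VAChT) or
#'   `"postsynaptic"` (CHRM1/3).
#' @param intensities optional peak intensities, one per punctum.
#' @return an object of class `PunctaSet`.
#' @export
puncta_set <- function(coords, channel = "unnamed", intensities = NULL) {
  coords <- if (is.null(coords)) matrix(numeric(0), 0, 3) else as.matrix(coords)
  if (nrow(coords) > 0) {
    assert_that(ncol(coords) == 3 && is.numeric(coords) && !anyNA(coords),
                "coords must be a numeric n x 3 matrix (x_um, y_um, z_um)")
  } else {
    coords <- matrix(numeric(0), 0, 3)
  }
  colnames(coords) <- c("x_um", "y_um", "z_um")
  if (!is.null(intensities)) {
    assert_that(length(intensities) == nrow(coords),
                "intensities must match the number of puncta")
  }
  structure(list(coords = coords, channel = as.character(channel),
                 intensities = intensities),
            class = "PunctaSet")
}

#' @export
print.PunctaSet <- function(x, ...) {
  cat(sprintf("PunctaSet '%s': %d puncta\n", x$channel, nrow(x$coords)))
  invisible(x)
}

# pad a matrix by edge replication and return the (dy, dx)-shifted view
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# disk-support structuring element for grayscale opening; heights are 0
# (flat disk): the ball's intensity-axis curvature would depend on an
# arbitrary pixel-to-intensity scaling, whereas the flat disk is scale-free
# and preserves any blob narrower than the disk essentially exactly
ball_offsets <- function(r_px) {
  d <- expand.grid(dy = -floor(r_px):floor(r_px),
                   dx = -floor(r_px):floor(r_px))
  d <- d[d$dy^2 + d$dx^2 <= r_px^2, ]
  d$h <- 0
  d
}

ball_erode <- function(m, off) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- pmin(out, shift_mat(m, off$dy[i], off$dx[i]) - off$h[i])
  }
  out
}

ball_dilate <- function(m, off) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- pmax(out, shift_mat(m, -off$dy[i], -off$dx[i]) + off$h[i])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of each z-plane by grayscale
#' morphological opening over a disk of the given ball radius (the
#' rolling-ball family of background estimators, applied in 2D per plane
#' as is standard for confocal stacks; a flat disk is used because the
#' ball's intensity-axis curvature depends on an arbitrary
#' intensity-to-pixel scaling, and the flat disk preserves sub-disk blobs
#' essentially exactly) and subtracts it. The radius is given in
#' micrometers and converted to in-plane pixels via the voxel size (the
#' mean of the y and x pixel sizes). Output is clipped at zero. A
#' constant image maps to all zeros; blobs smaller than the disk are
#' preserved.
#'
#' @param stack an [image_stack()].
#' @param radius_um ball radius in micrometers; must be at least 2 pixels
#'   and should exceed the largest blob scale.
#' @return the background-subtracted `ImageStack`.
#' @export
rolling_ball_subtract <- function(stack, radius_um) {
  assert_that(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  px <- mean(stack$voxel_size[2:3])
  r_px <- radius_um / px
  if (r_px < 2) abort("rolling-ball radius is below 2 pixels (", signif(r_px, 3),
                      "); increase radius_um")
  off <- ball_offsets(r_px)
  arr <- stack$intensities
  for (iz in seq_len(dim(arr)[1])) {
    plane <- arr[iz, , ]
    bg <- ball_dilate(ball_erode(plane, off), off)
    arr[iz, , ] <- pmax(plane - bg, 0)
  }
  out <- stack
  out$intensities <- arr
  out
}

# 1D Gaussian kernel, truncated at 3 sigma, renormalized
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-h:h)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# separable convolution along one axis of a 3D array, edge replication
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  h <- (length(kernel) - 1L) / 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    idx <- pmin(pmax(seq_len(n) + (j - 1L - h), 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

gaussian_blur3d <- function(arr, sigma_px) {
  for (axis in 1:3) {
    arr <- conv_axis(arr, gauss_kernel(sigma_px[axis]), axis)
  }
  arr
}

#' Difference-of-Gaussians puncta detection
#'
#' Band-pass filters the stack with a difference of two Gaussian blurs at
#' physical scales `sigma_um` and `k * sigma_um` (each converted per axis
#' to voxels, so anisotropic stacks are handled correctly) and reports
#' local maxima of the response above `min_peak`. The response is
#' normalized so that an ideal Gaussian blob of scale `sigma_um` and peak
#' amplitude A yields a response of about A regardless of `sigma_um`,
#' making `min_peak` comparable across scales. Peak coordinates are voxel
#' centers in micrometers (no subpixel refinement); maxima within one
#' sigma of any stack border are discarded.
#'
#' @param stack an [image_stack()].
#' @param sigma_um blob scale in micrometers; must exceed the voxel size
#'   on every axis.
#' @param k ratio of the two Gaussian scales (default 1.6).
#' @param min_peak detection threshold on the normalized DoG response.
#' @return a [puncta_set()] with the stack's channel label.
#' @export
dog_detect <- function(stack, sigma_um, k = 1.6, min_peak) {
  assert_that(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  assert_that(is_number(sigma_um) && sigma_um > 0, "sigma_um must be > 0")
  assert_that(is_number(k) && k > 1, "k must be > 1")
  d <- dim(stack$intensities)
  if (any(d == 0)) return(puncta_set(NULL, channel = stack$channel))
  sig_px <- sigma_um / stack$voxel_size     # (z, y, x) voxels
  assert_that(all(sig_px >= 1),
              "sigma_um must exceed the voxel size on every axis")
  g1 <- gaussian_blur3d(stack$intensities, sig_px)
  g2 <- gaussian_blur3d(stack$intensities, k * sig_px)
  # amplitude of the DoG response at the center of a matched Gaussian blob
  norm <- (1 / 2)^(3 / 2) - (1 / (1 + k^2))^(3 / 2)
  dog <- (g1 - g2) / norm
  peaks <- local_maxima3d(dog) & dog >= min_peak
  # discard border maxima within one sigma of any edge
  border <- pmax(1L, ceiling(sig_px))
  idx <- which(peaks, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ok <- idx[, 1] > border[1] & idx[, 1] <= d[1] - border[1] &
          idx[, 2] > border[2] & idx[, 2] <= d[2] - border[2] &
          idx[, 3] > border[3] & idx[, 3] <= d[3] - border[3]
    idx <- idx[ok, , drop = FALSE]
  }
  coords <- cbind(x_um = (idx[, 3] - 0.5) * stack$voxel_size[3],
                  y_um = (idx[, 2] - 0.5) * stack$voxel_size[2],
                  z_um = (idx[, 1] - 0.5) * stack$voxel_size[1])
  puncta_set(coords, channel = stack$channel,
             intensities = dog[idx])
}

# strict 26-neighborhood local maxima of a 3D array
local_maxima3d <- function(arr) {
  d <- dim(arr)
  res <- array(TRUE, d)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pad[(2 + dz):(d[1] + 1 + dz),
              (2 + dy):(d[2] + 1 + dy),
              (2 + dx):(d[3] + 1 + dx)]
    res <- res & (arr > nb)
  }
  res
}

#' Proximity colocalization of two puncta channels
#'
#' For each postsynaptic (glioma) punctum, finds whether any presynaptic
#' (neuron) punctum lies within `threshold` micrometers (3D Euclidean
#' distance in physical units; inclusive boundary) and reports the count
#' and percentage. The default implementation bins presynaptic points
#' into a uniform grid with cell edge equal to the threshold so only 27
#' neighboring cells are searched per query, which is exact for the
#' within-threshold decision; `method = "exhaustive"` computes all pairs.
#'
#' @param post postsynaptic [puncta_set()] (the scored channel).
#' @param pre presynaptic [puncta_set()].
#' @param threshold proximity threshold in micrometers (default 1.5).
#' @param method `"grid"` (default) or `"exhaustive"`.
#' @param projection `"3d"` (default) or `"2d"` (distances ignore z).
#' @return an object of class `ColocResult`: list with `n_post`,
#'   `n_within`, `percent`, `threshold`.
#' @export
coloc_percentage <- function(post, pre, threshold = 1.5,
                             method = c("grid", "exhaustive"),
                             projection = c("3d", "2d")) {
  method <- match.arg(method)
  projection <- match.arg(projection)
  assert_that(is_number(threshold) && threshold > 0, "threshold must be > 0")
  pc <- if (inherits(post, "PunctaSet")) post$coords else as.matrix(post)
  qc <- if (inherits(pre, "PunctaSet")) pre$coords else as.matrix(pre)
  if (nrow(pc) == 0) abort("no postsynaptic puncta")
  if (projection == "2d") {
    pc <- pc[, 1:2, drop = FALSE]
    qc <- qc[, 1:2, drop = FALSE]
  }
  if (nrow(qc) == 0) {
    warning("presynaptic set is empty; reporting 0%")
    n_within <- 0L
  } else if (method == "exhaustive") {
    n_within <- sum(vapply(seq_len(nrow(pc)), function(i) {
      min(sqrt(colSums((t(qc) - pc[i, ])^2))) <= threshold
    }, logical(1)))
  } else {
    n_within <- coloc_count_grid(pc, qc, threshold)
  }
  structure(list(n_post = nrow(pc), n_within = as.integer(n_within),
                 percent = 100 * n_within / nrow(pc),
                 threshold = threshold),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: %d / %d puncta within %.3g um (%.2f%%)\n",
              x$n_within, x$n_post, x$threshold, x$percent))
  invisible(x)
}

# exact within-threshold counting via uniform grid hashing
coloc_count_grid <- function(pc, qc, threshold) {
  nd <- ncol(pc)
  key <- function(cells) apply(cells, 1, paste, collapse = ",")
  qcell <- floor(sweep(qc, 2, rep(threshold, nd), "/"))
  lut <- split(seq_len(nrow(qc)), key(qcell))
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  thr2 <- threshold^2
  count <- 0L
  pcell <- floor(sweep(pc, 2, rep(threshold, nd), "/"))
  for (i in seq_len(nrow(pc))) {
    found <- FALSE
    for (j in seq_len(nrow(offs))) {
      k <- paste(pcell[i, ] + offs[j, ], collapse = ",")
      cand <- lut[[k]]
      if (is.null(cand)) next
      d2 <- colSums((t(qc[cand, , drop = FALSE]) - pc[i, ])^2)
      if (any(d2 <= thr2)) { found <- TRUE; break }
    }
    if (found) count <- count + 1L
  }
  count
}

#' Detect and colocalize a two-channel stack pair
#'
#' The full imaging quantification: rolling-ball background subtraction
#' on each channel, difference-of-Gaussians detection per channel, then
#' proximity colocalization of the postsynaptic detections against the
#' presynaptic ones.
#'
#' @param stack_pre,stack_post [image_stack()] pair sharing voxel size
#'   and extent.
#' @param radius_um rolling-ball radius in micrometers.
#' @param sigma_um DoG blob scale in micrometers.
#' @param k DoG scale ratio (default 1.6).
#' @param min_peak DoG detection threshold.
#' @param threshold colocalization threshold in micrometers (default 1.5).
#' @param projection `"3d"` or `"2d"`, see [coloc_percentage()].
#' @return list with `coloc` (a `ColocResult`), `pre` and `post`
#'   (`PunctaSet`s of the detections).
#' @export
quantify_pair <- function(stack_pre, stack_post, radius_um, sigma_um,
                          k = 1.6, min_peak, threshold = 1.5,
                          projection = "3d") {
  assert_that(identical(dim(stack_pre$intensities),
                        dim(stack_post$intensities)) &&
                identical(stack_pre$voxel_size, stack_post$voxel_size),
              "stacks must share extent and voxel size")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("quantify_pair failed at stage '", name, "': ",
            conditionMessage(e))
    })
  }
  pre_bg <- stage("rolling_ball[pre]", rolling_ball_subtract(stack_pre, radius_um))
  post_bg <- stage("rolling_ball[post]", rolling_ball_subtract(stack_post, radius_um))
  pre <- stage("dog_detect[pre]", dog_detect(pre_bg, sigma_um, k, min_peak))
  post <- stage("dog_detect[post]", dog_detect(post_bg, sigma_um, k, min_peak))
  coloc <- stage("coloc_percentage",
                 coloc_percentage(post, pre, threshold,
                                  projection = projection))
  list(coloc = coloc, pre = pre, post = post)
}
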