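#' Maximum-intensity projection of an image stack
#'
#' @param stack Non-empty list of numeric matrices of equal dimensions.
#' @return A matrix: the pixelwise maximum over the stack.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0)
    stop("stack must be a non-empty list of matrices")
  dims <- dim(stack[[1]])
  out <- stack[[1]]
  for (fr in stack[-1]) {
    if (!identical(dim(fr), dims))
      stop("all frames in the stack must share the same dimensions")
    out <- pmax(out, fr)
  }
  out
}

#' Gaussian blur (separable convolution, replicate padding)
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels; 0 returns `img` unchanged.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    idx <- vapply(seq_len(n),
                  function(i) as.integer(pmin(pmax(i + seq(-rad, rad), 1), n)),
                  integer(2 * rad + 1))
    if (along_rows) {
      out <- matrix(0, nrow(m), ncol(m))
      for (s in seq_along(k)) out <- out + k[s] * m[idx[s, ], , drop = FALSE]
      out
    } else {
      out <- matrix(0, nrow(m), ncol(m))
      for (s in seq_along(k)) out <- out + k[s] * m[, idx[s, ], drop = FALSE]
      out
    }
  }
  conv1(conv1(img, TRUE), FALSE)
}

#' Adaptive (local-mean) threshold
#'
#' A pixel is foreground when it exceeds the mean of its square
#' neighbourhood (clipped at the image border) by more than `offset`.
#'
#' @param img Numeric matrix.
#' @param window Odd window size in pixels.
#' @param offset Additive offset on the local mean.
#' @return Logical matrix (TRUE = foreground).
#' @export
adaptive_threshold <- function(img, window, offset = 0) {
  if (window < 1 || window %% 2 == 0) stop("window must be a positive odd integer")
  r <- (window - 1) / 2
  nr <- nrow(img)
  nc <- ncol(img)
  # integral image with zero padding; windows clipped at borders
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  r1 <- pmax(outer(seq_len(nr), rep(1L, nc)) - r, 1)
  r2 <- pmin(outer(seq_len(nr), rep(1L, nc)) + r, nr)
  c1 <- pmax(outer(rep(1L, nr), seq_len(nc)) - r, 1)
  c2 <- pmin(outer(rep(1L, nr), seq_len(nc)) + r, nc)
  sums <- ii[cbind(as.vector(r2 + 1), as.vector(c2 + 1))] -
    ii[cbind(as.vector(r1), as.vector(c2 + 1))] -
    ii[cbind(as.vector(r2 + 1), as.vector(c1))] +
    ii[cbind(as.vector(r1), as.vector(c1))]
  areas <- (r2 - r1 + 1) * (c2 - c1 + 1)
  local_mean <- matrix(sums, nr, nc) / areas
  img > local_mean + offset
}

.find_markers <- function(dist, min_dist) {
  rad <- max(1L, as.integer(round(min_dist)))
  mx <- .box_max_cpp(dist, rad)
  peaks <- (dist > 0) & (dist >= mx)
  .cc_label_cpp(peaks, 8L)
}

#' Segment nuclei in a 2D grayscale frame
#'
#' The fixed pipeline: Gaussian blur, adaptive local-mean threshold,
#' Euclidean distance transform of the foreground, inversion, and
#' marker-driven watershed on the inverted transform restricted to the
#' foreground, with markers at local maxima of the distance transform
#' (minimum peak separation `peak_min_dist`). Components smaller than
#' `min_area` are discarded and the surviving labels renumbered 1..n. A
#' circle is fitted per label: centre at the intensity-weighted centroid
#' (weights from the original frame), radius `sqrt(area / pi)`.
#'
#' @param frame Numeric matrix of intensities.
#' @param blur_sigma Gaussian blur s.d. in pixels.
#' @param min_area Minimum component area in pixels.
#' @param nucleus_diam Expected nucleus diameter in pixels; sets the default
#'   threshold window (4 diameters) and peak separation (1 radius).
#' @param threshold_window Odd adaptive-threshold window; default
#'   `4 * nucleus_diam + 1`.
#' @param threshold_offset Adaptive-threshold offset; default (`NULL`) is
#'   2\% of the frame's intensity range. With offset 0 every flat noisy
#'   region puts ~half its pixels above the local mean, flooding sparse
#'   frames with speckle components, so a small data-driven offset is the
#'   working default; pass 0 explicitly for the strict local-mean rule.
#' @param peak_min_dist Minimum separation of watershed seeds in pixels;
#'   default `nucleus_diam / 2`.
#' @return List with `mask` (integer label matrix) and `detections`
#'   (data.frame `label`, `x`, `y` 0-based pixel centre, `radius`, `area`).
#'   A blank frame yields zero detections, not an error.
#' @export
segment_nuclei <- function(frame, blur_sigma = 2, min_area = 9,
                           nucleus_diam = 8, threshold_window = NULL,
                           threshold_offset = NULL, peak_min_dist = NULL) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), min_area >= 1)
  if (is.null(threshold_window)) {
    threshold_window <- 4 * nucleus_diam + 1
    if (threshold_window %% 2 == 0) threshold_window <- threshold_window + 1
  }
  if (is.null(threshold_offset))
    threshold_offset <- 0.02 * diff(range(frame))
  if (is.null(peak_min_dist)) peak_min_dist <- nucleus_diam / 2
  blurred <- gaussian_blur(frame, blur_sigma)
  fg <- adaptive_threshold(blurred, threshold_window, threshold_offset)
  if (!any(fg))
    return(list(mask = matrix(0L, nrow(frame), ncol(frame)),
                detections = .empty_detections()))
  dist <- .edt_cpp(fg)
  markers <- .find_markers(dist, peak_min_dist)
  lab <- .watershed_cpp(-dist, markers, fg)
  lab <- .filter_relabel(lab, min_area)
  list(mask = lab, detections = .detections_from_mask(lab, frame))
}

.empty_detections <- function() {
  data.frame(label = integer(0), x = numeric(0), y = numeric(0),
             radius = numeric(0), area = integer(0))
}

.filter_relabel <- function(lab, min_area) {
  if (!any(lab > 0)) return(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0
  lab[pos] <- remap[lab[pos]]
  lab
}

.detections_from_mask <- function(lab, frame) {
  labs <- sort(unique(lab[lab > 0]))
  if (!length(labs)) return(.empty_detections())
  rows <- lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    w <- frame[idx]
    if (sum(w) <= 0) w <- rep(1, nrow(idx))
    data.frame(label = l,
               x = stats::weighted.mean(idx[, 2] - 1, w),
               y = stats::weighted.mean(idx[, 1] - 1, w),
               radius = sqrt(nrow(idx) / pi),
               area = nrow(idx))
  })
  do.call(rbind, rows)
}

#' Programmatic curation of a segmentation mask
#'
#' Mirrors the manual corrections applied to over- and under-segmentation:
#' `merge` relabels `b`'s pixels to `a` (background is never touched),
#' `delete` clears a label to background, and `split` re-runs a
#' marker-driven watershed inside one label's support, conserving its pixel
#' support while increasing the label count by `nrow(markers) - 1`.
#'
#' @param mask Integer label matrix.
#' @param action `"merge"`, `"split"` or `"delete"`.
#' @param a,b Labels to merge (`b` into `a`).
#' @param label Label to split or delete.
#' @param markers For `split`: a matrix/data.frame with columns `x`, `y`
#'   (0-based pixel coordinates) lying inside `label`'s support.
#' @return The edited label matrix (new labels renumbered consecutively
#'   after the current maximum for `split`).
#' @export
edit_labels <- function(mask, action = c("merge", "split", "delete"),
                        a = NULL, b = NULL, label = NULL, markers = NULL) {
  action <- match.arg(action)
  present <- unique(mask[mask > 0])
  need <- function(l, what) {
    if (is.null(l)) stop("missing ", what)
    if (!l %in% present) stop(sprintf("label %d not present in mask", l))
  }
  if (action == "merge") {
    need(a, "label 'a'"); need(b, "label 'b'")
    mask[mask == b] <- as.integer(a)
    return(mask)
  }
  if (action == "delete") {
    need(label, "'label'")
    mask[mask == label] <- 0L
    return(mask)
  }
  need(label, "'label'")
  if (is.null(markers) || nrow(markers) < 2)
    stop("split needs at least two markers")
  mk <- as.matrix(markers[, c("x", "y")])
  sup <- mask == label
  ri <- as.integer(mk[, "y"]) + 1L
  ci <- as.integer(mk[, "x"]) + 1L
  inside <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
  inside[inside] <- sup[cbind(ri[inside], ci[inside])]
  if (!all(inside))
    stop("all split markers must lie inside the label's support")
  seed <- matrix(0L, nrow(mask), ncol(mask))
  new_ids <- max(mask) + seq_len(nrow(mk))
  seed[cbind(ri, ci)] <- as.integer(new_ids)
  dist <- .edt_cpp(sup)
  sub <- .watershed_cpp(-dist, seed, sup)
  mask[sup] <- sub[sup]
  # keep the first fragment under the original label for continuity
  mask[mask == new_ids[1]] <- as.integer(label)
  mask
}
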