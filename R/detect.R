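# Spot detection: difference-of-Gaussians bandpass, local maxima,
# intensity-weighted sub-pixel centroids, size/intensity gating.

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable Gaussian blur with replicate padding.
gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  pad_conv <- function(v) {
    vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
    stats::convolve(vp, rev(k), type = "filter")
  }
  tmp <- apply(img, 2L, pad_conv)          # along rows (y)
  t(apply(tmp, 1L, pad_conv))              # along columns (x)
}

#' Detect diffraction-limited spots in one frame
#'
#' Bandpass (difference-of-Gaussians) filtering followed by local-maximum
#' candidate selection, intensity-weighted sub-pixel centroid refinement
#' against a local median background, and uniform gating on integrated
#' intensity and apparent size.
#'
#' @param frame Numeric matrix `[y, x]` in counts.
#' @param band_low,band_high Bandpass sigmas in pixels
#'   (`band_low < band_high`); spots of width ~`band_low` pass, structures
#'   larger than `band_high` are suppressed.
#' @param intensity_min Minimum integrated (background-subtracted)
#'   intensity, counts.
#' @param size_max Maximum apparent spot diameter, pixels.
#' @param pixel_size Micrometers per pixel (default 0.105).
#' @param dog_k Candidate threshold in robust SDs of the filtered image
#'   (default 5).
#' @param border_px Exclusion border in pixels (default 0): localizations
#'   closer than this to the frame edge are discarded, since a clipped
#'   point spread function biases both the centroid and the integrated
#'   intensity.
#' @return Data frame with `x_px`, `y_px` (0-based pixel coordinates),
#'   `x_um`, `y_um`, `intensity`, `diameter_px`; zero rows when nothing
#'   passes.
#' @export
detect_spots <- function(frame, band_low = 1, band_high = 3,
                         intensity_min = 50, size_max = 6,
                         pixel_size = 0.105, dog_k = 5, border_px = 0) {
  if (band_low >= band_high) {
    stop_smkin("band_low must be < band_high", "smkin_invalid_parameter")
  }
  if (max(frame) >= 65535) {
    warn_smkin("frame contains saturated pixels", "smkin_saturated")
  }
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), diameter_px = numeric(0))
  ny <- nrow(frame); nx <- ncol(frame)
  dog <- gaussian_blur(frame, band_low) - gaussian_blur(frame, band_high)
  thr <- dog_k * max(stats::mad(dog), 1e-12)

  # Interior local maxima over the 8-neighborhood, above threshold.
  ctr <- dog[2:(ny - 1), 2:(nx - 1)]
  is_max <- ctr > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- dog[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    is_max <- is_max & (ctr >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  rows <- idx[, 1L] + 1L; cols <- idx[, 2L] + 1L

  w <- max(2L, ceiling(band_high))
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r0 <- max(1L, rows[i] - w); r1 <- min(ny, rows[i] + w)
    c0 <- max(1L, cols[i] - w); c1 <- min(nx, cols[i] + w)
    win <- frame[r0:r1, c0:c1, drop = FALSE]
    border <- c(win[1L, ], win[nrow(win), ], win[, 1L], win[, ncol(win)])
    sig <- pmax(win - stats::median(border), 0)
    tot <- sum(sig)
    if (tot < intensity_min) next
    yy <- (r0:r1) - 1L; xx <- (c0:c1) - 1L  # 0-based pixel coords
    cy <- sum(rowSums(sig) * yy) / tot
    cx <- sum(colSums(sig) * xx) / tot
    m2 <- (sum(rowSums(sig) * (yy - cy)^2) +
           sum(colSums(sig) * (xx - cx)^2)) / tot
    diam <- 2 * sqrt(max(m2, 0))
    if (diam > size_max) next
    out[[i]] <- data.frame(x_px = cx, y_px = cy,
                           x_um = cx * pixel_size, y_um = cy * pixel_size,
                           intensity = tot, diameter_px = diam)
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  if (border_px > 0) {
    inside <- res$x_px >= border_px & res$x_px <= nx - 1L - border_px &
              res$y_px >= border_px & res$y_px <= ny - 1L - border_px
    res <- res[inside, , drop = FALSE]
    if (!nrow(res)) return(empty)
  }
  # Merge duplicate maxima that refined to the same centroid (< 1 px apart).
  if (nrow(res) > 1L) {
    keep <- rep(TRUE, nrow(res))
    ord <- order(-res$intensity)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      d <- sqrt((res$x_px - res$x_px[i])^2 + (res$y_px - res$y_px[i])^2)
      dup <- which(d < 1 & keep & seq_len(nrow(res)) != i)
      keep[dup] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Detect spots in every frame of a stack
#'
#' @param stack A `frame_stack` (array `[y, x, frame]`).
#' @param ... Passed to [detect_spots()].
#' @return Data frame with a 0-based `frame` column prepended.
#' @export
detect_spots_stack <- function(stack, ...) {
  nf <- dim(stack)[3]
  res <- lapply(seq_len(nf), function(f) {
    d <- detect_spots(stack[, , f], ...)
    if (nrow(d)) cbind(frame = f - 1L, d) else NULL
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) {
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      diameter_px = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
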