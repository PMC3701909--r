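# Two-channel fiducial registration: polynomial coordinate maps fitted to
# bead fields, used to read second-channel intensities at first-channel
# anchor positions.

poly_terms <- function(order) {
  if (order == 1L) c("1", "x", "y")
  else c("1", "x", "y", "x2", "xy", "y2")
}

poly_design <- function(xy, order) {
  x <- xy[, 1L]; y <- xy[, 2L]
  if (order == 1L) cbind(1, x, y)
  else cbind(1, x, y, x^2, x * y, y^2)
}

#' Fit a polynomial map between two camera channels
#'
#' Least-squares fit of `x' = P(x, y)`, `y' = Q(x, y)` with P, Q polynomials
#' of order 1 (affine) or 2, from matched fiducial bead coordinates. The
#' residual RMS (per-point Euclidean residual) is reported; a warning is
#' raised when it exceeds one pixel (0.105 um), the registration quality
#' the downstream colocalization criterion assumes.
#'
#' @param src,dst Two-column matrices (or data frames) of matched
#'   coordinates in micrometers, one row per bead.
#' @param order Polynomial order, 1 or 2 (default 2).
#' @return Object of class `channel_map`: `order`, `coef_x`, `coef_y`
#'   (named by term), `residual_rms_um`, `n_fiducials`.
#' @examples
#' src <- cbind(runif(30, 0, 50), runif(30, 0, 50))
#' m <- fit_channel_map(src, src + 0.2, order = 1)
#' m$residual_rms_um
#' @export
fit_channel_map <- function(src, dst, order = 2L) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) {
    stop_smkin("order must be 1 or 2", "smkin_invalid_parameter")
  }
  if (nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L) {
    stop_smkin("src and dst must be matched two-column coordinate sets",
               "smkin_schema")
  }
  if (anyDuplicated(src)) {
    stop_smkin("duplicated source points", "smkin_invalid_parameter")
  }
  n_coef <- length(poly_terms(order))
  if (nrow(src) < n_coef) {
    stop_smkin(sprintf(
      "underdetermined: %d beads for %d coefficients per coordinate",
      nrow(src), n_coef), "smkin_underdetermined")
  }
  A <- poly_design(src, order)
  qr_A <- qr(A)
  if (qr_A$rank < n_coef) {
    stop_smkin("rank-deficient design (degenerate bead geometry)",
               "smkin_rank_deficient")
  }
  cx <- qr.coef(qr_A, dst[, 1L])
  cy <- qr.coef(qr_A, dst[, 2L])
  pred <- cbind(A %*% cx, A %*% cy)
  res2 <- rowSums((dst - pred)^2)
  rms <- sqrt(mean(res2))
  if (rms > 0.105) {
    warn_smkin(sprintf(
      "registration residual RMS %.3g um exceeds one pixel (0.105 um)", rms),
      "smkin_poor_registration")
  }
  structure(list(order = order,
                 coef_x = stats::setNames(as.numeric(cx), poly_terms(order)),
                 coef_y = stats::setNames(as.numeric(cy), poly_terms(order)),
                 residual_rms_um = rms,
                 n_fiducials = nrow(src)),
            class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf(
    "<channel_map> order %d, %d fiducials, residual RMS %.4g um\n",
    x$order, x$n_fiducials, x$residual_rms_um))
  invisible(x)
}

#' Identity channel map
#'
#' @param order Polynomial order, 1 or 2.
#' @return A `channel_map` mapping every point to itself.
#' @export
identity_channel_map <- function(order = 1L) {
  terms <- poly_terms(order)
  cx <- stats::setNames(numeric(length(terms)), terms)
  cy <- cx
  cx["x"] <- 1; cy["y"] <- 1
  structure(list(order = as.integer(order), coef_x = cx, coef_y = cy,
                 residual_rms_um = 0, n_fiducials = 0L),
            class = "channel_map")
}

#' Apply a channel map to coordinates
#'
#' @param map A `channel_map`.
#' @param coords Two-column matrix/data frame of coordinates, micrometers.
#' @return Matrix of mapped coordinates, same shape.
#' @export
apply_channel_map <- function(map, coords) {
  stopifnot(inherits(map, "channel_map"))
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) {
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  A <- poly_design(coords, map$order)
  out <- cbind(A %*% map$coef_x, A %*% map$coef_y)
  colnames(out) <- c("x", "y")
  out
}

#' Simulate a fiducial bead field in two channels
#'
#' Scatters beads uniformly over the field and produces their coordinates
#' in a second channel through a known transform plus isotropic Gaussian
#' localization noise, mirroring the multicolor bead acquisitions used to
#' register two cameras.
#'
#' @param n_beads Number of beads; must be at least the coefficient count
#'   of `transform`.
#' @param transform A `channel_map` giving the true channel-to-channel
#'   distortion.
#' @param loc_noise Localization noise SD per axis, micrometers.
#' @param field Extent `c(width, height)` in micrometers.
#' @param seed Integer seed.
#' @return List with matrices `src` and `dst` (n_beads x 2, micrometers).
#' @export
simulate_bead_field <- function(n_beads, transform, loc_noise = 0.010,
                                field = c(67.2, 67.2), seed = NULL) {
  stopifnot(inherits(transform, "channel_map"))
  n_coef <- length(poly_terms(transform$order))
  if (!is_count(n_beads) || n_beads < n_coef) {
    stop_smkin(sprintf(
      "n_beads must be >= %d for an order-%d transform",
      n_coef, transform$order), "smkin_underdetermined")
  }
  with_seed(seed, {
    src <- cbind(stats::runif(n_beads, 0, field[1]),
                 stats::runif(n_beads, 0, field[2]))
    dst <- apply_channel_map(transform, src) +
      matrix(stats::rnorm(2L * n_beads, 0, loc_noise), ncol = 2L)
    colnames(src) <- c("x", "y")
    list(src = src, dst = dst)
  })
}
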