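# Preprocessing arms: frame registration, averaging, classical denoisers.

# Estimate the translation of `frame` relative to `ref` by Fourier phase
# correlation with parabolic sub-pixel refinement. Returns c(dr, dc) such
# that shift_image(frame, dr, dc) best aligns frame onto ref.
estimate_shift <- function(ref, frame, max_shift = 10, lowpass_sigma = 1.5) {
  a <- pixels_of(ref)
  b <- pixels_of(frame)
  if (!all(dim(a) == dim(b))) stop("frame dimensions differ", call. = FALSE)
  A <- stats::fft(a - mean(a))
  B <- stats::fft(b - mean(b))
  X <- A * Conj(B)
  X <- X / pmax(Mod(X), 1e-12)
  # Gaussian low-pass on the whitened cross-power spectrum: suppresses the
  # high frequencies where independent speckle dominates the phase
  if (lowpass_sigma > 0) {
    fr_ax <- function(n) {
      f <- seq_len(n) - 1
      f <- ifelse(f > n / 2, f - n, f) / n
      f^2
    }
    X <- X * exp(-2 * pi^2 * lowpass_sigma^2 *
      outer(fr_ax(nrow(a)), fr_ax(ncol(a)), "+"))
  }
  r <- Re(stats::fft(X, inverse = TRUE)) / length(a)
  peak <- arrayInd(which.max(r), dim(r))
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  nr <- nrow(a)
  nc <- ncol(a)
  # parabolic vertex offset along each axis, using cyclic neighbours
  sub <- function(vals) {
    y1 <- vals[1]; y2 <- vals[2]; y3 <- vals[3]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-12) 0 else clamp(0.5 * (y1 - y3) / den, -0.5, 0.5)
  }
  ri <- peak[1]; ci <- peak[2]
  cyc <- function(i, n) ((i - 1) %% n) + 1
  dr <- wrap(ri, nr) + sub(r[cyc(ri + c(-1, 0, 1), nr), ci])
  dc <- wrap(ci, nc) + sub(r[ri, cyc(ci + c(-1, 0, 1), nc)])
  d <- c(dr, dc)
  if (any(abs(d) > max_shift)) {
    warning(sprintf(
      "estimated shift (%.1f, %.1f) px exceeds max_shift = %g; treating frame as unshifted",
      d[1], d[2], max_shift
    ), call. = FALSE)
    d <- c(0, 0)
  }
  d
}

#' Register a frame stack by phase correlation
#'
#' Each frame is translated to maximise its cross-correlation with the
#' reference frame, at sub-pixel precision, using Fourier phase correlation
#' with parabolic peak refinement. Out-of-frame regions are filled by edge
#' replication. The reference frame is returned unchanged.
#'
#' @param frames list of [en_face_image()] with identical dimensions.
#' @param reference_index 1-based index of the reference frame.
#' @param max_shift shifts larger than this (pixels) are distrusted: a
#'   warning is issued and the frame is left unshifted.
#' @return the registered list, with the estimated per-frame shifts
#'   (rows `(dr, dc)`) attached as attribute `"shifts"`.
#' @export
register_frames <- function(frames, reference_index = 1, max_shift = 10) {
  if (length(frames) < 2) stop("need at least 2 frames to register", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  ref <- frames[[reference_index]]
  shifts <- matrix(0, length(frames), 2, dimnames = list(NULL, c("dr", "dc")))
  out <- frames
  for (i in seq_along(frames)) {
    if (i == reference_index) next
    d <- estimate_shift(ref, frames[[i]], max_shift = max_shift)
    if (max(abs(d)) < 1e-3) d <- c(0, 0) # below any meaningful resampling
    shifts[i, ] <- d
    if (any(d != 0)) {
      out[[i]] <- as_enface(shift_image(pixels_of(frames[[i]]), d[1], d[2]), frames[[i]])
    }
  }
  attr(out, "shifts") <- shifts
  out
}

#' Average a stack of registered frames
#'
#' Pixelwise arithmetic mean, computed in floating point; quantisation to
#' 8-bit happens only at export.
#'
#' @param frames non-empty list of [en_face_image()].
#' @return an [en_face_image()] with provenance `"averaged(n)"`.
#' @export
average_frames <- function(frames) {
  if (length(frames) == 0) stop("cannot average an empty frame list", call. = FALSE)
  acc <- pixels_of(frames[[1]])
  if (length(frames) > 1) {
    for (i in 2:length(frames)) acc <- acc + pixels_of(frames[[i]])
  }
  as_enface(acc / length(frames), frames[[1]],
    provenance = sprintf("averaged(%d)", length(frames))
  )
}

# --- denoisers ---------------------------------------------------------------

# 9-element median via a vectorised compare-exchange sorting network
# (full exchange sort; the median settles in the middle slot).
median9 <- function(stack) {
  for (i in 1:8) {
    for (j in 1:(9 - i)) {
      lo <- pmin(stack[[j]], stack[[j + 1]])
      hi <- pmax(stack[[j]], stack[[j + 1]])
      stack[[j]] <- lo
      stack[[j + 1]] <- hi
    }
  }
  stack[[5]]
}

median_filter <- function(px, radius = 1) {
  if (radius == 1) {
    offs <- expand.grid(dr = -1:1, dc = -1:1)
    stack <- lapply(seq_len(9), function(i) shift_int(px, offs$dr[i], offs$dc[i]))
    median9(stack)
  } else {
    nr <- nrow(px)
    nc <- ncol(px)
    offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    arr <- vapply(
      seq_len(nrow(offs)),
      function(i) shift_int(px, offs$dr[i], offs$dc[i]),
      px
    )
    matrix(apply(arr, c(1, 2), stats::median), nr, nc)
  }
}

gaussian_filter <- function(px, sigma) {
  if (sigma <= 0) return(px)
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  # separable convolution with edge replication via clamped index shifts
  tmp <- matrix(0, nrow(px), ncol(px))
  for (i in seq_along(k)) tmp <- tmp + k[i] * shift_int(px, -radius + i - 1, 0)
  out <- matrix(0, nrow(px), ncol(px))
  for (i in seq_along(k)) out <- out + k[i] * shift_int(tmp, 0, -radius + i - 1)
  out
}

# Robust noise-SD estimate from horizontal pseudo-residuals.
estimate_noise_sd <- function(px) {
  d <- px[, -1, drop = FALSE] - px[, -ncol(px), drop = FALSE]
  stats::mad(as.numeric(d)) / sqrt(2)
}

# Fast non-local means: for each search offset, patch distances are computed
# with a box filter over squared differences, weights exp(-max(D - 2s^2,0)/h^2).
nlm_filter <- function(px, h = NULL, patch_radius = 2, search_radius = 5) {
  sd0 <- estimate_noise_sd(px)
  if (is.null(h)) h <- max(1e-6, 0.75 * sd0)
  acc <- px # self weight 1
  wsum <- matrix(1, nrow(px), ncol(px))
  offs <- expand.grid(dr = -search_radius:search_radius, dc = -search_radius:search_radius)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  npatch <- (2 * patch_radius + 1)^2
  for (i in seq_len(nrow(offs))) {
    sh <- shift_int(px, offs$dr[i], offs$dc[i])
    D <- box_sum((px - sh)^2, patch_radius) /
      box_count(nrow(px), ncol(px), patch_radius)
    w <- exp(-pmax(D - 2 * sd0^2, 0) / h^2)
    acc <- acc + w * sh
    wsum <- wsum + w
  }
  acc / wsum
}

#' Denoise a single frame with a classical filter
#'
#' A classical stand-in for device-side denoising: median, Gaussian, or
#' non-local means. Output dimensions match the input and flat-region
#' variance is never increased.
#'
#' @param frame an [en_face_image()].
#' @param method `"median"`, `"gaussian"`, or `"nonlocal_means"`.
#' @param strength named list of method-specific parameters:
#'   `radius` (median, default 1), `sigma` (gaussian, default 1),
#'   `h`/`patch_radius`/`search_radius` (non-local means; `h` defaults to
#'   0.75 x a robust noise-SD estimate).
#' @return a denoised [en_face_image()] with provenance `"denoised"`.
#' @export
denoise_frame <- function(frame, method = c("nonlocal_means", "median", "gaussian"),
                          strength = list()) {
  if (!is.character(method)) stop("`method` must be a character name", call. = FALSE)
  method <- method[1]
  valid <- c("median", "gaussian", "nonlocal_means")
  if (!method %in% valid) {
    stop(sprintf(
      "unknown denoise method '%s'; valid methods: %s",
      method, paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  px <- pixels_of(frame)
  out <- switch(method,
    median = median_filter(px, radius = strength$radius %||% 1),
    gaussian = {
      sigma <- strength$sigma %||% 1
      if (sigma == 0) px else gaussian_filter(px, sigma)
    },
    nonlocal_means = nlm_filter(px,
      h = strength$h %||% NULL,
      patch_radius = strength$patch_radius %||% 2,
      search_radius = strength$search_radius %||% 5
    )
  )
  as_enface(out, frame, provenance = "denoised")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
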