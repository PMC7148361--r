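# Lesion cropping, Otsu binarisation (global and local), and
# topology-preserving skeletonisation.

#' Restrict an image to a lesion region of interest
#'
#' Pixels outside the mask are marked invalid (`NA`) so they can never enter
#' downstream histograms or counts; the ROI mask and its bounding box are
#' attached for display and grid anchoring.
#'
#' @param image an [en_face_image()].
#' @param lesion logical matrix, same shape as `image`.
#' @param min_area floor on the ROI area in pixels.
#' @return the masked [en_face_image()], with attributes `roi_mask` and
#'   `bbox` (`c(rmin, rmax, cmin, cmax)`).
#' @export
crop_lesion <- function(image, lesion, min_area = 64) {
  px <- pixels_of(image)
  if (!all(dim(px) == dim(lesion))) {
    stop("lesion mask shape does not match image shape", call. = FALSE)
  }
  lesion <- lesion > 0
  if (!any(lesion)) stop("lesion mask is empty", call. = FALSE)
  if (sum(lesion) < min_area) {
    stop(sprintf("lesion mask area %d px is below the floor of %d px", sum(lesion), min_area),
      call. = FALSE
    )
  }
  px[!lesion] <- NA_real_
  out <- as_enface(px, image)
  rr <- range(which(rowSums(lesion) > 0))
  cc <- range(which(colSums(lesion) > 0))
  attr(out, "roi_mask") <- lesion
  attr(out, "bbox") <- c(rmin = rr[1], rmax = rr[2], cmin = cc[1], cmax = cc[2])
  out
}

# Otsu threshold from a 256-bin histogram (bins are grey levels 0..255).
# Returns the split point t in 0..254 (foreground = level > t), maximising
# the between-class variance; ties go to the smallest t. NA for a constant
# histogram.
otsu_from_counts <- function(counts) {
  stopifnot(length(counts) == 256)
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total == 0 || sum(counts > 0) < 2) return(NA_integer_)
  lev <- 0:255
  W0 <- cumsum(counts)
  M0 <- cumsum(lev * counts)
  sum_all <- M0[256]
  t <- 0:254
  w0 <- W0[t + 1]
  m0 <- M0[t + 1]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  # between-class variance (up to the constant total): w0*w1*(mu0-mu1)^2
  num <- (sum_all * w0 - total * m0)^2
  sigma_b <- ifelse(valid, num / (w0 * w1), -Inf)
  as.integer(t[which.max(sigma_b)])
}

#' Binarise an angiogram by Otsu thresholding
#'
#' Global mode computes a single Otsu threshold from the ROI histogram
#' (maximising between-class variance over all 256 grey levels); local mode
#' computes a per-pixel Otsu threshold from the `window` x `window`
#' neighbourhood histogram centred at each ROI pixel (windows truncated at
#' the image border). Pixels outside the ROI are always 0. A constant ROI
#' yields an all-zero map with a warning.
#'
#' @param image an [en_face_image()], typically from [crop_lesion()].
#' @param roi logical ROI mask; if `NULL`, taken from the image's `roi_mask`
#'   attribute, or the full frame.
#' @param mode `"local"` (default) or `"global"`.
#' @param window odd window side in pixels (local mode only); the default of
#'   15 px spans roughly 200 um at the 3 mm / 232 px pitch.
#' @param min_contrast_frac homogeneous-window guard (local mode): where the
#'   window grey-level SD falls below this fraction of the global Otsu
#'   between-class mean separation, the pixel is thresholded against the
#'   global threshold instead. Prevents the local threshold from splitting
#'   featureless regions in half.
#' @return a logical matrix of class `binary_vessel_map` with a
#'   `threshold_record` attribute documenting the method and thresholds.
#' @export
binarize_otsu <- function(image, roi = NULL, mode = c("local", "global"), window = 15,
                          min_contrast_frac = 0.25) {
  mode <- match.arg(mode)
  px <- pixels_of(image)
  if (is.null(roi)) roi <- attr(image, "roi_mask")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(px), ncol(px))
  if (!all(dim(px) == dim(roi))) stop("ROI shape does not match image shape", call. = FALSE)
  roi <- roi > 0 & !is.na(px)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  bins <- matrix(as.integer(clamp(floor(px), 0, 255)), nrow(px), ncol(px))
  bins[is.na(px)] <- 0L

  if (mode == "global") {
    counts <- tabulate(bins[roi] + 1L, nbins = 256)
    t <- otsu_from_counts(counts)
    if (is.na(t)) {
      warning("ROI histogram is constant; returning an all-zero vessel map", call. = FALSE)
      mask <- matrix(FALSE, nrow(px), ncol(px))
      rec <- list(method = "otsu_global", threshold = NA_integer_, degenerate = TRUE)
    } else {
      mask <- roi & bins > t
      rec <- list(method = "otsu_global", threshold = t)
    }
  } else {
    if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3", call. = FALSE)
    h <- (window - 1) / 2
    # global reference: threshold and between-class mean separation over the
    # full ROI histogram, used by the homogeneous-window guard
    gcounts <- as.numeric(tabulate(bins[roi] + 1L, nbins = 256))
    tg <- otsu_from_counts(gcounts)
    if (is.na(tg)) {
      warning("ROI histogram is constant; returning an all-zero vessel map", call. = FALSE)
      mask <- matrix(FALSE, nrow(px), ncol(px))
      rec <- list(method = "otsu_local", window = window, degenerate = TRUE)
      return(structure(mask,
        threshold_record = rec,
        class = c("binary_vessel_map", "matrix", "array")
      ))
    }
    lev256 <- 0:255
    w0g <- sum(gcounts[lev256 <= tg])
    mu0g <- sum(lev256[lev256 <= tg] * gcounts[lev256 <= tg]) / w0g
    mu1g <- sum(lev256[lev256 > tg] * gcounts[lev256 > tg]) / (sum(gcounts) - w0g)
    sd_floor <- min_contrast_frac * (mu1g - mu0g)

    # work on the ROI bounding box padded by the window half-width
    rr <- range(which(rowSums(roi) > 0))
    cc <- range(which(colSums(roi) > 0))
    r1 <- max(1, rr[1] - h); r2 <- min(nrow(px), rr[2] + h)
    c1 <- max(1, cc[1] - h); c2 <- min(ncol(px), cc[2] + h)
    sub <- bins[r1:r2, c1:c2, drop = FALSE]
    # ROI-restricted histograms: pixels outside the lesion never influence
    # any threshold
    valid <- roi[r1:r2, c1:c2, drop = FALSE]
    sub_roi <- roi[r1:r2, c1:c2, drop = FALSE]
    pix <- which(sub_roi)
    present <- sort(unique(as.integer(sub[valid])))
    # per-pixel window moments over valid pixels, for the contrast guard
    nvalid <- box_sum(valid * 1, h)
    svalid <- box_sum(sub * (valid * 1), h)
    s2valid <- box_sum(sub^2 * (valid * 1), h)
    mloc <- svalid / pmax(nvalid, 1)
    sdloc <- sqrt(pmax(s2valid / pmax(nvalid, 1) - mloc^2, 0))
    # neighbourhood histogram of each ROI pixel, one row per present level
    H <- matrix(0, length(present), length(pix))
    for (i in seq_along(present)) {
      cnt <- box_sum((sub == present[i] & valid) * 1, h)
      H[i, ] <- cnt[pix]
    }
    lev <- present
    nL <- length(lev)
    W0 <- apply(H, 2, cumsum)
    M0 <- apply(H * lev, 2, cumsum)
    total <- W0[nL, ]
    sum_all <- M0[nL, ]
    W0s <- W0[-nL, , drop = FALSE]
    M0s <- M0[-nL, , drop = FALSE]
    num <- (rep(sum_all, each = nL - 1) * W0s - rep(total, each = nL - 1) * M0s)^2
    den <- W0s * (rep(total, each = nL - 1) - W0s)
    sigma_b <- matrix(ifelse(den > 0, num / den, -Inf), nL - 1, length(pix))
    best <- max.col(t(sigma_b), ties.method = "first")
    thr <- lev[best] # foreground = level strictly above the chosen split level
    flat <- sdloc[pix] < sd_floor
    thr[flat] <- tg
    mask <- matrix(FALSE, nrow(px), ncol(px))
    sel <- sub[pix] > thr
    sub_mask <- matrix(FALSE, nrow(sub), ncol(sub))
    sub_mask[pix[sel]] <- TRUE
    mask[r1:r2, c1:c2] <- sub_mask
    rec <- list(
      method = "otsu_local", window = window,
      global_threshold = tg, contrast_floor = sd_floor,
      fallback_fraction = mean(flat),
      threshold_range = range(thr)
    )
  }
  structure(mask,
    threshold_record = rec,
    class = c("binary_vessel_map", "matrix", "array")
  )
}

# --- skeletonisation ---------------------------------------------------------

# Neighbour order n0..n7 = E, NE, N, NW, W, SW, S, SE (even = 4-neighbours).
.NB_DR <- c(0, -1, -1, -1, 0, 1, 1, 1)
.NB_DC <- c(1, 1, 0, -1, -1, -1, 0, 1)

# Lookup tables over the 256 neighbourhood configurations: Yokoi
# connectivity number for 8-connected foreground, and neighbour count.
make_thin_luts <- function() {
  simple <- logical(256)
  count <- integer(256)
  for (code in 0:255) {
    x <- as.integer(bitwAnd(bitwShiftR(code, 0:7), 1L))
    b <- 1L - x
    c8 <- 0L
    for (k in c(0, 2, 4, 6)) {
      k1 <- (k + 1) %% 8
      k2 <- (k + 2) %% 8
      c8 <- c8 + b[k + 1] - b[k + 1] * b[k1 + 1] * b[k2 + 1]
    }
    simple[code + 1] <- (c8 == 1L)
    count[code + 1] <- sum(x)
  }
  # deletable: simple and not a curve endpoint or isolated pixel
  list(deletable = simple & count >= 2L)
}
.THIN_LUT <- make_thin_luts()

# Sequential simple-point thinning to a 1-px skeleton. Deletions are applied
# one pixel at a time in fixed raster (column-major) order, so topology
# (8-connected component count) is preserved exactly and results are
# deterministic. Curve endpoints and isolated pixels are retained.
thin_mask <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  # pad with a background border so neighbourhood reads never leave bounds
  P <- matrix(FALSE, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- mask > 0
  np <- nr + 2
  off <- .NB_DR + .NB_DC * np
  pow <- 2^(0:7)
  del <- .THIN_LUT$deletable
  repeat {
    fg <- which(P)
    if (length(fg) == 0) break
    # border pixels: at least one background 4-neighbour
    border <- fg[!(P[fg + 1] & P[fg - 1] & P[fg + np] & P[fg - np])]
    changed <- FALSE
    for (i in border) {
      if (!P[i]) next
      code <- sum(pow[P[i + off]])
      if (del[code + 1]) {
        P[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P[2:(nr + 1), 2:(nc + 1), drop = FALSE]
}

#' Skeletonise a binary vessel map
#'
#' Homotopy-preserving sequential thinning to 1-px-wide medial curves:
#' simple border pixels are deleted one at a time in fixed raster order
#' until no removable simple pixel remains, keeping curve endpoints. The
#' skeleton is always a pixelwise subset of the input and has the same
#' number of 8-connected components.
#'
#' @param binary a [binarize_otsu()] result or any logical matrix.
#' @return a logical matrix of class `skeleton_map`.
#' @export
skeletonize_vessels <- function(binary) {
  sk <- thin_mask(unclass(binary) > 0)
  structure(sk, class = c("skeleton_map", "matrix", "array"))
}

# 8-connected component count (two-pass flood fill via equivalence merging).
count_components8 <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(0L)
  nr <- nrow(mask)
  lab <- matrix(0L, nr, ncol(mask))
  nxt <- 0L
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1]) # column-major scan
  for (k in ord) {
    r <- idx[k, 1]
    cc <- idx[k, 2]
    nb <- c(
      if (r > 1 && cc > 1) lab[r - 1, cc - 1] else 0L,
      if (cc > 1) lab[r, cc - 1] else 0L,
      if (r < nr && cc > 1) lab[r + 1, cc - 1] else 0L,
      if (r > 1) lab[r - 1, cc] else 0L
    )
    nb <- nb[nb > 0L]
    if (length(nb) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, cc] <- nxt
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      keep <- min(roots)
      lab[r, cc] <- keep
      for (ro in roots) parent[ro] <- keep
    }
  }
  length(unique(vapply(seq_len(nxt), find, integer(1))))
}
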