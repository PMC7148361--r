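# The five quantitative CNV indices: VD, VLD, VDI, FD, CNR.

#' Per-image vessel metrics record
#'
#' @param vd vessel density, percent of ROI area occupied by binarised
#'   vessels.
#' @param vld vessel length density, percent of ROI area occupied by the
#'   1-px skeleton.
#' @param vdi vessel diameter index, `(VD/VLD) x littmann_coefficient`; an
#'   average-calibre index. `NA` when VLD is 0.
#' @param fd box-counting fractal dimension of the skeleton, in (0, 2].
#' @param cnr contrast-to-noise ratio of the lesion against its dark rim.
#' @param littmann_coefficient the magnification coefficient used for VDI.
#' @param threshold_record provenance of the binarisation.
#' @return an object of class `vessel_metrics`.
#' @export
vessel_metrics <- function(vd, vld, vdi, fd, cnr, littmann_coefficient,
                           threshold_record = NULL) {
  stopifnot(vd >= 0, vd <= 100, vld >= 0, vld <= vd + 1e-9)
  structure(
    list(
      vd = vd, vld = vld, vdi = vdi, fd = fd, cnr = cnr,
      littmann_coefficient = littmann_coefficient,
      threshold_record = threshold_record
    ),
    class = "vessel_metrics"
  )
}

#' @export
print.vessel_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(
    "<vessel_metrics> VD %s%%  VLD %s%%  VDI %s  FD %s  CNR %s\n",
    fmt(x$vd), fmt(x$vld), fmt(x$vdi), fmt(x$fd), fmt(x$cnr)
  ))
  invisible(x)
}

#' @export
as.data.frame.vessel_metrics <- function(x, ...) {
  data.frame(
    vd = x$vd, vld = x$vld, vdi = x$vdi, fd = x$fd, cnr = x$cnr,
    littmann_coefficient = x$littmann_coefficient
  )
}

#' Vessel density
#'
#' Percent of the ROI area occupied by binarised vessel pixels.
#'
#' @param binary logical vessel map (pixelwise subset of `roi`).
#' @param roi logical ROI mask.
#' @return percent in [0, 100].
#' @export
vessel_density <- function(binary, roi) {
  binary <- unclass(binary) > 0
  roi <- roi > 0
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  if (any(binary & !roi)) stop("vessel map has pixels outside the ROI", call. = FALSE)
  100 * sum(binary) / sum(roi)
}

#' Vessel length density
#'
#' Percent of the ROI area occupied by the 1-px vessel skeleton; a
#' calibre-independent length measure.
#'
#' @param skeleton logical skeleton map (pixelwise subset of `roi`).
#' @inheritParams vessel_density
#' @return percent in [0, 100].
#' @export
vessel_length_density <- function(skeleton, roi) {
  vessel_density(skeleton, roi)
}

#' Littmann/Bennett ocular magnification coefficient
#'
#' Converts on-image measurements to true retinal scale. The Bennett
#' reduced form is `t = 3.382 x 0.01306 x (AL - 1.82)` with the axial
#' length AL in mm; `method = "fixed"` passes a device- or
#' convention-specific coefficient through unchanged.
#'
#' @param axial_length axial length in mm (required for `"bennett"`; must
#'   lie in [20, 35]).
#' @param method `"bennett"` or `"fixed"`.
#' @param fixed_value the coefficient to return when `method = "fixed"`.
#' @return the dimensionless magnification coefficient.
#' @export
littmann_coefficient <- function(axial_length = NULL,
                                 method = c("bennett", "fixed"),
                                 fixed_value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("method = 'fixed' requires `fixed_value`", call. = FALSE)
    return(fixed_value)
  }
  if (is.null(axial_length)) stop("method = 'bennett' requires `axial_length`", call. = FALSE)
  if (axial_length < 20 || axial_length > 35) {
    stop(sprintf("axial length %.2f mm outside the supported range [20, 35]", axial_length),
      call. = FALSE
    )
  }
  3.382 * 0.01306 * (axial_length - 1.82)
}

#' Vessel diameter index
#'
#' `VDI = (VD / VLD) x` magnification coefficient: the mean vessel calibre
#' in corrected units. Undefined (`NA`) when VLD is 0 — never reported as
#' infinity.
#'
#' @param vd,vld vessel density and vessel length density, percent.
#' @param coefficient the [littmann_coefficient()].
#' @return the dimensionless index, or `NA` if `vld` is 0.
#' @export
vessel_diameter_index <- function(vd, vld, coefficient) {
  if (is.na(vld) || vld <= 0) return(NA_real_)
  (vd / vld) * coefficient
}

# Box sizes for FD: powers of two from 2 px to a quarter of the ROI
# bounding-box side, extended geometrically if that yields fewer than 4.
default_box_sizes <- function(roi) {
  roi <- roi > 0
  if (!any(roi)) return(c(2, 4, 8, 16))
  rr <- range(which(rowSums(roi) > 0))
  cc <- range(which(colSums(roi) > 0))
  side <- max(diff(rr), diff(cc)) + 1
  top <- max(2, floor(log2(side / 4)))
  s <- 2^seq(1, top)
  if (length(s) < 4) s <- unique(round(2^seq(1, log2(max(side / 2, 8)), length.out = 4)))
  s
}

#' Box-counting fractal dimension
#'
#' Counts the boxes of each size `s` (grid anchored at `origin`, by default
#' the bounding-box origin of the set) that contain at least one skeleton
#' pixel, and returns the slope of the least-squares fit of `log N(s)`
#' against `log(1/s)`.
#'
#' @param skeleton logical matrix (typically a [skeletonize_vessels()]
#'   result).
#' @param box_sizes integer box sides in pixels; at least 4 required.
#' @param origin `(row, col)` grid anchor; default anchors at the set's
#'   bounding-box origin.
#' @return the fractal dimension; `NA` for an empty skeleton.
#' @export
fractal_dimension <- function(skeleton, box_sizes = NULL, origin = NULL) {
  sk <- unclass(skeleton) > 0
  if (!any(sk)) return(NA_real_)
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(sk)
  if (length(box_sizes) < 4) stop("need at least 4 box sizes", call. = FALSE)
  idx <- which(sk, arr.ind = TRUE)
  if (is.null(origin)) origin <- c(min(idx[, 1]), min(idx[, 2]))
  N <- vapply(box_sizes, function(s) {
    br <- floor((idx[, 1] - origin[1]) / s)
    bc <- floor((idx[, 2] - origin[2]) / s)
    length(unique(br * 2147483647 + bc))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / box_sizes)), log(N))
  unname(fit$coefficients[2])
}

#' Foreground/background regions for the CNR
#'
#' The whole CNV lesion is the foreground; the darkest area around it (the
#' dark rim) is the background. The constructor computes the mean grey
#' values `f`, `b` and sample standard deviations `delta_f`, `delta_b` of
#' the image over the two masks.
#'
#' @param image an [en_face_image()].
#' @param foreground_mask,background_mask disjoint logical masks with at
#'   least 25 pixels each.
#' @return an object of class `cnr_regions` with the masks and moments.
#' @export
cnr_regions <- function(image, foreground_mask, background_mask) {
  px <- pixels_of(image)
  fg <- foreground_mask > 0
  bg <- background_mask > 0
  if (!all(dim(px) == dim(fg)) || !all(dim(px) == dim(bg))) {
    stop("mask shapes do not match image shape", call. = FALSE)
  }
  if (any(fg & bg)) stop("foreground and background masks overlap", call. = FALSE)
  if (sum(fg) < 25 || sum(bg) < 25) {
    stop("foreground and background masks need at least 25 pixels each", call. = FALSE)
  }
  structure(
    list(
      foreground_mask = fg, background_mask = bg,
      f = mean(px[fg]), b = mean(px[bg]),
      delta_f = stats::sd(px[fg]), delta_b = stats::sd(px[bg])
    ),
    class = "cnr_regions"
  )
}

cnr_value <- function(regions) {
  den <- sqrt(regions$delta_f^2 + regions$delta_b^2)
  if (!is.finite(den) || den == 0) return(NA_real_)
  (regions$f - regions$b) / den
}

#' Contrast-to-noise ratio
#'
#' `CNR = (f - b) / sqrt(delta_f^2 + delta_b^2)` with `f`, `b` the mean
#' grey values of the foreground (whole CNV area) and background (darkest
#' area around it) and `delta_f`, `delta_b` their standard deviations. The
#' sign is preserved; the value is `NA` when both spreads are zero. The
#' moments are always recomputed on `image` over the region masks, so the
#' same sites can be scored across the arms of a study.
#'
#' @param image an [en_face_image()].
#' @param regions a [cnr_regions()] object (its masks are reused; its
#'   stored moments are ignored).
#' @return the dimensionless CNR.
#' @export
cnr <- function(image, regions) {
  stopifnot(inherits(regions, "cnr_regions"))
  cnr_value(cnr_regions(image, regions$foreground_mask, regions$background_mask))
}

#' Metric-computation configuration
#'
#' @param threshold_mode `"local"` or `"global"` Otsu binarisation.
#' @param window local-Otsu window, odd pixels.
#' @param box_sizes FD box sizes; `NULL` selects powers of two from 2 px to
#'   a quarter of the ROI bounding-box side.
#' @param littmann_method `"bennett"` or `"fixed"`.
#' @param littmann_fixed coefficient used when `littmann_method = "fixed"`.
#' @param min_roi_area floor on the lesion ROI area, pixels.
#' @return a list of class `metrics_config`.
#' @export
metrics_config <- function(threshold_mode = "local", window = 15, box_sizes = NULL,
                           littmann_method = "bennett", littmann_fixed = NULL,
                           min_roi_area = 64) {
  structure(
    list(
      threshold_mode = threshold_mode, window = window, box_sizes = box_sizes,
      littmann_method = littmann_method, littmann_fixed = littmann_fixed,
      min_roi_area = min_roi_area
    ),
    class = "metrics_config"
  )
}

#' Compute all five metrics for one image
#'
#' Runs the full measurement path — crop to the lesion, Otsu binarisation,
#' skeletonisation — then VD, VLD, VDI (with the Littmann/Bennett
#' magnification coefficient), FD on the skeleton, and CNR on the original
#' grayscale image over the foreground/background sites.
#'
#' @param image an [en_face_image()].
#' @param lesion logical lesion mask.
#' @param regions a [cnr_regions()] object carrying the CNR sites.
#' @param axial_length axial length in mm (used when
#'   `littmann_method = "bennett"`).
#' @param config a [metrics_config()].
#' @return a [vessel_metrics()] record; the binary and skeleton maps are
#'   attached as attributes `binary` and `skeleton`.
#' @export
compute_metrics <- function(image, lesion, regions, axial_length = NULL,
                            config = metrics_config()) {
  cropped <- crop_lesion(image, lesion, min_area = config$min_roi_area)
  binary <- binarize_otsu(cropped,
    roi = lesion, mode = config$threshold_mode,
    window = config$window
  )
  skeleton <- skeletonize_vessels(binary)
  stopifnot(!any(skeleton & !binary), !any(binary & !(lesion > 0)))
  vd <- vessel_density(binary, lesion)
  vld <- vessel_length_density(skeleton, lesion)
  coef <- littmann_coefficient(axial_length,
    method = config$littmann_method,
    fixed_value = config$littmann_fixed
  )
  vdi <- vessel_diameter_index(vd, vld, coef)
  bs <- config$box_sizes %||% default_box_sizes(lesion)
  rr <- range(which(rowSums(lesion > 0) > 0))
  cc <- range(which(colSums(lesion > 0) > 0))
  fd <- fractal_dimension(skeleton, box_sizes = bs, origin = c(rr[1], cc[1]))
  m <- vessel_metrics(
    vd = vd, vld = vld, vdi = vdi, fd = fd,
    cnr = cnr(image, regions),
    littmann_coefficient = coef,
    threshold_record = attr(binary, "threshold_record")
  )
  attr(m, "binary") <- binary
  attr(m, "skeleton") <- skeleton
  m
}
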