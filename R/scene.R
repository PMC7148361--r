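# Synthetic neovascular phantom: ground-truth scene generation and
# speckled multi-frame rendering.

#' Parameters of a synthetic neovascular scene
#'
#' Defines the geometry and noise of a synthetic en-face angiogram: a bright
#' branching neovascular lesion inside a circular region, surrounded by a
#' dark rim on a mid-grey background, imaged repeatedly under multiplicative
#' speckle, additive read noise and small inter-frame translation jitter.
#'
#' Defaults emulate a 3 x 3 mm macular cube sampled by 232 x 232 A-scans
#' with up to 10 repeated frames.
#'
#' @param image_size pixels per side (>= 32).
#' @param pixel_pitch mm per pixel.
#' @param n_seed_vessels number of vessel trunks seeded on the lesion
#'   boundary.
#' @param branch_prob Bernoulli branching probability per centerline step.
#' @param calibre_range `(min, max)` vessel calibre in pixels; min >= 1.
#' @param lesion_center `(row, col)` of the lesion centre in pixels.
#' @param lesion_radius lesion radius in pixels.
#' @param rim_width width of the dark rim annulus, pixels.
#' @param rim_attenuation multiplicative attenuation of the rim in [0, 1).
#' @param vessel_level,interior_level,background_level grey levels (0--255)
#'   of vessels, non-vessel lesion interior, and the surround.
#' @param speckle_shape gamma shape of the mean-1 multiplicative speckle;
#'   coefficient of variation is `1/sqrt(speckle_shape)`. `Inf` disables it.
#' @param additive_sigma SD of additive zero-mean Gaussian noise, grey
#'   levels.
#' @param jitter_sigma SD of the per-frame global translation, pixels.
#' @param n_frames frames per acquisition sequence (>= 1).
#' @param rng_seed integer seed; all scene randomness derives from it.
#' @return an object of class `scene_params` (a validated list).
#' @export
scene_params <- function(image_size = 232,
                         pixel_pitch = 3 / 232,
                         n_seed_vessels = 3,
                         branch_prob = 0.03,
                         calibre_range = c(2, 3.5),
                         lesion_center = NULL,
                         lesion_radius = 40,
                         rim_width = 8,
                         rim_attenuation = 0.25,
                         vessel_level = 230,
                         interior_level = 120,
                         background_level = 120,
                         speckle_shape = 4,
                         additive_sigma = 8,
                         jitter_sigma = 0.5,
                         n_frames = 10,
                         rng_seed = 1L) {
  if (is.null(lesion_center)) lesion_center <- c(1, 1) + (image_size - 1) / 2
  p <- list(
    image_size = as.integer(image_size), pixel_pitch = pixel_pitch,
    n_seed_vessels = as.integer(n_seed_vessels), branch_prob = branch_prob,
    calibre_range = as.numeric(calibre_range), lesion_center = as.numeric(lesion_center),
    lesion_radius = as.numeric(lesion_radius), rim_width = as.numeric(rim_width),
    rim_attenuation = rim_attenuation, vessel_level = vessel_level,
    interior_level = interior_level, background_level = background_level,
    speckle_shape = speckle_shape, additive_sigma = additive_sigma,
    jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
    rng_seed = as.integer(rng_seed)
  )
  if (p$image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (p$branch_prob < 0 || p$branch_prob > 1) stop("branch_prob must be in [0, 1]", call. = FALSE)
  if (length(p$calibre_range) != 2 || p$calibre_range[1] < 1 || diff(p$calibre_range) < 0) {
    stop("calibre_range must be (min, max) with min >= 1 pixel", call. = FALSE)
  }
  if (p$rim_attenuation < 0 || p$rim_attenuation >= 1) {
    stop("rim_attenuation must be in [0, 1)", call. = FALSE)
  }
  if (p$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (p$n_seed_vessels < 0) stop("n_seed_vessels must be >= 0", call. = FALSE)
  if (p$additive_sigma < 0 || p$jitter_sigma < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (!(is.infinite(p$speckle_shape) || p$speckle_shape > 0)) {
    stop("speckle_shape must be positive (or Inf for no speckle)", call. = FALSE)
  }
  reach <- p$lesion_radius + p$rim_width
  if (any(p$lesion_center - reach < 1) || any(p$lesion_center + reach > p$image_size)) {
    stop("lesion_radius + rim_width exceeds image bounds", call. = FALSE)
  }
  structure(p, class = "scene_params")
}

# Disc offsets (relative row/col) for a given radius, cached on the
# half-pixel grid since stamping rounds calibre to 0.5 px.
.disc_cache <- new.env(parent = emptyenv())
disc_offsets <- function(radius) {
  r <- max(0, round(radius * 2) / 2)
  key <- as.character(r)
  hit <- .disc_cache[[key]]
  if (!is.null(hit)) return(hit)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  keep <- g$dr^2 + g$dc^2 <= r^2 + 1e-9
  out <- list(dr = g$dr[keep], dc = g$dc[keep])
  .disc_cache[[key]] <- out
  out
}

#' Generate the ground-truth scene
#'
#' Grows a branching vessel network from seed points on the lesion boundary
#' by biased random-walk centerlines with Bernoulli branching and linearly
#' tapering calibre, rasterised by stamping discs. Builds the noise-free
#' intensity image (bright vessels, mid-grey elsewhere, dark rim annulus),
#' the lesion/foreground/background masks, and the true metric values
#' computed directly on the binary vessel map.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `truth_scene`: a list with `vessel_map`,
#'   `calibre_map`, `intensity_truth`, `lesion_mask`, `foreground_mask`,
#'   `background_mask`, `true_metrics`, and `params`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$image_size
  ctr <- params$lesion_center
  R <- params$lesion_radius

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  D <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  lesion_mask <- D <= R
  # keep a 1-px guard band at both rim edges so jittered renderings do not
  # bleed lesion or surround intensity into the background sample
  rim_mask <- D > R & D <= R + params$rim_width
  background_mask <- D > R + 1 & D <= R + params$rim_width - 1

  vessel_map <- matrix(FALSE, n, n)
  calibre_map <- matrix(0, n, n)

  if (params$n_seed_vessels > 0) {
    with_seed(derive_seed(params$rng_seed, 101), {
      stamp <- function(pos, calibre) {
        off <- disc_offsets(calibre / 2)
        rr <- round(pos[1]) + off$dr
        cc <- round(pos[2]) + off$dc
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        idx <- cbind(rr[ok], cc[ok])
        inside <- lesion_mask[idx]
        idx <- idx[inside, , drop = FALSE]
        vessel_map[idx] <<- TRUE
        calibre_map[idx] <<- pmax(calibre_map[idx], calibre)
      }
      cmin <- params$calibre_range[1]
      cmax <- params$calibre_range[2]
      taper_len <- 2 * R
      # each walker: position, heading, steps walked, current calibre
      angles <- stats::runif(params$n_seed_vessels, 0, 2 * pi)
      walkers <- lapply(angles, function(a) {
        list(
          pos = ctr + (R - 0.5) * c(cos(a), sin(a)),
          dir = a + pi, # inward
          steps = 0, calibre = cmax
        )
      })
      max_walkers <- 64
      total_steps <- 0
      while (length(walkers) > 0 && total_steps < 20000) {
        w <- walkers[[1]]
        walkers <- walkers[-1]
        repeat {
          total_steps <- total_steps + 1
          stamp(w$pos, w$calibre)
          # heading: random wiggle plus a weak pull toward the lesion centre
          to_ctr <- atan2(ctr[2] - w$pos[2], ctr[1] - w$pos[1])
          # signed angular difference in (-pi, pi]
          dang <- atan2(sin(to_ctr - w$dir), cos(to_ctr - w$dir))
          w$dir <- w$dir + 0.12 * dang + stats::rnorm(1, 0, 0.35)
          w$pos <- w$pos + c(cos(w$dir), sin(w$dir))
          w$steps <- w$steps + 1
          w$calibre <- max(cmin, cmax - (cmax - cmin) * w$steps / taper_len)
          dctr <- sqrt(sum((w$pos - ctr)^2))
          if (dctr > R - 0.5 || w$steps > 4 * R || total_steps >= 20000) break
          if (stats::runif(1) < params$branch_prob && length(walkers) < max_walkers) {
            side <- if (stats::runif(1) < 0.5) -1 else 1
            walkers[[length(walkers) + 1]] <- list(
              pos = w$pos,
              dir = w$dir + side * stats::runif(1, 0.5, 1.1),
              steps = w$steps,
              calibre = max(cmin, w$calibre * 0.8)
            )
          }
        }
      }
    })
  }

  intensity <- matrix(params$background_level, n, n)
  intensity[lesion_mask] <- params$interior_level
  intensity[rim_mask] <- round(params$background_level * params$rim_attenuation)
  intensity[vessel_map] <- params$vessel_level

  scene <- structure(
    list(
      vessel_map = vessel_map,
      calibre_map = calibre_map,
      intensity_truth = intensity,
      lesion_mask = lesion_mask,
      foreground_mask = lesion_mask,
      background_mask = background_mask,
      true_metrics = NULL,
      params = params
    ),
    class = "truth_scene"
  )
  scene$true_metrics <- true_metrics_of(scene)
  scene
}

# True metrics on the noise-free scene: VD/VLD by direct pixel counts on the
# ground-truth vessel map, VDI with unit magnification (no eye attached to a
# phantom), FD on the true skeleton, CNR on the noise-free intensity image.
true_metrics_of <- function(scene) {
  roi <- scene$lesion_mask
  vm <- scene$vessel_map & roi
  if (!any(vm)) {
    sk <- vm
    vd <- 0
    vld <- 0
  } else {
    sk <- thin_mask(vm)
    vd <- 100 * sum(vm) / sum(roi)
    vld <- 100 * sum(sk) / sum(roi)
  }
  vdi <- if (vld > 0) (vd / vld) * 1 else NA_real_
  fd <- if (any(sk)) fractal_dimension(sk, box_sizes = default_box_sizes(roi)) else NA_real_
  img <- en_face_image(scene$intensity_truth,
    pixel_pitch = scene$params$pixel_pitch,
    provenance = "truth"
  )
  regions <- cnr_regions(img, scene$foreground_mask, scene$background_mask)
  vessel_metrics(
    vd = vd, vld = vld, vdi = vdi, fd = fd, cnr = cnr_value(regions),
    littmann_coefficient = 1,
    threshold_record = list(method = "ground_truth")
  )
}

#' @export
print.truth_scene <- function(x, ...) {
  cat(sprintf(
    "<truth_scene> %d x %d px, lesion radius %.0f px, %d vessel px (VD %.1f%%)\n",
    nrow(x$vessel_map), ncol(x$vessel_map), x$params$lesion_radius,
    sum(x$vessel_map), x$true_metrics$vd
  ))
  invisible(x)
}

#' Render one noisy frame of a scene
#'
#' The noise-free truth is translated by a per-frame random global jitter,
#' multiplied by i.i.d. per-pixel gamma speckle (mean 1, shape
#' `speckle_shape`), offset by additive Gaussian noise, then saturated and
#' quantised to 8-bit grey levels. Frames with different `frame_index` use
#' independent substreams derived from the scene seed, so they are
#' statistically independent yet individually reproducible.
#'
#' @param truth a [generate_truth()] scene.
#' @param params the [scene_params()] used to build it.
#' @param frame_index 0-based frame number.
#' @return an [en_face_image()] with provenance `"single"`.
#' @export
render_frame <- function(truth, params, frame_index) {
  stopifnot(inherits(truth, "truth_scene"), inherits(params, "scene_params"))
  if (frame_index < 0) stop("frame_index must be >= 0", call. = FALSE)
  n <- params$image_size
  px <- with_seed(derive_seed(params$rng_seed, 202, frame_index), {
    base <- truth$intensity_truth
    if (params$jitter_sigma > 0) {
      d <- stats::rnorm(2, 0, params$jitter_sigma)
      base <- shift_image(base, d[1], d[2])
    }
    if (is.finite(params$speckle_shape)) {
      m <- matrix(
        stats::rgamma(n * n, shape = params$speckle_shape, rate = params$speckle_shape),
        n, n
      )
      base <- base * m
    }
    if (params$additive_sigma > 0) {
      base <- base + matrix(stats::rnorm(n * n, 0, params$additive_sigma), n, n)
    }
    quantize8(base)
  })
  en_face_image(px, pixel_pitch = params$pixel_pitch, provenance = "single")
}

#' Render a full acquisition sequence
#'
#' @inheritParams render_frame
#' @return a list of `params$n_frames` independent [en_face_image()] frames;
#'   element 1 (frame index 0) is the designated first single image.
#' @export
render_sequence <- function(truth, params) {
  lapply(seq_len(params$n_frames) - 1L, function(k) render_frame(truth, params, k))
}
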