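# Internal numeric helpers shared across modules.

.MOD31 <- 2147483647

#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed;
#' independent stages (per eye, per frame) draw from substreams derived with
#' this mixing function, so adding a stage never perturbs another stage's
#' stream. The result is always in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param ... integer stream indices (e.g. eye number, frame number).
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% .MOD31
  # multiplicative congruential mix; all intermediates stay below 2^53
  for (k in idx) s <- (s * 69069 + as.double(k) + 12345) %% .MOD31
  as.integer(s %% (.MOD31 - 2L) + 1L)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Saturating 8-bit quantisation: grey levels in [0, 255], integral values.
quantize8 <- function(x) round(clamp(x, 0, 255))

# Translate an image by a (possibly fractional) shift, bilinear interpolation,
# edge replication outside the frame. out[r, c] = in[r - dr, c - dc].
shift_image <- function(px, dr, dc) {
  nr <- nrow(px)
  nc <- ncol(px)
  r <- seq_len(nr) - dr
  cc <- seq_len(nc) - dc
  r0 <- floor(r)
  c0 <- floor(cc)
  fr <- r - r0
  fc <- cc - c0
  r0a <- clamp(r0, 1, nr)
  r1a <- clamp(r0 + 1, 1, nr)
  c0a <- clamp(c0, 1, nc)
  c1a <- clamp(c0 + 1, 1, nc)
  px[r0a, c0a, drop = FALSE] * outer(1 - fr, 1 - fc) +
    px[r1a, c0a, drop = FALSE] * outer(fr, 1 - fc) +
    px[r0a, c1a, drop = FALSE] * outer(1 - fr, fc) +
    px[r1a, c1a, drop = FALSE] * outer(fr, fc)
}

# Integer translate with edge replication (no interpolation).
shift_int <- function(px, dr, dc) {
  nr <- nrow(px)
  nc <- ncol(px)
  px[clamp(seq_len(nr) - dr, 1, nr), clamp(seq_len(nc) - dc, 1, nc), drop = FALSE]
}

# Padded integral image; returns function (r1, r2, c1, c2) -> window sums for
# vectors of clamped bounds.
integral_image <- function(m) {
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  rbind(0, cbind(0, S)) # 1-based padding row/col of zeros
}

# Sum of m over the (2h+1)x(2h+1) window centred at every pixel, windows
# truncated at the image border. Returns a matrix of the same shape.
box_sum <- function(m, h) {
  nr <- nrow(m)
  nc <- ncol(m)
  S <- integral_image(m)
  r1 <- clamp(seq_len(nr) - h, 1, nr)
  r2 <- clamp(seq_len(nr) + h, 1, nr)
  c1 <- clamp(seq_len(nc) - h, 1, nc)
  c2 <- clamp(seq_len(nc) + h, 1, nc)
  S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Number of pixels in each truncated window (denominator for box means).
box_count <- function(nr, nc, h) {
  box_sum(matrix(1, nr, nc), h)
}
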