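# Shared fixtures and independent oracles, built in code.

# Small fast phantom for unit tests.
small_scene <- function(seed = 1, ...) {
  scene_params(
    image_size = 96, lesion_radius = 24, rim_width = 6,
    rng_seed = seed, ...
  )
}

# Cyclic integer roll (wrap-around), used to construct exact known shifts.
roll_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# Exhaustive 256-level Otsu oracle: direct two-class mean/weight computation
# for every candidate threshold, no cumulative-sum shortcuts.
otsu_oracle <- function(counts) {
  lev <- 0:255
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:254) {
    lo <- lev <= t
    w0 <- sum(counts[lo])
    w1 <- sum(counts[!lo])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lev[lo] * counts[lo]) / w0
    mu1 <- sum(lev[!lo] * counts[!lo]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) {
      best <- v
      bt <- t
    }
  }
  bt
}

# Brute-force box-count oracle: examines every grid offset and takes the
# minimal covering (the box-counting definition), bounding the anchoring
# error of any single grid placement.
box_count_oracle <- function(mask, s) {
  idx <- which(mask, arr.ind = TRUE)
  counts <- numeric(0)
  for (or in 0:(s - 1)) {
    for (oc in 0:(s - 1)) {
      counts <- c(counts, length(unique(paste(
        (idx[, 1] + or) %/% s,
        (idx[, 2] + oc) %/% s
      ))))
    }
  }
  min(counts)
}

fd_oracle <- function(mask, sizes) {
  N <- vapply(sizes, function(s) box_count_oracle(mask, s), numeric(1))
  unname(stats::lm.fit(cbind(1, log(1 / sizes)), log(N))$coefficients[2])
}

# Rasterised Sierpinski triangle of the given subdivision order.
sierpinski_mask <- function(order) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(order)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, z), cbind(m, m))
  }
  m
}

# From-scratch sums-of-squares decomposition for the one-way
# repeated-measures ANOVA on an eyes x conditions matrix.
rm_anova_oracle <- function(M) {
  n <- nrow(M)
  a <- ncol(M)
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- a * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  df1 <- a - 1
  df2 <- (a - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_res / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}

# Null study table: three exchangeable arms, no condition effect.
null_table <- function(n = 20, seed = 1) {
  M <- octaquant:::with_seed(seed, matrix(stats::rnorm(n * 3), n, 3))
  df <- data.frame(
    eye = rep(sprintf("e%02d", seq_len(n)), each = 3),
    arm = rep(c("single", "denoised", "averaged"), times = n),
    vd = as.numeric(t(M))
  )
  df$vld <- df$vd
  df$vdi <- df$vd
  df$fd <- df$vd
  df$cnr <- df$vd
  study_table(df)
}
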