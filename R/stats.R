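# Three-arm within-subject comparison: repeated-measures ANOVA with
# Bonferroni-adjusted paired pairwise tests, summarised in the shape of a
# clinical comparison table.

.METRIC_COLS <- c("vd", "vld", "vdi", "fd", "cnr")
.ARM_LEVELS <- c("single", "denoised", "averaged")

#' Assemble a per-eye study table
#'
#' One row per eye and arm, with the five metric columns. Only complete
#' cases (eyes measured in every arm, no missing metric) are retained for a
#' given metric's analysis; the design is within-eye.
#'
#' @param rows a data frame with columns `eye`, `arm`, and the metrics
#'   `vd`, `vld`, `vdi`, `fd`, `cnr`.
#' @param arms arm levels, in display order.
#' @return a `study_table` data frame.
#' @export
study_table <- function(rows, arms = .ARM_LEVELS) {
  req <- c("eye", "arm", .METRIC_COLS)
  miss <- setdiff(req, names(rows))
  if (length(miss) > 0) {
    stop(sprintf("study table is missing columns: %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  rows$arm <- factor(as.character(rows$arm), levels = arms)
  if (anyNA(rows$arm)) stop("unknown arm labels in study table", call. = FALSE)
  rows <- rows[order(rows$eye, rows$arm), , drop = FALSE]
  class(rows) <- c("study_table", "data.frame")
  rows
}

# Wide eye x arm matrix for one metric, complete cases only.
metric_matrix <- function(table, metric) {
  if (!metric %in% .METRIC_COLS) {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }
  arms <- levels(table$arm)
  eyes <- unique(table$eye)
  M <- matrix(NA_real_, length(eyes), length(arms), dimnames = list(eyes, arms))
  for (i in seq_len(nrow(table))) {
    M[as.character(table$eye[i]), as.character(table$arm[i])] <- table[[metric]][i]
  }
  M[stats::complete.cases(M), , drop = FALSE]
}

#' One-way repeated-measures ANOVA for a metric
#'
#' Within-subject one-way ANOVA across the study arms, fitted with
#' [stats::aov()] using an `Error(eye)` stratum:
#' `F = MS_arm / MS_(arm x eye)` on `(a - 1, (a - 1)(n - 1))` degrees of
#' freedom.
#'
#' @param table a [study_table()].
#' @param metric one of `"vd"`, `"vld"`, `"vdi"`, `"fd"`, `"cnr"`.
#' @return a list with `F`, `p`, `df` (length 2), and `n` (subjects used).
#' @export
rm_anova <- function(table, metric) {
  M <- metric_matrix(table, metric)
  n <- nrow(M)
  a <- ncol(M)
  if (n < 3) stop("repeated-measures ANOVA needs at least 3 complete subjects", call. = FALSE)
  long <- data.frame(
    y = as.numeric(M),
    arm = factor(rep(colnames(M), each = n), levels = colnames(M)),
    eye = factor(rep(rownames(M), times = a))
  )
  fit <- stats::aov(y ~ arm + Error(eye), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fval <- unname(tab["arm", "F value"])
  p <- unname(tab["arm", "Pr(>F)"])
  df <- unname(c(tab["arm", "Df"], tab["Residuals", "Df"]))
  # degenerate structures: a condition sum of squares that is zero at the
  # data scale means no condition effect (F = 0, p = 1); a zero residual
  # with a real effect is a perfect separation (p = 0)
  ss_arm <- unname(tab["arm", "Sum Sq"])
  ss_res <- unname(tab["Residuals", "Sum Sq"])
  scale2 <- max(mean(long$y^2), .Machine$double.eps)
  if (ss_arm <= 1e-12 * scale2 * length(long$y)) {
    Fval <- 0
    p <- 1
  } else if (ss_res <= 1e-12 * scale2 * length(long$y)) {
    Fval <- Inf
    p <- 0
  }
  list(F = Fval, p = p, df = df, n = n)
}

#' Bonferroni-adjusted pairwise paired t-tests
#'
#' Two-sided paired t-tests for each pair of arms; each raw p-value is
#' multiplied by the number of pairs (3) and capped at 1. A zero-variance
#' difference yields p = 1 with a warning.
#'
#' @inheritParams rm_anova
#' @return a named numeric vector of adjusted p-values, one per arm pair
#'   (names like `"single_vs_denoised"`), with raw p-values in attribute
#'   `"raw"`.
#' @export
bonferroni_pairwise <- function(table, metric) {
  M <- metric_matrix(table, metric)
  arms <- colnames(M)
  pairs <- utils::combn(arms, 2)
  m <- ncol(pairs)
  raw <- numeric(m)
  nm <- character(m)
  for (j in seq_len(m)) {
    d <- M[, pairs[1, j]] - M[, pairs[2, j]]
    nm[j] <- paste(pairs[1, j], "vs", pairs[2, j], sep = "_")
    if (stats::sd(d) == 0) {
      warning(sprintf(
        "zero-variance paired differences for %s (%s); p set to 1",
        metric, nm[j]
      ), call. = FALSE)
      raw[j] <- 1
    } else {
      raw[j] <- stats::t.test(M[, pairs[1, j]], M[, pairs[2, j]], paired = TRUE)$p.value
    }
  }
  adj <- pmin(1, m * raw)
  names(adj) <- nm
  attr(adj, "raw") <- stats::setNames(raw, nm)
  adj
}

#' Compare the study arms metric by metric
#'
#' The package's summary fit: per metric, group means and sample standard
#' deviations per arm, the repeated-measures ANOVA omnibus test, and the
#' three Bonferroni-adjusted pairwise paired t-tests, with significance
#' flags at `alpha`.
#'
#' @param table a [study_table()].
#' @param metrics metrics to analyse (default all five).
#' @param alpha significance level for the flags.
#' @return an object of class `octa_comparison`.
#' @export
octa_compare <- function(table, metrics = .METRIC_COLS, alpha = 0.05) {
  stopifnot(inherits(table, "study_table"))
  res <- lapply(metrics, function(m) {
    M <- metric_matrix(table, m)
    means <- colMeans(M)
    sds <- apply(M, 2, stats::sd)
    if (nrow(M) >= 3) {
      om <- rm_anova(table, m)
      pw <- bonferroni_pairwise(table, m)
    } else {
      warning(sprintf("metric '%s': fewer than 3 complete eyes; tests skipped", m),
        call. = FALSE
      )
      om <- list(F = NA_real_, p = NA_real_, df = c(NA, NA), n = nrow(M))
      pw <- stats::setNames(
        rep(NA_real_, choose(ncol(M), 2)),
        apply(utils::combn(colnames(M), 2), 2, paste, collapse = "_vs_")
      )
    }
    if (nrow(M) < 2) sds[] <- NA_real_
    list(metric = m, mean = means, sd = sds, omnibus = om, pairwise = pw)
  })
  names(res) <- metrics
  structure(list(results = res, alpha = alpha, n_eyes = length(unique(table$eye))),
    class = "octa_comparison"
  )
}

#' @export
as.data.frame.octa_comparison <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    arms <- names(r$mean)
    out <- data.frame(metric = r$metric)
    for (a in arms) {
      out[[a]] <- sprintf("%.2f ± %.2f", r$mean[[a]], r$sd[[a]])
    }
    out$F <- r$omnibus$F
    out$p_omnibus <- r$omnibus$p
    pw <- r$pairwise
    for (nm in names(pw)) out[[paste0("p_", nm)]] <- pw[[nm]]
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.octa_comparison <- function(x, ...) {
  cat(sprintf(
    "Three-arm OCTA comparison (%d eyes): repeated-measures ANOVA + Bonferroni\n",
    x$n_eyes
  ))
  star <- function(p) ifelse(!is.na(p) & p < x$alpha, "*", " ")
  fmtp <- function(p) {
    ifelse(is.na(p), "NA", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  }
  for (r in x$results) {
    arms <- names(r$mean)
    cells <- paste(sprintf("%s %.2f±%.2f", arms, r$mean, r$sd), collapse = "  ")
    cat(sprintf(
      "  %-4s %s  | p=%s%s", toupper(r$metric), cells,
      fmtp(r$omnibus$p), star(r$omnibus$p)
    ))
    pw <- paste(sprintf("%s=%s%s", names(r$pairwise), fmtp(r$pairwise), star(r$pairwise)),
      collapse = " "
    )
    cat(sprintf("  | %s\n", pw))
  }
  invisible(x)
}

#' Write a comparison as a clinical-table-shaped CSV
#'
#' One row per metric: per-arm `mean ± SD`, the omnibus p-value, and the
#' three Bonferroni-adjusted pairwise p-values.
#'
#' @param comparison an [octa_compare()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  df <- as.data.frame(comparison)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
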