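#' Mask-transfer overlap ratio (Ov)
#'
#' `Ov = #pixels(CMSK & GT) / #pixels(GT)`: the fraction of ground-truth
#' mask pixels covered by the transferred mask. Note this is asymmetric —
#' it normalizes by GT only, so transferred-mask pixels outside GT (false
#' positives) do not lower it; it is not Dice or Jaccard, which are offered
#' separately as [dice_coefficient()] and [jaccard_index()].
#'
#' @param cmsk logical transferred (co-registered) cancer mask.
#' @param gt logical ground-truth cancer mask, nonempty.
#' @return scalar in `[0, 1]`.
#' @export
overlap_ratio <- function(cmsk, gt) {
  if (!all(dim(cmsk) == dim(gt))) stop("mask shapes differ")
  n_gt <- sum(gt != 0)
  if (n_gt == 0) stop("ground-truth mask is empty; Ov is undefined")
  sum(cmsk != 0 & gt != 0) / n_gt
}

#' @rdname overlap_ratio
#' @export
dice_coefficient <- function(cmsk, gt) {
  2 * sum(cmsk != 0 & gt != 0) / (sum(cmsk != 0) + sum(gt != 0))
}

#' @rdname overlap_ratio
#' @export
jaccard_index <- function(cmsk, gt) {
  sum(cmsk != 0 & gt != 0) / sum(cmsk != 0 | gt != 0)
}

#' Tumor cell count error (TCe)
#'
#' `TCe = |n_cmsk - n_gt| / n_gt`: the relative absolute difference between
#' the tumor-cell count under the transferred mask and under the
#' ground-truth mask. 0 when the counts agree; 1 when no tumor cells fall
#' under the transferred mask.
#'
#' @param n_cmsk cell count under the transferred mask.
#' @param n_gt cell count under the ground-truth mask; must be positive.
#' @return nonnegative scalar.
#' @export
tumor_count_error <- function(n_cmsk, n_gt) {
  stopifnot_scalar(n_cmsk, "n_cmsk"); stopifnot_scalar(n_gt, "n_gt")
  if (n_gt <= 0) stop("ground-truth cell count must be positive; TCe is undefined")
  abs(n_cmsk - n_gt) / n_gt
}

#' Joint mask-agreement summary
#'
#' Convenience wrapper computing Ov, TCe and the supplementary symmetric
#' overlap measures for one transferred/ground-truth mask pair and the
#' tumor-cell counts under each.
#'
#' @param cmsk,gt logical masks.
#' @param cells optional cell table (`row`, `col`, `label`); tumor-cell
#'   counts are the cells labeled `tumor` (or all cells if no `label`
#'   column) whose centroid lies under each mask.
#' @return list of class `mask_agreement`: `Ov`, `TCe` (`NA` without cells),
#'   `dice`, `jaccard`, pixel and cell counts.
#' @export
mask_agreement <- function(cmsk, gt, cells = NULL) {
  ov <- overlap_ratio(cmsk, gt)
  n_cmsk <- n_gt <- NA_integer_; tce <- NA_real_
  if (!is.null(cells) && nrow(cells)) {
    tum <- if ("label" %in% names(cells)) cells[cells$label == "tumor", ] else cells
    if (nrow(tum)) {
      at <- cbind(pmin(pmax(round(tum$row), 1L), nrow(gt)),
                  pmin(pmax(round(tum$col), 1L), ncol(gt)))
      n_cmsk <- sum(cmsk[at]); n_gt <- sum(gt[at])
      if (n_gt > 0) tce <- tumor_count_error(n_cmsk, n_gt)
    }
  }
  structure(list(Ov = ov, TCe = tce, dice = dice_coefficient(cmsk, gt),
                 jaccard = jaccard_index(cmsk, gt),
                 n_pixels_cmsk = sum(cmsk != 0), n_pixels_gt = sum(gt != 0),
                 n_cells_cmsk = n_cmsk, n_cells_gt = n_gt),
            class = "mask_agreement")
}

#' Pearson correlation with validity checks
#'
#' Sample product-moment correlation; errors on constant input or fewer
#' than 3 pairs, where the coefficient is undefined or meaningless.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; reports their mean, sd (n-1 denominator), 95%
#' limits of agreement `mean +/- 1.96 sd`, and a one-sided paired t-test
#' p-value for the mean difference (direction configurable). With zero
#' variance the t statistic is degenerate: p is 0 if the mean difference
#' already lies strictly in the tested direction, 1 if strictly opposite,
#' and 0.5 at exactly zero.
#'
#' @param a,b paired numeric vectors, equal length >= 2.
#' @param direction alternative for the t-test: `"greater"` tests
#'   `mean(a - b) > 0`.
#' @return list of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `p_one_sided`, `n`, and the per-pair `means`/`diffs` for
#'   plotting.
#' @export
bland_altman <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) stop("lengths differ")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  p <- if (s == 0) {
    if (m == 0) 0.5
    else if ((m > 0) == (direction == "greater")) 0 else 1
  } else {
    stats::t.test(d, mu = 0, alternative = direction)$p.value
  }
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 p_one_sided = p, n = length(d),
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' One-way ANOVA
#'
#' Classic between/within mean-square F with `(k - 1, N - k)` degrees of
#' freedom, p-value from the F distribution. Fails explicitly when the
#' pooled within-group variance is zero.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  N <- length(x); k <- nlevels(g)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) stop("zero within-group variance; F is undefined")
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k)
}

#' Bland-Altman plot
#'
#' Mean of each pair on x, difference on y, with the mean-difference line
#' and the two limits of agreement.
#'
#' @param ba a [bland_altman()] result.
#' @param file optional PNG path; plots to the current device if `NULL`.
#' @param ... passed to [plot()].
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, file = NULL, ...) {
  if (!is.null(file)) { grDevices::png(file, width = 600, height = 480); on.exit(grDevices::dev.off()) }
  plot(ba$means, ba$diffs, xlab = "Mean of pair", ylab = "Difference",
       main = "Bland-Altman", pch = 19, ...)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
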