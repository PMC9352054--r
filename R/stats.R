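#' Standardized median difference
#'
#' Robust effect-size summary comparing a treatment distribution to its
#' control: `(median(sample) - median(control)) / s_pool`. The pooled scale
#' is `sqrt((s1^2 + s2^2) / 2)` with per-group scale `s = 1.4826 * MAD` by
#' default (consistent with the median-based numerator and the heavy tails
#' of posture features); a classical standard-deviation scale is available
#' behind `scale`.
#'
#' @param sample,control numeric vectors (non-empty; `NA` dropped).
#' @param scale `"mad"` (default) or `"sd"`.
#' @return The SMD; `NaN` with a warning if the pooled scale is zero.
#' @export
smd <- function(sample, control, scale = c("mad", "sd")) {
  scale <- match.arg(scale)
  sample <- sample[!is.na(sample)]; control <- control[!is.na(control)]
  if (!length(sample) || !length(control))
    stop_domain("both samples must be non-empty")
  s1 <- if (scale == "mad") mad(sample) else sd(sample)
  s2 <- if (scale == "mad") mad(control) else sd(control)
  s_pool <- sqrt((s1^2 + s2^2) / 2)
  if (!is.finite(s_pool) || s_pool == 0) {
    warning("pooled scale is zero or undefined; SMD is NaN")
    return(NaN)
  }
  (median(sample) - median(control)) / s_pool
}

#' Shapiro-Wilk normality report
#'
#' Applies the Shapiro-Wilk test at the given alpha. The test is defined
#' for 3 <= n <= 5000; larger samples are thinned to 5000 evenly spaced
#' order-preserving values (deterministic, flagged in the result).
#'
#' @param sample numeric vector (`NA` dropped).
#' @param alpha significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `reject` (normality rejected),
#'   `n`, `subsampled`.
#' @export
normality <- function(sample, alpha = 0.05) {
  x <- sample[!is.na(sample)]
  if (length(x) < 3) stop_domain("need at least 3 observations")
  subsampled <- length(x) > 5000
  if (subsampled) x <- x[round(seq(1, length(x), length.out = 5000))]
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       reject = sw$p.value < alpha, n = length(x), subsampled = subsampled)
}

comparison_result <- function(feature, n1, n2, statistic, p_two, p_less,
                              p_greater, effect, alpha) {
  structure(list(feature = feature, n1 = n1, n2 = n2, statistic = statistic,
                 p_two_sided = p_two, p_less = p_less, p_greater = p_greater,
                 effect_size = effect, alpha = alpha,
                 significant = is.finite(p_two) && p_two < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: stat %.4g, p (two-sided) %.4g%s, n = %d/%d\n",
              x$feature, x$statistic, x$p_two_sided,
              if (x$significant) " *" else "", x$n1, x$n2))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(feature = x$feature, n1 = x$n1, n2 = x$n2,
             statistic = x$statistic, p_two_sided = x$p_two_sided,
             p_less = x$p_less, p_greater = x$p_greater,
             effect_size = x$effect_size, alpha = x$alpha,
             significant = x$significant)
}

#' Wilcoxon signed-rank comparison of paired samples
#'
#' Two-sided and both one-sided p values for the paired signed-rank test
#' (zero differences dropped by the signed-rank convention; exact null for
#' small samples without ties, normal approximation with tie correction
#' otherwise). Used for comparing features across body segments, where
#' values along one animal's body are dependent.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alpha significance level (default 0.05).
#' @param feature label carried into the result.
#' @return A `comparison_result`; `degenerate = TRUE` attribute when all
#'   differences are zero.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05, feature = "feature") {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  d <- x - y
  if (all(d == 0)) {
    res <- comparison_result(feature, length(x), length(y), NA_real_,
                             NA_real_, NA_real_, NA_real_, NA_real_, alpha)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
  w2 <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  wl <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                     alternative = "less"))
  wg <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                     alternative = "greater"))
  comparison_result(feature, length(x), length(y), unname(w2$statistic),
                    w2$p.value, wl$p.value, wg$p.value, NA_real_, alpha)
}

#' Pairwise signed-rank tests of a feature across body segments
#'
#' @param values n x S matrix: one column per segment, rows paired (frames
#'   or animals).
#' @param alpha significance level.
#' @return data.frame of all segment pairs with two- and one-sided p values.
#' @export
paired_segment_test <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  segs <- colnames(values) %||% paste0("seg", seq_len(ncol(values)))
  out <- list()
  for (i in seq_len(ncol(values) - 1)) for (j in (i + 1):ncol(values)) {
    r <- wilcoxon_signed_rank(values[, i], values[, j], alpha,
                              feature = paste(segs[i], "vs", segs[j]))
    out[[length(out) + 1L]] <- as.data.frame(r)
  }
  do.call(rbind, out)
}

#' Mann-Whitney U comparison of a feature between a drug and its control
#'
#' Two-sided and one-sided p values, the U statistic and the effect size
#' `U / (n1 * n2)` (in \[0, 1\], 0.5 under exchangeability). Significance is
#' judged at the Bonferroni-corrected level `0.05 / n_features`, 0.002 for
#' the 25-feature posture panel.
#'
#' @param x feature values under the condition.
#' @param y feature values under the control.
#' @param n_features Bonferroni divisor (default 25).
#' @param base_alpha uncorrected alpha (default 0.05).
#' @param feature label carried into the result.
#' @return A `comparison_result` with `alpha = base_alpha / n_features`.
#' @export
drug_vs_control_test <- function(x, y, n_features = 25, base_alpha = 0.05,
                                 feature = "feature") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop_domain("both samples must be non-empty")
  alpha <- base_alpha / n_features
  w2 <- suppressWarnings(wilcox.test(x, y))
  wl <- suppressWarnings(wilcox.test(x, y, alternative = "less"))
  wg <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  U <- unname(w2$statistic)
  comparison_result(feature, length(x), length(y), U, w2$p.value, wl$p.value,
                    wg$p.value, U / (length(x) * length(y)), alpha)
}

#' Compare per-video usage percentages between condition and control
#'
#' Mann-Whitney U on the distributions of per-video percentage usage of a
#' state or cluster (each video contributes the percentage of its frames
#' spent in the state), at alpha = 0.05 uncorrected.
#'
#' @param pct_condition,pct_control numeric vectors of per-video
#'   percentages.
#' @param alpha significance level.
#' @param feature label.
#' @return A `comparison_result`.
#' @export
usage_comparison <- function(pct_condition, pct_control, alpha = 0.05,
                             feature = "usage") {
  pct_condition <- pct_condition[!is.na(pct_condition)]
  pct_control <- pct_control[!is.na(pct_control)]
  if (length(pct_condition) < 2 || length(pct_control) < 2)
    stop_domain("need at least 2 videos per group")
  w2 <- suppressWarnings(wilcox.test(pct_condition, pct_control))
  wl <- suppressWarnings(wilcox.test(pct_condition, pct_control,
                                     alternative = "less"))
  wg <- suppressWarnings(wilcox.test(pct_condition, pct_control,
                                     alternative = "greater"))
  U <- unname(w2$statistic)
  comparison_result(feature, length(pct_condition), length(pct_control), U,
                    w2$p.value, wl$p.value, wg$p.value,
                    U / (length(pct_condition) * length(pct_control)), alpha)
}

#' Per-video usage percentages from labeled sequences
#'
#' @param label_seqs list of per-video label vectors (`NA` skipped).
#' @param n_labels number of states/clusters.
#' @return matrix videos x labels of percentages (rows sum to 100).
#' @export
per_video_usage <- function(label_seqs, n_labels) {
  t(vapply(label_seqs, function(ls) {
    ls <- ls[!is.na(ls) & ls >= 1]
    100 * tabulate(ls, n_labels) / length(ls)
  }, numeric(n_labels)))
}

#' Light-stimulus protocol
#'
#' A 60-second stimulus window presented at the 30th second of the
#' recording, in one of four colors.
#'
#' @param color stimulus color.
#' @param onset_s stimulus onset in seconds (>= 10, leaving room for the
#'   10-second before-window).
#' @param duration_s stimulus duration in seconds.
#' @param fps frames per second.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(color = c("white", "red", "green", "blue"),
                              onset_s = 30, duration_s = 60, fps = 30) {
  color <- match.arg(color)
  if (onset_s < 10)
    stop_domain("onset must be at least 10 s to fit the before-window")
  structure(list(color = color, onset_s = onset_s, duration_s = duration_s,
                 fps = fps), class = "stimulus_protocol")
}

#' Event analysis windows around stimulus ON and OFF
#'
#' Frame ranges (0-based, half-open, start-inclusive) computed from the
#' protocol: a 10-second window immediately before each event and a
#' 2.5-second window starting 0.5 s after it (the post-event skip applies
#' to both the ON and the OFF event). At 30 fps with onset 30 s, the ON
#' windows are frames \[600, 900) and \[915, 990).
#'
#' @param protocol a [stimulus_protocol()].
#' @param n_frames optional recording length for bounds checking.
#' @return List of 4 two-element integer vectors `c(start, end)` (half-open
#'   0-based frame ranges): `before_on`, `after_on`, `before_off`,
#'   `after_off`.
#' @export
event_windows <- function(protocol, n_frames = NULL) {
  fps <- protocol$fps
  on <- protocol$onset_s * fps
  off <- (protocol$onset_s + protocol$duration_s) * fps
  w <- list(before_on = c(on - 10 * fps, on),
            after_on = c(on + 0.5 * fps, on + 3.0 * fps),
            before_off = c(off - 10 * fps, off),
            after_off = c(off + 0.5 * fps, off + 3.0 * fps))
  w <- lapply(w, function(v) as.integer(round(v)))
  if (w$before_on[1] < 0)
    stop_domain("recording does not span the before-ON window")
  if (!is.null(n_frames) && w$after_off[2] > n_frames)
    stop_domain("recording too short for the after-OFF window (needs ",
                w$after_off[2], " frames)")
  w
}

#' Per-feature stimulus-response SMDs
#'
#' For each feature of the 25-feature panel, the standardized median
#' difference between the after and before windows (sign convention:
#' after - before), separately for the ON and OFF events.
#'
#' @param panel a [feature_panel()] data.frame (with `frame_index`).
#' @param windows an [event_windows()] list.
#' @param scale passed to [smd()].
#' @return data.frame with `feature`, `smd_on`, `smd_off`.
#' @export
event_response <- function(panel, windows, scale = "mad") {
  feats <- panel_feature_names()
  in_win <- function(w) panel$frame_index >= w[1] & panel$frame_index < w[2]
  pick <- lapply(windows, function(w) panel[in_win(w), feats, drop = FALSE])
  one <- function(f, after, before) {
    a <- after[[f]]; b <- before[[f]]
    if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
    suppressWarnings(smd(a, b, scale = scale))
  }
  data.frame(feature = feats,
             smd_on = vapply(feats, one, numeric(1),
                             after = pick$after_on, before = pick$before_on),
             smd_off = vapply(feats, one, numeric(1),
                              after = pick$after_off, before = pick$before_off),
             row.names = NULL)
}
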