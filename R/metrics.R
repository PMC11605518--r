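#' Intended and unintended movement RMSE for a trial
#'
#' Intended RMSE is the error on the DOF(s) the trial actively moves (the
#' nonzero target), averaged across active DOFs if there are several.
#' Unintended RMSE is the cross-talk: each resting DOF's RMSE against its
#' zero (rest) target, averaged across the resting DOFs. Both are computed
#' over the trial's annotated frame span only.
#'
#' @param decoded A `decoded_trace` (or 12 x frames matrix).
#' @param target A `kin_trace` (or 12 x frames matrix) of target kinematics.
#' @param annotation One-row annotation (from a session's `annotations`)
#'   giving `dofs`, `frame_start`, `frame_end`.
#' @return Named numeric vector `c(intended, unintended)`.
#' @export
intended_unintended_rmse <- function(decoded, target, annotation) {
  D <- trace_values(decoded)
  Tg <- trace_values(target)
  dofs <- unlist(annotation$dofs)
  if (length(dofs) == 0) stopf("annotation has no active DOF")
  span <- annotation$frame_start:annotation$frame_end
  rest <- setdiff(seq_len(nrow(Tg)), dofs)
  err <- D[, span, drop = FALSE] - Tg[, span, drop = FALSE]
  per_dof_rmse <- sqrt(rowMeans(err^2))
  c(intended = mean(per_dof_rmse[dofs]),
    unintended = if (length(rest)) mean(per_dof_rmse[rest]) else NA_real_)
}

trace_values <- function(x) {
  if (inherits(x, "decoded_trace") || inherits(x, "kin_trace")) x$values
  else as.matrix(x)
}

#' RMSE with an error-free tolerance window
#'
#' Per-frame error is reduced by the window half-width before squaring:
#' a DOF anywhere within `window` of its target contributes zero, matching
#' the visual feedback of the target-holding task.
#'
#' @param decoded,target 12 x frames traces (or single-DOF vectors).
#' @param window Tolerance half-width in kinematic units (0.15 = the 15%
#'   window of the normalized range).
#' @return Scalar windowed RMSE over all supplied entries.
#' @export
windowed_rmse <- function(decoded, target, window = 0.15) {
  if (window < 0) stopf("window must be nonnegative")
  d <- as.numeric(trace_values(decoded))
  t <- as.numeric(trace_values(target))
  e <- pmax(abs(d - t) - window, 0)
  sqrt(mean(e^2))
}

#' Time-in-target occupancy and longest hold
#'
#' A frame counts as "in target" when every DOF is within `window` of its
#' target. Returns the percentage of in-target frames over the span and the
#' longest consecutive in-target run in seconds.
#'
#' @param decoded,target 12 x frames traces over a single trial span.
#' @param window Tolerance half-width.
#' @param frame_rate Frames per second.
#' @return Named vector `c(pct_time_in_target, max_hold_s)`.
#' @export
ttt_occupancy <- function(decoded, target, window = 0.15, frame_rate = 30) {
  D <- trace_values(decoded)
  Tg <- trace_values(target)
  if (ncol(D) == 0) stopf("empty trial span")
  ok <- colSums(abs(D - Tg) > window) == 0
  runs <- rle(ok)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  c(pct_time_in_target = 100 * mean(ok),
    max_hold_s = max_run / frame_rate)
}

#' Log mean absolute jerk of a decoded trajectory
#'
#' Jerk is the third time-derivative, estimated by third-order central
#' finite differences scaled by `frame_rate^3`; the statistic is the natural
#' log of the mean absolute jerk over frames and the supplied DOFs (use the
#' trial's active DOFs). Lower is smoother. A constant trace has zero jerk;
#' `-Inf` is returned with a warning.
#'
#' @param decoded Trace matrix (DOFs x frames) or vector; pass only the
#'   active DOF rows.
#' @param frame_rate Frames per second.
#' @return Scalar, log(position units / s^3).
#' @export
log_mean_abs_jerk <- function(decoded, frame_rate = 30) {
  x <- if (is.numeric(decoded) && is.null(dim(decoded)))
    matrix(decoded, nrow = 1) else trace_values(decoded)
  if (ncol(x) < 4) stopf("need at least 4 frames for a third difference")
  # central third difference: (x[t+2] - 2 x[t+1] + 2 x[t-1] - x[t-2]) / 2
  n <- ncol(x)
  j <- (x[, 5:n, drop = FALSE] - 2 * x[, 4:(n - 1), drop = FALSE] +
          2 * x[, 2:(n - 3), drop = FALSE] - x[, 1:(n - 4), drop = FALSE]) / 2
  mj <- mean(abs(j)) * frame_rate^3
  if (mj <= 0) {
    warning("constant trace: jerk is zero, returning -Inf")
    return(-Inf)
  }
  log(mj)
}

#' Per-DOF least-squares robustness slopes
#'
#' Fits an ordinary least-squares line to test RMSE as a function of days
#' since training, separately per DOF (and any further grouping columns
#' present): the slope (RMSE/day) measures how fast performance decays.
#'
#' @param rmse_by_day Data frame with columns `dof`, `day`, `rmse`.
#' @return Data frame with one row per DOF: `dof`, `slope`, `intercept`,
#'   `n_points`, plus a `summary` attribute with the median and IQR of the
#'   slopes.
#' @export
robustness_slopes <- function(rmse_by_day) {
  stopifnot(all(c("dof", "day", "rmse") %in% names(rmse_by_day)))
  fits <- lapply(split(rmse_by_day, rmse_by_day$dof), function(d) {
    if (length(unique(d$day)) < 2)
      stopf("DOF %s has fewer than 2 distinct days", d$dof[1])
    co <- stats::coef(stats::lm(rmse ~ day, data = d))
    data.frame(dof = d$dof[1], slope = unname(co["day"]),
               intercept = unname(co["(Intercept)"]), n_points = nrow(d))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  attr(out, "summary") <- c(median = stats::median(out$slope),
                            iqr_lo = unname(stats::quantile(out$slope, 0.25)),
                            iqr_hi = unname(stats::quantile(out$slope, 0.75)))
  out
}

#' Nonparametric comparison across conditions
#'
#' Kruskal-Wallis test across the conditions; when significant at
#' `alpha`, pairwise Wilcoxon rank-sum comparisons with a Tukey-style
#' studentized-range correction applied to the rank statistics (the normal
#' approximation of each pairwise rank-sum z is referred to the studentized
#' range distribution over the number of groups; approximate, as is
#' conventional for rank-based post hoc tests).
#'
#' @param samples_by_condition Named list of numeric vectors (>= 2
#'   conditions with >= 3 samples each).
#' @param alpha Significance gate for running the post hoc comparisons.
#' @return List with `H`, `df`, `p_value`, and (when run) `pairwise`, a data
#'   frame of group pairs with corrected p-values and effect directions.
#' @export
compare_groups <- function(samples_by_condition, alpha = 0.05) {
  g <- samples_by_condition
  if (length(g) < 2) stopf("need at least 2 conditions")
  if (any(vapply(g, length, 1L) < 3)) stopf("need >= 3 samples per condition")
  if (is.null(names(g))) names(g) <- paste0("g", seq_along(g))
  pooled <- unlist(g, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    warning("all observations tied; comparison is degenerate")
    return(list(H = 0, df = length(g) - 1L, p_value = 1, pairwise = NULL))
  }
  kw <- stats::kruskal.test(g)
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              p_value = kw$p.value, pairwise = NULL)
  if (kw$p.value < alpha) {
    nms <- names(g)
    pr <- utils::combn(length(g), 2)
    rows <- lapply(seq_len(ncol(pr)), function(i) {
      a <- g[[pr[1, i]]]; b <- g[[pr[2, i]]]
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      # normal approximation of the rank-sum statistic -> studentized range
      z <- stats::qnorm(pmax(pmin(wt$p.value, 1 - 1e-15), 1e-15) / 2,
                        lower.tail = FALSE)
      p_adj <- stats::ptukey(z * sqrt(2), nmeans = length(g), df = Inf,
                             lower.tail = FALSE)
      data.frame(group1 = nms[pr[1, i]], group2 = nms[pr[2, i]],
                 direction = sign(stats::median(a) - stats::median(b)),
                 p_raw = wt$p.value, p_adj = p_adj)
    })
    out$pairwise <- do.call(rbind, rows)
  }
  out
}
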