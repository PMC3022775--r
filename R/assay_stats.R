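#' Summarize one condition with QC accounting
#'
#' Excludes larvae failing the orientation check, then larvae in which no
#' neuromast ROI was detected (not data-producing), and reports
#' mean +/- SEM of the remaining scores. `min_n_ok` records whether the
#' number of analyzed larvae reaches the assay's minimum (30 for the
#' automated intensity mode, 15 for the manual-analogue count mode).
#'
#' @param measurements data.frame of per-larva rows (see
#'   [measurements_df()]) sharing one condition label.
#' @param min_n minimum larvae per condition; default 30 for intensity
#'   mode, 15 for count mode.
#' @param score_col which score to aggregate; default
#'   `"inflammation_score"` for intensity mode, `"band_count"` for count
#'   mode.
#' @return one-row data.frame of class `condition_summary`: condition,
#'   n_assigned, n_excluded_orientation, n_excluded_no_roi, n_analyzed,
#'   mean, sem, min_n_ok.
#' @export
summarize_condition <- function(measurements, min_n = NULL,
                                score_col = NULL) {
  m <- as.data.frame(measurements)
  if (nrow(m) && length(unique(m$condition)) > 1L)
    .chin_stop("'measurements' must share one condition label")
  mode <- if (nrow(m)) m$mode[1] else "intensity"
  min_n <- min_n %||% (if (identical(mode, "count")) 15L else 30L)
  score_col <- score_col %||%
    (if (identical(mode, "count")) "band_count" else "inflammation_score")

  n_assigned <- nrow(m)
  ok_orient <- if (n_assigned) m$orientation_ok else logical(0)
  n_excl_orient <- sum(!ok_orient)
  m2 <- m[ok_orient, , drop = FALSE]
  producing <- if (nrow(m2)) m2$data_producing & !is.na(m2[[score_col]])
    else logical(0)
  n_excl_no_roi <- sum(!producing)
  scores <- m2[[score_col]][producing]
  n <- length(scores)
  data.frame(
    condition = if (n_assigned) m$condition[1] else NA_character_,
    n_assigned = n_assigned,
    n_excluded_orientation = n_excl_orient,
    n_excluded_no_roi = n_excl_no_roi,
    n_analyzed = n,
    mean = if (n >= 1) mean(scores) else NA_real_,
    sem = if (n >= 2) sd(scores) / sqrt(n) else NA_real_,
    min_n_ok = n >= min_n,
    stringsAsFactors = FALSE)
}

#' Welch's unpaired two-sample t-test
#'
#' Two-sided unpaired t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom) — the test the assay uses for
#' every between-condition comparison. Backed by [stats::t.test()] with
#' `var.equal = FALSE`.
#'
#' @param scores_a,scores_b numeric score vectors, each of length >= 2.
#' @param condition_a,condition_b optional labels for reporting.
#' @return an object of class `welch_test`: `t_statistic`,
#'   `degrees_freedom`, `p_value`, `stars`, plus the group labels.
#' @export
welch_t_test <- function(scores_a, scores_b,
                         condition_a = "a", condition_b = "b") {
  scores_a <- as.numeric(scores_a); scores_b <- as.numeric(scores_b)
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    .chin_stop("each group needs at least 2 observations")
  if (anyNA(scores_a) || anyNA(scores_b) ||
      any(!is.finite(c(scores_a, scores_b))))
    .chin_stop("scores must be finite and non-missing")
  if (var(scores_a) == 0 && var(scores_b) == 0) {
    # degenerate: both groups constant; identical groups are a clean null
    if (mean(scores_a) == mean(scores_b)) {
      t_stat <- 0; df <- length(scores_a) + length(scores_b) - 2; p <- 1
    } else .chin_stop("both groups have zero variance; t-test undefined")
  } else {
    tt <- t.test(scores_a, scores_b, var.equal = FALSE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 t_statistic = t_stat, degrees_freedom = df, p_value = p,
                 stars = significance_stars(p)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test %s vs %s: t = %.4g, df = %.4g, p = %.4g %s\n",
              x$condition_a, x$condition_b, x$t_statistic,
              x$degrees_freedom, x$p_value, x$stars))
  invisible(x)
}

#' Map a p-value to significance stars
#'
#' `p < 0.001` gives `"***"`, `0.001 <= p < 0.01` gives `"**"`,
#' `0.01 <= p < 0.05` gives `"*"`, anything else `"ns"`. Boundary values
#' resolve toward the weaker claim.
#'
#' @param p_value numeric vector of p-values in `[0, 1]`.
#' @return character vector of labels.
#' @export
significance_stars <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1))
    .chin_stop("'p_value' must lie in [0, 1]")
  ifelse(p_value < 0.001, "***",
         ifelse(p_value < 0.01, "**",
                ifelse(p_value < 0.05, "*", "ns")))
}

#' Per-condition screen statistics
#'
#' Aggregates per-larva measurements into condition summaries and compares
#' every treatment condition against the designated control with Welch's
#' t-test (no multiple-testing correction by default, matching the assay's
#' original analysis; set `bonferroni = TRUE` to adjust).
#'
#' @param measurements data.frame of per-larva rows (see
#'   [measurements_df()]).
#' @param control the control condition label (must be present).
#' @param min_n minimum analyzed larvae per condition (default by mode).
#' @param bonferroni apply Bonferroni correction across comparisons.
#' @return an object of class `chin_screen`: `summaries` and
#'   `comparisons` data.frames plus bookkeeping fields.
#' @export
screen_stats <- function(measurements, control, min_n = NULL,
                         bonferroni = FALSE) {
  m <- as.data.frame(measurements)
  if (missing(control) || is.null(control) || is.na(control))
    .chin_stop("a control condition must be designated")
  if (!control %in% m$condition)
    .chin_stop("control condition '", control,
               "' not present in the measurements")
  conds <- unique(m$condition)
  summaries <- do.call(rbind, lapply(conds, function(cc)
    summarize_condition(m[m$condition == cc, , drop = FALSE],
                        min_n = min_n)))
  score_col <- if (identical(m$mode[1], "count")) "band_count"
    else "inflammation_score"
  usable <- function(cc) {
    r <- m[m$condition == cc & m$orientation_ok & m$data_producing, ,
           drop = FALSE]
    r[[score_col]][!is.na(r[[score_col]])]
  }
  ctrl_scores <- usable(control)
  others <- setdiff(conds, control)
  comparisons <- do.call(rbind, lapply(others, function(cc) {
    w <- welch_t_test(usable(cc), ctrl_scores, cc, control)
    data.frame(condition_a = cc, condition_b = control,
               t_statistic = w$t_statistic,
               degrees_freedom = w$degrees_freedom,
               p_value = w$p_value, stars = w$stars,
               stringsAsFactors = FALSE)
  }))
  if (is.null(comparisons))
    comparisons <- data.frame(condition_a = character(),
                              condition_b = character(),
                              t_statistic = numeric(),
                              degrees_freedom = numeric(),
                              p_value = numeric(), stars = character())
  if (bonferroni && nrow(comparisons)) {
    comparisons$p_value <- stats::p.adjust(comparisons$p_value,
                                           method = "bonferroni")
    comparisons$stars <- significance_stars(comparisons$p_value)
  }
  structure(list(summaries = summaries, comparisons = comparisons,
                 control = control, mode = if (nrow(m)) m$mode[1] else NA,
                 n_larvae = nrow(m)),
            class = "chin_screen")
}

#' @export
print.chin_screen <- function(x, ...) {
  cat(sprintf("ChIn screen (%s mode), %d larvae, control = %s\n\n",
              x$mode, x$n_larvae, x$control))
  cat("Condition summaries (mean +/- SEM):\n")
  print(x$summaries, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nWelch t-tests vs control:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.chin_screen <- function(object, ...) object

#' Bar chart of the screen: mean +/- SEM with significance stars
#'
#' @param x a `chin_screen`.
#' @param main plot title.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.chin_screen <- function(x, main = "ChIn assay",
                             ylab = NULL, ...) {
  s <- x$summaries
  ylab <- ylab %||% if (identical(x$mode, "count"))
    "leukocytes in myoseptum band" else "mean relative red intensity"
  sem <- ifelse(is.na(s$sem), 0, s$sem)
  top <- max(s$mean + sem, na.rm = TRUE)
  mids <- graphics::barplot(s$mean, names.arg = s$condition,
                            ylim = c(0, 1.25 * top), main = main,
                            ylab = ylab, col = "grey80", ...)
  graphics::arrows(mids, s$mean - sem, mids, s$mean + sem, angle = 90,
                   code = 3, length = 0.05)
  if (nrow(x$comparisons)) {
    lab <- x$comparisons$stars[match(s$condition,
                                     x$comparisons$condition_a)]
    lab[is.na(lab)] <- ""
    graphics::text(mids, s$mean + sem + 0.06 * top, lab)
  }
  invisible(mids)
}

#' Write the screen report to disk
#'
#' Writes `summary.csv` (per-condition n, exclusions, mean, SEM),
#' `comparisons.csv` (Welch tests of each treatment against the control)
#' and `report.png` (bar chart with error bars and stars) under `out_dir`.
#'
#' @param screen a [screen_stats()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
screen_report <- function(screen, out_dir) {
  stopifnot(inherits(screen, "chin_screen"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("summary.csv", "comparisons.csv",
                                "report.png"))
  write.csv(screen$summaries, paths[1], row.names = FALSE)
  write.csv(screen$comparisons, paths[2], row.names = FALSE)
  grDevices::png(paths[3], width = 900, height = 600)
  on.exit(grDevices::dev.off())
  plot(screen)
  invisible(paths)
}
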