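# Per-metric QC scoring on a 0-10 scale, stage aggregation and
# Poor/Warning/Good flags. Score bands: [0,6) Poor, [6,8) Warning, [8,10]
# Good; each metric's raw range [min, t1, t2, upper] is mapped piecewise
# affinely onto 0/6/8/10.

#' Define a QC metric specification
#'
#' @param name Metric name.
#' @param direction `"higher_better"` or `"lower_better"`. For lower-better
#'   metrics the score is complemented (`10 - score`) after mapping.
#' @param t1 Poor/Warning boundary on the raw scale (maps to score 6).
#' @param t2 Warning/Good boundary (maps to score 8).
#' @param min_value Lower end of the raw range (maps to score 0).
#' @param upper_bound Fixed raw maximum (maps to score 10), or `NA` to
#'   resolve it from a cohort as `75th percentile + 1.5 * IQR` (upper
#'   outliers score 10).
#' @param stage Processing stage the metric belongs to (used by
#'   [qc_flag_table()]).
#' @return A `metric_spec` list.
#' @export
metric_spec <- function(name, direction = c("higher_better", "lower_better"),
                        t1, t2, min_value = 0, upper_bound = NA,
                        stage = "alignment") {
  direction <- match.arg(direction)
  structure(list(name = name, direction = direction, t1 = t1, t2 = t2,
                 min_value = min_value, upper_bound = upper_bound,
                 stage = stage),
            class = "metric_spec")
}

resolve_upper <- function(spec, cohort) {
  if (!is.na(spec$upper_bound)) return(spec$upper_bound)
  if (is.null(cohort) || !length(cohort))
    abort(paste0("metric '", spec$name,
                 "' needs a cohort to resolve its IQR upper bound"))
  q <- quantile(cohort, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Score a raw metric value on the 0-10 QC scale
#'
#' Piecewise-affine normalization: `[min, t1]` maps onto `[0, 6]`,
#' `[t1, t2]` onto `[6, 8]`, `[t2, upper]` onto `[8, 10]`; values at or
#' beyond the bounds are clamped to 0 / 10. Lower-better metrics return the
#' complement `10 - score`.
#'
#' @param value Raw metric value(s); must be finite.
#' @param spec A [metric_spec()].
#' @param cohort Cohort of raw values of the same metric, required only when
#'   `spec$upper_bound` is `NA` (IQR rule).
#' @return Numeric score(s) in \eqn{[0, 10]}.
#' @export
score_metric <- function(value, spec, cohort = NULL) {
  if (any(!is.finite(value))) abort("metric value must be finite")
  upper <- resolve_upper(spec, cohort)
  brk <- c(spec$min_value, spec$t1, spec$t2, upper)
  if (any(diff(brk) <= 0))
    abort(paste0("degenerate metric intervals for '", spec$name,
                 "': need min < t1 < t2 < upper"))
  sc <- numeric(length(value))
  lo <- value <= brk[1]; hi <- value >= brk[4]
  sc[lo] <- 0; sc[hi] <- 10
  mid <- !lo & !hi
  if (any(mid)) {
    v <- value[mid]
    seg <- findInterval(v, brk, rightmost.closed = TRUE)
    lows <- c(0, 6, 8); highs <- c(6, 8, 10)
    sc[mid] <- lows[seg] + (highs[seg] - lows[seg]) *
      (v - brk[seg]) / (brk[seg + 1] - brk[seg])
  }
  if (spec$direction == "lower_better") sc <- 10 - sc
  pmin(10, pmax(0, sc))
}

#' Aggregate metric scores into a stage score and flag
#'
#' @param scores Numeric vector of metric scores in \eqn{[0, 10]} (>= 1).
#' @return A one-row tibble `(s_agg, flag)` where `s_agg` is the mean score
#'   and `flag` is Poor (`s_agg < 6`), Warning (`6 <= s_agg < 8`) or Good
#'   (`s_agg >= 8`).
#' @export
aggregate_stage <- function(scores) {
  if (!length(scores)) abort("need at least one metric score")
  s <- mean(scores)
  tibble(s_agg = s, flag = flag_from_score(s))
}

flag_from_score <- function(s) {
  if_else(s < 6, "Poor", if_else(s < 8, "Warning", "Good"))
}

flag_levels <- c("Poor", "Warning", "Good")

#' Combine stage flags into a final QC flag
#'
#' Good only when every stage flag is Good; otherwise worst-of (Poor if any
#' stage is Poor, else Warning).
#'
#' @param stage_flags Character vector of stage flags (>= 1), each one of
#'   `"Poor"`, `"Warning"`, `"Good"`.
#' @return A single flag string.
#' @export
final_flag <- function(stage_flags) {
  if (!length(stage_flags)) abort("need at least one stage flag")
  if (!all(stage_flags %in% flag_levels)) abort("unknown flag value")
  flag_levels[min(match(stage_flags, flag_levels))]
}

#' Score a sample-by-metric table and assign stage and final flags
#'
#' @param metrics Tibble with a `sample_id` column and one numeric column
#'   per metric named in `specs`. Each metric's cohort (for IQR upper
#'   bounds) is its own column.
#' @param specs List of [metric_spec()] objects.
#' @return A list of tibbles: `scores` (sample, metric, stage, value,
#'   score), `stages` (sample, stage, s_agg, flag) and `final` (sample,
#'   flag).
#' @export
qc_flag_table <- function(metrics, specs) {
  stopifnot("sample_id" %in% names(metrics))
  scores <- bind_rows(map(specs, function(sp) {
    if (!sp$name %in% names(metrics))
      abort(paste0("metric column missing: ", sp$name))
    v <- metrics[[sp$name]]
    tibble(sample_id = metrics$sample_id, metric = sp$name,
           stage = sp$stage, value = v,
           score = score_metric(v, sp, cohort = v))
  }))
  stages <- scores |>
    group_by(.data$sample_id, .data$stage) |>
    summarise(s_agg = mean(.data$score), .groups = "drop") |>
    mutate(flag = flag_from_score(.data$s_agg))
  final <- stages |>
    group_by(.data$sample_id) |>
    summarise(flag = final_flag(.data$flag), .groups = "drop")
  list(scores = scores, stages = stages, final = final)
}

#' Load metric specifications from a YAML config
#'
#' The package ships a default config (`system.file("extdata",
#' "qc_metric_specs.yaml", package = "loopkit")`) with field-standard
#' defaults; users override by supplying their own file.
#'
#' @param path Path to a YAML file: a list of entries with fields `name,
#'   direction, t1, t2, min_value, upper_bound, stage` (`upper_bound: null`
#'   selects the cohort IQR rule).
#' @return A list of [metric_spec()] objects.
#' @export
read_metric_specs <- function(path = system.file("extdata",
                                                 "qc_metric_specs.yaml",
                                                 package = "loopkit")) {
  raw <- yaml::read_yaml(path)
  map(raw, function(x) metric_spec(
    name = x$name, direction = x$direction, t1 = x$t1, t2 = x$t2,
    min_value = x$min_value %||% 0,
    upper_bound = if (is.null(x$upper_bound)) NA else x$upper_bound,
    stage = x$stage %||% "alignment"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select high-confidence samples
#'
#' Keeps samples flagged Good or Warning whose stringent 5 kb loop count
#' strictly exceeds the pulldown-specific threshold (10,000 for H3K27ac
#' regulatory sets, 2,000 for CTCF structural sets by default).
#'
#' @param samples Tibble with columns `sample_id, flag, n_loops, pulldown`.
#' @param thresholds Named vector of loop-count thresholds per pulldown.
#' @return The filtered sample tibble.
#' @export
select_high_confidence <- function(samples,
                                   thresholds = c(H3K27ac = 10000,
                                                  CTCF = 2000)) {
  if (!all(samples$pulldown %in% names(thresholds)))
    abort("pulldown without a configured loop-count threshold")
  filter(samples, .data$flag %in% c("Good", "Warning"),
         .data$n_loops > thresholds[.data$pulldown])
}
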