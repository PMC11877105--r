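fmt_num <- function(x, digits = 3) formatC(signif(x, digits), format = "fg")

#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric and nonparametric two-sample path: the
#' parametric branch is taken only when Shapiro-Wilk finds no evidence of
#' non-normality (p >= alpha) in *both* groups. Groups too small to test
#' (< 3 non-missing values) or with zero variance fall back to the
#' nonparametric branch with a warning.
#'
#' @param values_a,values_b numeric vectors; `NA`s are dropped.
#' @param alpha normality-test significance level, default 0.05.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(values_a, values_b, alpha = 0.05) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3L || length(b) < 3L) {
    warning("group too small for a normality test; using nonparametric path")
    return("nonparametric")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a group; using nonparametric path")
    return("nonparametric")
  }
  p_a <- stats::shapiro.test(a)$p.value
  p_b <- stats::shapiro.test(b)$p.value
  if (p_a >= alpha && p_b >= alpha) "parametric" else "nonparametric"
}

#' Two-group comparison of a continuous variable
#'
#' Dispatches on the [normality_gate()]: Student's equal-variance two-sample
#' t-test on the parametric path (Welch available via `var_equal = FALSE`),
#' Mann-Whitney (Wilcoxon rank-sum) otherwise. Summaries follow the
#' convention of the chosen path: mean (SD) for parametric, median (IQR) for
#' nonparametric.
#'
#' @inheritParams normality_gate
#' @param variable label carried into the result.
#' @param var_equal use the pooled-variance Student t-test (default TRUE).
#' @param alpha normality-gate level passed to [normality_gate()].
#' @return A one-row data.frame (`ComparisonResult`): `variable`,
#'   `test_used` (`student_t`, `welch_t` or `mann_whitney`), `statistic`,
#'   `p_value`, `summary_a`, `summary_b`, `n_a`, `n_b`.
#' @export
compare_continuous <- function(values_a, values_b, variable = "",
                               var_equal = TRUE, alpha = 0.05) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("a group has no non-missing values for '", variable, "'")
  res <- function(test, stat, p, sa, sb) {
    data.frame(variable = variable, test_used = test, statistic = stat,
               p_value = p, summary_a = sa, summary_b = sb,
               n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
  }
  mean_sd <- function(v) sprintf("%s (%s)", fmt_num(mean(v)),
                                 fmt_num(stats::sd(v)))
  med_iqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%s (%s-%s)", fmt_num(q[2]), fmt_num(q[1]), fmt_num(q[3]))
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    # both groups constant and equal: no evidence of any difference
    message("all values identical in both groups for '", variable,
            "'; p = 1 by convention")
    return(res("student_t", 0, 1, mean_sd(a), mean_sd(b)))
  }
  gate <- normality_gate(a, b, alpha)
  if (gate == "parametric") {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res(if (var_equal) "student_t" else "welch_t",
        unname(tt$statistic), tt$p.value, mean_sd(a), mean_sd(b))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    res("mann_whitney", unname(wt$statistic), wt$p.value,
        med_iqr(a), med_iqr(b))
  }
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact test for a two-group categorical comparison, with the two-sided
#' probability-mass convention: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins that are at most as
#' probable as the observed table. A zero margin gives p = 1.
#'
#' The table is
#' \preformatted{          positive  negative
#'   group A     a          b
#'   group B     c          d}
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(0, 32, 4, 21)   # 0.032: 0/32 vs 4/25 subjects affected
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty table")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Sample size for a two-group comparison of means
#'
#' Normal-approximation sample size per arm to detect a fractional reduction
#' of a mean with a two-sided test:
#' `n = 2 sigma^2 (z_{1-alpha/2} + z_{power})^2 / delta^2`, with
#' `delta = mean x pct_reduction`. Equal SDs and equal arms are assumed. The
#' study's own calculation (chemotactic index 0.30, SD 0.13, 62% reduction,
#' alpha 0.05, power 0.90) gives 10 per arm.
#'
#' @param mean control-group mean of the endpoint.
#' @param sd common standard deviation (> 0).
#' @param pct_reduction fractional reduction in the mean to detect, in (0, 1).
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power, default 0.90.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return A list: `n_per_arm` (integer) and `n_unrounded`.
#' @examples
#' sample_size_two_means(0.30, 0.13, 0.62)  # 10 per arm
#' @export
sample_size_two_means <- function(mean, sd, pct_reduction, alpha = 0.05,
                                  power = 0.90,
                                  rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  delta <- mean * pct_reduction
  if (delta == 0) stop("effect size is zero")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- 2 * sd^2 * z^2 / delta^2
  list(n_per_arm = if (rounding == "nearest") as.integer(round(n))
                   else as.integer(ceiling(n)),
       n_unrounded = n)
}

#' Annexin V / propidium iodide viability quadrants
#'
#' Maps per-cell AnV/PI positivity onto the four mutually exclusive states:
#' viable (AnV-/PI-), early apoptotic (AnV+/PI-), late apoptotic (AnV+/PI+),
#' necrotic (AnV-/PI+). Fractions sum to exactly 1.
#'
#' @param anv,pi logical vectors of per-event positivity, equal length >= 1.
#' @return A one-row data.frame: `viable`, `early_apoptotic`,
#'   `late_apoptotic`, `necrotic`, `n_events`.
#' @export
viability_quadrants <- function(anv, pi) {
  anv <- as.logical(anv); pi <- as.logical(pi)
  if (length(anv) == 0L || length(anv) != length(pi))
    stop("anv and pi must be non-empty and of equal length")
  if (anyNA(anv) || anyNA(pi)) stop("missing event classifications")
  n <- length(anv)
  data.frame(
    viable = sum(!anv & !pi) / n,
    early_apoptotic = sum(anv & !pi) / n,
    late_apoptotic = sum(anv & pi) / n,
    necrotic = sum(!anv & pi) / n,
    n_events = n
  )
}

#' Isotype-gated surface-marker summary
#'
#' Percent-positive and MFI of one marker on a cell population. The positive
#' gate is set from the matched isotype control (default: its 99th
#' percentile), so an isotype is mandatory — there is no default gate.
#'
#' @param events numeric per-cell fluorescence of the stained population.
#' @param isotype_events numeric fluorescence of the isotype control.
#' @param marker marker name carried into the result.
#' @param gate_quantile isotype quantile defining the positive gate,
#'   default 0.99.
#' @return A one-row data.frame: `marker`, `percent_positive` (0-100),
#'   `mfi` (median fluorescence of all events), `gate`, `n_events`.
#' @export
marker_summary <- function(events, isotype_events, marker = "",
                           gate_quantile = 0.99) {
  if (length(events) == 0L) stop("no events")
  if (missing(isotype_events) || is.null(isotype_events) ||
      length(isotype_events) == 0L)
    stop("isotype control required: no default gate")
  gate <- stats::quantile(isotype_events, gate_quantile, names = FALSE)
  data.frame(
    marker = marker,
    percent_positive = 100 * mean(events > gate),
    mfi = stats::median(events),
    gate = gate,
    n_events = length(events),
    stringsAsFactors = FALSE
  )
}

#' Neutrophil maturity fraction (CD66b+/CD10+)
#'
#' Mature neutrophils are defined as double-positive for CD66b and CD10.
#' Gates for each marker come from its own isotype control, as in
#' [marker_summary()].
#'
#' @param cd66b,cd10 per-cell fluorescence, equal length (same events).
#' @param isotype_cd66b,isotype_cd10 matched isotype controls.
#' @param gate_quantile isotype quantile for both gates, default 0.99.
#' @return Percent of events positive for both markers (0-100).
#' @export
maturity_fraction <- function(cd66b, cd10, isotype_cd66b, isotype_cd10,
                              gate_quantile = 0.99) {
  if (length(cd66b) != length(cd10))
    stop("cd66b and cd10 must describe the same events")
  if (length(isotype_cd66b) == 0L || length(isotype_cd10) == 0L)
    stop("isotype control required: no default gate")
  g66 <- stats::quantile(isotype_cd66b, gate_quantile, names = FALSE)
  g10 <- stats::quantile(isotype_cd10, gate_quantile, names = FALSE)
  100 * mean(cd66b > g66 & cd10 > g10)
}

#' Two-group comparison table for a cohort
#'
#' Runs the per-variable test dispatch over a subject-level table: continuous
#' variables go through [compare_continuous()] (Shapiro-Wilk gate, then
#' Student t or Mann-Whitney), categorical variables through a 2x2 Fisher's
#' exact test per level (each level vs the rest). Missing values are dropped
#' per variable (pairwise deletion). No multiple-comparison adjustment is
#' applied by default; `adjust = "BH"` appends a Benjamini-Hochberg column.
#' Variables that cannot be tested (unknown name, or all-missing in a group)
#' are collected in an exceptions report and the run continues.
#'
#' @param cohort data.frame with a `group` column and one column per
#'   variable.
#' @param variables character vector of column names to compare; default all
#'   columns except `subject_id` and `group`.
#' @param groups length-2 character vector picking the two groups to compare
#'   (default: first two levels present, in order of appearance).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param var_equal,alpha passed to [compare_continuous()].
#' @return A list: `results` (data.frame of `ComparisonResult` rows, plus
#'   `p_adjusted` when requested) and `exceptions` (data.frame of skipped
#'   variables with reasons).
#' @export
run_comparison_table <- function(cohort, variables = NULL, groups = NULL,
                                 adjust = c("none", "BH"),
                                 var_equal = TRUE, alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  present <- unique(as.character(cohort$group))
  if (length(present) < 2L) stop("need at least 2 groups")
  if (is.null(groups)) groups <- present[1:2]
  if (!all(groups %in% present))
    stop("requested groups not in cohort: ",
         paste(setdiff(groups, present), collapse = ", "))
  if (is.null(variables))
    variables <- setdiff(names(cohort), c("subject_id", "group"))
  in_a <- cohort$group == groups[1]
  in_b <- cohort$group == groups[2]

  results <- list(); exceptions <- list()
  skip <- function(v, why) {
    exceptions[[length(exceptions) + 1L]] <<-
      data.frame(variable = v, reason = why, stringsAsFactors = FALSE)
  }
  for (v in variables) {
    if (!v %in% names(cohort)) { skip(v, "unknown variable"); next }
    col <- cohort[[v]]
    a <- col[in_a]; b <- col[in_b]
    if (all(is.na(a)) || all(is.na(b))) {
      skip(v, "all values missing in one group"); next
    }
    if (is.numeric(col)) {
      results[[length(results) + 1L]] <-
        compare_continuous(a, b, variable = v, var_equal = var_equal,
                           alpha = alpha)
    } else {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      # binary variable: one row for the second level; multi-level: one
      # row per level (level vs rest)
      report_lv <- if (length(lv) == 2L) lv[2] else lv
      for (l in report_lv) {
        p <- fisher_exact_2x2(sum(a == l), sum(a != l),
                              sum(b == l), sum(b != l))
        results[[length(results) + 1L]] <- data.frame(
          variable = if (length(lv) == 2L) v else paste0(v, ":", l),
          test_used = "fisher_exact", statistic = NA_real_, p_value = p,
          summary_a = sprintf("%d/%d (%.1f%%)", sum(a == l), length(a),
                              100 * mean(a == l)),
          summary_b = sprintf("%d/%d (%.1f%%)", sum(b == l), length(b),
                              100 * mean(b == l)),
          n_a = length(a), n_b = length(b), stringsAsFactors = FALSE)
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame()
  if (adjust == "BH" && nrow(results))
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
  exceptions <- if (length(exceptions)) do.call(rbind, exceptions) else
    data.frame(variable = character(), reason = character())
  list(results = results, exceptions = exceptions,
       groups = groups)
}
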