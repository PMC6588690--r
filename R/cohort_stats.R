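new_test_result <- function(method, statistic, df, p_value,
                            estimate = NA_real_, sidedness = "two",
                            defined = TRUE, note = NA_character_) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 df = as.character(df), p_value = unname(p_value),
                 estimate = unname(estimate), sidedness = sidedness,
                 defined = defined, note = note)
}

#' Residualize confounds out of a metric
#'
#' Ordinary-least-squares residuals of `values` on
#' `[intercept | confounds]` with the grand mean added back, so the
#' metric keeps its scale. Residuals (minus the grand mean) are orthogonal
#' to every confound column, and the operation is idempotent. Used to
#' remove education, gender, and mean FD before group contrasts.
#'
#' @param values numeric vector, one entry per participant.
#' @param confounds numeric matrix or data frame (factors must be coded
#'   numerically, e.g. gender as 0/1), rows aligned with `values`.
#' @return numeric vector of adjusted values.
#' @export
residualize_confounds <- function(values, confounds) {
  X0 <- as.matrix(confounds)
  storage.mode(X0) <- "double"
  n <- length(values)
  if (nrow(X0) != n) abort("rows of `confounds` must match `values`.")
  if (n <= ncol(X0) + 1L) abort("need n > k + 1 observations.")
  X <- cbind(1, X0)
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("confound design is rank deficient.")
  as.numeric(qr.resid(qx, values)) + mean(values)
}

#' Group contrasts on cohort metrics
#'
#' Runs the named design on a metric column of a cohort table and returns
#' a one-row tidy result. Paired designs operate on follow-up-minus-
#' baseline differences computed per participant; all tests are two-sided.
#'
#' @param table data frame with columns `participant_id`, `group`,
#'   `timepoint`, and the metric.
#' @param metric name of the metric column.
#' @param design one of `"two_sample_t"`, `"paired_t"`, `"wilcoxon"`,
#'   `"kruskal_wallis"`, `"one_way_anova"`. Two-sample designs compare the
#'   two levels of `group` (error if not exactly 2); `kruskal_wallis` and
#'   `one_way_anova` use all levels.
#' @param timepoints for paired designs, the (baseline, follow-up) labels.
#' @return a one-row tibble (see `new_test_result`): `method`,
#'   `statistic`, `df`, `p_value`, `estimate`, `sidedness`, `defined`.
#' @export
group_contrast <- function(table, metric, design = c(
                             "two_sample_t", "paired_t", "wilcoxon",
                             "kruskal_wallis", "one_way_anova"),
                           timepoints = c("baseline", "follow-up")) {
  design <- match.arg(design)
  if (!metric %in% names(table)) abort(sprintf("no column `%s`.", metric))
  y <- table[[metric]]

  if (design == "paired_t") {
    d <- paired_differences(table, metric, timepoints)
    if (length(d) < 2L) abort("paired design needs >= 2 participants.")
    if (sd(d) == 0)
      return(new_test_result("paired_t", NA_real_, length(d) - 1, NA_real_,
                             estimate = mean(d), defined = FALSE,
                             note = "zero-variance paired differences"))
    tt <- stats::t.test(d)
    return(new_test_result("paired_t", unname(tt$statistic),
                           unname(tt$parameter), tt$p.value,
                           estimate = unname(tt$estimate)))
  }

  g <- factor(table$group)
  if (any(tabulate(g) < 2L)) abort("every group needs n >= 2.")
  if (design %in% c("two_sample_t", "wilcoxon") && nlevels(g) != 2L)
    abort("two-group designs need exactly 2 group levels.")
  res <- switch(design,
    two_sample_t = {
      tt <- stats::t.test(y ~ g, var.equal = TRUE)
      new_test_result("two_sample_t", unname(tt$statistic),
                      unname(tt$parameter), tt$p.value,
                      estimate = unname(diff(rev(tt$estimate))))
    },
    wilcoxon = {
      wt <- suppressWarnings(stats::wilcox.test(y ~ g))
      new_test_result("wilcoxon", unname(wt$statistic), NA_real_,
                      wt$p.value)
    },
    kruskal_wallis = {
      kt <- stats::kruskal.test(y ~ g)
      new_test_result("kruskal_wallis", unname(kt$statistic),
                      unname(kt$parameter), kt$p.value)
    },
    one_way_anova = {
      ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
      new_test_result("one_way_anova", unname(ft$statistic),
                      paste(ft$parameter, collapse = ","), ft$p.value)
    })
  res
}

# follow-up minus baseline, per participant, ordered by participant id
paired_differences <- function(table, metric, timepoints = c("baseline", "follow-up")) {
  wide <- table |>
    dplyr::filter(.data$timepoint %in% timepoints) |>
    dplyr::select(dplyr::all_of(c("participant_id", "timepoint", metric))) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = dplyr::all_of(metric)) |>
    dplyr::arrange(.data$participant_id)
  if (!all(timepoints %in% names(wide)))
    abort("both timepoints must be present for paired designs.")
  ok <- stats::complete.cases(wide[timepoints])
  wide <- wide[ok, ]
  stats::setNames(wide[[timepoints[2]]] - wide[[timepoints[1]]],
                  wide$participant_id)
}

#' Mixed Group-by-Threshold ANOVA on before-after differences
#'
#' For each participant and each extraction threshold, forms the
#' follow-up-minus-baseline difference of the metric, then fits a mixed
#' (split-plot) ANOVA with one between-participant factor (`group`) and
#' one within-participant repeated measure (`threshold`), via `aov` with
#' an `Error(participant/threshold)` stratum. Reports the group main
#' effect and the Group x Threshold interaction.
#'
#' @param table long cohort table with columns `participant_id`, `group`,
#'   `timepoint`, `threshold`, and the metric.
#' @param metric metric column name.
#' @param thresholds thresholds every participant must have (default the
#'   canonical 5/10/15/20%).
#' @return two-row tibble: group main effect and interaction, each with
#'   `statistic` (F), `df` ("df1,df2"), `p_value`.
#' @export
rm_anova_group_by_threshold <- function(table, metric,
                                        thresholds = c(0.05, 0.10, 0.15, 0.20)) {
  diffs <- table |>
    dplyr::filter(.data$threshold %in% thresholds) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$threshold) |>
    dplyr::summarise(
      diff = difference_or_na(.data[[metric]], .data$timepoint),
      .groups = "drop")
  bad <- diffs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = sum(!is.na(.data$diff)) == length(thresholds)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad))
    abort(paste0("missing threshold cells for participants: ",
                 paste(bad$participant_id, collapse = ", ")))
  diffs$participant_id <- factor(diffs$participant_id)
  diffs$group <- factor(diffs$group)
  diffs$threshold <- factor(diffs$threshold)
  fit <- stats::aov(diff ~ group * threshold +
                      Error(participant_id / threshold), data = diffs)
  s <- summary(fit)
  between <- s[["Error: participant_id"]][[1]]
  within <- s[["Error: participant_id:threshold"]][[1]]
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  gm <- grab(between, "group")
  ia <- grab(within, "group:threshold")
  dplyr::bind_rows(
    new_test_result("rm_anova_group_main", gm["F"],
                    sprintf("%d,%d", as.integer(gm["df1"]),
                            as.integer(gm["df2"])), gm["p"]),
    new_test_result("rm_anova_interaction", ia["F"],
                    sprintf("%d,%d", as.integer(ia["df1"]),
                            as.integer(ia["df2"])), ia["p"]))
}

difference_or_na <- function(values, timepoint) {
  b <- values[timepoint == "baseline"]
  f <- values[timepoint == "follow-up"]
  if (length(b) == 1L && length(f) == 1L) f - b else NA_real_
}

#' Correlation with two-sided p-value
#'
#' Pearson or Spearman correlation between two vectors; zero-variance
#' input is flagged undefined rather than reported as 0.
#'
#' @param x,y numeric vectors, length >= 4, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row tidy result with `estimate` = the coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must match in length.")
  if (length(x) < 4L) abort("need n >= 4.")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("inputs must be finite.")
  if (sd(x) == 0 || sd(y) == 0)
    return(new_test_result(paste0("cor_", method), NA_real_, NA_real_,
                           NA_real_, defined = FALSE,
                           note = "zero variance"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  new_test_result(paste0("cor_", method),
                  unname(ct$statistic),
                  if (!is.null(ct$parameter)) unname(ct$parameter) else NA_real_,
                  ct$p.value, estimate = unname(ct$estimate))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' adjusted values are monotone in raw-p rank order and never below the
#' raw p.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same order.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1].")
  stats::p.adjust(p_values, method = "BH")
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with the sample's
#' mean and SD (estimated-parameter variant: the reported p-value is
#' conservative because the reference distribution is fitted to the same
#' data). Used to route metrics to parametric or non-parametric contrasts.
#'
#' @param values numeric vector, n >= 5.
#' @return one-row tidy result; `defined = FALSE` for constant input.
#' @export
ks_normality <- function(values) {
  if (length(values) < 5L) abort("need n >= 5.")
  if (sd(values) == 0)
    return(new_test_result("ks_normality", NA_real_, NA_real_, NA_real_,
                           defined = FALSE, note = "constant input"))
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), sd(values)))
  new_test_result("ks_normality", unname(kt$statistic), NA_real_,
                  kt$p.value)
}
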