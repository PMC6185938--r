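#' Group mean and standard error
#'
#' @param values numeric vector of observations (n >= 1).
#' @param group group label echoed into the output.
#' @return One-row data frame: `group`, `n`, `mean`, `sem` (sample standard
#'   deviation over sqrt(n); `NA` when n = 1).
#' @examples
#' group_summary(c(1, 2, 3), "WT")  # mean 2, sem 1/sqrt(3)
#' @export
group_summary <- function(values, group = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("empty group")
  data.frame(group = as.character(group), n = n, mean = mean(values),
             sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Significance stars
#'
#' The conventional mapping: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `n.s.` otherwise.
#'
#' @param p p value(s).
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 5e-2, "*", "n.s.")))))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F = between-group mean square over
#' within-group mean square, with (k - 1, N - k) degrees of freedom. When
#' both the between- and within-group variances are zero (all observations
#' identical) the test is vacuous and p = 1 is returned.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return A list of class `comparison_result`: `test`, `statistic` (F),
#'   `df` (numerator, denominator), `p_value`, `stars`.
#' @examples
#' anova_oneway(list(WT = c(1, 2, 3), RP = c(4, 5, 6)))
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(ft$statistic)
  p <- unname(ft$p.value)
  if (!is.finite(f) && stats::var(values) == 0) {
    f <- 0
    p <- 1
  }
  structure(list(test = "one-way ANOVA", statistic = f,
                 df = unname(ft$parameter), p_value = p,
                 stars = significance_stars(p)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", df = (", paste(format(x$df, digits = 4), collapse = ", "),
      "), p = ", format(x$p_value, digits = 4), " ", x$stars, "\n", sep = "")
  if (!is.null(x$comparisons)) {
    cat("comparisons vs control:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

# Evaluate P(max_j |T_j| <= q) for the Dunnett null: multivariate t with
# correlation R[i,j] = lambda_i * lambda_j, lambda_i = sqrt(n_i/(n_i+n0)),
# df = N - k. Uses mvtnorm's quasi-Monte-Carlo integration under a fixed
# internal RNG state so repeated calls give identical values (documented
# absolute tolerance ~1e-5).
dunnett_prob <- function(q, lambda, df) {
  m <- length(lambda)
  if (m == 1L) return(2 * stats::pt(q, df) - 1)
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(20240901L)
  as.numeric(mvtnorm::pmvt(
    lower = rep(-q, m), upper = rep(q, m), df = as.integer(df), corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000L)))
}

#' Dunnett's post hoc test versus a control group
#'
#' Compares each treatment group against one named control using t
#' statistics on the pooled within-group variance, with two-sided adjusted p
#' values from the equicorrelated multivariate-t null distribution (the
#' classical Dunnett procedure; correlations derived from group sizes in the
#' unbalanced case). Also reports the omnibus one-way ANOVA of the same
#' groups. Raw (unadjusted) pairwise p values come from the pooled t
#' distribution; adjusted p values are never below raw ones.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param control name or index of the control group (default first).
#' @return A `comparison_result` with the ANOVA fields plus a `comparisons`
#'   data frame: `group`, `estimate` (treatment mean minus control mean),
#'   `t`, `df`, `p_raw`, `p_adjusted`, `stars`.
#' @examples
#' set.seed(1)
#' g <- list(WT = rnorm(20, 3.5, 0.8), RP11 = rnorm(20, 2.5, 0.8))
#' dunnett_vs_control(g, control = "WT")
#' @export
dunnett_vs_control <- function(groups, control = 1L) {
  groups <- check_groups(groups)
  if (is.numeric(control)) control <- names(groups)[as.integer(control)]
  if (is.na(control) || !control %in% names(groups))
    stop("control group '", control, "' not found")
  omnibus <- anova_oneway(groups)
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, 0)
  df <- sum(ns) - k
  s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df
  trt <- setdiff(names(groups), control)
  n0 <- ns[[control]]
  est <- means[trt] - means[[control]]
  se <- sqrt(s2 * (1 / ns[trt] + 1 / n0))
  tstat <- if (s2 > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  lambda <- sqrt(ns[trt] / (ns[trt] + n0))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  p_adj <- vapply(abs(tstat), function(q) {
    if (!is.finite(q)) return(0)
    1 - dunnett_prob(q, lambda, df)
  }, 0)
  p_adj <- pmin(pmax(p_adj, p_raw), 1)
  comparisons <- data.frame(
    group = trt, estimate = unname(est), t = unname(tstat), df = df,
    p_raw = unname(p_raw), p_adjusted = unname(p_adj),
    stars = significance_stars(unname(p_adj)),
    stringsAsFactors = FALSE)
  structure(list(test = "Dunnett vs control", control = control,
                 statistic = omnibus$statistic, df = omnibus$df,
                 p_value = omnibus$p_value, stars = omnibus$stars,
                 comparisons = comparisons),
            class = "comparison_result")
}

#' Minimum-count quality-control thresholds
#'
#' The assay's sampling adequacy rules: at least 150 cilia measured per
#' sample, at least 300 cells counted per sample, at least 100 cells per
#' population, counted from more than `min_fields` fields of view.
#'
#' @param min_cilia_per_sample,min_cells_per_sample,min_cells_per_population,min_fields
#'   non-negative integers.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_cilia_per_sample = 150L,
                          min_cells_per_sample = 300L,
                          min_cells_per_population = 100L,
                          min_fields = 10L) {
  vals <- c(min_cilia_per_sample, min_cells_per_sample,
            min_cells_per_population, min_fields)
  if (any(vals < 0)) stop("QC thresholds must be >= 0")
  structure(list(min_cilia_per_sample = as.integer(min_cilia_per_sample),
                 min_cells_per_sample = as.integer(min_cells_per_sample),
                 min_cells_per_population = as.integer(min_cells_per_population),
                 min_fields = as.integer(min_fields)),
            class = "qc_thresholds")
}

#' Evaluate sample-level QC rules
#'
#' Checks the counts accumulated for one sample against [qc_thresholds()]
#' and returns the identifiers of violated rules. Flags annotate the output;
#' they never block the pipeline.
#'
#' @param counts named list/vector with any of `n_cilia`, `n_cells`,
#'   `n_cells_population`, `n_fields`; missing entries skip their rule.
#' @param thresholds a [qc_thresholds()].
#' @return Character vector of flag identifiers (empty when clean):
#'   `min_cilia_not_met`, `min_cells_not_met`, `min_population_not_met`,
#'   `min_fields_not_met`.
#' @examples
#' qc_flags(list(n_cilia = 149, n_cells = 300))  # "min_cilia_not_met"
#' @export
qc_flags <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- as.list(counts)
  if (any(unlist(counts) < 0)) stop("counts must be >= 0")
  flags <- character()
  rule <- function(count, minimum, flag) {
    if (!is.null(count) && count < minimum) flag else character()
  }
  flags <- c(
    rule(counts$n_cilia, thresholds$min_cilia_per_sample, "min_cilia_not_met"),
    rule(counts$n_cells, thresholds$min_cells_per_sample, "min_cells_not_met"),
    rule(counts$n_cells_population, thresholds$min_cells_per_population,
         "min_population_not_met"),
    # fields rule is strict: "more than" min_fields fields of view
    if (!is.null(counts$n_fields) && counts$n_fields <= thresholds$min_fields)
      "min_fields_not_met" else character())
  flags
}
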