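#' Group sample for two-sample and multi-group tests
#'
#' Holds either raw values or summary statistics (mean, SEM or SD, n). When a
#' dispersion is given as `sem` it is converted internally to SD. Published
#' "mean +/- x" values are often SEM-labelled only implicitly; the `sem`/`sd`
#' arguments make the reading explicit.
#'
#' @param label group label.
#' @param values raw numeric values, or `NULL` when using summary form.
#' @param mean,n summary form: group mean and size.
#' @param sem,sd summary form: exactly one of standard error of the mean or
#'   standard deviation, > 0.
#' @return an object of class `group_sample` with fields `label`, `values`
#'   (possibly NULL), `mean`, `sd`, `n`.
#' @export
group_sample <- function(label, values = NULL, mean = NULL, sem = NULL,
                         sd = NULL, n = NULL) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) < 2) stop("n must be >= 2")
    out <- list(label = label, values = values, mean = base::mean(values),
                sd = stats::sd(values), n = length(values))
  } else {
    if (is.null(mean) || is.null(n)) stop("summary form needs `mean` and `n`")
    if (n < 2) stop("n must be >= 2")
    if (is.null(sd) == is.null(sem))
      stop("summary form needs exactly one of `sd` or `sem`")
    if (is.null(sd)) {
      if (sem <= 0) stop("`sem` must be > 0")
      sd <- sem * sqrt(n)
    } else if (sd <= 0) stop("`sd` must be > 0")
    out <- list(label = label, values = NULL, mean = mean, sd = sd, n = n)
  }
  structure(out, class = "group_sample")
}

as_group_sample <- function(x, label = deparse(substitute(x))) {
  if (inherits(x, "group_sample")) x else group_sample(label, values = x)
}

#' Unpaired two-tailed t-test (raw values or summary statistics)
#'
#' Pooled-variance (Student) or Welch variant; accepts raw samples or
#' (mean, SEM-or-SD, n) summary triplets, so printed summary statistics can be
#' checked directly against reported p-values.
#'
#' @param a,b [group_sample()] objects or numeric vectors.
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @return list with `statistic`, `df`, `p`, `method`.
#' @export
unpaired_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_sample(a, "a")
  b <- as_group_sample(b, "b")
  se2a <- a$sd^2 / a$n
  se2b <- b$sd^2 / b$n
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  }
  t <- if (se == 0 && a$mean == b$mean) 0 else (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p = p,
       method = paste0("unpaired t (", variant, ", two-tailed)"))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons, computed via
#' `expm1` for numerical stability at small p.
#'
#' @param p raw p-value(s).
#' @param m family size.
#' @return adjusted p-value(s), in `[p, 1]`.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, -expm1(m * log1p(-p)))
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Omnibus F from a standard one-way ANOVA; each requested pairwise comparison
#' uses the pooled within-group variance (the ANOVA mean-square error, with
#' `N - k` degrees of freedom) and a two-tailed p, Sidak-adjusted for the
#' number of requested comparisons (default: all pairs).
#'
#' @param data data.frame with columns `group` and `value`, or a list of
#'   [group_sample()] objects with raw values.
#' @param comparisons list of 2-element character vectors of group labels, or
#'   `NULL` for all pairs.
#' @return list with `omnibus` (F, df, p) and `comparisons`, a data.frame with
#'   one row per pair (`statistic`, `df`, `p`, `p_adj`).
#' @export
anova_sidak <- function(data, comparisons = NULL) {
  if (is.list(data) && !is.data.frame(data) &&
      all(vapply(data, inherits, logical(1), "group_sample"))) {
    data <- do.call(rbind, lapply(data, function(g) {
      if (is.null(g$values)) stop("ANOVA needs raw values per group")
      data.frame(group = g$label, value = g$values)
    }))
  }
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)))
  data$group <- factor(data$group)
  ns <- table(data$group)
  if (length(ns) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("every group needs n >= 2")

  fit <- stats::aov(value ~ group, data = data)
  an <- suppressWarnings(stats::anova(fit))
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  if (mse <= .Machine$double.eps * max(1, mean(data$value^2)))
    stop("zero within-group variance")
  omnibus <- list(F = an["group", "F value"],
                  df = c(an["group", "Df"], df_err),
                  p = an["group", "Pr(>F)"])

  labs <- levels(data$group)
  if (is.null(comparisons))
    comparisons <- utils::combn(labs, 2, simplify = FALSE)
  m <- length(comparisons)
  means <- tapply(data$value, data$group, mean)
  res <- lapply(comparisons, function(pr) {
    if (!all(pr %in% labs)) stop("unknown group in comparison: ",
                                 paste(pr, collapse = " vs "))
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    t <- (means[[pr[1]]] - means[[pr[2]]]) / se
    p <- 2 * stats::pt(-abs(t), df_err)
    data.frame(group1 = pr[1], group2 = pr[2], statistic = t, df = df_err,
               p = p, p_adj = sidak_adjust(p, m))
  })
  list(omnibus = omnibus, comparisons = do.call(rbind, res))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the same result shape
#' as the other tests in this package.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `statistic` (W), `p`, `method`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  s <- stats::shapiro.test(values)
  list(statistic = unname(s$statistic), p = s$p.value, method = "Shapiro-Wilk")
}

#' Robust FDR-controlled outlier screen
#'
#' One-sample location version of a ROUT-style screen: residuals from a robust
#' center (median) are scaled by the MAD-derived robust SD, converted to
#' two-sided p-values under the t distribution (n - 1 df), and flagged by
#' Benjamini-Hochberg at FDR `q`. Constant data produce no outliers; with a
#' zero MAD but non-constant data, the deviating points are flagged directly.
#'
#' @param values numeric vector, n >= 3.
#' @param q target false-discovery rate for the screen.
#' @return logical vector, `TRUE` where a value is flagged as an outlier.
#' @export
outlier_screen <- function(values, q = 0.01) {
  if (length(values) < 3) stop("need at least 3 values")
  center <- stats::median(values)
  scale <- stats::mad(values)
  if (scale == 0) return(values != center)
  z <- (values - center) / scale
  p <- 2 * stats::pt(-abs(z), df = length(values) - 1)
  stats::p.adjust(p, "BH") < q
}
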