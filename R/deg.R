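#' TPM expression matrix with group map
#'
#' @param tpm numeric matrix, genes x samples, non-negative, with gene ids as
#'   rownames and sample ids as colnames.
#' @param groups named character vector (or factor) mapping every sample id to
#'   exactly one group.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, groups) {
  if (!is.matrix(tpm) || !is.numeric(tpm))
    stop("`tpm` must be a numeric genes x samples matrix")
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("`tpm` needs gene rownames and sample colnames")
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups))) stop("`groups` must be named by sample id")
  missing <- setdiff(colnames(tpm), names(groups))
  if (length(missing))
    stop("samples without a group: ", paste(missing, collapse = ", "))
  structure(list(tpm = tpm, groups = groups[colnames(tpm)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$tpm), " genes x ", ncol(x$tpm),
      " samples; groups: ",
      paste(sprintf("%s(%d)", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter low-expression genes
#'
#' A gene is retained iff at least `min_valid` samples have TPM strictly above
#' `min_value` (default: 7 valid values above 0.1 across the 20 samples of the
#' four-group design). Idempotent.
#'
#' @param em an [expression_matrix()].
#' @param min_valid minimum number of samples above `min_value`.
#' @param min_value expression floor, TPM.
#' @return the filtered [expression_matrix()].
#' @export
filter_low_expression <- function(em, min_valid = 7, min_value = 0.1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (min_valid > ncol(em$tpm))
    stop("`min_valid` exceeds the number of samples")
  keep <- rowSums(em$tpm > min_value) >= min_valid
  expression_matrix(em$tpm[keep, , drop = FALSE], em$groups)
}

# vectorized pooled two-sample t on the rows of two matrices
row_pooled_t <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0 & m1 == m2] <- 1 # no variance, no difference
  p[se == 0 & m1 != m2] <- 0
  list(t = t, p = p, df = df)
}

#' Call differentially expressed genes by threshold criteria
#'
#' Per-gene unpaired two-tailed pooled t-test on `log2(TPM + offset)`;
#' absolute difference and fold change are computed on the linear-scale group
#' means. A gene is classed `up` (higher in `test` than in `ref`) or `down`
#' only when all three criteria hold strictly:
#' `|mean_test - mean_ref| > min_diff` (TPM), `FC > min_fc`, and `p < alpha`.
#' FC is `max(means)/min(means)` with the means floored at `mean_floor` TPM to
#' avoid division by zero; direction is carried by the sign of log2 FC.
#'
#' @param em an [expression_matrix()].
#' @param ref,test group labels; fold-change direction is `test` vs `ref`.
#' @param min_diff absolute difference threshold, linear TPM.
#' @param min_fc fold-change threshold (ratio >= 1).
#' @param alpha p-value threshold.
#' @param log_offset offset inside the log2 transform.
#' @param mean_floor floor applied to group means before the ratio.
#' @return data.frame with one row per gene: `gene`, `mean_ref`, `mean_test`,
#'   `difference`, `fc`, `log2fc`, `p`, `class` (up/down/ns).
#' @export
call_degs <- function(em, ref, test, min_diff = 4, min_fc = 2, alpha = 0.05,
                      log_offset = 1, mean_floor = 0.01) {
  stopifnot(inherits(em, "expression_matrix"))
  for (g in c(ref, test))
    if (!g %in% em$groups) stop("group not in sample map: ", g)
  a <- em$tpm[, em$groups == ref, drop = FALSE]
  b <- em$tpm[, em$groups == test, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("both groups need >= 2 samples")

  tt <- row_pooled_t(log2(a + log_offset), log2(b + log_offset))
  mean_ref <- rowMeans(a)
  mean_test <- rowMeans(b)
  difference <- abs(mean_test - mean_ref)
  fa <- pmax(mean_ref, mean_floor)
  fb <- pmax(mean_test, mean_floor)
  fc <- pmax(fa, fb) / pmin(fa, fb)
  log2fc <- log2(fb / fa)
  sig <- difference > min_diff & fc > min_fc & tt$p < alpha
  class <- ifelse(!sig, "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(gene = rownames(em$tpm), mean_ref = mean_ref,
             mean_test = mean_test, difference = difference, fc = fc,
             log2fc = log2fc, p = tt$p, class = class,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene z-score matrix
#'
#' Scales each selected gene to mean 0 and SD 1 across samples (sample SD,
#' n - 1 denominator, as in `scale()`), the convention used for relative
#' expression heatmaps.
#'
#' @param em an [expression_matrix()] or a numeric genes x samples matrix.
#' @param genes gene ids to include; default all.
#' @return numeric matrix of z-scores, genes x samples.
#' @export
zscore_matrix <- function(em, genes = NULL) {
  m <- if (inherits(em, "expression_matrix")) em$tpm else em
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  if (any(sdv == 0))
    stop("constant gene(s), z-score undefined: ",
         paste(rownames(m)[sdv == 0], collapse = ", "))
  (m - mu) / sdv
}
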