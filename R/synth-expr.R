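#' Configuration for a synthetic TPM expression matrix
#'
#' Describes a four-group bulk RNA-seq design at two developmental stages
#' (60 and 90 days in vitro, mock- and drug-treated), with log-normal baseline
#' expression, Gaussian replicate noise on the log2(TPM + 1) scale, a
#' "maturation" differential-expression signature (90 vs 60 div, applied to
#' both 90 div groups), and treatment signatures at each stage. The 60 div
#' treatment signature overlaps the maturation signature by a configurable
#' fraction, which is what the representation-factor overlap statistics
#' downstream are designed to quantify.
#'
#' @param n_genes number of genes.
#' @param groups character vector of 4 group labels, ordered
#'   (stage-1 mock, stage-1 treated, stage-2 mock, stage-2 treated).
#' @param n_per_group replicates per group.
#' @param baseline_log2_mean,baseline_log2_sd location and scale of the
#'   log-normal baseline on the log2(TPM + 1) scale.
#' @param noise_sd replicate noise SD, log2 units.
#' @param maturation_n,maturation_effect number of maturation-DE genes and
#'   their absolute log2 effect size (applied to both stage-2 groups).
#' @param maturation_frac_up fraction of maturation-DE genes that are
#'   up-regulated with maturation.
#' @param treatment60_n,treatment60_effect number and absolute log2 effect of
#'   treatment-DE genes at the first stage (treated group only); these genes
#'   are up-regulated.
#' @param treatment60_overlap fraction of the stage-1 treatment-DE genes drawn
#'   from the maturation up-regulated set.
#' @param treatment90_n,treatment90_effect number and absolute log2 effect of
#'   treatment-DE genes at the second stage; these genes are down-regulated
#'   (sign convention: stage-2 treatment opposes maturation) and are drawn
#'   from the maturation up-regulated set where possible.
#' @param de_min_baseline minimum baseline TPM for a gene to be eligible as a
#'   DE gene (threshold-based DE calling on TPM differences cannot see fold
#'   changes of near-zero genes, so realistic signatures sit on expressed
#'   genes).
#' @param seed integer RNG seed.
#' @return an object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 5000,
                            groups = c("mock60", "prop60", "mock90", "prop90"),
                            n_per_group = 5,
                            baseline_log2_mean = 3, baseline_log2_sd = 2,
                            noise_sd = 0.25,
                            maturation_n = 400, maturation_effect = 2,
                            maturation_frac_up = 0.85,
                            treatment60_n = 40, treatment60_effect = 2,
                            treatment60_overlap = 0.8,
                            treatment90_n = 30, treatment90_effect = 2,
                            de_min_baseline = 5,
                            seed = 1L) {
  cfg <- list(n_genes = n_genes, groups = groups, n_per_group = n_per_group,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
              maturation_n = maturation_n, maturation_effect = maturation_effect,
              maturation_frac_up = maturation_frac_up,
              treatment60_n = treatment60_n, treatment60_effect = treatment60_effect,
              treatment60_overlap = treatment60_overlap,
              treatment90_n = treatment90_n, treatment90_effect = treatment90_effect,
              de_min_baseline = de_min_baseline, seed = as.integer(seed))
  if (length(cfg$groups) != 4 || anyDuplicated(cfg$groups))
    stop("invalid `groups`: need 4 distinct labels", call. = FALSE)
  num_ok <- function(field, ok, what) {
    v <- cfg[[field]]
    if (length(v) != 1 || !is.numeric(v) || is.na(v) || !ok(v))
      stop("invalid `", field, "`: must be ", what, call. = FALSE)
  }
  num_ok("n_genes", function(v) v >= 1, ">= 1")
  num_ok("n_per_group", function(v) v >= 2, ">= 2")
  num_ok("noise_sd", function(v) v >= 0, ">= 0")
  num_ok("baseline_log2_sd", function(v) v >= 0, ">= 0")
  num_ok("maturation_frac_up", function(v) v >= 0 && v <= 1, "in [0, 1]")
  num_ok("treatment60_overlap", function(v) v >= 0 && v <= 1, "in [0, 1]")
  for (f in c("maturation_n", "treatment60_n", "treatment90_n")) {
    num_ok(f, function(v) v >= 0 && v == floor(v), "a non-negative integer")
    if (cfg[[f]] > cfg$n_genes)
      stop("invalid `", f, "`: exceeds n_genes", call. = FALSE)
  }
  structure(cfg, class = "expr_sim_config")
}

#' Generate a synthetic TPM expression matrix with ground truth
#'
#' Expression is built on the log2(TPM + 1) scale as
#' baseline + signature effects + Gaussian noise, then mapped back to TPM
#' (negative log2 values are truncated at TPM = 0). DE genes are sampled among
#' genes whose baseline TPM exceeds `de_min_baseline`; the stage-1 treatment
#' signature shares `treatment60_overlap` of its genes with the maturation
#' up-regulated set, and the stage-2 treatment signature down-regulates
#' maturation-up genes.
#'
#' @param cfg an [expr_sim_config()].
#' @return a list with `matrix` (an [expression_matrix()]) and `truth`, a
#'   data.frame with one row per gene and columns `gene`, `maturation`,
#'   `treatment60`, `treatment90` (each -1/0/+1) and the corresponding
#'   realized log2 effect columns.
#' @export
generate_expression_matrix <- function(cfg) {
  if (!inherits(cfg, "expr_sim_config")) cfg <- do.call(expr_sim_config, cfg)
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  baseline <- stats::rnorm(ng, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  eligible <- which(2^baseline - 1 > cfg$de_min_baseline)

  need <- cfg$maturation_n + cfg$treatment90_n # worst-case distinct eligible genes
  if (length(eligible) < need)
    stop("too few genes above `de_min_baseline` to place the requested signatures")

  maturation <- integer(ng)
  mat_genes <- sample(eligible, cfg$maturation_n)
  n_up <- round(cfg$maturation_frac_up * cfg$maturation_n)
  mat_up <- mat_genes[seq_len(n_up)]
  mat_down <- setdiff(mat_genes, mat_up)
  maturation[mat_up] <- 1L
  maturation[mat_down] <- -1L

  # stage-1 treatment: up-regulated, overlapping the maturation-up set
  n_shared <- round(cfg$treatment60_overlap * cfg$treatment60_n)
  if (n_shared > length(mat_up))
    stop("`treatment60_overlap` demands more shared genes than the maturation",
         " up-regulated set provides (", n_shared, " > ", length(mat_up), ")")
  n_own <- cfg$treatment60_n - n_shared
  pool60 <- setdiff(eligible, mat_genes)
  if (n_own > length(pool60))
    stop("too few eligible genes outside the maturation set for the stage-1",
         " treatment signature")
  t60_genes <- c(if (n_shared > 0) sample(mat_up, n_shared),
                 if (n_own > 0) sample(pool60, n_own))
  treatment60 <- integer(ng)
  treatment60[t60_genes] <- 1L

  # stage-2 treatment: down-regulated, preferentially on maturation-up genes
  pool90 <- setdiff(mat_up, t60_genes)
  if (length(pool90) < cfg$treatment90_n)
    pool90 <- c(pool90, sample(setdiff(eligible, c(mat_genes, t60_genes)),
                               cfg$treatment90_n - length(pool90)))
  t90_genes <- if (cfg$treatment90_n > 0) sample(pool90, cfg$treatment90_n) else integer(0)
  treatment90 <- integer(ng)
  treatment90[t90_genes] <- -1L

  grp <- rep(cfg$groups, each = cfg$n_per_group)
  samples <- paste0(grp, "_", sequence(rep(cfg$n_per_group, 4)))
  stage2 <- grp %in% cfg$groups[3:4]
  treated60 <- grp == cfg$groups[2]
  treated90 <- grp == cfg$groups[4]

  mu <- matrix(baseline, nrow = ng, ncol = length(grp))
  mu <- mu + outer(maturation * cfg$maturation_effect, as.numeric(stage2))
  mu <- mu + outer(treatment60 * cfg$treatment60_effect, as.numeric(treated60))
  mu <- mu + outer(treatment90 * cfg$treatment90_effect, as.numeric(treated90))
  l2 <- mu + matrix(stats::rnorm(length(mu), sd = cfg$noise_sd), nrow = ng)
  tpm <- pmax(2^l2 - 1, 0)
  dimnames(tpm) <- list(genes, samples)

  em <- expression_matrix(tpm, stats::setNames(grp, samples))
  truth <- data.frame(
    gene = genes,
    maturation = maturation,
    treatment60 = treatment60,
    treatment90 = treatment90,
    maturation_log2fc = maturation * cfg$maturation_effect,
    treatment60_log2fc = treatment60 * cfg$treatment60_effect,
    treatment90_log2fc = treatment90 * cfg$treatment90_effect,
    stringsAsFactors = FALSE)
  list(matrix = em, truth = truth)
}

#' Generate a synthetic gene-set collection
#'
#' Draws random gene sets from a universe, optionally planting sets enriched
#' in a supplied gene list (a fraction of each planted set is drawn from the
#' list). Used to exercise over-representation and pre-ranked enrichment on
#' fully synthetic inputs.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of random sets.
#' @param size_range integer range of set sizes.
#' @param planted optional character vector; when given, `n_planted` sets are
#'   created with `planted_frac` of their members sampled from it.
#' @param n_planted,planted_frac see `planted`.
#' @param seed integer RNG seed.
#' @return a [gene_set_collection()].
#' @export
synthetic_collection <- function(universe, n_sets = 50, size_range = c(10, 100),
                                 planted = NULL, n_planted = 0,
                                 planted_frac = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  sets <- vector("list", n_sets + n_planted)
  names(sets) <- c(sprintf("RANDOM_SET_%03d", seq_len(n_sets)),
                   if (n_planted > 0) sprintf("PLANTED_SET_%03d", seq_len(n_planted)))
  for (i in seq_len(n_sets)) {
    sz <- sample(size_range[1]:size_range[2], 1)
    sets[[i]] <- sample(universe, sz)
  }
  for (j in seq_len(n_planted)) {
    sz <- sample(size_range[1]:size_range[2], 1)
    n_in <- min(round(planted_frac * sz), length(planted))
    sets[[n_sets + j]] <- unique(c(sample(planted, n_in),
                                   sample(setdiff(universe, planted), sz - n_in)))
  }
  gene_set_collection(sets)
}
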