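#' Upper-tail hypergeometric probability of a gene-list overlap
#'
#' Probability of observing an overlap of at least `x` genes between two lists
#' of sizes `n1` and `n2` drawn from a background universe of `N` genes,
#' `P(X >= x)` with `X ~ Hypergeometric(N, n1, n2)`. Computed with
#' [stats::phyper()] (log-space option for very small tails).
#'
#' @param x observed overlap.
#' @param n1,n2 list sizes.
#' @param N background universe size.
#' @param log return the natural log of the tail probability.
#' @return upper-tail probability (or its log).
#' @export
hypergeom_tail <- function(x, n1, n2, N, log = FALSE) {
  check_overlap(x, n1, n2, N)
  stats::phyper(x - 1, n1, N - n1, n2, lower.tail = FALSE, log.p = log)
}

check_overlap <- function(x, n1, n2, N) {
  if (x < 0 || n1 < 0 || n2 < 0 || N < 1) stop("overlap arguments must be non-negative, N >= 1")
  if (x > min(n1, n2)) stop("overlap x exceeds min(n1, n2)")
  if (n1 + n2 - x > N) stop("lists cannot fit the background: n1 + n2 - x > N")
  invisible(TRUE)
}

#' Representation factor of a gene-list overlap
#'
#' Ratio of the observed overlap to the overlap expected by chance:
#' `RF = x * N / (n1 * n2)`, with the exact hypergeometric upper-tail p-value.
#' RF > 1 indicates more overlap than expected for independent lists.
#'
#' @inheritParams hypergeom_tail
#' @return an object of class `overlap_result`: `n1`, `n2`, `x`, `N`,
#'   `expected`, `rf`, `p`.
#' @export
representation_factor <- function(x, n1, n2, N) {
  check_overlap(x, n1, n2, N)
  expected <- n1 * n2 / N
  structure(list(n1 = n1, n2 = n2, x = x, N = N, expected = expected,
                 rf = x * N / (n1 * n2),
                 p = hypergeom_tail(x, n1, n2, N)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> x = %d of (n1 = %d, n2 = %d) in N = %d; RF = %.2f (expected %.2f), p = %.3g\n",
              x$x, x$n1, x$n2, x$N, x$rf, x$expected, x$p))
  invisible(x)
}

#' Reconstruct the background size behind a reported representation factor
#'
#' Inverts `RF = x * N / (n1 * n2)` to `N = RF * n1 * n2 / x`. Useful when a
#' publication reports RF but not the background universe.
#'
#' @param rf reported representation factor.
#' @param x,n1,n2 overlap and list sizes.
#' @return implied background size (not rounded).
#' @export
background_from_rf <- function(rf, x, n1, n2) rf * n1 * n2 / x

#' Reconstruct the background size behind a reported hypergeometric p-value
#'
#' Solves `P(X >= x | N) = p` for the background size `N` by monotone root
#' finding on the log tail probability. The tail is strictly increasing in N
#' (a larger universe makes a given overlap rarer is false -- it makes it
#' *less* surprising for fixed lists is also false; for fixed x, n1, n2 the
#' tail decreases as N grows), so the root is unique.
#'
#' @param p reported upper-tail p-value.
#' @param x,n1,n2 overlap and list sizes.
#' @param upper upper bound of the search interval.
#' @return implied integer background size.
#' @export
background_from_p <- function(p, x, n1, n2, upper = 1e8) {
  stopifnot(p > 0, p < 1, x >= 1)
  lo <- max(n1 + n2 - x, n1, n2) + 1
  f <- function(N) hypergeom_tail(x, n1, n2, round(N), log = TRUE) - log(p)
  root <- stats::uniroot(f, c(lo, upper))$root
  cand <- unique(pmax(round(root) + (-2:2), lo))
  err <- vapply(cand, function(N) abs(f(N)), numeric(1))
  cand[which.min(err)]
}

#' Venn partition of 2 or 3 gene lists
#'
#' Counts every disjoint membership region. Region names are binary codes
#' over the input sets (e.g. `"110"` = in sets 1 and 2, not in set 3); the
#' counts sum to the size of the union.
#'
#' @param sets named list of 2 or 3 character vectors (unique ids).
#' @return named integer vector of region counts.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2, 3)) stop("venn_partition takes 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  codes <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  all_codes <- apply(expand.grid(rep(list(1:0), k))[-(2^k), , drop = FALSE],
                     1, paste, collapse = "")
  out <- stats::setNames(integer(length(all_codes)), sort(all_codes, decreasing = TRUE))
  tab <- table(codes)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (member gene ids); names
#'   unique, every set non-empty.
#' @param category optional tag (e.g. "GOBP", "GOCC", "GOMF", "hallmark").
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = NA_character_) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (any(lengths(sets) < 1)) stop("every set needs at least one member")
  structure(list(sets = lapply(sets, as.character), category = category),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path file path.
#' @param category optional category tag stored on the collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = NA_character_) {
  gene_set_collection(fgsea::gmtPathways(path), category = category)
}

#' Write a GMT gene-set file
#'
#' @param collection a [gene_set_collection()] (or named list of sets).
#' @param path file path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For every set in the collection, tests whether the query gene list overlaps
#' the set more than expected by chance given the background universe
#' (hypergeometric upper tail), with Benjamini-Hochberg adjustment across
#' sets. Set memberships are restricted to the background before testing.
#'
#' @param genes query gene list (must be a subset of `background`).
#' @param background background universe of gene ids.
#' @param collection a [gene_set_collection()].
#' @param q_threshold keep sets with BH-adjusted q below this (default: all).
#' @return data.frame sorted by q then p: `set`, `set_size`, `overlap`,
#'   `expected`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(genes, background, collection,
                                 q_threshold = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- unique(genes)
  background <- unique(background)
  outside <- setdiff(genes, background)
  if (length(outside))
    stop("query genes outside the background: ",
         paste(utils::head(outside, 10), collapse = ", "))
  if (length(genes) == 0)
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  N <- length(background)
  n_query <- length(genes)
  rows <- lapply(names(collection$sets), function(nm) {
    set_bg <- intersect(collection$sets[[nm]], background)
    K <- length(set_bg)
    if (K == 0) return(NULL)
    k <- length(intersect(genes, set_bg))
    data.frame(set = nm, set_size = K, overlap = k,
               expected = n_query * K / N,
               p = hypergeom_tail(k, K, n_query, N))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[out$q <= q_threshold, , drop = FALSE]
}

# order scores descending with deterministic tie-break by gene id
order_ranking <- function(scores) {
  stopifnot(!is.null(names(scores)))
  scores[order(-scores, names(scores))]
}

# running-sum ES given sorted hit positions in a ranked list of length n;
# absw = |score|^weight for every position. Extrema of the running sum occur
# at hit positions (just after a hit) and just before the next hit.
es_from_positions <- function(pos, absw, n) {
  s <- length(pos)
  hw <- absw[pos]
  tot <- sum(hw)
  miss <- 1 / (n - s)
  if (tot == 0) { # degenerate: all hit scores zero -> uniform hit steps
    hw <- rep(1, s); tot <- s
  }
  cumhit <- cumsum(hw) / tot
  at_hit <- cumhit - (pos - seq_len(s)) * miss
  before_hit <- c(0, cumhit[-s]) - (pos - seq_len(s)) * miss
  cand <- c(at_hit, before_hit)
  unname(cand[which.max(abs(cand))])
}

#' Pre-ranked enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic over a ranked gene list:
#' walking down the ranking, the sum increases by `|score|^weight`
#' (normalized) at set members ("hits") and decreases uniformly at non-members.
#' The enrichment score is the maximum-magnitude deviation of the running sum;
#' `weight = 0` reduces to the classical KS statistic on ranks.
#'
#' @param scores named numeric vector of per-gene ranking scores; sorted
#'   internally in decreasing order with ties broken by gene id.
#' @param set character vector of member gene ids; must intersect the ranking.
#' @param weight hit-weight exponent.
#' @return the enrichment score, in `[-1, 1]`.
#' @export
preranked_es <- function(scores, set, weight = 1) {
  scores <- order_ranking(scores)
  hit <- names(scores) %in% set
  if (!any(hit)) stop("set has no genes in the ranked list")
  if (all(hit)) stop("set covers the whole ranked list")
  es_from_positions(which(hit), abs(scores)^weight, length(scores))
}

#' Pre-ranked gene-set enrichment analysis with gene-set permutation
#'
#' For each set, computes the weighted running-sum enrichment score and a
#' null distribution by repeatedly sampling random gene positions of the same
#' size from the ranking (`n_perm` gene-set permutations). The permutation
#' p-value and the normalized enrichment score (NES, ES divided by the mean
#' magnitude of same-signed null ES) follow the published GSEA procedure, as
#' does the FDR: for a set with NES*, the fraction of pooled null NES at least
#' as extreme (same sign) divided by the fraction of observed NES at least as
#' extreme, capped at 1.
#'
#' @param scores named numeric ranking scores (see [rank_genes()]).
#' @param collection a [gene_set_collection()].
#' @param n_perm number of gene-set permutations per set.
#' @param seed integer RNG seed (seeded determinism).
#' @param min_size,max_size set-size bounds (after restriction to the ranking).
#' @param weight hit-weight exponent.
#' @return data.frame sorted by p then set: `set`, `size`, `es`, `nes`, `p`,
#'   `fdr`.
#' @export
preranked_gsea <- function(scores, collection, n_perm = 1000, seed = NULL,
                           min_size = 5, max_size = 500, weight = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  scores <- order_ranking(scores)
  n <- length(scores)
  absw <- abs(scores)^weight
  ids <- names(scores)

  sizes <- vapply(collection$sets, function(s) sum(ids %in% s), integer(1))
  keep <- which(sizes >= min_size & sizes <= max_size & sizes < n)
  if (!length(keep))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0)))

  null_by_size <- new.env(parent = emptyenv())
  get_null <- function(k) {
    key <- as.character(k)
    if (!is.null(null_by_size[[key]])) return(null_by_size[[key]])
    es0 <- vapply(seq_len(n_perm), function(i)
      es_from_positions(sort(sample.int(n, k)), absw, n), numeric(1))
    null_by_size[[key]] <- es0
    es0
  }

  res <- lapply(keep, function(i) {
    set <- collection$sets[[i]]
    pos <- which(ids %in% set)
    es <- es_from_positions(pos, absw, n)
    null <- get_null(length(pos))
    same <- if (es >= 0) null[null >= 0] else -null[null < 0]
    p <- if (length(same) == 0) 1 /
      (n_perm + 1) else (1 + sum(same >= abs(es))) / (1 + length(same))
    # NES = ES / mean(|same-sign null ES|), sign preserved
    mean_same <- if (length(same)) mean(same) else NA_real_
    nes <- if (is.na(mean_same) || mean_same == 0) NA_real_ else
      sign(es) * abs(es) / mean_same
    null_nes <- c(null[null >= 0] / (if (any(null >= 0)) mean(null[null >= 0]) else NA),
                  null[null < 0] / (if (any(null < 0)) abs(mean(null[null < 0])) else NA))
    list(set = names(collection$sets)[i], size = length(pos), es = es,
         nes = nes, p = p, null_nes = null_nes)
  })

  obs_nes <- vapply(res, `[[`, numeric(1), "nes")
  pool <- unlist(lapply(res, `[[`, "null_nes"))
  pool <- pool[is.finite(pool)]
  fdr <- vapply(obs_nes, function(ns) {
    if (is.na(ns)) return(NA_real_)
    if (ns >= 0) {
      num <- mean(pool >= ns)
      den <- mean(obs_nes >= ns, na.rm = TRUE)
    } else {
      num <- mean(pool <= ns)
      den <- mean(obs_nes <= ns, na.rm = TRUE)
    }
    if (den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set = vapply(res, `[[`, character(1), "set"),
                    size = vapply(res, `[[`, integer(1), "size"),
                    es = vapply(res, `[[`, numeric(1), "es"),
                    nes = obs_nes,
                    p = vapply(res, `[[`, numeric(1), "p"),
                    fdr = fdr, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes for pre-ranked enrichment
#'
#' Score is `sign(log2FC) * (-log10 p)` (fold-difference direction combined
#' with significance), sorted descending with deterministic tie-break by gene
#' id. Zero p-values are floored at the smallest representable double.
#'
#' @param deg_stats data.frame with columns `gene`, `log2fc`, `p`
#'   (e.g. from [call_degs()]).
#' @return named numeric vector of ranking scores, in ranking order.
#' @export
rank_genes <- function(deg_stats) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(deg_stats)))
  p <- pmax(deg_stats$p, .Machine$double.xmin)
  score <- sign(deg_stats$log2fc) * (-log10(p))
  order_ranking(stats::setNames(score, deg_stats$gene))
}

#' Genes or sets shared by all lists
#'
#' Intersection of an arbitrary number of id lists; the "oppositely regulated
#' at the two stages" contingent is the intersection of (up with maturation),
#' (up under stage-1 treatment) and (down under stage-2 treatment).
#'
#' @param sets list of character vectors.
#' @return character vector of ids present in every list.
#' @export
shared_all <- function(sets) Reduce(intersect, sets)
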