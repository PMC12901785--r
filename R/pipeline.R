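pipeline_defaults <- function() list(
  seed = 1L,
  # signal cleaning and filtering
  fs = 19754, excision_border = 100, band_low = 150, band_high = 3000,
  fir_taps = c(401, 113), fir_trans = c(100, 300),
  saturation_frac = 0.9, flash_channel_frac = 0.5, flash_pad = 0,
  # spike detection
  detect_k = 5, detect_window_ms = 5, refractory_ms = 1, guard_ms = 1,
  # channel selection and organoid inclusion
  top_n = 30, max_channel_hz = 5, min_mean_hz = 0.5,
  # expression filter and DEG thresholds
  expr_min_valid = 7, expr_min_value = 0.1,
  deg_min_diff = 4, deg_min_fc = 2, deg_alpha = 0.05,
  # enrichment thresholds
  enrich_fdr = 0.05, enrich_p = 0.05, gsea_n_perm = 200,
  # synthetic MEA arm (sizes kept desk-scale; the acquisition constants above
  # are the analysis parameters and do not depend on these)
  mea_organoids_per_group = 2, mea_channels = 36, mea_duration = 20,
  mea_group_rates = c(mock60 = 0.8, prop60 = 1.6, mock90 = 1.6, prop90 = 1.6),
  mea_active_fraction = 1, mea_spike_amp = 80, mea_noise_sd = 10,
  # synthetic expression arm: overrides passed to expr_sim_config()
  expr = list(n_genes = 3000, maturation_n = 300, treatment60_n = 40,
              treatment60_overlap = 0.8, treatment90_n = 30)
)

#' Pipeline configuration
#'
#' All tunables of the end-to-end synthetic pipeline, with the analysis
#' constants of the supported study design as defaults: 19,754 Hz sampling,
#' 100-sample excision borders, 150-3000 Hz band, 5xSD detection in a 5 ms
#' window, top-30 channel selection with the 5 Hz channel exclusion and
#' 0.5 Hz organoid inclusion floor, 7-of-20 > 0.1 TPM expression filter, DEG
#' thresholds (difference > 4 TPM, FC > 2, p < 0.05), and enrichment
#' significance at FDR < 0.05 / p < 0.05. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see `pipeline_defaults` in the
#'   source, or call with no arguments and inspect the result).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    if (!is.null(over$expr)) {
      bad <- setdiff(names(over$expr), names(formals(expr_sim_config)))
      if (length(bad)) stop("unknown expr config keys: ", paste(bad, collapse = ", "))
      cfg$expr <- utils::modifyList(cfg$expr, over$expr)
      over$expr <- NULL
    }
    cfg[names(over)] <- over
  }
  for (f in c("fs", "band_low", "band_high", "mea_duration", "detect_k",
              "detect_window_ms", "top_n"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("invalid config field `", f, "`: must be > 0")
  if (cfg$excision_border < 0) stop("invalid config field `excision_border`")
  if (!(cfg$band_low < cfg$band_high && cfg$band_high < cfg$fs / 2))
    stop("invalid band: need band_low < band_high < fs/2")
  if (length(cfg$mea_group_rates) != 4 || is.null(names(cfg$mea_group_rates)))
    stop("invalid config field `mea_group_rates`: need 4 named rates")
  structure(cfg, class = "pipeline_config")
}

# canonical YAML form (named vectors as maps, so names survive the round trip)
config_as_yaml <- function(config) {
  x <- unclass(config)
  x$mea_group_rates <- as.list(x$mea_group_rates)
  yaml::as.yaml(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file; keys as in [pipeline_config()]. Unknown keys are
#'   rejected on read.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(config_as_yaml(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("mea_group_rates", "fir_taps", "fir_trans"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  do.call(pipeline_config, x)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; carried on every output of
#' [run_pipeline()] so results can be matched to the exact configuration.
#'
#' @param config a [pipeline_config()].
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(config_as_yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Process one recording: mask, filter, detect, select, summarize
#'
#' Applies the full single-organoid signal chain: recalibration excision,
#' flash removal, per-channel band-pass filtering over valid segments, spike
#' detection, per-channel frequencies over the effective duration, top-N
#' channel selection with the high-activity exclusion, and the organoid-level
#' activity summary.
#'
#' @param rec an [recording()].
#' @param config a [pipeline_config()].
#' @param organoid organoid identifier carried on the summary.
#' @return list with `mask`, `activities` (per-channel data.frame),
#'   `selection`, `summary`, and `spikes` (list of [spike_train()]).
#' @export
process_recording <- function(rec, config = pipeline_config(), organoid = NA) {
  mask <- excise_recalibration(rec, config$excision_border)
  mask <- detect_flashes(rec, mask, config$saturation_frac,
                         config$flash_channel_frac, config$flash_pad)
  coefs <- design_bandpass_fir(rec$fs, config$band_low, config$band_high,
                               config$fir_taps, config$fir_trans)
  trains <- vector("list", nrow(rec$samples))
  acts <- vector("list", nrow(rec$samples))
  for (ch in seq_len(nrow(rec$samples))) {
    filt <- bandpass_filter(rec$samples[ch, ], rec$fs, mask = mask,
                            coefs = coefs)
    tr <- detect_spikes(filt, mask, rec$fs, config$detect_window_ms,
                        config$detect_k, config$refractory_ms,
                        config$guard_ms, channel = rec$channel_ids[ch])
    trains[[ch]] <- tr
    acts[[ch]] <- channel_frequency(tr, mask, rec$fs)
  }
  activities <- do.call(rbind, acts)
  selection <- select_channels(activities, config$top_n, config$max_channel_hz)
  summary <- organoid_summary(selection, organoid, config$min_mean_hz)
  list(mask = mask, activities = activities, selection = selection,
       summary = summary, spikes = trains)
}

# derive a child seed from the master seed, kept within 32-bit integer range
derive_seed <- function(seed, mult, offset) {
  as.integer((as.numeric(seed) * mult + offset) %% 2147483629)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulates the four-group, two-stage study design on synthetic data with
#' ground truth and runs the full analysis: per-organoid MEA processing and
#' activity summaries, one-way ANOVA with Sidak comparisons on the included
#' organoids, expression filtering, DEG calling for the three contrasts
#' (maturation: stage-2 vs stage-1 mock; treatment at each stage),
#' representation-factor overlaps of the DEG lists against the maturation
#' signature (background: genes surviving the expression filter), Venn
#' partitioning, over-representation and pre-ranked GSEA on a synthetic
#' gene-set collection, and the oppositely-regulated contingent. Every source
#' of randomness is derived from `config$seed`, so two runs with the same
#' configuration produce identical bundles.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, tables are written as
#'   CSV and a machine-readable run log (JSON, including the config hash) is
#'   produced.
#' @return results bundle (list) with elements `activity`, `group_stats`,
#'   `degs`, `overlaps`, `venn`, `enrichment`, `gsea`, `opposed_genes`,
#'   `truth`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  log <- list(config_hash = hash)
  groups <- names(config$mea_group_rates)

  activity <- run_stage("mea", {
    rows <- list()
    idx <- 0L
    for (g in groups) for (o in seq_len(config$mea_organoids_per_group)) {
      idx <- idx + 1L
      cfg <- mea_sim_config(
        n_channels = config$mea_channels, fs = config$fs,
        duration = config$mea_duration,
        active_fraction = config$mea_active_fraction,
        rate_hz = config$mea_group_rates[[g]],
        spike_amp = config$mea_spike_amp, noise_sd = config$mea_noise_sd,
        seed = derive_seed(config$seed, 131, idx))
      sim <- generate_mea_recording(cfg)
      res <- process_recording(sim$recording, config,
                               organoid = paste0(g, "_", o))
      rows[[idx]] <- data.frame(
        organoid = res$summary$organoid, group = g,
        n_selected = length(res$summary$channels),
        mean_freq_hz = res$summary$mean_freq,
        included = res$summary$included)
    }
    do.call(rbind, rows)
  })
  log$organoids_recorded <- nrow(activity)
  log$organoids_included <- sum(activity$included)

  group_stats <- run_stage("group_stats", {
    inc <- activity[activity$included, ]
    if (all(table(factor(inc$group, levels = groups)) >= 2))
      anova_sidak(data.frame(group = inc$group, value = inc$mean_freq_hz))
    else NULL
  })

  expr_seed <- derive_seed(config$seed, 977, 7)
  sim <- run_stage("simulate_expression", {
    generate_expression_matrix(
      do.call(expr_sim_config, c(config$expr, list(seed = expr_seed))))
  })
  em <- run_stage("expression_filter", {
    filter_low_expression(sim$matrix, config$expr_min_valid,
                          config$expr_min_value)
  })
  log$genes_simulated <- nrow(sim$matrix$tpm)
  log$genes_after_filter <- nrow(em$tpm)

  glab <- unique(sim$matrix$groups)
  contrasts <- list(
    maturation = c(glab[1], glab[3]), # stage-2 mock vs stage-1 mock
    treatment60 = c(glab[1], glab[2]),
    treatment90 = c(glab[3], glab[4]))
  degs <- run_stage("deg", {
    lapply(contrasts, function(cc)
      call_degs(em, cc[1], cc[2], config$deg_min_diff, config$deg_min_fc,
                config$deg_alpha))
  })
  log$deg_counts <- vapply(degs, function(d) sum(d$class != "ns"), numeric(1))

  up <- lapply(degs, function(d) d$gene[d$class == "up"])
  down <- lapply(degs, function(d) d$gene[d$class == "down"])
  N <- nrow(em$tpm)
  overlaps <- run_stage("overlap", {
    ov <- function(l1, l2) {
      if (!length(l1) || !length(l2)) return(NULL)
      representation_factor(length(intersect(l1, l2)), length(l1),
                            length(l2), N)
    }
    list(up60_vs_maturation_up = ov(up$maturation, up$treatment60),
         up90_vs_maturation_up = ov(up$maturation, up$treatment90),
         down90_vs_maturation_down = ov(down$maturation, down$treatment90))
  })

  venn <- run_stage("venn", {
    venn_partition(list(maturation_up = up$maturation,
                        treatment60_up = up$treatment60,
                        treatment90_down = down$treatment90))
  })
  opposed_genes <- shared_all(list(up$maturation, up$treatment60,
                                   down$treatment90))

  coll <- run_stage("collection", {
    synthetic_collection(rownames(em$tpm), n_sets = 40,
                         size_range = c(15, 80),
                         planted = intersect(up$maturation, rownames(em$tpm)),
                         n_planted = 3, planted_frac = 0.7,
                         seed = derive_seed(config$seed, 389, 11))
  })
  enrichment <- run_stage("enrich", {
    lapply(degs, function(d) {
      sig <- d$gene[d$class != "ns"]
      hypergeom_enrichment(sig, rownames(em$tpm), coll)
    })
  })
  gsea <- run_stage("gsea", {
    preranked_gsea(rank_genes(degs$maturation), coll,
                   n_perm = config$gsea_n_perm,
                   seed = derive_seed(config$seed, 593, 13))
  })
  log$gsea_significant <- sum(gsea$fdr < config$enrich_fdr &
                                gsea$p < config$enrich_p, na.rm = TRUE)

  bundle <- list(activity = activity, group_stats = group_stats, degs = degs,
                 overlaps = overlaps, venn = venn, enrichment = enrichment,
                 gsea = gsea, opposed_genes = opposed_genes,
                 truth = sim$truth, log = log)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(output_dir, paste0(nm, ".csv")), row.names = FALSE)
    wr(activity, "activity")
    for (nm in names(degs)) wr(degs[[nm]], paste0("degs_", nm))
    wr(gsea, "gsea")
    ov_df <- do.call(rbind, lapply(names(overlaps), function(nm) {
      o <- overlaps[[nm]]
      if (is.null(o)) return(NULL)
      data.frame(comparison = nm, x = o$x, n1 = o$n1, n2 = o$n2, N = o$N,
                 rf = o$rf, p = o$p)
    }))
    if (!is.null(ov_df)) wr(ov_df, "overlaps")
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
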