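#' Read a study configuration from JSON
#'
#' The configuration names the input files and analysis settings for
#' [run_full_analysis()]: paths (`responses`, `item_map`, `dosages`,
#' `alleles` or `vcf`, `summary_stats`), the scale definition (`scale`:
#' `items`, `reverse_keyed`, `range`), thresholds (`p_threshold`,
#' `r2_threshold`), the circular `order`, the `null` calibration settings
#' (`distribution`, `lo`, `hi`, `mean`, `sd`, `n_samples`), SFI
#' `thresholds`, and a `seed`.
#'
#' @param path JSON file.
#' @return a named list (class `study_config`).
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- c("study_config", class(cfg))
  cfg
}

config_defaults <- function(cfg) {
  defaults <- list(p_threshold = 0.5, r2_threshold = 0.2,
                   order = schwartz_value_order(),
                   thresholds = c(0.05, 0.10, 0.15, 0.20),
                   null = list(distribution = "uniform", lo = -0.5, hi = 0.5,
                               n_samples = 100000),
                   seed = 1, n_starts = 16)
  out <- utils::modifyList(defaults, as.list(cfg))
  out$null <- utils::modifyList(defaults$null, as.list(out$null))
  out
}

#' Run the full value/trait/polygenic-score study
#'
#' Orchestrates every stage: scores the value survey (ipsatization,
#' type aggregation, per-type reliabilities), scores the trait scale,
#' builds the polygenic score (p-value thresholding, allele alignment,
#' greedy LD pruning, weighted averaging), joins participants present in
#' all three data sources, computes the two ordered correlation profiles
#' (trait and polygenic score against the ten value types), fits the
#' constrained sinusoid to each, calibrates the SFI null and reports
#' empirical p-values, plus the trait-score Pearson correlation.
#'
#' @param config a `study_config` list (see [read_study_config()]) or a
#'   path to a JSON configuration.
#' @return a `study_report` list with elements `n_joined`, `value_alphas`,
#'   `trait_profile`, `trait_fit`, `pgs_profile`, `pgs_fit`, `trait_p`,
#'   `pgs_p`, `trait_pgs_cor`, `calibration`, `pruning_audit`, `config`
#'   and `config_md5`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  cfg <- config_defaults(config)
  for (role in c("responses", "summary_stats")) {
    if (is.null(cfg[[role]])) stop("config is missing '", role, "'")
  }
  if (is.null(cfg$scale) || is.null(cfg$scale$items)) {
    stop("config is missing the trait 'scale' definition")
  }

  # --- value survey ---------------------------------------------------
  responses <- read_value_responses(cfg$responses,
                                    sep = cfg$sep %||% "\t")
  item_map <- if (!is.null(cfg$item_map)) {
    read_item_map(cfg$item_map)
  } else {
    schwartz_item_map()
  }
  centered <- ipsatize(responses)
  vscores <- aggregate_value_types(centered, item_map)
  alphas <- value_type_alphas(centered, item_map)

  # --- trait scale ----------------------------------------------------
  # the scale has its own questionnaire file; falling back to the value
  # survey itself is allowed but items must then be survey columns
  scale_ratings <- if (!is.null(cfg$scale$responses)) {
    tab <- read.delim(cfg$scale$responses, sep = cfg$sep %||% "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1]])
    m
  } else {
    responses$ratings
  }
  trait <- score_scale(scale_ratings, cfg$scale$items,
                       reverse_keyed = cfg$scale$reverse_keyed %||%
                         character(),
                       scale_range = cfg$scale$range %||% c(-1, 7))

  # --- polygenic score ------------------------------------------------
  genotypes <- if (!is.null(cfg$vcf)) {
    read_vcf_genotypes(cfg$vcf)
  } else if (!is.null(cfg$dosages)) {
    read_dosage_matrix(cfg$dosages, cfg$alleles)
  } else {
    stop("config must provide either 'vcf' or 'dosages' + 'alleles'")
  }
  sumstats <- read_summary_stats(cfg$summary_stats,
                                 column_map = cfg$column_map %||% list())
  pgs <- polygenic_score_pipeline(genotypes, sumstats,
                                  p_threshold = cfg$p_threshold,
                                  r2_threshold = cfg$r2_threshold)

  # --- join ------------------------------------------------------------
  ids <- Reduce(intersect, list(vscores$participant_ids, names(trait),
                                pgs$scores$sample_id))
  if (length(ids) < 2) {
    stop("fewer than 2 participants present in all data sources (",
         length(ids), " joined)")
  }
  message("joined ", length(ids), " participants across survey, scale and ",
          "genotype data")
  vs <- vscores$scores[ids, , drop = FALSE]
  trait_z <- as.numeric(scale(trait[ids]))
  pgs_vec <- pgs$scores$score[match(ids, pgs$scores$sample_id)]

  # --- profiles and fits ----------------------------------------------
  order <- cfg$order
  trait_profile <- correlate_profile(vs, trait_z, order = order)
  pgs_profile <- correlate_profile(vs, pgs_vec, order = order)
  trait_fit <- fit_sine(trait_profile, n_starts = cfg$n_starts)
  pgs_fit <- fit_sine(pgs_profile, n_starts = cfg$n_starts)

  # --- calibration -----------------------------------------------------
  nullcfg <- cfg$null
  spec <- null_spec(distribution = nullcfg$distribution %||% "uniform",
                    lo = nullcfg$lo %||% -0.5, hi = nullcfg$hi %||% 0.5,
                    mean = nullcfg$mean %||% 0, sd = nullcfg$sd %||% 0.1,
                    k = length(order),
                    n_samples = nullcfg$n_samples %||% 100000,
                    seed = cfg$seed)
  calibration <- calibrate_sfi(spec, thresholds = sort(cfg$thresholds),
                               n_starts = cfg$n_starts)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)

  out <- list(
    n_joined = length(ids),
    participant_ids = ids,
    value_alphas = alphas,
    trait_profile = trait_profile,
    trait_fit = trait_fit,
    pgs_profile = pgs_profile,
    pgs_fit = pgs_fit,
    trait_p = empirical_pvalue(trait_fit$sfi, calibration),
    pgs_p = empirical_pvalue(pgs_fit$sfi, calibration),
    trait_pgs_cor = list(r = cor(trait_z, pgs_vec), n = length(ids)),
    calibration = calibration,
    pruning_audit = pgs$pruned$audit,
    config = cfg,
    config_md5 = cfg_md5
  )
  class(out) <- "study_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", x$n_joined, " participants joined)\n", sep = "")
  cat(sprintf("  trait profile:  SFI = %.4f, empirical p = %.4g\n",
              x$trait_fit$sfi, x$trait_p$p))
  cat(sprintf("  PGS profile:    SFI = %.4f, empirical p = %.4g\n",
              x$pgs_fit$sfi, x$pgs_p$p))
  cat(sprintf("  trait-PGS Pearson r = %.3f (n = %d)\n",
              x$trait_pgs_cor$r, x$trait_pgs_cor$n))
  invisible(x)
}

#' Refit the sinusoid excluding one value type
#'
#' Drops the named point from the profile, re-indexes the remaining
#' positions contiguously 1..K-1 (the frequency bounds rescale with the
#' new K) and refits.
#'
#' @param profile a [correlation_profile()].
#' @param drop_label label of the value type to exclude.
#' @param ... passed to [fit_sine()].
#' @return a `sine_fit` on the reduced profile.
#' @export
refit_excluding <- function(profile, drop_label, ...) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (!drop_label %in% profile$label) {
    stop("label '", drop_label, "' not present in the profile")
  }
  keep <- profile$label != drop_label
  if (sum(keep) < 4) stop("fewer than 4 points would remain")
  reduced <- correlation_profile(profile$r[keep],
                                 labels = profile$label[keep])
  fit_sine(reduced, ...)
}

#' Write a study report to disk
#'
#' Emits a JSON report (parameters, SFIs, empirical p-values, correlation,
#' calibration rates, config hash) plus TSV tables of the two profiles
#' with fitted values and the pruning audit.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    n_joined = report$n_joined,
    trait = list(params = report$trait_fit$params,
                 sfi = report$trait_fit$sfi,
                 empirical_p = report$trait_p$p),
    pgs = list(params = report$pgs_fit$params,
               sfi = report$pgs_fit$sfi,
               empirical_p = report$pgs_p$p),
    trait_pgs_cor = report$trait_pgs_cor,
    calibration = report$calibration$rates,
    value_alphas = report$value_alphas,
    config_md5 = report$config_md5,
    config = report$config
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write_sine_fit(report$trait_fit,
                 tsv_path = file.path(dir, "trait_profile.tsv"))
  write_sine_fit(report$pgs_fit,
                 tsv_path = file.path(dir, "pgs_profile.tsv"))
  write.table(report$pruning_audit, file.path(dir, "pruning_audit.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
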