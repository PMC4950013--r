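#' Specification for circumplex-structured survey responses
#'
#' Participants get two latent axis scores (the two dimensions of the value
#' circle); each item loads on the axes through the angle of its value
#' type, so inter-item correlations decay with angular distance as
#' `cos(delta_theta) * loading^2 / (loading^2 + noise_sd^2)`. Latent item
#' scores are mapped affinely onto the -1..7 rating scale and rounded with
#' clamping.
#'
#' @param n_participants cohort size.
#' @param item_map item -> value type map (default [schwartz_item_map()]);
#'   unassigned items are placed between tradition and benevolence on the
#'   circle so they still receive plausible ratings.
#' @param type_angles named vector of angles (radians) per value type;
#'   default equally spaced in [schwartz_value_order()] order.
#' @param loading common loading of each item on its circumplex direction
#'   (default 1).
#' @param noise_sd item-specific noise standard deviation (default 1.6,
#'   giving same-type inter-item correlations near 0.28 and so type alphas
#'   in the moderate-to-good range typical of value surveys).
#' @param seed integer seed.
#' @return a `circumplex_spec` list.
#' @export
circumplex_spec <- function(n_participants = 100,
                            item_map = schwartz_item_map(),
                            type_angles = NULL, loading = 1,
                            noise_sd = 1.6, seed = 1) {
  if (is.null(type_angles)) {
    ord <- schwartz_value_order()
    type_angles <- stats::setNames(2 * pi * (seq_along(ord) - 1) /
                                     length(ord), ord)
  }
  types <- unique(item_map[!is.na(item_map)])
  missing <- setdiff(types, names(type_angles))
  if (length(missing) > 0) {
    stop("no angle for value type(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(type_angles[types])) stop("type angles must be distinct")
  if (loading < 0 || loading > 1 + 1e-12) stop("loading must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  out <- list(n_participants = as.integer(n_participants),
              item_map = item_map, type_angles = type_angles,
              loading = loading, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(out) <- "circumplex_spec"
  out
}

# angle of every item; unassigned items sit between positions 2 and 3
item_angles <- function(spec) {
  ang <- spec$type_angles[spec$item_map]
  gap <- mean(spec$type_angles[c("tradition", "benevolence")])
  ang[is.na(spec$item_map)] <- gap
  stats::setNames(ang, names(spec$item_map))
}

#' Generate circumplex-structured value-survey responses
#'
#' @param spec a [circumplex_spec()].
#' @return a `value_survey_responses` object (ratings on -1..7). The
#'   continuous latent item scores are attached as attribute `"latent"`
#'   for diagnostic use.
#' @export
#' @examples
#' resp <- gen_value_responses(circumplex_spec(n_participants = 50, seed = 3))
#' dim(resp$ratings)
gen_value_responses <- function(spec) {
  stopifnot(inherits(spec, "circumplex_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  ang <- item_angles(spec)
  m <- length(ang)
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  latent <- spec$loading * (outer(f1, cos(ang)) + outer(f2, sin(ang))) +
    matrix(rnorm(n * m, 0, spec$noise_sd), n, m)
  sd_latent <- sqrt(spec$loading^2 + spec$noise_sd^2)
  if (sd_latent == 0) sd_latent <- 1
  # map +-3 latent SDs onto the -1..7 span around the scale midpoint 3
  ratings <- round(3 + (4 / 3) * latent / sd_latent)
  ratings <- pmin(pmax(ratings, -1), 7)
  dimnames(ratings) <- list(sprintf("p%04d", seq_len(n)), names(ang))
  dimnames(latent) <- dimnames(ratings)
  out <- value_survey_responses(ratings)
  attr(out, "latent") <- latent
  out
}

#' Specification for an external trait with a sinusoidal value profile
#'
#' @param target_sine list `(a, b, c, d)`: the population correlation
#'   between the trait and the value type at position k is
#'   `a + b * sin(c * k + d)`. `|a| + |b|` must not exceed 1. The default
#'   (offset 0, amplitude 0.25, phase putting the trough at the openness
#'   values self-direction/stimulation) mimics a neuroticism-like trait.
#'   Note that ipsatized type scores are nearly linearly dependent (their
#'   item-count-weighted sum is close to zero), so targets with a non-zero
#'   offset `a` are usually infeasible against them.
#' @param residual_sd standard deviation of the trait's residual noise
#'   (must be positive; the mixing weights absorb the scale).
#' @param seed integer seed.
#' @return a `trait_sim_spec` list.
#' @export
trait_sim_spec <- function(target_sine = list(a = 0, b = 0.25,
                                              c = 0.9 * 2 * pi / 10, d = 1.6),
                           residual_sd = 0.5, seed = 1) {
  for (nm in c("a", "b", "c", "d")) {
    if (is.null(target_sine[[nm]])) stop("target_sine must contain '", nm, "'")
  }
  if (abs(target_sine$a) + abs(target_sine$b) > 1) {
    stop("implied correlations exceed 1 in magnitude: need |a| + |b| <= 1")
  }
  if (residual_sd <= 0) stop("residual_sd must be positive")
  out <- list(target_sine = target_sine, residual_sd = residual_sd,
              seed = as.integer(seed))
  class(out) <- "trait_sim_spec"
  out
}

#' Generate an external trait with a target sinusoidal correlation profile
#'
#' Builds `trait = sum_k w_k z(value_k) + residual` where the weights `w`
#' are solved through the sample correlation matrix of the value-type
#' scores so that the population correlation between the trait and value
#' type k (conditional on those scores) equals the target sinusoid at
#' position k.
#'
#' @param value_scores a `value_type_scores` object (ipsatized type
#'   scores), columns in the circular order used for the target positions.
#' @param spec a [trait_sim_spec()].
#' @param order circular order of the value types (default
#'   [schwartz_value_order()]).
#' @return named numeric trait vector (one per participant), with the
#'   target correlations attached as attribute `"target_r"`.
#' @export
gen_external_trait <- function(value_scores, spec,
                               order = schwartz_value_order()) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  scores <- if (inherits(value_scores, "value_type_scores")) {
    value_scores$scores
  } else {
    as.matrix(value_scores)
  }
  missing <- setdiff(order, colnames(scores))
  if (length(missing) > 0) {
    stop("value types absent from scores: ", paste(missing, collapse = ", "))
  }
  z <- scale(scores[, order, drop = FALSE])
  K <- length(order)
  rho <- sine_model(seq_len(K), spec$target_sine)
  if (any(abs(rho) >= 1)) stop("target correlations must lie inside (-1, 1)")
  R <- cor(z)
  w0 <- tryCatch(solve(R, rho), error = function(e) {
    ls <- qr.solve(qr(R, LAPACK = TRUE), rho)
    resid <- max(abs(R %*% ls - rho))
    stop("target correlations infeasible for this covariance ",
         "(least-squares residual ", signif(resid, 3), ")")
  })
  q <- sum(rho * w0)
  if (q >= 1) {
    stop("target correlations infeasible: the value scores would have to ",
         "explain ", signif(100 * q, 4), "% of the trait variance")
  }
  sigma_t <- spec$residual_sd / sqrt(1 - q)
  w <- sigma_t * w0
  set.seed(spec$seed)
  trait <- as.numeric(z %*% w) + rnorm(nrow(z), 0, spec$residual_sd)
  names(trait) <- rownames(scores)
  attr(trait, "target_r") <- stats::setNames(rho, order)
  trait
}

#' Specification for synthetic genotypes with a polygenic trait
#'
#' @param n_samples cohort size.
#' @param n_snps number of independent SNPs.
#' @param maf_range minor-allele-frequency range (uniform per SNP).
#' @param target_rho desired correlation between the polygenic score and
#'   the trait (default 0.22, a realistic single-cohort polygenic
#'   association for a behavioural trait).
#' @param effect_sd standard deviation of per-SNP log odds ratios.
#' @param ld_block_size with the default 1, SNPs are independent; larger
#'   values group SNPs into blocks whose haplotypes share a latent factor,
#'   creating within-block linkage disequilibrium (used to exercise LD
#'   pruning).
#' @param ld_rho within-block haplotype correlation of the latent factor.
#' @param seed integer seed.
#' @return a `geno_sim_spec` list.
#' @export
geno_sim_spec <- function(n_samples = 500, n_snps = 200,
                          maf_range = c(0.05, 0.5), target_rho = 0.22,
                          effect_sd = 0.05, ld_block_size = 1, ld_rho = 0.9,
                          seed = 1) {
  if (maf_range[1] <= 0.01 - 1e-12 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0.01, 0.5]")
  }
  if (abs(target_rho) >= 1) stop("|target_rho| must be < 1")
  if (effect_sd < 0) stop("effect_sd must be non-negative")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  out <- list(n_samples = as.integer(n_samples),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              target_rho = target_rho, effect_sd = effect_sd,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              seed = as.integer(seed))
  class(out) <- "geno_sim_spec"
  out
}

#' Generate genotypes, summary statistics and a polygenic trait
#'
#' Dosages are binomial(2, maf) per SNP (independent across SNPs by
#' default, or with within-block LD). Log odds ratios are normal with
#' standard deviation `effect_sd`; p-values are assigned consistently with
#' the effect sizes (two-sided normal tail of the standardized effect).
#' The trait is built from the standardized weighted-average score:
#' `trait = z(score) * target_rho + sqrt(1 - target_rho^2) * noise`, so
#' the population score-trait correlation equals `target_rho`.
#'
#' @param spec a [geno_sim_spec()].
#' @return list with `genotypes` (a [genotype_matrix()]), `records` (a
#'   [summary_stats()] table; effect allele A, other allele G) and `trait`
#'   (named numeric vector).
#' @export
#' @examples
#' sim <- gen_genotypes_with_trait(geno_sim_spec(n_samples = 200,
#'                                               n_snps = 50, seed = 2))
#' cor(polygenic_score_pipeline(sim$genotypes, sim$records,
#'                              p_threshold = 1)$scores$score, sim$trait)
gen_genotypes_with_trait <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_snps
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  if (spec$ld_block_size <= 1) {
    dos <- vapply(maf, function(p) rbinom(n, 2, p), numeric(n))
  } else {
    # two haplotypes per sample; within a block both share a latent
    # factor, so thresholded allele indicators are correlated across SNPs
    block <- (seq_len(m) - 1) %/% spec$ld_block_size
    dos <- matrix(0, n, m)
    for (h in 1:2) {
      common <- vapply(unique(block), function(b) rnorm(n), numeric(n))
      eps <- matrix(rnorm(n * m), n, m)
      lat <- sqrt(spec$ld_rho) * common[, block + 1, drop = FALSE] +
        sqrt(1 - spec$ld_rho) * eps
      dos <- dos + (lat < matrix(stats::qnorm(maf), n, m, byrow = TRUE))
    }
  }
  snp_ids <- sprintf("snp%05d", seq_len(m))
  dimnames(dos) <- list(sprintf("s%05d", seq_len(n)), snp_ids)
  geno <- genotype_matrix(dos, counted_allele = rep("A", m),
                          alt_allele = rep("G", m))
  ln_or <- rnorm(m, 0, spec$effect_sd)
  pval <- if (spec$effect_sd > 0) {
    2 * stats::pnorm(-abs(ln_or) / spec$effect_sd)
  } else {
    runif(m)
  }
  records <- summary_stats(snp_id = snp_ids, effect_allele = "A",
                           other_allele = "G", odds_ratio = exp(ln_or),
                           p_value = pval)
  raw_score <- as.numeric(dos %*% ln_or) / m
  if (sd(raw_score) == 0) {
    stop("polygenic scores are constant (all effects zero?); ",
         "score-trait correlation is undefined")
  }
  z <- as.numeric(scale(raw_score))
  trait <- z * spec$target_rho +
    sqrt(1 - spec$target_rho^2) * rnorm(n)
  names(trait) <- rownames(dos)
  list(genotypes = geno, records = records, trait = trait)
}

#' Write a synthetic cohort to the pipeline's input formats
#'
#' Emits the survey responses (TSV), item map (TSV), dosage matrix with
#' allele sidecar (TSV) and summary statistics (TSV) plus the simulated
#' trait, so the file-based pipeline entry points can be exercised
#' end-to-end.
#'
#' @param dir output directory (created if needed).
#' @param responses a `value_survey_responses` object.
#' @param item_map item -> type map.
#' @param sim result of [gen_genotypes_with_trait()] (optional).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_cohort <- function(dir, responses,
                                   item_map = schwartz_item_map(),
                                   sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(responses = file.path(dir, "responses.tsv"),
             item_map = file.path(dir, "item_map.tsv"))
  tab <- data.frame(participant_id = responses$participant_ids,
                    responses$ratings, check.names = FALSE)
  write.table(tab, paths["responses"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(item_id = names(item_map), value_type = item_map),
              paths["item_map"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  if (!is.null(sim)) {
    paths <- c(paths, dosages = file.path(dir, "dosages.tsv"),
               alleles = file.path(dir, "alleles.tsv"),
               sumstats = file.path(dir, "sumstats.tsv"),
               trait = file.path(dir, "trait.tsv"))
    g <- sim$genotypes
    write.table(data.frame(sample_id = g$sample_ids, g$dosages,
                           check.names = FALSE),
                paths["dosages"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(snp_id = g$snp_ids,
                           counted_allele = g$counted_allele,
                           alt_allele = g$alt_allele),
                paths["alleles"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    ss <- sim$records
    write.table(data.frame(SNP = ss$snp_id, A1 = ss$effect_allele,
                           A2 = ss$other_allele, OR = ss$odds_ratio,
                           P = ss$p_value),
                paths["sumstats"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample_id = names(sim$trait), trait = sim$trait),
                paths["trait"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
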