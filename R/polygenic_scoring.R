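#' Read GWAS summary statistics
#'
#' Reads a delimited table of per-SNP association results. Effect sizes are
#' taken from an odds-ratio column, or from a BETA (log-odds) column which
#' is exponentiated. Records are validated: odds ratios must be positive,
#' p-values in \[0, 1\], alleles distinct, SNP ids unique.
#'
#' @param path delimited file with a header.
#' @param column_map named list mapping the roles `snp`, `effect_allele`,
#'   `other_allele`, `or` (or `beta`), `p` to column names; defaults to
#'   `SNP, A1, A2, OR, P` (with `BETA` used if `OR` is absent).
#' @param sep field separator.
#' @return data.frame of class `summary_stats` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `odds_ratio`, `p_value`.
#' @export
read_summary_stats <- function(path, column_map = list(), sep = "\t") {
  defaults <- list(snp = "SNP", effect_allele = "A1", other_allele = "A2",
                   or = "OR", beta = "BETA", p = "P")
  cm <- utils::modifyList(defaults, column_map)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  for (role in c("snp", "effect_allele", "other_allele", "p")) {
    if (!cm[[role]] %in% names(tab)) {
      stop("column '", cm[[role]], "' (", role, ") not found in ", path)
    }
  }
  if (cm$or %in% names(tab)) {
    or <- as.numeric(tab[[cm$or]])
  } else if (cm$beta %in% names(tab)) {
    or <- exp(as.numeric(tab[[cm$beta]]))
  } else {
    stop("neither an odds-ratio ('", cm$or, "') nor a beta ('", cm$beta,
         "') column found in ", path)
  }
  summary_stats(snp_id = as.character(tab[[cm$snp]]),
                effect_allele = toupper(as.character(tab[[cm$effect_allele]])),
                other_allele = toupper(as.character(tab[[cm$other_allele]])),
                odds_ratio = or,
                p_value = as.numeric(tab[[cm$p]]))
}

#' Construct a validated summary-statistics table
#'
#' @param snp_id,effect_allele,other_allele,odds_ratio,p_value per-SNP
#'   vectors of equal length.
#' @return data.frame of class `summary_stats`.
#' @export
summary_stats <- function(snp_id, effect_allele, other_allele, odds_ratio,
                          p_value) {
  tab <- data.frame(snp_id = as.character(snp_id),
                    effect_allele = as.character(effect_allele),
                    other_allele = as.character(other_allele),
                    odds_ratio = as.numeric(odds_ratio),
                    p_value = as.numeric(p_value),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(tab$odds_ratio) | tab$odds_ratio <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing odds ratio at row(s): ",
         paste(head(bad, 5), collapse = ", "), " (snp ",
         paste(head(tab$snp_id[bad], 5), collapse = ", "), ")")
  }
  bad <- which(is.na(tab$p_value) | tab$p_value < 0 | tab$p_value > 1)
  if (length(bad) > 0) {
    stop("p-value outside [0, 1] at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(tab$effect_allele == tab$other_allele)
  if (length(bad) > 0) {
    stop("effect and other allele identical for snp ",
         paste(head(tab$snp_id[bad], 5), collapse = ", "))
  }
  dup <- unique(tab$snp_id[duplicated(tab$snp_id)])
  if (length(dup) > 0) {
    stop("duplicate snp ids: ", paste(head(dup, 5), collapse = ", "))
  }
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Construct a genotype matrix
#'
#' Hard-call dosages counted on a declared per-SNP allele.
#'
#' @param dosages numeric matrix, samples x SNPs, values 0/1/2 or `NA`;
#'   sample ids as row names, SNP ids as column names.
#' @param counted_allele,alt_allele character vectors (one per SNP): the
#'   allele whose copies the dosage counts, and the other allele.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, counted_allele, alt_allele) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(colnames(dosages))) stop("dosage matrix needs SNP column names")
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("s", seq_len(nrow(dosages)))
  }
  m <- ncol(dosages)
  if (length(counted_allele) != m || length(alt_allele) != m) {
    stop("allele vectors must have one entry per SNP")
  }
  vals <- dosages[!is.na(dosages)]
  if (any(vals < 0 | vals > 2)) stop("dosages must lie in [0, 2]")
  out <- list(sample_ids = rownames(dosages),
              snp_ids = colnames(dosages),
              dosages = dosages,
              counted_allele = stats::setNames(toupper(counted_allele),
                                               colnames(dosages)),
              alt_allele = stats::setNames(toupper(alt_allele),
                                            colnames(dosages)))
  class(out) <- "genotype_matrix"
  out
}

#' Read a dosage matrix with its allele sidecar table
#'
#' The dosage file is a delimited table: first column sample id, header of
#' SNP ids, entries 0/1/2 or missing. The sidecar table has columns
#' `snp_id`, `counted_allele`, `alt_allele`.
#'
#' @param dosage_path,allele_path file paths.
#' @param sep field separator.
#' @return a [genotype_matrix()].
#' @export
read_dosage_matrix <- function(dosage_path, allele_path, sep = "\t") {
  tab <- read.delim(dosage_path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- as.character(tab[[1]])
  al <- read.delim(allele_path, sep = sep, stringsAsFactors = FALSE)
  need <- c("snp_id", "counted_allele", "alt_allele")
  if (!all(need %in% names(al))) {
    stop("allele table must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(dos), al$snp_id)
  if (length(missing) > 0) {
    stop("SNPs missing from the allele table: ",
         paste(head(missing, 5), collapse = ", "))
  }
  idx <- match(colnames(dos), al$snp_id)
  genotype_matrix(dos, al$counted_allele[idx], al$alt_allele[idx])
}

#' Read genotypes from a VCF
#'
#' Extracts diploid hard-call genotypes from the GT field; the dosage
#' counts copies of the ALT allele. Requires the `vcfR` package.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  snp_ids <- fix[, "ID"]
  if (anyNA(snp_ids) || any(snp_ids == ".")) {
    stop("all VCF records must carry an ID")
  }
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, count_alt, numeric(1))))
  dimnames(dos) <- list(snp_ids, colnames(gt))
  genotype_matrix(t(dos), counted_allele = fix[, "ALT"],
                  alt_allele = fix[, "REF"])
}

#' Threshold summary statistics by p-value
#'
#' Keeps exactly the records with `p_value` strictly below the threshold
#' (the conventional "PT < t" rule), preserving input order.
#'
#' @param records a [summary_stats()] table.
#' @param p_threshold inclusion threshold in (0, 1].
#' @return the retained subset (same class).
#' @export
threshold_by_p <- function(records, p_threshold) {
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    stop("p_threshold must lie in (0, 1]")
  }
  keep <- records$p_value < p_threshold
  if (!any(keep)) {
    stop("no SNPs pass the p-value threshold ", p_threshold)
  }
  records[keep, , drop = FALSE]
}

#' Greedy linkage-disequilibrium pruning
#'
#' Walks the candidate SNPs in ascending GWAS p-value (ties broken by SNP
#' id) and retains a SNP iff its squared Pearson correlation with every
#' already-retained SNP stays below `r2_threshold` (strict). r-squared is
#' computed from the dosage vectors over samples where both calls are
#' present. A SNP with constant dosage carries no LD information and is
#' always retained.
#'
#' @param genotypes a [genotype_matrix()].
#' @param records a [summary_stats()] table (provides the p-value order).
#' @param r2_threshold exclusion threshold on pairwise r-squared (default
#'   0.2).
#' @return a `pruned_snp_set`: list with `retained` (snp ids),
#'   `r2_threshold` and an `audit` data.frame of
#'   (removed_snp, retained_partner, r2).
#' @export
ld_prune_greedy <- function(genotypes, records, r2_threshold = 0.2) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  missing <- setdiff(records$snp_id, genotypes$snp_ids)
  if (length(missing) > 0) {
    stop("SNPs absent from the genotypes: ",
         paste(head(missing, 10), collapse = ", "))
  }
  ord <- order(records$p_value, records$snp_id)
  candidates <- records$snp_id[ord]
  dos <- genotypes$dosages
  retained <- character(0)
  audit <- list()
  for (snp in candidates) {
    v <- dos[, snp]
    partner <- NA_character_
    partner_r2 <- NA_real_
    for (kept in retained) {
      w <- dos[, kept]
      ok <- !is.na(v) & !is.na(w)
      if (sum(ok) < 2 || sd(v[ok]) == 0 || sd(w[ok]) == 0) next
      r2 <- cor(v[ok], w[ok])^2
      if (r2 >= r2_threshold) {
        partner <- kept
        partner_r2 <- r2
        break
      }
    }
    if (is.na(partner)) {
      retained <- c(retained, snp)
    } else {
      audit[[length(audit) + 1]] <-
        data.frame(removed_snp = snp, retained_partner = partner,
                   r2 = partner_r2, stringsAsFactors = FALSE)
    }
  }
  audit <- if (length(audit) > 0) {
    do.call(rbind, audit)
  } else {
    data.frame(removed_snp = character(0), retained_partner = character(0),
               r2 = numeric(0), stringsAsFactors = FALSE)
  }
  out <- list(retained = retained, r2_threshold = r2_threshold, audit = audit)
  class(out) <- "pruned_snp_set"
  out
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align genotype dosages to the GWAS effect allele
#'
#' Ensures every SNP's dosage counts copies of the summary-statistics
#' effect allele: SNPs already counted on the effect allele pass through;
#' SNPs counted on the other allele are flipped (`d -> 2 - d`); any other
#' allele combination is an error. Strand-ambiguous (A/T, C/G) SNPs cannot
#' be aligned unambiguously across strand conventions and are dropped when
#' `strict = TRUE` (default) or kept as-is with a warning otherwise.
#'
#' @param genotypes a [genotype_matrix()].
#' @param records a [summary_stats()] table covering the genotype SNPs.
#' @param strict drop strand-ambiguous SNPs (default `TRUE`).
#' @return a [genotype_matrix()] restricted to alignable SNPs in `records`,
#'   with attribute `"flipped"` (ids whose dosages were flipped) and
#'   `"dropped_ambiguous"`.
#' @export
align_alleles <- function(genotypes, records, strict = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- intersect(records$snp_id, genotypes$snp_ids)
  if (length(snps) == 0) stop("no overlapping SNPs to align")
  idx <- match(snps, records$snp_id)
  eff <- toupper(records$effect_allele[idx])
  oth <- toupper(records$other_allele[idx])
  cnt <- genotypes$counted_allele[snps]
  alt <- genotypes$alt_allele[snps]

  same <- cnt == eff & alt == oth
  flip <- cnt == oth & alt == eff
  mismatch <- !(same | flip)
  if (any(mismatch)) {
    stop("allele pair mismatch between genotypes and summary statistics ",
         "for snp(s): ", paste(head(snps[mismatch], 5), collapse = ", "))
  }
  ambiguous <- strand_ambiguous(eff, oth)
  dropped <- character(0)
  if (any(ambiguous)) {
    if (strict) {
      dropped <- snps[ambiguous]
      keep <- !ambiguous
      snps <- snps[keep]; same <- same[keep]; flip <- flip[keep]
      eff <- eff[keep]; oth <- oth[keep]
      if (length(snps) == 0) stop("all SNPs are strand-ambiguous")
    } else {
      warning("strand-ambiguous SNPs kept as-is: ",
              paste(head(snps[ambiguous], 5), collapse = ", "))
    }
  }
  dos <- genotypes$dosages[, snps, drop = FALSE]
  if (any(flip)) {
    dos[, snps[flip]] <- 2 - dos[, snps[flip], drop = FALSE]
  }
  out <- genotype_matrix(dos, counted_allele = eff, alt_allele = oth)
  attr(out, "flipped") <- snps[flip]
  attr(out, "dropped_ambiguous") <- dropped
  out
}

#' Compute polygenic scores
#'
#' Per sample, averages the counted risk-allele dosages over the scored
#' SNPs, each weighted by the natural logarithm of its odds ratio:
#' `score_i = sum_j ln(OR_j) * dosage_ij / n`. By default `n` is the number
#' of SNPs used; `divisor = "per_allele"` divides by twice that (the
#' number of alleles). Missing dosages are imputed to the per-SNP mean
#' dosage among called samples (`missing = "mean_impute"`), or samples
#' with any missing call can be dropped (`missing = "complete"`).
#'
#' @param genotypes a [genotype_matrix()] already aligned so dosages count
#'   the effect allele (see [align_alleles()]).
#' @param records the [summary_stats()] records to score (typically
#'   thresholded and pruned); every record must be present in the
#'   genotypes.
#' @param missing missing-dosage policy.
#' @param divisor `"per_snp"` (default) or `"per_allele"`.
#' @return a `polygenic_scores` data.frame: `sample_id`, `score`,
#'   `n_snps_used`.
#' @export
compute_scores <- function(genotypes, records,
                           missing = c("mean_impute", "complete"),
                           divisor = c("per_snp", "per_allele")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  missing <- match.arg(missing)
  divisor <- match.arg(divisor)
  absent <- setdiff(records$snp_id, genotypes$snp_ids)
  if (length(absent) > 0) {
    stop("SNPs absent from the genotypes: ",
         paste(head(absent, 10), collapse = ", "))
  }
  snps <- records$snp_id
  if (length(snps) == 0) stop("no SNPs to score")
  misaligned <- genotypes$counted_allele[snps] !=
    toupper(records$effect_allele[match(snps, records$snp_id)])
  if (any(misaligned)) {
    stop("genotypes are not aligned to the effect allele for snp(s): ",
         paste(head(snps[misaligned], 5), collapse = ", "),
         "; run align_alleles() first")
  }
  dos <- genotypes$dosages[, snps, drop = FALSE]
  if (missing == "complete") {
    keep <- complete.cases(dos)
    if (!any(keep)) stop("no samples with complete calls on the scored SNPs")
    dos <- dos[keep, , drop = FALSE]
  } else if (anyNA(dos)) {
    means <- colMeans(dos, na.rm = TRUE)
    if (anyNA(means)) {
      stop("SNP(s) with no called samples: ",
           paste(head(snps[is.na(means)], 5), collapse = ", "))
    }
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- means[idx[, 2]]
  }
  w <- log(records$odds_ratio)
  n_used <- length(snps)
  denom <- if (divisor == "per_snp") n_used else 2 * n_used
  score <- as.numeric(dos %*% w) / denom
  out <- data.frame(sample_id = rownames(dos), score = score,
                    n_snps_used = n_used, stringsAsFactors = FALSE)
  class(out) <- c("polygenic_scores", "data.frame")
  out
}

#' Full polygenic-scoring pipeline
#'
#' Convenience wrapper: p-value thresholding, allele alignment, greedy LD
#' pruning, then weighted-average scoring.
#'
#' @param genotypes a [genotype_matrix()].
#' @param records a [summary_stats()] table.
#' @param p_threshold GWAS p-value inclusion threshold (default 0.5).
#' @param r2_threshold LD pruning threshold (default 0.2).
#' @param ... passed to [compute_scores()].
#' @return list with `scores` (a `polygenic_scores` data.frame), `pruned`
#'   (the [ld_prune_greedy()] result) and `records_used`.
#' @export
polygenic_score_pipeline <- function(genotypes, records, p_threshold = 0.5,
                                     r2_threshold = 0.2, ...) {
  thresholded <- threshold_by_p(records, p_threshold)
  aligned <- align_alleles(genotypes, thresholded)
  usable <- thresholded[thresholded$snp_id %in% aligned$snp_ids, ,
                        drop = FALSE]
  pruned <- ld_prune_greedy(aligned, usable, r2_threshold)
  final <- usable[usable$snp_id %in% pruned$retained, , drop = FALSE]
  scores <- compute_scores(aligned, final, ...)
  list(scores = scores, pruned = pruned, records_used = final)
}
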