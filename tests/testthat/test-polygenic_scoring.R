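test_that("summary-statistics reader validates and converts", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = "A", A2 = "G",
                   OR = c(1.2, 0.9, 1.0), P = c(0.01, 0.5, 0.99))
  recs <- read_summary_stats(write_sumstats_file(df))
  expect_s3_class(recs, "summary_stats")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$odds_ratio, c(1.2, 0.9, 1.0))

  # BETA column exponentiated: zero effects become OR = 1
  df_beta <- data.frame(SNP = c("rs1", "rs2"), A1 = "A", A2 = "G",
                        BETA = c(0, 0), P = c(0.1, 0.2))
  recs_b <- read_summary_stats(write_sumstats_file(df_beta))
  expect_equal(recs_b$odds_ratio, c(1, 1))

  df_dup <- df
  df_dup$SNP <- c("rs1", "rs1", "rs3")
  expect_error(read_summary_stats(write_sumstats_file(df_dup)), "duplicate")
  df_neg <- df
  df_neg$OR[2] <- -0.5
  expect_error(read_summary_stats(write_sumstats_file(df_neg)), "odds ratio")
  df_p <- df
  df_p$P[1] <- 1.5
  expect_error(read_summary_stats(write_sumstats_file(df_p)), "p-value")
  df_al <- df
  df_al$A2 <- "A"
  expect_error(read_summary_stats(write_sumstats_file(df_al)), "allele")
})

test_that("p-value thresholding keeps strictly-smaller records in order", {
  recs <- summary_stats(paste0("rs", 1:3), "A", "G", c(1.1, 1.2, 0.9),
                        c(0.01, 0.49, 0.51))
  kept <- threshold_by_p(recs, 0.5)
  expect_equal(kept$snp_id, c("rs1", "rs2"))

  # threshold 1.0 with strict inequality drops only p = 1
  recs2 <- summary_stats(paste0("rs", 1:3), "A", "G", rep(1.1, 3),
                         c(0.2, 1.0, 0.999))
  expect_equal(threshold_by_p(recs2, 1.0)$snp_id, c("rs1", "rs3"))

  # random records equal a brute-force filter
  set.seed(7)
  recs3 <- summary_stats(paste0("rs", 1:50), "A", "G", exp(rnorm(50, 0, 0.1)),
                         runif(50))
  t <- 0.3
  expect_equal(threshold_by_p(recs3, t)$snp_id,
               recs3$snp_id[recs3$p_value < t])
  expect_error(threshold_by_p(recs3, 1e-9), "no SNPs")
  expect_error(threshold_by_p(recs3, 0), "p_threshold")
})

test_that("greedy LD pruning retains quasi-independent SNPs", {
  # independent simulated SNPs: everything retained
  set.seed(17)
  n <- 400
  dos <- vapply(runif(8, 0.2, 0.5), function(p) rbinom(n, 2, p), numeric(n))
  colnames(dos) <- paste0("rs", 1:8)
  rownames(dos) <- paste0("s", 1:n)
  geno <- genotype_matrix(dos, rep("A", 8), rep("G", 8))
  recs <- summary_stats(paste0("rs", 1:8), "A", "G", rep(1.1, 8),
                        seq(0.01, 0.08, by = 0.01))
  pruned <- ld_prune_greedy(geno, recs, 0.2)
  expect_setequal(pruned$retained, paste0("rs", 1:8))
  expect_equal(nrow(pruned$audit), 0)

  # a perfect copy is removed in favour of the smaller-p SNP
  dos2 <- cbind(dos, rs9 = dos[, "rs1"])
  geno2 <- genotype_matrix(dos2, rep("A", 9), rep("G", 9))
  recs2 <- summary_stats(paste0("rs", 1:9), "A", "G", rep(1.1, 9),
                         c(seq(0.01, 0.08, by = 0.01), 0.001))
  pruned2 <- ld_prune_greedy(geno2, recs2, 0.2)
  expect_true("rs9" %in% pruned2$retained)   # rs9 has the smallest p
  expect_false("rs1" %in% pruned2$retained)
  expect_equal(pruned2$audit$removed_snp, "rs1")
  expect_equal(pruned2$audit$retained_partner, "rs9")

  expect_error(ld_prune_greedy(geno, summary_stats("rsX", "A", "G", 1.1, 0.1)),
               "rsX")
})

test_that("pruning output passes exhaustive pairwise verification", {
  sim <- gen_genotypes_with_trait(geno_sim_spec(n_samples = 300, n_snps = 40,
                                                ld_block_size = 4,
                                                ld_rho = 0.95, seed = 23))
  pruned <- ld_prune_greedy(sim$genotypes, sim$records, 0.2)
  dos <- sim$genotypes$dosages
  ret <- pruned$retained
  expect_true(length(ret) < 40)    # the planted LD removes some SNPs
  # every retained pair is below threshold
  for (i in seq_along(ret)) {
    for (j in seq_len(i - 1)) {
      expect_lt(cor(dos[, ret[i]], dos[, ret[j]])^2, 0.2)
    }
  }
  # every removed SNP clashes with at least one retained SNP
  removed <- setdiff(sim$records$snp_id, ret)
  for (snp in removed) {
    r2s <- vapply(ret, function(k) cor(dos[, snp], dos[, k])^2, numeric(1))
    expect_gte(max(r2s), 0.2)
  }
})

test_that("allele alignment flips, rejects mismatches and drops palindromes", {
  geno <- tiny_genotypes()
  recs <- tiny_sumstats()
  aligned <- align_alleles(geno, recs)
  expect_equal(aligned$dosages, geno$dosages)  # already aligned: unchanged

  # one flipped SNP: dosages complement to 2 - d
  recs_flip <- recs
  recs_flip$effect_allele[1] <- "G"
  recs_flip$other_allele[1] <- "A"
  flipped <- align_alleles(geno, recs_flip)
  expect_equal(unname(flipped$dosages[, "rs1"]),
               unname(2 - geno$dosages[, "rs1"]))
  expect_equal(attr(flipped, "flipped"), "rs1")
  # the other SNPs are untouched; per-record manual alignment agrees
  expect_equal(flipped$dosages[, c("rs2", "rs3")],
               geno$dosages[, c("rs2", "rs3")])

  recs_bad <- recs
  recs_bad$effect_allele[2] <- "A"
  recs_bad$other_allele[2] <- "G"
  expect_error(align_alleles(geno, recs_bad), "mismatch")

  # A/T pair is strand-ambiguous: dropped under strict, kept with warning
  recs_amb <- recs
  recs_amb$effect_allele[3] <- "A"
  recs_amb$other_allele[3] <- "T"
  geno_amb <- geno
  geno_amb$counted_allele["rs3"] <- "A"
  geno_amb$alt_allele["rs3"] <- "T"
  strict <- align_alleles(geno_amb, recs_amb)
  expect_false("rs3" %in% strict$snp_ids)
  expect_equal(attr(strict, "dropped_ambiguous"), "rs3")
  expect_warning(lax <- align_alleles(geno_amb, recs_amb, strict = FALSE),
                 "ambiguous")
  expect_true("rs3" %in% lax$snp_ids)
})

test_that("polygenic scores match a pencil-and-paper oracle", {
  # 2 samples x 3 SNPs, hand-set dosages and odds ratios
  dos <- rbind(s1 = c(0, 1, 2), s2 = c(2, 0, 1))
  colnames(dos) <- c("rs1", "rs2", "rs3")
  geno <- genotype_matrix(dos, rep("A", 3), rep("G", 3))
  recs <- summary_stats(c("rs1", "rs2", "rs3"), "A", "G",
                        c(1.5, 0.8, 1.2), c(0.1, 0.2, 0.3))
  sc <- compute_scores(geno, recs)
  w <- log(c(1.5, 0.8, 1.2))
  expect_equal(sc$score,
               c(sum(w * c(0, 1, 2)), sum(w * c(2, 0, 1))) / 3)
  expect_equal(sc$n_snps_used, c(3, 3))

  # all OR = 1: every score is zero
  recs1 <- summary_stats(c("rs1", "rs2", "rs3"), "A", "G", rep(1, 3),
                         c(0.1, 0.2, 0.3))
  expect_equal(compute_scores(geno, recs1)$score, c(0, 0))

  # per-allele divisor halves the per-SNP average
  expect_equal(compute_scores(geno, recs, divisor = "per_allele")$score,
               sc$score / 2)

  # SNP column permutation leaves scores unchanged
  geno_perm <- genotype_matrix(dos[, c(3, 1, 2)], rep("A", 3), rep("G", 3))
  sc_perm <- compute_scores(geno_perm, recs)
  expect_equal(sc_perm$score, sc$score)
})

test_that("missing dosages are mean-imputed or dropped as configured", {
  dos <- rbind(s1 = c(0, 1), s2 = c(2, NA), s3 = c(1, 1))
  colnames(dos) <- c("rs1", "rs2")
  geno <- genotype_matrix(dos, rep("A", 2), rep("G", 2))
  recs <- summary_stats(c("rs1", "rs2"), "A", "G", c(1.4, 1.3),
                        c(0.1, 0.2))
  w <- log(c(1.4, 1.3))
  sc <- compute_scores(geno, recs)  # rs2 mean among called = 1
  expect_equal(sc$score[2], (2 * w[1] + 1 * w[2]) / 2)
  cc <- compute_scores(geno, recs, missing = "complete")
  expect_equal(cc$sample_id, c("s1", "s3"))
})

test_that("flipping labels with OR -> 1/OR leaves score correlations intact", {
  set.seed(37)
  sim <- gen_genotypes_with_trait(geno_sim_spec(n_samples = 300, n_snps = 30,
                                                seed = 37))
  geno <- sim$genotypes
  recs <- sim$records
  sc <- compute_scores(geno, recs)$score
  # flip the first 10 SNPs: swap allele labels, invert OR, complement dosage
  flip <- recs$snp_id[1:10]
  recs2 <- recs
  i <- match(flip, recs2$snp_id)
  tmp <- recs2$effect_allele[i]
  recs2$effect_allele[i] <- recs2$other_allele[i]
  recs2$other_allele[i] <- tmp
  recs2$odds_ratio[i] <- 1 / recs2$odds_ratio[i]
  dos2 <- geno$dosages
  dos2[, flip] <- 2 - dos2[, flip]
  geno2 <- genotype_matrix(dos2,
                           ifelse(geno$snp_ids %in% flip, "G", "A"),
                           ifelse(geno$snp_ids %in% flip, "A", "G"))
  sc2 <- compute_scores(geno2, recs2)$score
  expect_equal(cor(sc, sim$trait), cor(sc2, sim$trait), tolerance = 1e-12)
})

test_that("dosage and VCF readers agree on the same genotypes", {
  dos <- rbind(s1 = c(0, 1), s2 = c(2, 0), s3 = c(1, 2))
  colnames(dos) <- c("rs1", "rs2")
  d_path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rownames(dos), dos,
                                check.names = FALSE),
                     d_path, sep = "\t", quote = FALSE, row.names = FALSE)
  a_path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(snp_id = c("rs1", "rs2"),
                                counted_allele = c("C", "T"),
                                alt_allele = c("A", "G")),
                     a_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g1 <- read_dosage_matrix(d_path, a_path)
  expect_equal(g1$dosages, dos)
  expect_equal(unname(g1$counted_allele), c("C", "T"))

  gt <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  gts <- rbind(names(gt)[dos[, 1] + 1], names(gt)[dos[, 2] + 1])
  vcf_path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    paste(c("1", "100", "rs1", "A", "C", ".", "PASS", ".", "GT", gts[1, ]),
          collapse = "\t"),
    paste(c("1", "200", "rs2", "G", "T", ".", "PASS", ".", "GT", gts[2, ]),
          collapse = "\t")), vcf_path)
  g2 <- read_vcf_genotypes(vcf_path)
  expect_equal(g2$dosages[rownames(dos), colnames(dos)], dos)
  expect_equal(unname(g2$counted_allele), c("C", "T"))
})

test_that("the scoring pipeline recovers a planted score-trait correlation", {
  sim <- gen_genotypes_with_trait(geno_sim_spec(n_samples = 2000,
                                                n_snps = 120, seed = 53))
  out <- polygenic_score_pipeline(sim$genotypes, sim$records,
                                  p_threshold = 1.0)
  r <- cor(out$scores$score, sim$trait[out$scores$sample_id])
  expect_lt(abs(r - 0.22), 3 / sqrt(2000) + 0.02)
})
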