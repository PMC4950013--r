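# Small fixtures built in code at test time.

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deterministic tiny genotype set: 4 samples x 3 SNPs with hand-set dosages
tiny_genotypes <- function() {
  dos <- rbind(s1 = c(0, 1, 2),
               s2 = c(2, 1, 0),
               s3 = c(1, 0, 1),
               s4 = c(2, 2, 2))
  colnames(dos) <- c("rs1", "rs2", "rs3")
  genotype_matrix(dos, counted_allele = c("A", "C", "A"),
                  alt_allele = c("G", "T", "C"))
}

tiny_sumstats <- function() {
  summary_stats(snp_id = c("rs1", "rs2", "rs3"),
                effect_allele = c("A", "C", "A"),
                other_allele = c("G", "T", "C"),
                odds_ratio = c(1.2, 0.8, 1.05),
                p_value = c(0.01, 0.2, 0.45))
}

# integer questionnaire items that carry a continuous trait: k noisy
# indicators on the -1..7 scale, half of them reverse keyed
make_scale_items <- function(trait, k = 8, seed = 99) {
  set.seed(seed)
  z <- as.numeric(scale(trait))
  items <- vapply(seq_len(k), function(j) {
    raw <- round(3 + 1.2 * z + stats::rnorm(length(z), 0, 0.8))
    pmin(pmax(raw, -1), 7)
  }, numeric(length(trait)))
  colnames(items) <- sprintf("ns%02d", seq_len(k))
  rev <- colnames(items)[seq(2, k, by = 2)]
  items[, rev] <- -1 + 7 - items[, rev]   # store them reversed
  list(items = items, reverse_keyed = rev)
}
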