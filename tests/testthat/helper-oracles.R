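# Independent oracles and fixture builders. Everything here is written
# against the published formulas / by brute force, separately from the
# package implementations it checks.

random_gm <- function(n, L, miss = 0.1, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (miss > 0) g[runif(n * L) < miss] <- NA
  geno_matrix(g)
}

# Literal transcription of the Weir & Cockerham (1984) per-locus variance
# components, loop form, pairwise deletion.
naive_wc_locus <- function(geno, pops) {
  pops <- factor(pops)
  keep <- !is.na(geno)
  geno <- geno[keep]
  pops <- droplevels(pops[keep])
  r <- nlevels(pops)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  ni <- as.numeric(table(pops))
  pi <- tapply(geno, pops, function(g) sum(g) / (2 * length(g)))
  hi <- tapply(geno, pops, function(g) mean(g == 1))
  nbar <- mean(ni)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi) / sum(ni)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

naive_multilocus_theta <- function(gm, pops) {
  comp <- sapply(seq_len(n_loci(gm)), function(j) {
    naive_wc_locus(gm$genotypes[, j], pops)
  })
  ok <- colSums(is.na(comp)) == 0
  sum(comp["a", ok]) / sum(comp[, ok])
}

# Effect-class oracle: translate the whole ORF before and after the
# substitution with Biostrings and compare amino-acid strings.
translate_classify <- function(seq, orf_start, orf_end, pos, alt) {
  if (pos < orf_start || pos >= orf_end) return("oCDS")
  orf <- substr(seq, orf_start + 1, orf_end)
  mut_seq <- seq
  substr(mut_seq, pos + 1, pos + 1) <- alt
  orf_mut <- substr(mut_seq, orf_start + 1, orf_end)
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(orf_mut),
                                               no.init.codon = TRUE))
  if (aa_ref == aa_alt) return("synonymous")
  idx <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  ref_aa <- substr(aa_ref, idx, idx)
  alt_aa <- substr(aa_alt, idx, idx)
  if (ref_aa == "*" || alt_aa == "*") return("nonsense")
  "nonsynonymous"
}

# Exact one-tailed Wilcoxon p by enumeration: probability, over all
# C(m, n1) placements of the kN labels on ranks 1..m, that the kN rank sum
# is <= the observed one.
enum_wilcoxon_p <- function(lab) {
  m <- length(lab)
  n1 <- sum(lab)
  obs <- sum(seq_len(m)[lab])
  combos <- utils::combn(m, n1)
  mean(colSums(matrix(seq_len(m)[combos], nrow = n1)) <= obs)
}

impute_mean_for_test <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

# Minimal VCF text fixture writer.
write_vcf_text <- function(path, records, samples = c("s1", "s2", "s3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP4,Number=4,Type=Integer,Description="d">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
}
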