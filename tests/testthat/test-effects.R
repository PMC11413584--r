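test_that("predict_orfs finds ATG-to-stop spans with 0-based half-open ends", {
  orfs <- predict_orfs(c(tx = "AAAATGGCTGGTTAAAAA"), min_codons = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$orf_start, 3L)
  expect_equal(orfs$orf_end, 15L)      # includes the TAA stop codon
  expect_equal(orfs$n_codons, 3L)      # ATG GCT GGT

  expect_equal(nrow(predict_orfs(c(tx = "AAACCCGGGTTT"), min_codons = 1)), 0)
  expect_equal(nrow(predict_orfs(c(tx = "AT"))), 0)
})

test_that("single-ORF filtering drops exactly the multi-ORF transcripts", {
  tr <- simulate_transcriptome(20, cds_len_codons = 105, utr_len = 20,
                               snp_plan = c(synonymous = 2), seed = 5)
  tx <- tr$transcripts
  # append a second long ORF to 5 transcripts
  extra <- paste(c("ATG", rep("GCT", 104), "TAA"), collapse = "")
  for (i in 1:5) tx[i] <- paste0(tx[i], extra)
  orfs <- predict_orfs(tx, min_codons = 100)
  res <- filter_single_orf(tx, orfs)
  expect_equal(res$n_multi_orf, 5)
  expect_equal(length(res$transcripts), 15)
  expect_setequal(names(res$transcripts), names(tx)[6:20])
})

test_that("classify_snp handles the canonical codon cases", {
  # transcript: UTR(3) + ATG GCT TAC TAA + UTR(3)
  seq <- paste0("AAA", "ATG", "GCT", "TAC", "TAA", "CCC")
  orf <- tibble::tibble(orf_start = 3, orf_end = 15)
  # GCT -> GCA (third position T>A): Ala -> Ala
  expect_equal(classify_snp(seq, orf, 8, "T", "A"), "synonymous")
  # GCT -> GTT (second position C>T): Ala -> Val
  expect_equal(classify_snp(seq, orf, 7, "C", "T"), "nonsynonymous")
  # TAC -> TAA: Tyr -> stop
  expect_equal(classify_snp(seq, orf, 11, "C", "A"), "nonsense")
  # stop loss TAA -> CAA
  expect_equal(classify_snp(seq, orf, 12, "T", "C"), "nonsense")
  # stop-to-stop TAA -> TAG is synonymous by convention
  expect_equal(classify_snp(seq, orf, 14, "A", "G"), "synonymous")
  # UTR positions
  expect_equal(classify_snp(seq, orf, 1, "A", "G"), "oCDS")
  expect_equal(classify_snp(seq, orf, 16, "C", "T"), "oCDS")
  # errors
  expect_error(classify_snp(seq, orf, 8, "G", "A"), "mismatch")
  expect_error(classify_snp(seq, orf, 8, "T", "N"), "ambiguous")
})

test_that("classification matches exhaustive enumeration over all sense codons", {
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  n_checked <- 0
  for (codon in sense) {
    seq <- paste0("AA", "ATG", codon, "TAA", "GG")
    orf <- tibble::tibble(orf_start = 2, orf_end = 11)
    for (pos_in in 0:2) {
      ref <- substr(codon, pos_in + 1, pos_in + 1)
      for (alt in setdiff(bases, ref)) {
        ours <- classify_snp(seq, orf, 5 + pos_in, ref, alt)
        # oracle: amino-acid comparison via the code table, written out
        mut <- codon
        substr(mut, pos_in + 1, pos_in + 1) <- alt
        expected <- if (code[codon] == code[mut]) "synonymous"
          else if (code[mut] == "*") "nonsense"
          else "nonsynonymous"
        expect_identical(ours, expected,
                         info = paste(codon, pos_in, alt))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, length(sense) * 9)  # 61 x 3 x 3
})

test_that("classification agrees with whole-ORF translation on planted SNPs", {
  tr <- simulate_transcriptome(
    20, cds_len_codons = 105, utr_len = 25,
    snp_plan = c(synonymous = 60, nonsynonymous = 60, nonsense = 30,
                 utr = 50),
    seed = 13
  )
  orfs <- predict_orfs(tr$transcripts, min_codons = 100)
  single <- filter_single_orf(tr$transcripts, orfs)
  cls <- classify_snps(tr$snps, single$transcripts, single$orfs)
  oracle <- vapply(seq_len(nrow(cls)), function(i) {
    tx <- cls$transcript_id[i]
    o <- orfs[orfs$transcript_id == tx, ]
    translate_classify(tr$transcripts[[tx]], o$orf_start, o$orf_end,
                       cls$pos[i], cls$alt[i])
  }, character(1))
  expect_identical(cls$class, oracle)
})

test_that("effect counts and the kN/kS ratio follow the tally rules", {
  counts <- count_effects(rep(c("nonsynonymous", "synonymous"), c(37, 266)))
  expect_equal(counts$ratio, 0.139)
  expect_equal(counts$cds_total, 303)

  zero <- count_effects(rep("synonymous", 10))
  expect_equal(zero$ratio, 0)
  no_syn <- count_effects(rep("nonsynonymous", 5))
  expect_true(is.na(no_syn$ratio))

  mixed <- count_effects(c("nonsynonymous", "nonsense", "synonymous",
                           "oCDS", "synonymous"))
  expect_equal(mixed$kN, 1)          # nonsense excluded from kN
  expect_equal(mixed$nonsense, 1)
  expect_equal(mixed$cds_total, 4)   # kN + kS + nonsense
  expect_error(count_effects("frameshift"), "unknown effect class")
})

test_that("kN/kS chi-square matches the hand formula and is row-symmetric", {
  a <- tibble::tibble(kN = 37, kS = 266)
  expect_equal(compare_knks(a, a)$chi2, 0)
  expect_equal(compare_knks(a, a)$p_value, 1)

  x <- tibble::tibble(kN = 50, kS = 50)
  y <- tibble::tibble(kN = 10, kS = 90)
  res <- compare_knks(x, y)
  # direct evaluation of sum (O-E)^2 / E on the 2x2 table
  O <- matrix(c(50, 10, 50, 90), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$chi2, 800 / 21, tolerance = 1e-12)  # = 38.095
  expect_equal(res$df, 1)
  expect_equal(compare_knks(y, x)$chi2, res$chi2, tolerance = 1e-12)

  z <- tibble::tibble(kN = 0, kS = 0)
  expect_error(compare_knks(z, y), "zero margin")
})
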