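GENCODE <- Biostrings::GENETIC_CODE  # standard code; stops translate to "*"

codon_aa <- function(codon) {
  aa <- GENCODE[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

#' Predict open reading frames on transcripts
#'
#' Scans the three forward frames of each transcript for ATG-to-stop spans:
#' within a frame, each stop codon closes the ORF opened by the leftmost ATG
#' since the previous stop. Spans with at least `min_codons` codons between
#' the ATG and the stop (the translated protein length, Met included) are
#' reported, longest first. Coordinates are 0-based half-open and include
#' the stop codon.
#'
#' @param transcripts Named character vector of transcript sequences (a
#'   single unnamed sequence is accepted).
#' @param min_codons Minimum protein length in codons (default 100, a common
#'   ORF-prediction default).
#' @return A tibble: `transcript_id`, `orf_start`, `orf_end`, `frame`,
#'   `n_codons`.
#' @export
#' @examples
#' predict_orfs(c(tx = "AAAATGGCTGGTTAAAAA"), min_codons = 2)
predict_orfs <- function(transcripts, min_codons = 100) {
  if (is.null(names(transcripts))) {
    names(transcripts) <- if (length(transcripts) == 1) "transcript" else
      paste0("tx", seq_along(transcripts))
  }
  stops <- c("TAA", "TAG", "TGA")
  one <- function(id, s) {
    n <- nchar(s)
    if (n < 3) return(NULL)
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    res <- list()
    for (fr in 0:2) {
      if (n - fr < 3) next
      starts <- seq(fr + 1, n - 2, by = 3)
      codons <- paste0(ch[starts], ch[starts + 1], ch[starts + 2])
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open) && codons[i] == "ATG") open <- i
        if (!is.na(open) && codons[i] %in% stops) {
          len <- i - open   # protein length: ATG .. codon before stop
          if (len >= min_codons) {
            res[[length(res) + 1]] <- tibble::tibble(
              transcript_id = id,
              orf_start = starts[open] - 1L,
              orf_end = starts[i] + 2L,
              frame = fr,
              n_codons = len
            )
          }
          open <- NA_integer_
        }
      }
    }
    if (length(res)) dplyr::bind_rows(res) else NULL
  }
  out <- purrr::map2(names(transcripts), unname(transcripts), one) |>
    dplyr::bind_rows()
  if (!nrow(out)) {
    return(tibble::tibble(transcript_id = character(), orf_start = integer(),
                          orf_end = integer(), frame = integer(),
                          n_codons = integer()))
  }
  dplyr::arrange(out, dplyr::desc(.data$n_codons), .data$transcript_id)
}

#' Keep transcripts with exactly one predicted ORF
#'
#' Multi-ORF transcripts would make SNP effect annotation ambiguous and are
#' dropped; transcripts with zero predicted ORFs are also excluded from the
#' effect-classification universe (their SNPs cannot be classified against a
#' CDS) and counted.
#'
#' @param transcripts Named character vector of sequences.
#' @param orfs ORF tibble as returned by [predict_orfs()].
#' @return A list: `transcripts` (retained), `orfs` (their single ORFs),
#'   `n_multi_orf`, `n_zero_orf`.
#' @export
filter_single_orf <- function(transcripts, orfs) {
  cnt <- table(factor(orfs$transcript_id, levels = names(transcripts)))
  keep <- names(cnt)[cnt == 1]
  n_multi <- sum(cnt > 1)
  n_zero <- sum(cnt == 0)
  if (n_zero > 0) {
    rlang::inform(sprintf(
      "filter_single_orf: %d transcript(s) without a predicted ORF excluded",
      n_zero))
  }
  list(
    transcripts = transcripts[keep],
    orfs = orfs[orfs$transcript_id %in% keep, , drop = FALSE],
    n_multi_orf = n_multi,
    n_zero_orf = n_zero
  )
}

#' Classify a transcript SNP by its coding effect
#'
#' Positions outside the ORF (0-based half-open, stop codon included) are
#' `oCDS` (untranslated region of a coding transcript). Inside the ORF the
#' alternate base is substituted into its codon: same amino acid is
#' `synonymous`, a sense-to-stop or stop-to-sense change is `nonsense`
#' (stop-gain/stop-loss, tallied separately from kN), and a sense-to-sense
#' amino-acid change is `nonsynonymous`. Standard genetic code;
#' stop-to-stop changes are synonymous.
#'
#' @param transcript_seq The transcript sequence (A/C/G/T).
#' @param orf One-row ORF annotation (`orf_start`, `orf_end`) for the
#'   transcript.
#' @param pos 0-based SNP position within the transcript.
#' @param ref,alt Reference and alternate bases; `transcript_seq[pos]` must
#'   equal `ref`.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`, `"oCDS"`.
#' @export
#' @examples
#' classify_snp("AAAATGGCTGGTTAAAAA",
#'              tibble::tibble(orf_start = 3, orf_end = 15), 8, "T", "A")
classify_snp <- function(transcript_seq, orf, pos, ref, alt) {
  base_at <- substr(transcript_seq, pos + 1, pos + 1)
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
    rlang::abort(sprintf("ambiguous base in SNP at position %d (%s>%s)",
                         pos, ref, alt))
  }
  if (base_at != ref) {
    rlang::abort(sprintf(
      "reference mismatch at position %d: transcript has %s, SNP claims %s",
      pos, base_at, ref))
  }
  if (alt == ref) rlang::abort("alt allele equals ref")
  start <- orf$orf_start[[1]]
  end <- orf$orf_end[[1]]
  if (pos < start || pos >= end) return("oCDS")
  codon_idx <- (pos - start) %/% 3
  within <- (pos - start) %% 3
  cstart <- start + 3 * codon_idx
  codon <- substr(transcript_seq, cstart + 1, cstart + 3)
  alt_codon <- codon
  substr(alt_codon, within + 1, within + 1) <- alt
  aa_ref <- codon_aa(codon)
  aa_alt <- codon_aa(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) {
    rlang::abort(sprintf("ambiguous codon at position %d", pos))
  }
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_ref == "*" || aa_alt == "*") return("nonsense")
  "nonsynonymous"
}

#' Classify a table of transcript SNPs
#'
#' Vectorized driver over [classify_snp()]: SNPs on transcripts absent from
#' the retained single-ORF set are dropped with a count (they have no CDS
#' reference to classify against).
#'
#' @param snps Tibble with `locus_id`, `transcript_id`, `pos`, `ref`, `alt`.
#' @param transcripts Named character vector of retained transcripts.
#' @param orfs Their ORF annotations (one row per transcript).
#' @return The `snps` tibble restricted to classifiable SNPs, with a `class`
#'   column appended; attribute `n_unclassifiable` counts dropped SNPs.
#' @export
classify_snps <- function(snps, transcripts, orfs) {
  ok <- snps$transcript_id %in% names(transcripts) &
    snps$transcript_id %in% orfs$transcript_id
  n_un <- sum(!ok)
  if (n_un > 0) {
    rlang::inform(sprintf(
      "classify_snps: %d SNP(s) on transcripts without a single retained ORF dropped",
      n_un))
  }
  snps <- snps[ok, , drop = FALSE]
  cls <- vapply(seq_len(nrow(snps)), function(i) {
    tx <- snps$transcript_id[i]
    classify_snp(transcripts[[tx]],
                 orfs[orfs$transcript_id == tx, , drop = FALSE],
                 snps$pos[i], snps$ref[i], snps$alt[i])
  }, character(1))
  out <- dplyr::mutate(snps, class = cls)
  attr(out, "n_unclassifiable") <- n_un
  out
}

#' Tally SNP effect classes and the kN/kS count ratio
#'
#' `kN` counts non-synonymous SNPs excluding premature-stop (nonsense)
#' variants, which are tallied separately; `kS` counts synonymous SNPs;
#' `oCDS` counts UTR SNPs. The ratio is the plain count ratio `kN / kS`
#' (not a site-normalized rate), `NA` when `kS = 0`.
#'
#' @param classified Tibble with a `class` column
#'   (output of [classify_snps()]), or a character vector of classes.
#' @param digits Rounding for the reported ratio (default 3).
#' @return A one-row tibble: `kN`, `kS`, `nonsense`, `oCDS`, `cds_total`,
#'   `ratio`.
#' @export
#' @examples
#' count_effects(rep(c("nonsynonymous", "synonymous"), c(37, 266)))
count_effects <- function(classified, digits = 3) {
  cls <- if (is.data.frame(classified)) classified$class else classified
  valid <- c("synonymous", "nonsynonymous", "nonsense", "oCDS")
  bad <- setdiff(unique(cls), valid)
  if (length(bad)) {
    rlang::abort(paste("unknown effect class:", paste(bad, collapse = ", ")))
  }
  kN <- sum(cls == "nonsynonymous")
  kS <- sum(cls == "synonymous")
  non <- sum(cls == "nonsense")
  ocds <- sum(cls == "oCDS")
  tibble::tibble(
    kN = kN, kS = kS, nonsense = non, oCDS = ocds,
    cds_total = kN + kS + non,
    ratio = if (kS > 0) round(kN / kS, digits) else NA_real_
  )
}

#' Chi-square comparison of kN/kS proportions between SNP sets
#'
#' Pearson's chi-square (no continuity correction by default) on the 2x2
#' table `[adaptive, neutral] x [kN, kS]`. All margins must be positive.
#'
#' @param adaptive,neutral One-row tibbles from [count_effects()].
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return A one-row tibble: `chi2`, `df`, `p_value`.
#' @export
compare_knks <- function(adaptive, neutral, correct = FALSE) {
  tab <- rbind(adaptive = c(kN = adaptive$kN, kS = adaptive$kS),
               neutral = c(kN = neutral$kN, kS = neutral$kS))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("zero margin in kN/kS table; use an exact test instead")
  }
  ct <- stats::chisq.test(tab, correct = correct)
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}
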