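#' Read a VCF file into a genotype matrix
#'
#' Reads a VCF v4.x file (plain or bgzipped) and converts the GT field into a
#' samples-by-loci integer matrix of alternate-allele counts. Only biallelic
#' SNP records are kept: indels are skipped and multiallelic sites dropped,
#' each with a logged count. `QUAL` and, when present, the `INFO/DP4` key
#' (alternate-allele forward + reverse read support) are captured into the
#' per-locus QC columns used by [filter_rna_variants()].
#'
#' Positions are 1-based on disk (VCF convention) and stored 0-based in the
#' `pos` column of the locus table, with `CHROM` kept as `transcript_id` so
#' transcript-coordinate loci retain their source.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) rlang::abort(paste("no such VCF:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(geno_matrix(
      matrix(integer(), nrow = max(0L, ncol(v@gt) - 1L), ncol = 0,
             dimnames = list(colnames(v@gt)[-1], NULL)),
      tibble::tibble(locus_id = character(), ref = character(),
                     alt = character(), transcript_id = character(),
                     pos = integer(), qual = double(), dp4 = double())
    ))
  }
  ref <- fix$REF
  alt <- fix$ALT
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_indel <- !is_multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(is_indel)) {
    rlang::inform(sprintf("read_vcf: skipped %d non-SNP (indel) record(s)",
                          sum(is_indel)))
  }
  if (any(is_multi)) {
    rlang::warn(sprintf("read_vcf: dropped %d multiallelic record(s)",
                        sum(is_multi)))
  }
  keep <- !is_multi & !is_indel
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- v@gt[keep, -1, drop = FALSE]

  ids <- fix$ID
  fallback <- paste0(fix$CHROM, "_", fix$POS)
  ids[is.na(ids) | ids == "."] <- fallback[is.na(ids) | ids == "."]

  gt_field <- sub(":.*$", "", gt_raw)
  code <- matrix(NA_integer_, nrow = nrow(gt_field), ncol = ncol(gt_field))
  code[gt_field %in% c("0/0", "0|0")] <- 0L
  code[gt_field %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt_field %in% c("1/1", "1|1")] <- 2L
  g <- t(code)
  rownames(g) <- colnames(gt_raw)

  dp4 <- rep(NA_real_, nrow(fix))
  has_info <- !is.na(fix$INFO) & grepl("DP4=", fix$INFO, fixed = TRUE)
  if (any(has_info)) {
    raw <- sub(".*DP4=([0-9,]+).*", "\\1", fix$INFO[has_info])
    dp4[has_info] <- vapply(strsplit(raw, ","), function(z) {
      z <- as.numeric(z)
      if (length(z) >= 4) z[3] + z[4] else sum(z)
    }, numeric(1))
  }
  loci <- tibble::tibble(
    locus_id = ids,
    ref = fix$REF,
    alt = fix$ALT,
    transcript_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    dp4 = dp4
  )
  geno_matrix(g, loci)
}

#' Write a genotype matrix as a plain-text VCF v4.2 file
#'
#' The inverse of [read_vcf()] at the genotype level:
#' `read_vcf(write_vcf(gm, f))` reproduces genotypes, locus ids and ref/alt
#' alleles exactly. Internal 0-based positions are written 1-based; loci with
#' no transcript source are written with `CHROM = locus_id`, `POS = 1`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  lt <- gm$loci
  g <- gm$genotypes
  chrom <- if ("transcript_id" %in% names(lt)) lt$transcript_id else lt$locus_id
  chrom[is.na(chrom)] <- lt$locus_id[is.na(chrom)]
  pos1 <- if ("pos" %in% names(lt)) lt$pos + 1L else rep(1L, nrow(lt))
  pos1[is.na(pos1)] <- 1L
  qual <- if ("qual" %in% names(lt)) lt$qual else rep(NA_real_, nrow(lt))
  dp4 <- if ("dp4" %in% names(lt)) lt$dp4 else rep(NA_real_, nrow(lt))
  info <- ifelse(is.na(dp4), ".", sprintf("DP4=0,0,%d,0", as.integer(dp4)))
  qual_s <- ifelse(is.na(qual), ".", format(qual, trim = TRUE, scientific = FALSE))

  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$genotypes + 1L],
                   nrow = nrow(g), ncol = ncol(g))
  gt_str[is.na(g)] <- "./."

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=seaselect",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref fwd, ref rev, alt fwd, alt rev read counts\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  )
  body <- if (nrow(lt)) {
    fixed <- cbind(chrom, pos1, lt$locus_id, lt$ref, lt$alt, qual_s, ".", info, "GT")
    apply(cbind(fixed, t(gt_str)), 1, paste, collapse = "\t")
  } else character()
  con <- file(path, "w")
  on.exit(close(con))
  ok <- tryCatch({ writeLines(c(header, body), con); TRUE },
                 error = function(e) FALSE)
  if (!ok) rlang::abort(paste("failed to write VCF:", path))
  invisible(path)
}

#' Read the sample map, environmental table and optional ORF table
#'
#' @description
#' Readers for the three tabular inputs:
#' * `read_sample_map()`: TSV with columns `sample_id`, `locality`, `region`
#'   and optional `transect_m`. Every locality must map to exactly one region.
#' * `read_env_table()`: CSV with a `locality` column and numeric predictor
#'   columns, one row per locality.
#' * `read_orf_table()`: TSV with `transcript_id`, `orf_start`, `orf_end`
#'   (0-based half-open) and `frame`.
#'
#' `read_tables()` bundles them and cross-checks that every locality in the
#' sample map has a row in the environmental table.
#'
#' @param path Path to the file.
#' @return A tibble (validated).
#' @export
read_sample_map <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                           stringsAsFactors = FALSE))
  need <- setdiff(c("sample_id", "locality", "region"), names(x))
  if (length(need)) rlang::abort(paste("sample map missing columns:",
                                       paste(need, collapse = ", ")))
  if (anyDuplicated(x$sample_id)) rlang::abort("duplicate sample_id in sample map")
  bad <- x |>
    dplyr::distinct(.data$locality, .data$region) |>
    dplyr::count(.data$locality) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad)) {
    rlang::abort(paste("locality mapped to more than one region:",
                       paste(bad$locality, collapse = ", ")))
  }
  x
}

#' @rdname read_sample_map
#' @export
read_env_table <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                         stringsAsFactors = FALSE))
  if (!"locality" %in% names(x)) rlang::abort("env table needs a 'locality' column")
  if (anyDuplicated(x$locality)) rlang::abort("duplicate locality row in env table")
  num <- x |> dplyr::select(-"locality")
  if (!all(vapply(num, is.numeric, logical(1)))) {
    rlang::abort("all env predictors must be numeric")
  }
  if (any(!is.finite(as.matrix(num)))) rlang::abort("non-finite env predictor value")
  x
}

#' @rdname read_sample_map
#' @export
read_orf_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- setdiff(c("transcript_id", "orf_start", "orf_end"), names(x))
  if (length(need)) rlang::abort(paste("ORF table missing columns:",
                                       paste(need, collapse = ", ")))
  x
}

#' @rdname read_sample_map
#' @param sample_map_path,env_path,orf_path Paths; `orf_path` may be `NULL`.
#' @return For `read_tables()`, a list with `samples`, `env` and `orfs`
#'   (`NULL` when no ORF path given).
#' @export
read_tables <- function(sample_map_path, env_path, orf_path = NULL) {
  samples <- read_sample_map(sample_map_path)
  env <- read_env_table(env_path)
  missing_loc <- setdiff(samples$locality, env$locality)
  if (length(missing_loc)) {
    rlang::abort(paste("localities absent from env table:",
                       paste(missing_loc, collapse = ", ")))
  }
  orfs <- if (!is.null(orf_path)) read_orf_table(orf_path) else NULL
  list(samples = samples, env = env, orfs = orfs)
}

#' Read / write transcript sequences (FASTA)
#'
#' Thin wrappers over Biostrings keeping the `TranscriptSet` contract: unique
#' ids, non-empty A/C/G/T/N sequences.
#'
#' @param path FASTA path.
#' @return A named character vector of transcript sequences.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) rlang::abort("duplicate transcript ids in FASTA")
  seqs <- as.character(x)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) rlang::abort("empty transcript sequence in FASTA")
  seqs
}

#' @rdname read_transcripts
#' @param transcripts Named character vector of sequences.
#' @export
write_transcripts <- function(transcripts, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(transcripts), path, width = 70
  )
  invisible(path)
}
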