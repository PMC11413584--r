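#' Samples-by-loci genotype matrix
#'
#' The central container of the package: an integer matrix of biallelic
#' genotype calls (0/1/2 = count of the alternate allele, `NA` = missing)
#' with per-locus metadata. All downstream statistics consume this object;
#' results come back as tibbles.
#'
#' @param genotypes Integer matrix, samples in rows, loci in columns. Values
#'   must be 0, 1, 2 or `NA` (the missing sentinel; it never enters
#'   arithmetic).
#' @param loci A data frame with one row per locus: `locus_id` (unique),
#'   `ref`, `alt` (single nucleotides), and optionally `transcript_id` and
#'   `pos` (0-based position within the transcript), `qual` (phred-scaled
#'   variant quality) and `dp4` (alternate-allele read support). If `NULL`,
#'   minimal metadata is fabricated from column names.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `genotypes` (the integer matrix, dimnames set), and `loci` (tibble).
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("L1", "L2"))))
#' n_loci(g)
geno_matrix <- function(genotypes, loci = NULL, sample_ids = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  if (is.null(loci)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("L", seq_len(ncol(genotypes)))
    loci <- tibble::tibble(locus_id = ids, ref = "A", alt = "T")
  }
  loci <- tibble::as_tibble(loci)
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- loci$locus_id
  out <- structure(list(genotypes = genotypes, loci = loci),
                   class = "geno_matrix")
  validate_geno_matrix(out)
}

validate_geno_matrix <- function(x) {
  g <- x$genotypes
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) {
    rlang::abort("genotype values must be 0, 1, 2 or NA (missing)")
  }
  if (anyDuplicated(rownames(g))) rlang::abort("duplicate sample ids")
  if (anyDuplicated(x$loci$locus_id)) rlang::abort("duplicate locus ids")
  if (nrow(x$loci) != ncol(g)) {
    rlang::abort("loci table and genotype columns disagree in length")
  }
  need <- setdiff(c("locus_id", "ref", "alt"), names(x$loci))
  if (length(need)) {
    rlang::abort(paste("loci table missing columns:", paste(need, collapse = ", ")))
  }
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  g <- x$genotypes
  miss <- mean(is.na(g))
  cat(sprintf("<geno_matrix> %d samples x %d loci (%.1f%% missing)\n",
              nrow(g), ncol(g), 100 * miss))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) nrow(x$genotypes)

#' @rdname geno_matrix
#' @export
n_loci <- function(x) ncol(x$genotypes)

#' @rdname geno_matrix
#' @export
locus_ids <- function(x) x$loci$locus_id

#' @rdname geno_matrix
#' @export
sample_ids <- function(x) rownames(x$genotypes)

#' Subset a genotype matrix by loci and/or samples
#'
#' @param x A `geno_matrix`.
#' @param loci Locus ids or a logical/integer index over loci.
#' @param samples Sample ids or a logical/integer index over samples.
#' @return A `geno_matrix` restricted to the selection, metadata kept in sync.
#' @export
subset_geno <- function(x, loci = NULL, samples = NULL) {
  g <- x$genotypes
  lt <- x$loci
  if (!is.null(loci)) {
    j <- if (is.character(loci)) match(loci, lt$locus_id) else seq_len(ncol(g))[loci]
    if (anyNA(j)) rlang::abort("unknown locus id in subset")
    g <- g[, j, drop = FALSE]
    lt <- lt[j, , drop = FALSE]
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, rownames(x$genotypes)) else seq_len(nrow(g))[samples]
    if (anyNA(i)) rlang::abort("unknown sample id in subset")
    g <- g[i, , drop = FALSE]
  }
  geno_matrix(g, lt)
}

#' Convert a genotype matrix to a long tibble
#'
#' One row per (sample, locus) call; missing calls are `NA`. Convenient for
#' dplyr/ggplot2 work on small matrices.
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `locus_id`, `genotype`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  g <- x$genotypes
  tibble::tibble(
    sample_id = rep(rownames(g), times = ncol(g)),
    locus_id = rep(colnames(g), each = nrow(g)),
    genotype = as.integer(g)
  )
}

#' One-line summary of a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: sample/locus counts, missing fraction, mean MAF.
#' @export
glance.geno_matrix <- function(x, ...) {
  g <- x$genotypes
  tibble::tibble(
    n_samples = nrow(g),
    n_loci = ncol(g),
    missing_frac = mean(is.na(g)),
    mean_maf = mean(locus_maf(g), na.rm = TRUE)
  )
}

# Per-locus alternate allele frequency on non-missing gene copies.
locus_alt_freq <- function(g) {
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  ifelse(called > 0, alt / (2 * called), NA_real_)
}

# Per-locus minor allele frequency: min(p, 1 - p).
locus_maf <- function(g) {
  p <- locus_alt_freq(g)
  pmin(p, 1 - p)
}

# Mean-impute missing calls per locus (common ordination practice); loci with
# no calls at all become 0 after centering.
impute_mean <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

# Validate a population/locality factor against a geno_matrix; returns a
# factor aligned with samples.
align_pops <- function(x, pops) {
  if (is.data.frame(pops)) {
    m <- match(sample_ids(x), pops$sample_id)
    if (anyNA(m)) {
      rlang::abort(paste("samples missing from metadata:",
                         paste(sample_ids(x)[is.na(m)], collapse = ", ")))
    }
    pops <- pops$locality[m]
  }
  if (length(pops) != n_samples(x)) {
    rlang::abort("population labels and samples differ in length")
  }
  factor(pops)
}
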