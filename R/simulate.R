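#' Simulation parameters for synthetic genotype data
#'
#' Bundles the knobs of the Balding–Nichols genotype simulator. Defaults
#' describe the reference synthetic study design used throughout the package:
#' 8 localities of 30 diploid individuals, 1,000 biallelic loci of which 20
#' are adaptive with a logit-scale effect of 2 per SD of their driving
#' predictor, differentiation F = 0.10 and 5% uniformly missing calls.
#'
#' @param n_pops Number of populations (localities).
#' @param n_per_pop Diploid individuals per population.
#' @param n_loci Total biallelic loci.
#' @param F Balding–Nichols differentiation parameter in (0, 1); the analytic
#'   FST target of the neutral loci.
#' @param ancestral_freq_range Range of the Uniform ancestral allele frequency.
#' @param n_adaptive Number of environment-linked loci (`<= n_loci`).
#' @param beta Logit-scale effect size per standard deviation of the driving
#'   predictor at adaptive loci.
#' @param missing_rate Probability a call is missing (uniform, MCAR).
#' @param seed Integer seed; all outputs are pure functions of (params, seed).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 8, n_per_pop = 30, n_loci = 1000,
                       F = 0.10, ancestral_freq_range = c(0.1, 0.9),
                       n_adaptive = 20, beta = 2, missing_rate = 0.05,
                       seed = 1L) {
  stopifnot(F > 0, F < 1, n_adaptive <= n_loci, missing_rate >= 0,
            missing_rate < 1, length(ancestral_freq_range) == 2)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate environmental predictors per locality
#'
#' Draws one multivariate-normal row per locality with the requested
#' predictor correlation structure. Defaults mirror the ten seascape
#' predictors retained after collinearity pruning in typical coastal studies
#' (longitude, latitude, precipitation, temperature range, chlorophyll, pH,
#' salinity, SST range, current-velocity range).
#'
#' @param n_pops Number of localities.
#' @param predictor_names Character vector of predictor names.
#' @param env_corr Correlation matrix among predictors (symmetric PSD);
#'   identity by default.
#' @param seed Integer seed.
#' @return A tibble: `locality` plus one numeric column per predictor.
#' @export
#' @examples
#' simulate_env(4, c("pH", "Salinity"), seed = 1)
simulate_env <- function(n_pops,
                         predictor_names = c("Long", "Lat", "AnnPrec",
                                             "PrecWett", "TempAnnRang",
                                             "ChloMean", "pH", "Salinity",
                                             "Sstrange", "Curvssrange"),
                         env_corr = NULL, seed = 1L) {
  p <- length(predictor_names)
  if (is.null(env_corr)) env_corr <- diag(p)
  env_corr <- as.matrix(env_corr)
  if (!isSymmetric(unname(env_corr), tol = 1e-8)) {
    rlang::abort("env_corr must be symmetric")
  }
  ev <- eigen(env_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) rlang::abort("env_corr must be positive semi-definite")
  set.seed(seed)
  x <- MASS::mvrnorm(n_pops, mu = rep(0, p), Sigma = env_corr)
  x <- matrix(x, nrow = n_pops, dimnames = list(NULL, predictor_names))
  dplyr::bind_cols(
    tibble::tibble(locality = sprintf("P%02d", seq_len(n_pops))),
    tibble::as_tibble(x)
  )
}

#' Simulate multi-population biallelic genotypes with planted adaptive loci
#'
#' Neutral loci follow the Balding–Nichols model: an ancestral frequency
#' `p ~ Uniform(range)` and population frequencies
#' `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the loci have analytic FST = F.
#' Each adaptive locus is tied to one environmental predictor and its
#' population frequencies are shifted on the logit scale:
#' `logit(p_k) = logit(p) + beta * z_k` with `z` the standardized predictor.
#' Genotypes are `Binomial(2, p_k)` per individual (Hardy–Weinberg within
#' populations); missing calls are planted uniformly at `missing_rate`.
#' Frequencies that leave (0, 1) are clamped to [0.001, 0.999] and counted.
#'
#' @param params A [sim_params()] object.
#' @param env Environment tibble from [simulate_env()] with
#'   `params$n_pops` rows; adaptive loci are assigned predictors round-robin.
#' @param adaptive_idx Optional integer vector forcing which loci are
#'   adaptive (length `params$n_adaptive`); by default drawn at random.
#' @return A list: `gm` (the [geno_matrix()], samples named
#'   `<locality>_<i>`), `samples` (sample metadata tibble with `locality` and
#'   `region`), and `truth` (list: `adaptive_locus_ids`, `ancestral_freq`,
#'   `pop_freqs` matrix, `adaptive_predictor`, `n_clamped`, `seed`).
#' @export
simulate_genotypes <- function(params, env = NULL, adaptive_idx = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(env)) {
    env <- simulate_env(params$n_pops, seed = params$seed + 1L)
  }
  if (nrow(env) != params$n_pops) {
    rlang::abort("env must have one row per population")
  }
  set.seed(params$seed)
  np <- params$n_pops
  L <- params$n_loci
  n_ind <- np * params$n_per_pop
  Fst <- params$F

  anc <- stats::runif(L, params$ancestral_freq_range[1],
                      params$ancestral_freq_range[2])
  shape1 <- anc * (1 - Fst) / Fst
  shape2 <- (1 - anc) * (1 - Fst) / Fst
  pop_freqs <- matrix(stats::rbeta(np * L, rep(shape1, each = np),
                                   rep(shape2, each = np)),
                      nrow = np, ncol = L)

  if (is.null(adaptive_idx)) {
    adaptive_idx <- if (params$n_adaptive > 0) {
      sort(sample.int(L, params$n_adaptive))
    } else integer()
  } else {
    stopifnot(length(adaptive_idx) == params$n_adaptive,
              all(adaptive_idx >= 1), all(adaptive_idx <= L))
    adaptive_idx <- sort(as.integer(adaptive_idx))
  }
  pred_cols <- setdiff(names(env), "locality")
  adaptive_predictor <- character(0)
  n_clamped <- 0L
  if (length(adaptive_idx)) {
    adaptive_predictor <- pred_cols[(seq_along(adaptive_idx) - 1) %%
                                      length(pred_cols) + 1]
    for (i in seq_along(adaptive_idx)) {
      l <- adaptive_idx[i]
      z <- as.numeric(scale(env[[adaptive_predictor[i]]]))
      lp <- stats::qlogis(anc[l]) + params$beta * z
      pk <- stats::plogis(lp)
      out_of_range <- pk < 0.001 | pk > 0.999
      n_clamped <- n_clamped + sum(out_of_range)
      pop_freqs[, l] <- pmin(pmax(pk, 0.001), 0.999)
    }
    if (n_clamped > 0) {
      rlang::inform(sprintf(
        "simulate_genotypes: clamped %d adaptive population frequencies to [0.001, 0.999]",
        n_clamped))
    }
  }

  pop_of <- rep(seq_len(np), each = params$n_per_pop)
  g <- matrix(stats::rbinom(n_ind * L, size = 2,
                            prob = pop_freqs[pop_of, ]),
              nrow = n_ind, ncol = L)
  if (params$missing_rate > 0) {
    g[stats::runif(n_ind * L) < params$missing_rate] <- NA_integer_
  }
  locus_id <- sprintf("snp%05d", seq_len(L))
  samp_id <- paste0(env$locality[pop_of], "_",
                    stats::ave(pop_of, pop_of, FUN = seq_along))
  rownames(g) <- samp_id
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  gm <- geno_matrix(g, tibble::tibble(locus_id = locus_id,
                                      ref = ref, alt = unname(alt)))
  region <- rep(c("NE", "SE", "S"), length.out = np)
  samples <- tibble::tibble(
    sample_id = samp_id,
    locality = env$locality[pop_of],
    region = region[pop_of]
  )
  truth <- list(
    adaptive_locus_ids = locus_id[adaptive_idx],
    ancestral_freq = stats::setNames(anc, locus_id),
    pop_freqs = `dimnames<-`(pop_freqs, list(env$locality, locus_id)),
    adaptive_predictor = stats::setNames(adaptive_predictor,
                                         locus_id[adaptive_idx]),
    n_clamped = n_clamped,
    seed = params$seed
  )
  list(gm = gm, samples = samples, truth = truth)
}

# Substitutions with a guaranteed effect class under the standard genetic
# code. codon_pos is 0-based within the codon.
.planted_subs <- list(
  synonymous = list(
    c("GCT", 2, "A"), c("GCC", 2, "G"), c("GGA", 2, "T"), c("CTG", 2, "C"),
    c("GTT", 2, "G"), c("ACA", 2, "C"), c("TCC", 2, "T"), c("CGG", 2, "A")
  ),
  nonsynonymous = list(
    c("GCT", 1, "T"), c("AAA", 0, "G"), c("TTC", 0, "C"), c("GAT", 1, "G"),
    c("CAT", 1, "G"), c("ATT", 0, "G")
  ),
  nonsense = list(
    c("TAC", 2, "A"), c("TGG", 1, "A"), c("CAA", 0, "T"), c("CGA", 0, "T")
  )
)

#' Simulate a transcriptome with SNPs planted at positions of known effect
#'
#' Each transcript is `5'UTR + ATG + sense codons + stop + 3'UTR` with no
#' internal in-frame stop codon; transcripts carrying a secondary ORF of at
#' least `min_codons` sense codons (any forward frame) are rejection-sampled
#' away. SNPs are planted at positions whose effect class is guaranteed by
#' construction — e.g. third positions of 4-fold degenerate codons for
#' synonymous changes — and the planted class is recorded as ground truth.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_len_codons Sense codons per CDS (excluding start ATG and stop).
#' @param utr_len Length of each UTR in nucleotides.
#' @param snp_plan Named integer vector with desired counts of classes among
#'   `synonymous`, `nonsynonymous`, `nonsense`, `utr`.
#' @param min_codons Secondary-ORF rejection threshold (sense codons).
#' @param seed Integer seed; the FASTA is byte-identical across calls with
#'   the same arguments.
#' @return A list: `transcripts` (named character vector), `orfs` (tibble:
#'   `transcript_id`, `orf_start`, `orf_end` 0-based half-open including the
#'   stop codon, `frame`, `n_codons`), `snps` (tibble: `locus_id`,
#'   `transcript_id`, `pos` 0-based, `ref`, `alt`, `true_class`), and `truth`
#'   (the same planted classes keyed by locus id, plus the seed).
#' @export
simulate_transcriptome <- function(n_transcripts, cds_len_codons = 120,
                                   utr_len = 30,
                                   snp_plan = c(synonymous = 5,
                                                nonsynonymous = 5,
                                                nonsense = 0, utr = 5),
                                   min_codons = 100, seed = 1L) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  bases <- c("A", "C", "G", "T")

  make_one <- function() {
    repeat {
      utr5 <- paste(sample(bases, utr_len, replace = TRUE), collapse = "")
      cds <- paste(c("ATG", sample(sense, cds_len_codons, replace = TRUE),
                     sample(stops, 1)), collapse = "")
      utr3 <- paste(sample(bases, utr_len, replace = TRUE), collapse = "")
      s <- paste0(utr5, cds, utr3)
      spans <- .orf_scan(s)
      main <- spans[spans$start == utr_len & spans$n_codons == cds_len_codons + 1, ]
      others <- spans[spans$n_codons >= min_codons &
                        !(spans$start == utr_len), ]
      if (nrow(main) == 1 && nrow(others) == 0) return(s)
    }
  }
  transcripts <- vapply(seq_len(n_transcripts), function(i) make_one(),
                        character(1))
  names(transcripts) <- sprintf("TRX%04d", seq_len(n_transcripts))
  orf_start <- utr_len
  orf_end <- utr_len + 3 * (cds_len_codons + 2)  # includes ATG and stop
  orfs <- tibble::tibble(
    transcript_id = names(transcripts),
    orf_start = orf_start, orf_end = orf_end,
    frame = orf_start %% 3L,
    n_codons = cds_len_codons + 1L  # ATG + sense codons, stop excluded
  )

  plan <- snp_plan[snp_plan > 0]
  n_snps <- sum(plan)
  # codon slots available for CDS planting: sense codons after the ATG
  slots <- expand.grid(tx = names(transcripts),
                       codon = seq_len(cds_len_codons),
                       stringsAsFactors = FALSE)
  if (sum(plan[setdiff(names(plan), "utr")]) > nrow(slots)) {
    rlang::abort("snp_plan requests more CDS SNPs than available codon slots")
  }
  if (isTRUE(unname(plan["utr"]) > n_transcripts * 2 * utr_len)) {
    rlang::abort("snp_plan requests more UTR SNPs than available UTR sites")
  }
  slots <- slots[sample.int(nrow(slots)), ]
  slot_i <- 0L
  snps <- vector("list", n_snps)
  k <- 0L
  for (cls in names(plan)) {
    for (j in seq_len(plan[[cls]])) {
      k <- k + 1L
      if (cls == "utr") {
        tx <- sample(names(transcripts), 1)
        in5 <- stats::runif(1) < 0.5
        pos <- if (in5) sample.int(utr_len, 1) - 1L else
          orf_end + sample.int(utr_len, 1) - 1L
        ref <- substr(transcripts[[tx]], pos + 1, pos + 1)
        alt <- sample(setdiff(bases, ref), 1)
        snps[[k]] <- tibble::tibble(transcript_id = tx, pos = pos,
                                    ref = ref, alt = alt, true_class = "oCDS")
      } else {
        # overwriting a codon can open a secondary reading frame elsewhere;
        # retry with the next slot until the single-ORF guarantee holds
        repeat {
          slot_i <- slot_i + 1L
          if (slot_i > nrow(slots)) {
            rlang::abort("snp_plan exhausted the available codon slots")
          }
          tx <- slots$tx[slot_i]
          codon_idx <- slots$codon[slot_i]  # 1-based among sense codons
          sub <- .planted_subs[[cls]][[sample.int(length(.planted_subs[[cls]]), 1)]]
          codon_start <- orf_start + 3L * codon_idx  # skip the ATG
          s <- transcripts[[tx]]
          substr(s, codon_start + 1, codon_start + 3) <- sub[[1]]
          spans <- .orf_scan(s)
          n_qual <- sum(spans$n_codons >= min_codons | spans$start == orf_start)
          if (n_qual == 1L) {
            transcripts[[tx]] <- s
            break
          }
        }
        pos <- codon_start + as.integer(sub[[2]])
        ref <- substr(sub[[1]], as.integer(sub[[2]]) + 1,
                      as.integer(sub[[2]]) + 1)
        snps[[k]] <- tibble::tibble(transcript_id = tx, pos = pos,
                                    ref = ref, alt = sub[[3]],
                                    true_class = cls)
      }
    }
  }
  snps <- dplyr::bind_rows(snps)
  # codon overwriting cannot create stops (all planted ref codons are sense),
  # but re-check the single-ORF property after planting
  snps$locus_id <- sprintf("tsnp%04d", seq_len(nrow(snps)))
  snps <- snps[, c("locus_id", "transcript_id", "pos", "ref", "alt",
                   "true_class")]
  list(
    transcripts = transcripts,
    orfs = orfs,
    snps = snps,
    truth = list(planted_class = stats::setNames(snps$true_class,
                                                 snps$locus_id),
                 seed = seed)
  )
}

# Minimal forward-frame ORF scanner used for rejection sampling: every
# leftmost-ATG-to-stop span per (frame, stop). Returns 0-based starts and
# n_codons counting ATG..stop inclusive of ATG, exclusive of stop... counts
# codons from ATG through the codon before the stop.
.orf_scan <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  res <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (fr in 0:2) {
    starts <- seq(fr + 1, n - 2, by = 3)
    codons <- paste0(ch[starts], ch[starts + 1], ch[starts + 2])
    open <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open) && codons[i] == "ATG") open <- i
      if (!is.na(open) && codons[i] %in% stops) {
        res[[length(res) + 1]] <- data.frame(
          start = starts[open] - 1L,
          end = starts[i] + 2L,
          frame = fr,
          n_codons = i - open  # ATG + sense codons, stop not counted
        )
        open <- NA_integer_
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), n_codons = integer()))
  }
  do.call(rbind, res)
}
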