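#' Cohort simulation parameters
#'
#' Collects every knob of the synthetic two-arm cohort generator.  Group A
#' plays the role of the persistent-disease arm (more clonal expansion,
#' more public-clone sharing), group B the newly diagnosed arm; the
#' parameters `expanded_mass`, `public_prob` and `n_expanded` may be a
#' single value (both groups) or a length-2 vector `(group A, group B)`.
#'
#' Defaults encode the study design the package emulates: 13 vs 20
#' samples, 62 V and 14 J germline segments, 2,000 clonotypes and 50,000
#' reads per sample, Zipf(1) background clone sizes, ten expanded clones
#' carrying an average 30% of the repertoire in group A and none in
#' group B, a shared public pool of 5,000 junctions drawn with
#' probability 0.3 (A) vs 0.05 (B), and four planted genes whose
#' log2-expression declines with repertoire entropy (slope -2, noise SD
#' 0.5), mirroring the inflammation/chemotaxis genes negatively
#' correlated with TCR diversity.
#'
#' @param n_group_a,n_group_b Samples per group.
#' @param n_v,n_j Germline segment counts.
#' @param clones_per_sample,reads_per_sample Clonotypes and sequencing
#'   reads per sample.
#' @param zipf_alpha Exponent (>= 0) of the Zipf background clone-size law.
#' @param n_expanded Expanded clones per sample (scalar or per group).
#' @param expanded_mass Total frequency mass of expanded clones, in
#'   `[0, 1)` (scalar or per group); each sample draws its own mass
#'   uniformly on `(0, 2 * group mean)`.
#' @param public_pool_size Size of the shared public junction pool.
#' @param public_prob Probability a clone is drawn from the public pool
#'   (scalar or per group).
#' @param error_rate Per-base substitution probability in `[0, 1)` used
#'   by [synthesize_reads()].
#' @param n_genes Genes in the expression matrix (including planted ones).
#' @param planted_genes Tibble with columns `gene_id`, `slope`,
#'   `noise_sd` tying `log2(expression)` to per-sample entropy.
#' @param expression_intercept Intercept of the planted linear model
#'   (log2 scale).
#' @param seed Master seed; the whole cohort bundle is reproducible
#'   from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 13, n_group_b = 20,
                          n_v = 62, n_j = 14,
                          clones_per_sample = 2000,
                          reads_per_sample = 50000,
                          zipf_alpha = 1,
                          n_expanded = 10,
                          expanded_mass = c(0.3, 0),
                          public_pool_size = 5000,
                          public_prob = c(0.3, 0.05),
                          error_rate = 0.001,
                          n_genes = 1000,
                          planted_genes = tibble::tibble(
                            gene_id = c("FASLG", "IL18R1", "CCL24", "CCL14"),
                            slope = -2,
                            noise_sd = 0.5),
                          expression_intercept = 16,
                          seed = 1L) {
  for (nm in c("n_group_a", "n_group_b", "n_v", "n_j",
               "clones_per_sample", "reads_per_sample",
               "public_pool_size", "n_genes")) {
    check_number(get(nm), nm, lower = 1)
  }
  check_number(zipf_alpha, "zipf_alpha", lower = 0)
  check_number(error_rate, "error_rate", lower = 0, upper = 1,
               allow_upper = FALSE)
  n_expanded <- rep(n_expanded, length.out = 2)
  expanded_mass <- rep(expanded_mass, length.out = 2)
  public_prob <- rep(public_prob, length.out = 2)
  if (any(n_expanded < 0)) abort("`n_expanded` must be >= 0.")
  if (any(expanded_mass < 0 | expanded_mass >= 1)) {
    abort("`expanded_mass` must lie in [0, 1).")
  }
  if (any(public_prob < 0 | public_prob > 1)) {
    abort("`public_prob` must lie in [0, 1].")
  }
  if (!is.data.frame(planted_genes) ||
      !all(c("gene_id", "slope", "noise_sd") %in% names(planted_genes))) {
    abort("`planted_genes` needs columns gene_id, slope, noise_sd.")
  }
  if (anyDuplicated(planted_genes$gene_id)) {
    abort("`planted_genes` gene ids must be unique.")
  }
  if (nrow(planted_genes) > n_genes) abort("more planted genes than `n_genes`.")

  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_v = as.integer(n_v), n_j = as.integer(n_j),
    clones_per_sample = as.integer(clones_per_sample),
    reads_per_sample = as.integer(reads_per_sample),
    zipf_alpha = zipf_alpha,
    n_expanded = as.integer(n_expanded),
    expanded_mass = expanded_mass,
    public_pool_size = as.integer(public_pool_size),
    public_prob = public_prob,
    error_rate = error_rate,
    n_genes = as.integer(n_genes),
    planted_genes = tibble::as_tibble(planted_genes),
    expression_intercept = expression_intercept,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Zipf frequencies over n ranks with exponent alpha (alpha = 0 -> uniform)
zipf_frequencies <- function(n, alpha) {
  w <- seq_len(n)^(-alpha)
  w / sum(w)
}

# internal: draw one V(D)J recombination per row -- a V suffix whose 3'
# end is exonuclease-trimmed by 0-6 nt (never into the 2nd-CYS anchor),
# a 0-12 nt N-region of uniform composition, and a J prefix trimmed by
# 0-6 nt at its 5' end (never into the F/W anchor) -- and locate both
# anchors on the product
recombine_clones <- function(reference, n) {
  v_tab <- reference[reference$segment_type == "V", ]
  j_tab <- reference[reference$segment_type == "J", ]
  vi <- sample(nrow(v_tab), n, replace = TRUE)
  ji <- sample(nrow(j_tab), n, replace = TRUE)
  n_len <- sample(0:12, n, replace = TRUE)
  n_seq <- random_dna(n_len)

  v_len <- nchar(v_tab$sequence[vi])
  v_anchor <- v_tab$anchor_pos[vi]
  trim_v <- pmin(sample(0:6, n, replace = TRUE),
                 v_len - v_anchor - 2L)
  v_part <- substr(v_tab$sequence[vi], 1L, v_len - trim_v)

  j_anchor_ref <- j_tab$anchor_pos[ji]
  trim_j <- pmin(sample(0:6, n, replace = TRUE),
                 pmax(j_anchor_ref - 1L, 0L))
  j_part <- substr(j_tab$sequence[ji], trim_j + 1L,
                   nchar(j_tab$sequence[ji]))

  sequence <- paste0(v_part, n_seq, j_part)
  j_anchor <- nchar(v_part) + n_len + (j_anchor_ref - trim_j)
  junction <- substr(sequence, v_anchor, j_anchor + 2L)
  tibble::tibble(
    v_call = v_tab$segment_id[vi], j_call = j_tab$segment_id[ji],
    junction = junction, sequence = sequence,
    v_anchor = v_anchor, j_anchor = j_anchor
  )
}

#' Simulate one sample's clonotype repertoire
#'
#' Clone frequencies follow a Zipf background carrying `1 - expanded_mass`
#' of the repertoire, plus `n_expanded` expanded clones sharing
#' `expanded_mass` evenly.  Each clone is a recombination of a V segment,
#' a 0-12 nt uniform N-region and a J segment; with probability
#' `public_prob` its identity is replaced by a draw from the shared
#' public pool.  Observed counts are a multinomial draw of
#' `reads_per_sample` reads from the true frequencies.
#'
#' @param reference Germline tibble (needs >= 1 V and >= 1 J).
#' @param sample_seed Integer seed for this sample.
#' @param sample_id,group Sample label and group label.
#' @param clones_per_sample,zipf_alpha,n_expanded,expanded_mass,reads_per_sample
#'   See [cohort_config()]; `expanded_mass` here is the exact mass used.
#' @param public_pool Optional pool tibble from an enclosing cohort.
#' @param public_prob Probability of drawing a clone from `public_pool`.
#' @return A tibble (one row per simulated clone) with identity columns
#'   (`v_call`, `j_call`, `junction`, `junction_aa`, `sequence`), truth
#'   columns (`true_freq`, `expanded`, `public`, anchors) and observed
#'   `count` / `frequency`.
#' @export
simulate_repertoire <- function(reference, sample_seed,
                                sample_id = "S1", group = NA_character_,
                                clones_per_sample = 2000,
                                zipf_alpha = 1,
                                n_expanded = 0, expanded_mass = 0,
                                public_pool = NULL, public_prob = 0,
                                reads_per_sample = 50000) {
  validate_germline(reference)
  check_number(expanded_mass, "expanded_mass", 0, 1, allow_upper = FALSE)
  check_number(public_prob, "public_prob", 0, 1)
  if (n_expanded < 0) abort("`n_expanded` must be >= 0.")
  if (expanded_mass > 0 && n_expanded == 0) {
    abort("`expanded_mass` > 0 requires `n_expanded` >= 1.")
  }
  if (expanded_mass == 0) n_expanded <- 0L # no zero-frequency clones
  n_bg <- clones_per_sample - n_expanded
  if (n_bg < 1) abort("`clones_per_sample` must exceed `n_expanded`.")
  if (public_prob > 0 && is.null(public_pool)) {
    abort("`public_prob` > 0 requires a `public_pool`.")
  }

  withr::with_seed(as.integer(sample_seed), {
    freq <- c((1 - expanded_mass) * zipf_frequencies(n_bg, zipf_alpha),
              rep(expanded_mass / max(n_expanded, 1L), n_expanded))
    clones <- recombine_clones(reference, clones_per_sample)
    public <- runif(clones_per_sample) < public_prob
    if (any(public) && !is.null(public_pool)) {
      take <- sample(nrow(public_pool), sum(public), replace = TRUE)
      for (col in c("v_call", "j_call", "junction", "sequence",
                    "v_anchor", "j_anchor")) {
        clones[[col]][public] <- public_pool[[col]][take]
      }
    }
    count <- as.vector(rmultinom(1, reads_per_sample, freq))
    tibble::tibble(
      sample_id = sample_id, group = group,
      clone_id = sprintf("%s_c%05d", sample_id, seq_len(clones_per_sample)),
      v_call = clones$v_call, j_call = clones$j_call,
      junction = clones$junction,
      junction_aa = translate_nt(clones$junction),
      sequence = clones$sequence,
      v_anchor = clones$v_anchor, j_anchor = clones$j_anchor,
      true_freq = freq,
      expanded = rep(c(FALSE, TRUE), c(n_bg, n_expanded)),
      public = public,
      count = count,
      frequency = count / reads_per_sample
    )
  })
}

#' Aggregate simulator truth into a clonotype table
#'
#' Collapses a simulated repertoire to distinct clonotype keys (identical
#' keys can arise from repeated public-pool draws), summing true
#' frequencies and observed counts.
#'
#' @param sim Tibble from [simulate_repertoire()].
#' @param key_mode `"nt"` (V + J + nucleotide junction) or `"aa"`
#'   (V + J + amino-acid junction).
#' @return Tibble of distinct clonotypes with `true_freq`, `count` and
#'   observed `frequency`.
#' @export
true_clonotypes <- function(sim, key_mode = c("nt", "aa")) {
  key_mode <- match.arg(key_mode)
  keyvar <- if (key_mode == "nt") "junction" else "junction_aa"
  sim |>
    dplyr::group_by(.data$sample_id, .data$group, .data$v_call,
                    .data$j_call, .data[[keyvar]]) |>
    dplyr::summarise(
      junction_aa = dplyr::first(.data$junction_aa),
      true_freq = sum(.data$true_freq),
      count = sum(.data$count),
      expanded = any(.data$expanded),
      public = any(.data$public),
      .groups = "drop"
    ) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count),
                  .by = "sample_id")
}

#' Synthesize error-bearing sequencing reads from a simulated sample
#'
#' Reads are drawn multinomially from the true clone frequencies and each
#' base is substituted independently with probability `error_rate`.  Read
#' identifiers encode the originating clone (`read000001|clone=<id>`) so
#' downstream tests can consult the truth.
#'
#' @param sim Tibble from [simulate_repertoire()].
#' @param reads_per_sample Number of reads (>= 1).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `contig_id`, `sequence`, `quality` (constant
#'   Phred+33 "I" = Q40) and the truth columns `true_clone`, `true_v`,
#'   `true_j`, `true_junction`.
#' @export
synthesize_reads <- function(sim, reads_per_sample = 50000,
                             error_rate = 0, seed = 1L) {
  check_number(reads_per_sample, "reads_per_sample", lower = 1)
  check_number(error_rate, "error_rate", 0, 1, allow_upper = FALSE)
  withr::with_seed(as.integer(seed), {
    counts <- as.vector(rmultinom(1, reads_per_sample, sim$true_freq))
    take <- rep.int(seq_len(nrow(sim)), counts)
    seqs <- sim$sequence[take]
    if (error_rate > 0) {
      lens <- nchar(seqs)
      n_mut <- rbinom(length(seqs), lens, error_rate)
      for (i in which(n_mut > 0)) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(lens[i], n_mut[i])
        for (p in pos) {
          s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
        }
        seqs[i] <- paste(s, collapse = "")
      }
    }
    tibble::tibble(
      contig_id = sprintf("read%06d|clone=%s", seq_along(seqs),
                          sim$clone_id[take]),
      sequence = seqs,
      quality = strrep("I", nchar(seqs)),
      true_clone = sim$clone_id[take],
      true_v = sim$v_call[take],
      true_j = sim$j_call[take],
      true_junction = sim$junction[take]
    )
  })
}

#' Simulate a full two-arm cohort
#'
#' Generates the germline reference, a shared public-clone pool, per-sample
#' repertoires for both groups and a matched gene-by-sample expression
#' matrix in which the planted genes follow
#' `log2(expr) = intercept + slope * entropy + Normal(0, noise_sd)` with
#' `entropy` the sample's true clonotype Shannon entropy (nats); all other
#' genes are independent log-normal noise.  Every sample draws its
#' expanded-clone mass uniformly on `(0, 2 * group mean)` so that entropy
#' varies across samples within a group.
#'
#' @param config A [cohort_config()] object.
#' @param include_reads If `TRUE`, also synthesize error-bearing reads for
#'   every sample (slow; off by default).
#' @return A list of class `repdiv_cohort` with elements `samples`
#'   (per-sample metadata incl. `true_entropy`), `clonotypes` (combined
#'   simulated repertoires), `expression` (tibble, `gene_id` + one column
#'   per sample), `reference`, `public_pool`, `config` and optionally
#'   `reads`.
#' @examples
#' cfg <- cohort_config(n_group_a = 3, n_group_b = 3,
#'                      clones_per_sample = 50, reads_per_sample = 500,
#'                      n_genes = 10, public_pool_size = 100, seed = 7)
#' coh <- simulate_cohort(cfg)
#' coh$samples
#' @export
simulate_cohort <- function(config, include_reads = FALSE) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must come from cohort_config().")
  }
  n_a <- config$n_group_a; n_b <- config$n_group_b
  n_tot <- n_a + n_b

  setup <- withr::with_seed(config$seed, {
    list(
      seeds = sample.int(2^31 - 2, 3 + 2 * n_tot),
      mass_a = pmin(runif(n_a, 0, 2 * config$expanded_mass[1]), 0.9),
      mass_b = pmin(runif(n_b, 0, 2 * config$expanded_mass[2]), 0.9)
    )
  })
  seeds <- setup$seeds
  reference <- make_germline_reference(config$n_v, config$n_j,
                                       seed = seeds[1])
  public_pool <- withr::with_seed(seeds[2], {
    recombine_clones(reference, config$public_pool_size)
  })

  samples <- tibble::tibble(
    sample_id = c(sprintf("P%02d", seq_len(n_a)),
                  sprintf("N%02d", seq_len(n_b))),
    group = rep(c("pGD-like", "nGD-like"), c(n_a, n_b)),
    expanded_mass = c(setup$mass_a, setup$mass_b),
    n_expanded = rep(config$n_expanded, c(n_a, n_b)),
    public_prob = rep(config$public_prob, c(n_a, n_b)),
    sample_seed = seeds[3 + seq_len(n_tot)]
  )
  # a drawn mass needs at least one expanded clone to sit in
  samples$expanded_mass[samples$n_expanded == 0] <- 0

  sims <- purrr::pmap(samples, function(sample_id, group, expanded_mass,
                                        n_expanded, public_prob,
                                        sample_seed) {
    simulate_repertoire(
      reference, sample_seed = sample_seed, sample_id = sample_id,
      group = group, clones_per_sample = config$clones_per_sample,
      zipf_alpha = config$zipf_alpha, n_expanded = n_expanded,
      expanded_mass = expanded_mass, public_pool = public_pool,
      public_prob = public_prob,
      reads_per_sample = config$reads_per_sample
    )
  })
  clonotypes <- dplyr::bind_rows(sims)

  samples$true_entropy <- vapply(sims, function(s) {
    tf <- tapply(s$true_freq, paste(s$v_call, s$j_call, s$junction), sum)
    shannon_entropy(as.vector(tf))
  }, numeric(1))

  expression <- withr::with_seed(seeds[3], {
    planted <- config$planted_genes
    n_noise <- config$n_genes - nrow(planted)
    ids <- c(planted$gene_id, sprintf("GENE%04d", seq_len(n_noise)))
    mat <- matrix(NA_real_, config$n_genes, n_tot,
                  dimnames = list(ids, samples$sample_id))
    for (g in seq_len(nrow(planted))) {
      mat[g, ] <- 2^(config$expression_intercept +
                       planted$slope[g] * samples$true_entropy +
                       rnorm(n_tot, 0, planted$noise_sd[g]))
    }
    if (n_noise > 0) {
      mu <- runif(n_noise, 2, 10)
      mat[nrow(planted) + seq_len(n_noise), ] <-
        2^(mu + matrix(rnorm(n_noise * n_tot), n_noise, n_tot))
    }
    dplyr::bind_cols(tibble::tibble(gene_id = ids),
                     tibble::as_tibble(mat))
  })

  out <- list(samples = samples, clonotypes = clonotypes,
              expression = expression, reference = reference,
              public_pool = public_pool, config = config)
  if (include_reads) {
    out$reads <- purrr::map2(
      sims, seeds[3 + n_tot + seq_len(n_tot)],
      ~ synthesize_reads(.x, config$reads_per_sample,
                         config$error_rate, seed = .y)
    )
    names(out$reads) <- samples$sample_id
  }
  structure(out, class = "repdiv_cohort")
}

#' @export
print.repdiv_cohort <- function(x, ...) {
  cat(sprintf(
    "<repdiv_cohort> %d + %d samples, %d clonotypes/sample, %d genes\n",
    x$config$n_group_a, x$config$n_group_b,
    x$config$clones_per_sample, x$config$n_genes))
  print(x$samples, n = 5)
  invisible(x)
}

#' Write reads / expression tables to disk
#'
#' Reads are written as FASTQ (Sanger Phred+33) or FASTA depending on the
#' file extension; the expression matrix as TSV with genes in rows and a
#' `gene_id` first column.
#'
#' @param reads Tibble from [synthesize_reads()].
#' @param path Output file (`.fastq`/`.fq` for FASTQ, else FASTA).
#' @return The input, invisibly.
#' @export
write_reads <- function(reads, path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path)
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence,
                                            reads$contig_id))
  if (fastq) {
    qual <- Biostrings::BStringSet(reads$quality)
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = qual)
  } else {
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(reads)
}

#' @rdname write_reads
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(expression)
}
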