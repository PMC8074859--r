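test_that("clonotype aggregation collapses keys at the requested resolution", {
  rearr <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    v_call = "TRBV1", j_call = "TRBJ1",
    junction = c("TGTAAATTT", "TGTAAATTT", "TGCAAGTTC"),
    junction_aa = c("CKF", "CKF", "CKF"),
    productive = TRUE,
    duplicate_count = c(3L, 2L, 4L))

  nt <- build_clonotype_table(rearr, "nt")
  expect_equal(nrow(nt), 2)
  expect_equal(sum(nt$count), 9)
  expect_equal(nt$count[nt$junction == "TGTAAATTT"], 5)
  expect_equal(sum(nt$frequency), 1, tolerance = 1e-12)

  # synonymous junctions collapse under amino-acid keys
  aa <- build_clonotype_table(rearr, "aa")
  expect_equal(nrow(aa), 1)
  expect_equal(aa$count, 9)
  expect_equal(aa$frequency, 1)

  expect_error(build_clonotype_table(rearr[0, ]), "non-empty")

  # simulator truth round trip at nucleotide keys
  ref <- tiny_reference()
  sim <- simulate_repertoire(ref, sample_seed = 61,
                             clones_per_sample = 100, zipf_alpha = 0,
                             reads_per_sample = 2000)
  reads <- synthesize_reads(sim, 2000, error_rate = 0, seed = 6)
  airr <- annotate_repertoire(reads, ref, keep_nonproductive = TRUE,
                              quiet = TRUE)
  tab <- build_clonotype_table(airr, "nt")
  truth <- reads |>
    dplyr::count(.data$true_v, .data$true_j, .data$true_junction)
  expect_setequal(paste(tab$v_call, tab$j_call, tab$junction),
                  paste(truth$true_v, truth$true_j, truth$true_junction))
})

test_that("entropy matches its worked values and the summation oracle", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(4, 2, 1, 1)), 1.75 * log(2),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(c(4, 2, 1, 1), base = 2), 1.75,
               tolerance = 1e-12)
  expect_error(shannon_entropy(numeric(0)), "non-empty")

  withr::local_seed(7)
  for (i in 1:100) {
    f <- runif(sample(2:60, 1))
    expect_equal(shannon_entropy(f), entropy_oracle(f),
                 tolerance = 1e-12)
  }
})

test_that("Gini matches its worked values and the pairwise oracle", {
  expect_equal(gini_coefficient(rep(0.2, 5)), 0, tolerance = 1e-12)
  expect_equal(gini_coefficient(c(1, 0, 0, 0)), 0.75, tolerance = 1e-12)
  expect_equal(gini_coefficient(c(3, 1)), 0.25, tolerance = 1e-12)
  expect_equal(gini_coefficient(c(3, 1)), gini_coefficient(c(30, 10)),
               tolerance = 1e-12) # scale invariance
  expect_error(gini_coefficient(c(0, 0)), "positive sum")

  withr::local_seed(8)
  for (i in 1:100) {
    x <- runif(sample(2:40, 1))
    expect_equal(gini_coefficient(x), gini_oracle(x), tolerance = 1e-12)
  }
})

test_that("HEC detection uses a strict frequency threshold", {
  # 150/100000 qualifies; exactly 0.001 does not
  counts <- c(150L, 100L, rep(50L, 1995))
  tab <- clonotype_fixture(counts)
  expect_equal(sum(tab$count), 100000)
  hec <- detect_hec(tab)
  expect_equal(hec$hec_count, 1)
  expect_equal(hec$hec_cum_freq, 0.0015)

  single <- clonotype_fixture(10L)
  expect_equal(detect_hec(single)$hec_count, 1)
  expect_equal(detect_hec(single)$hec_cum_freq, 1)

  expect_error(detect_hec(tab, threshold = 0), "threshold")
  expect_error(detect_hec(tab, threshold = 1), "threshold")

  # brute-force filter oracle on a random table
  withr::local_seed(9)
  counts <- sample(1:400, 500, replace = TRUE)
  tab <- clonotype_fixture(counts)
  manual <- sum(counts / sum(counts) > 0.001)
  expect_equal(detect_hec(tab)$hec_count, manual)
})

test_that("V-J usage is read-weighted and sums to one", {
  tab <- tibble::tibble(
    sample_id = "S1", group = NA,
    v_call = c("V1", "V2"), j_call = c("J1", "J1"),
    junction = c("TGTA", "TGCC"), junction_aa = c("CA", "CB"),
    count = c(3L, 1L), frequency = c(0.75, 0.25))
  u <- vj_usage(tab)
  expect_equal(u$v_freqs$frequency[u$v_freqs$v_call == "V1"], 0.75)
  expect_equal(u$j_freqs$frequency, 1)
  expect_equal(u$top_vj_pair, c("V1", "J1"))
  expect_equal(u$top_vj_freq, 0.75)
  expect_equal(sum(u$vj_pairs$frequency), 1, tolerance = 1e-9)

  # degenerate single clonotype
  u1 <- vj_usage(tab[1, ])
  expect_equal(u1$top_vj_freq, 1)
  # uniform pair fixture has zero V-J Gini
  even <- tibble::tibble(sample_id = "S1", group = NA,
                         v_call = c("V1", "V2"), j_call = c("J1", "J2"),
                         junction = c("A", "B"), junction_aa = c("A", "B"),
                         count = c(5L, 5L), frequency = c(0.5, 0.5))
  expect_equal(gini_coefficient(vj_usage(even)$vj_pairs$frequency), 0)
})

test_that("public clonotype sharing matches set-operation oracles", {
  mk <- function(sample_id, keys) {
    tibble::tibble(sample_id = sample_id, group = NA, v_call = "V1",
                   j_call = "J1", junction = keys, junction_aa = keys,
                   count = 1L, frequency = 1 / length(keys))
  }
  tab <- dplyr::bind_rows(mk("S1", c("a", "b", "c")),
                          mk("S2", c("b", "c", "d")),
                          mk("S3", "e"))
  sh <- public_clonotypes(tab, key_mode = "aa")
  expect_equal(sh$core_count, 2)
  expect_setequal(sh$public_keys, c("b", "c"))
  expect_equal(sh$petal_counts$private, c(1L, 1L, 1L))
  # core + private keys account for every distinct key
  expect_equal(sh$core_count + sum(sh$petal_counts$private), 5)
  # overlap matrix symmetric with per-sample richness on the diagonal
  expect_equal(sh$pairwise_overlap, t(sh$pairwise_overlap))
  expect_equal(unname(diag(sh$pairwise_overlap)), c(3L, 3L, 1L))
  expect_equal(sh$pairwise_overlap["S1", "S2"], 2L)

  all_same <- dplyr::bind_rows(mk("S1", c("a", "b")), mk("S2", c("a", "b")))
  expect_equal(public_clonotypes(all_same)$core_count, 2)
  expect_equal(sum(public_clonotypes(all_same)$petal_counts$private), 0)

  disjoint <- dplyr::bind_rows(mk("S1", c("a", "b")), mk("S2", c("c", "d")))
  expect_equal(public_clonotypes(disjoint)$core_count, 0)

  expect_error(public_clonotypes(mk("S1", "a")), "2 samples")

  # random cohorts against the hash-set oracle
  withr::local_seed(10)
  for (i in 1:20) {
    n_samp <- sample(3:6, 1)
    tabs <- lapply(seq_len(n_samp), function(s) {
      keys <- unique(sprintf("K%d", sample(1:50, sample(5:30, 1))))
      mk(sprintf("S%d", s), keys)
    })
    tab <- dplyr::bind_rows(tabs)
    expect_equal(public_clonotypes(tab, "aa")$core_count,
                 public_count_oracle(tab$sample_id, tab$junction_aa))
  }
})

test_that("sample summaries compose the diversity statistics", {
  uniform <- clonotype_fixture(rep(5L, 100))
  s <- summarize_sample(uniform)
  expect_equal(s$richness, 100)
  expect_equal(s$entropy, log(100), tolerance = 1e-12)
  expect_equal(s$gini_clone, 0, tolerance = 1e-12)
  expect_equal(s$hec_count, 100) # 1/100 > 0.001
  expect_equal(s$hec_cum_freq, 1)

  singleton <- clonotype_fixture(7L)
  s1 <- summarize_sample(singleton)
  expect_equal(s1$richness, 1)
  expect_equal(s1$entropy, 0)
  expect_equal(s1$hec_cum_freq, 1)

  # expansion lowers entropy and raises the top V-J share (paired seeds)
  ref <- tiny_reference()
  hi <- simulate_repertoire(ref, sample_seed = 71,
                            clones_per_sample = 300, n_expanded = 1,
                            expanded_mass = 0.5, reads_per_sample = 5000)
  lo <- simulate_repertoire(ref, sample_seed = 71,
                            clones_per_sample = 300,
                            reads_per_sample = 5000)
  s_hi <- summarize_sample(true_clonotypes(hi)[true_clonotypes(hi)$count > 0, ])
  s_lo <- summarize_sample(true_clonotypes(lo)[true_clonotypes(lo)$count > 0, ])
  expect_lt(s_hi$entropy, s_lo$entropy)
  expect_gt(s_hi$top_vj_freq, s_lo$top_vj_freq)

  # grouped wrapper covers every sample
  both <- dplyr::bind_rows(clonotype_fixture(rep(2L, 10), "A"),
                           clonotype_fixture(c(5L, 5L), "B"))
  summ <- summarize_repertoire(both)
  expect_equal(nrow(summ), 2)
  expect_setequal(summ$sample_id, c("A", "B"))
})

test_that("entropy bounds and concentration monotonicity hold", {
  withr::local_seed(11)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    f <- runif(n)
    f <- f / sum(f)
    h <- shannon_entropy(f)
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)

    # merging two clonotypes never increases entropy
    merged <- f
    merged[1] <- f[1] + f[2]
    merged <- merged[-2]
    expect_lte(shannon_entropy(merged), h + 1e-12)

    # moving mass onto a larger clone (fixed length) never lowers Gini
    shifted <- f
    hi_i <- which.max(f); lo_i <- which.min(f)
    if (hi_i != lo_i) {
      shifted[hi_i] <- shifted[hi_i] + f[lo_i]
      shifted[lo_i] <- 0
      expect_gte(gini_coefficient(shifted), gini_coefficient(f) - 1e-12)
    }
  }
})

test_that("HEC cumulative frequency is stable under downsampling", {
  withr::local_seed(12)
  counts <- as.vector(rmultinom(1, 100000,
                                repdiv:::zipf_frequencies(2000, 1)))
  counts <- counts[counts > 0]
  full <- detect_hec(clonotype_fixture(counts))$hec_cum_freq
  ok <- vapply(1:50, function(i) {
    sub <- as.vector(rmultinom(1, 20000, counts / sum(counts)))
    sub <- sub[sub > 0]
    down <- detect_hec(clonotype_fixture(sub))$hec_cum_freq
    abs(down - full) <= 0.05
  }, logical(1))
  expect_gte(sum(ok), 48)
})
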