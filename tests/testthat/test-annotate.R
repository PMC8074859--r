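ref <- tiny_reference()
idx <- kmer_index(ref)

test_that("read pairs merge on their best 3' overlap", {
  # 12-base overlap, 8 novel bases on the mate -> merged length 23
  r1 <- "ACGTACGTACGTACG"
  tail12 <- substr(r1, 4, 15)
  novel <- "TTGGCCAA"
  r2 <- rev_comp_chr(paste0(tail12, novel))
  m <- merge_read_pairs(r1, r2)
  expect_true(m$merged)
  expect_equal(nchar(m$sequence), 23)
  expect_equal(m$sequence, paste0(r1, novel))

  # no sufficient overlap -> unmerged flag
  expect_false(merge_read_pairs("AAAAAAAAAAAAAAA",
                                "GGGGGGGGGGGGGGG")$merged)

  # full containment: r2 the exact reverse complement of r1
  m2 <- merge_read_pairs(r1, rev_comp_chr(r1))
  expect_true(m2$merged)
  expect_equal(m2$sequence, r1)

  # mismatch in the overlap resolves to the higher-quality base
  r1m <- "ACGTACGTACGTACG"
  over <- "ACGTACGTACGTACG" # r2 = revcomp of r1 with one changed base
  substr(over, 8, 8) <- "T"
  hi <- strrep("I", 15); lo <- strrep("#", 15)
  m3 <- merge_read_pairs(r1m, rev_comp_chr(over), q1 = lo, q2 = hi)
  expect_equal(substr(m3$sequence, 8, 8), "T")
  m4 <- merge_read_pairs(r1m, rev_comp_chr(over), q1 = hi, q2 = hi)
  expect_equal(substr(m4$sequence, 8, 8), substr(r1m, 8, 8)) # tie -> r1
})

test_that("junction extraction follows the IMGT anchor convention", {
  res <- extract_cdr3("TGTGCCAGCAGCCTGGGCTTT", 1, 19)
  expect_equal(res$junction, "TGTGCCAGCAGCCTGGGCTTT")
  expect_equal(res$junction_aa, "CASSLGF")
  expect_true(res$productive)

  # out-of-frame junction (20 nt) is nonproductive
  res20 <- extract_cdr3(paste0("TGTGCCAGCAGCCTGGGCTT", "TTT"), 1, 18)
  expect_equal(nchar(res20$junction), 20)
  expect_false(res20$productive)

  # in-frame stop codon is nonproductive
  stop_res <- extract_cdr3("TGTTGACTGGGCTTT", 1, 13)
  expect_true(grepl("\\*", stop_res$junction_aa))
  expect_false(stop_res$productive)

  # missing J anchor falls back to the first in-frame F/W-G-X-G motif
  contig <- paste0("TGTGCCAGC", "TTTGGAAAAGGA", "ACGT")
  fb <- extract_cdr3(contig, 1, NA)
  expect_equal(fb$junction, "TGTGCCAGCTTT")
  expect_equal(fb$junction_aa, "CASF")

  # anchors out of order -> failure record
  expect_false(extract_cdr3("TGTGCCAGC", 5, 2)$productive)
})

test_that("identical contigs collapse with summed duplicate counts", {
  v1 <- ref[ref$segment_type == "V", ][1, ]
  j1 <- ref[ref$segment_type == "J", ][1, ]
  contig <- paste0(v1$sequence, "ACG", j1$sequence)
  contigs <- tibble::tibble(contig_id = sprintf("r%d", 1:5),
                            sequence = contig)
  out <- annotate_repertoire(contigs, ref, keep_nonproductive = TRUE,
                             quiet = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(out$duplicate_count, 5)
  expect_equal(out$v_call, v1$segment_id)
})

test_that("collapsing is invariant to the order of the contig stream", {
  sim <- simulate_repertoire(ref, sample_seed = 21,
                             clones_per_sample = 50,
                             reads_per_sample = 400)
  reads <- synthesize_reads(sim, 400, error_rate = 0, seed = 5)
  shuffled <- reads[withr::with_seed(1, sample(nrow(reads))), ]
  a <- annotate_repertoire(reads, idx, keep_nonproductive = TRUE,
                           quiet = TRUE)
  b <- annotate_repertoire(shuffled, idx, keep_nonproductive = TRUE,
                           quiet = TRUE)
  cols <- c("v_call", "j_call", "junction", "junction_aa", "productive",
            "duplicate_count")
  expect_equal(a[cols], b[cols])
})

test_that("error-free reads recover the simulated truth exactly", {
  sim <- simulate_repertoire(ref, sample_seed = 31,
                             clones_per_sample = 200, zipf_alpha = 0,
                             reads_per_sample = 3000)
  reads <- synthesize_reads(sim, 3000, error_rate = 0, seed = 6)
  airr <- annotate_repertoire(reads, idx, keep_nonproductive = TRUE,
                              quiet = TRUE)
  tab <- build_clonotype_table(airr, "nt")

  truth <- reads |>
    dplyr::count(.data$true_v, .data$true_j, .data$true_junction,
                 name = "count")
  expect_setequal(paste(tab$v_call, tab$j_call, tab$junction),
                  paste(truth$true_v, truth$true_j, truth$true_junction))
  m <- match(paste(tab$v_call, tab$j_call, tab$junction),
             paste(truth$true_v, truth$true_j, truth$true_junction))
  expect_equal(tab$count, truth$count[m])
})

test_that("V/J calls stay accurate on error-bearing reads", {
  big_ref <- make_germline_reference(62, 14, seed = 5)
  big_idx <- kmer_index(big_ref)
  sim <- simulate_repertoire(big_ref, sample_seed = 41,
                             clones_per_sample = 2000, zipf_alpha = 1,
                             reads_per_sample = 10000)
  reads <- synthesize_reads(sim, 10000, error_rate = 0.005, seed = 7)
  uniq <- unique(reads$sequence)
  calls <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    calls[[i]] <- repdiv:::.assign_segments(uniq[i], big_idx)
  }
  v_call <- vapply(calls, `[[`, character(1), "v_call")[
    match(reads$sequence, uniq)]
  j_call <- vapply(calls, `[[`, character(1), "j_call")[
    match(reads$sequence, uniq)]
  ok <- !is.na(v_call) & !is.na(j_call) &
    v_call == reads$true_v & j_call == reads$true_j
  expect_gte(mean(ok), 0.99)
})

test_that("QC drops low-quality and N-run contigs; empty output errors", {
  v1 <- ref[ref$segment_type == "V", ][1, ]
  j1 <- ref[ref$segment_type == "J", ][1, ]
  good <- paste0(v1$sequence, "ACG", j1$sequence)
  contigs <- tibble::tibble(
    contig_id = c("ok", "lowq", "nrun"),
    sequence = c(good, good, paste0(good, "NNNNNN")),
    quality = c(strrep("I", nchar(good)), strrep("#", nchar(good)),
                strrep("I", nchar(good) + 6)))
  out <- annotate_repertoire(contigs, idx, keep_nonproductive = TRUE,
                             quiet = TRUE)
  expect_equal(sum(out$duplicate_count), 1)

  rubbish <- tibble::tibble(
    contig_id = c("x1", "x2"),
    sequence = withr::with_seed(9, vapply(1:2, function(i) {
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    }, character(1))))
  expect_error(annotate_repertoire(rubbish, idx, quiet = TRUE),
               "annotated")
})

test_that("AIRR TSV and FASTA/FASTQ round trips preserve records", {
  sim <- simulate_repertoire(ref, sample_seed = 51,
                             clones_per_sample = 20,
                             reads_per_sample = 200)
  reads <- synthesize_reads(sim, 50, error_rate = 0, seed = 8)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(reads, fq)
  back <- read_contigs(fq)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)

  airr <- annotate_repertoire(reads, idx, keep_nonproductive = TRUE,
                              quiet = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_airr(airr, tsv)
  back2 <- read_airr(tsv)
  expect_equal(as.data.frame(back2), as.data.frame(airr))
})
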