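#' Merge a read pair into a contig
#'
#' Scans the reverse complement of `r2` against the 3' end of `r1` for
#' the longest overlap of at least `min_overlap` bases whose mismatch
#' fraction does not exceed `max_mismatch_frac`.  Mismatching overlap
#' bases are resolved to the higher-quality base (ties keep `r1`).
#'
#' @param r1,r2 Read sequences (nucleotide strings).
#' @param q1,q2 Optional Phred+33 quality strings.
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch_frac Maximum fraction of mismatches in the overlap.
#' @return A list with `merged` (logical), `sequence` and `quality`
#'   (`NA` when unmerged).
#' @examples
#' merge_read_pairs("ACGTACGTACGT", rev_comp_chr("GTACGTACGT"))
#' @export
merge_read_pairs <- function(r1, r2, q1 = NULL, q2 = NULL,
                             min_overlap = 10L, max_mismatch_frac = 0.1) {
  if (!nzchar(r1) || !nzchar(r2)) abort("reads must be non-empty.")
  rc2 <- rev_comp(r2)
  qc2 <- if (!is.null(q2)) {
    paste(rev(strsplit(q2, "", fixed = TRUE)[[1]]), collapse = "")
  }
  n1 <- nchar(r1); n2 <- nchar(rc2)
  s1 <- strsplit(r1, "", fixed = TRUE)[[1]]
  s2 <- strsplit(rc2, "", fixed = TRUE)[[1]]

  for (o in seq.int(min(n1, n2), min_overlap)) {
    a <- s1[(n1 - o + 1L):n1]
    b <- s2[seq_len(o)]
    mm <- which(a != b)
    if (length(mm) / o > max_mismatch_frac) next

    if (length(mm) > 0) {
      use_r2 <- rep(FALSE, length(mm))
      if (!is.null(q1) && !is.null(qc2)) {
        qa <- utf8ToInt(substr(q1, n1 - o + 1L, n1))[mm]
        qb <- utf8ToInt(substr(qc2, 1L, o))[mm]
        use_r2 <- qb > qa
      }
      a[mm[use_r2]] <- b[mm[use_r2]]
    }
    merged <- paste(c(s1[seq_len(n1 - o)], a,
                      if (o < n2) s2[(o + 1L):n2]), collapse = "")
    qual <- if (!is.null(q1) && !is.null(qc2)) {
      paste0(substr(q1, 1L, n1 - o), substr(q1, n1 - o + 1L, n1),
             if (o < n2) substr(qc2, o + 1L, n2) else "")
    } else {
      NA_character_
    }
    return(list(merged = TRUE, sequence = merged, quality = qual))
  }
  list(merged = FALSE, sequence = NA_character_, quality = NA_character_)
}

#' Reverse complement of a nucleotide string
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
rev_comp_chr <- function(x) rev_comp(x)

#' Extract the IMGT CDR3 junction from an annotated contig
#'
#' The junction spans from the first base of the V 2nd-CYS anchor codon
#' through the last base of the J F/W anchor codon, inclusive
#' (`contig[v_anchor .. j_anchor + 2]`).  A rearrangement is productive
#' when the junction is in frame, stop-free, starts with C and ends with
#' F or W.  If the J anchor failed to project (`NA`), the region 3' of
#' the V anchor is scanned for the first in-frame F/W-G-X-G motif and its
#' F/W codon becomes the anchor.
#'
#' @param contig Contig nucleotide string.
#' @param v_anchor,j_anchor 1-based contig positions of the anchor codons
#'   (`j_anchor` may be `NA` to trigger the motif fallback).
#' @return A one-row tibble with `junction`, `junction_aa`, `productive`;
#'   all `NA`/`FALSE` when the anchors are out of order or out of range.
#' @examples
#' extract_cdr3("TGTGCCAGCAGCCTGGGCTTT", 1, 19)
#' @export
extract_cdr3 <- function(contig, v_anchor, j_anchor = NA) {
  L <- nchar(contig)
  fail <- tibble::tibble(junction = NA_character_,
                         junction_aa = NA_character_, productive = FALSE)
  if (is.na(v_anchor) || v_anchor < 1 || v_anchor > L) return(fail)

  if (is.na(j_anchor)) {
    aa <- translate_nt(substr(contig, v_anchor, L))
    m <- regexpr("[FW]G.G", aa)
    if (m == -1) return(fail)
    j_anchor <- v_anchor + 3L * (as.integer(m) - 1L)
  }
  if (j_anchor <= v_anchor || j_anchor + 2L > L) return(fail)

  junction <- substr(contig, v_anchor, j_anchor + 2L)
  junction_aa <- translate_nt(junction)
  tibble::tibble(junction = junction, junction_aa = junction_aa,
                 productive = is_productive_junction(junction, junction_aa))
}

#' Annotate a stream of contigs into an AIRR-style rearrangement table
#'
#' Applies quality control (drop contigs with mean Phred < 20 when
#' qualities are present, or any run of >= 5 N's), assigns V and J
#' segments ([assign_segments()]) and extracts the IMGT junction
#' ([extract_cdr3()]) for every contig, then collapses identical
#' `(v_call, j_call, junction)` rows, summing `duplicate_count`.
#' Nonproductive rows are dropped unless `keep_nonproductive`.  Counts of
#' input, QC-passing, annotated, productive and collapsed records are
#' reported via `message()`.
#'
#' Identical sequences are annotated once and their results shared, so
#' deeply sequenced repertoires with few distinct clones annotate
#' quickly.
#'
#' @param contigs Tibble with columns `contig_id`, `sequence` and
#'   optionally `quality` (e.g. from [read_contigs()] or
#'   [synthesize_reads()]).
#' @param reference Germline tibble, or a prebuilt [kmer_index()].
#' @param keep_nonproductive Keep rows failing the productivity rule.
#' @param min_seed Seed length passed to [assign_segments()].
#' @param quiet Suppress progress messages.
#' @return An AIRR-style tibble with columns `sequence_id`, `v_call`,
#'   `j_call`, `junction`, `junction_aa`, `productive`,
#'   `duplicate_count`.
#' @export
annotate_repertoire <- function(contigs, reference,
                                keep_nonproductive = FALSE,
                                min_seed = 12L, quiet = FALSE) {
  if (!is.data.frame(contigs) || nrow(contigs) == 0) {
    abort("`contigs` must be a non-empty tibble.")
  }
  n_in <- nrow(contigs)

  keep <- rep(TRUE, n_in)
  if ("quality" %in% names(contigs)) {
    mp <- mean_phred(contigs$quality)
    keep <- keep & (is.na(mp) | mp >= 20)
  }
  keep <- keep & !grepl("N{5,}", contigs$sequence)
  contigs <- contigs[keep, ]
  n_qc <- nrow(contigs)
  if (n_qc == 0) abort("no contigs passed quality control.")

  index <- if (inherits(reference, "kmer_index")) reference
           else kmer_index(reference, min_seed)

  uniq <- contigs |>
    dplyr::count(.data$sequence, name = "duplicate_count") |>
    dplyr::left_join(
      contigs |> dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
        dplyr::select("sequence", "contig_id"),
      by = "sequence")

  n_uniq <- nrow(uniq)
  seqs <- uniq$sequence
  v_call <- j_call <- character(n_uniq)
  v_anchor <- j_anchor <- integer(n_uniq)
  for (i in seq_len(n_uniq)) {
    seg <- .assign_segments(seqs[i], index, min_seed = min_seed)
    v_call[i] <- seg$v_call; j_call[i] <- seg$j_call
    v_anchor[i] <- seg$v_anchor; j_anchor[i] <- seg$j_anchor
  }

  # junction = contig[v_anchor .. j_anchor + 2], vectorised; the motif
  # fallback (J anchor missing) goes through extract_cdr3() row-wise
  lens <- nchar(seqs)
  ok <- !is.na(v_anchor) & !is.na(j_anchor) & v_anchor >= 1 &
    j_anchor > v_anchor & (j_anchor + 2L) <= lens
  junction <- rep(NA_character_, n_uniq)
  junction[ok] <- substr(seqs[ok], v_anchor[ok], j_anchor[ok] + 2L)
  fallback <- which(!is.na(v_call) & !is.na(v_anchor) & is.na(j_anchor))
  for (i in fallback) {
    junction[i] <- extract_cdr3(seqs[i], v_anchor[i], NA)$junction
  }
  junction_aa <- rep(NA_character_, n_uniq)
  has_j <- !is.na(junction)
  junction_aa[has_j] <- translate_nt(junction[has_j])
  productive <- rep(FALSE, n_uniq)
  productive[has_j] <- is_productive_junction(junction[has_j],
                                              junction_aa[has_j])

  out <- tibble::tibble(sequence_id = uniq$contig_id,
                        duplicate_count = uniq$duplicate_count,
                        v_call = v_call, j_call = j_call,
                        junction = junction, junction_aa = junction_aa,
                        productive = productive)
  annotated <- !is.na(out$v_call) & !is.na(out$j_call) &
    !is.na(out$junction)
  n_ann <- sum(out$duplicate_count[annotated])
  out <- out[annotated, ]
  if (nrow(out) == 0) abort("no contigs could be annotated.")
  n_prod <- sum(out$duplicate_count[out$productive])
  if (!keep_nonproductive) out <- out[out$productive, ]
  if (nrow(out) == 0) abort("no productive rearrangements found.")

  out <- out |>
    dplyr::group_by(.data$v_call, .data$j_call, .data$junction) |>
    dplyr::summarise(
      sequence_id = dplyr::first(.data$sequence_id),
      junction_aa = dplyr::first(.data$junction_aa),
      productive = dplyr::first(.data$productive),
      duplicate_count = sum(.data$duplicate_count),
      .groups = "drop") |>
    dplyr::arrange(.data$v_call, .data$j_call, .data$junction) |>
    dplyr::select("sequence_id", "v_call", "j_call", "junction",
                  "junction_aa", "productive", "duplicate_count")

  if (!quiet) {
    message(sprintf(
      "annotate_repertoire: %d contigs in, %d passed QC, %d annotated, %d productive, %d clonotypes after collapse",
      n_in, n_qc, n_ann, n_prod, nrow(out)))
  }
  out
}

#' Read sequencing contigs from FASTA/FASTQ
#'
#' @param path Input file; format detected from the extension
#'   (`.fastq`/`.fq` including `.gz` read as FASTQ, else FASTA).
#' @return Tibble with `contig_id`, `sequence` and, for FASTQ, `quality`.
#' @export
read_contigs <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path)
  if (fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    tibble::tibble(
      contig_id = names(x),
      sequence = unname(as.character(x)),
      quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    tibble::tibble(contig_id = names(x),
                   sequence = unname(as.character(x)))
  }
}

#' Write / read an AIRR-style rearrangement TSV
#'
#' Columns follow the AIRR Rearrangement standard (`sequence_id`,
#' `v_call`, `j_call`, `junction`, `junction_aa`, `productive` as T/F,
#' `duplicate_count`).
#'
#' @param rearrangements Tibble from [annotate_repertoire()].
#' @param path File path.
#' @return The tibble (invisibly for the writer).
#' @export
write_airr <- function(rearrangements, path) {
  out <- rearrangements
  out$productive <- ifelse(out$productive, "T", "F")
  readr::write_tsv(out, path)
  invisible(rearrangements)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           productive = readr::col_character()))
  out$productive <- out$productive %in% c("T", "TRUE", "true")
  out
}
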