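#' Build a k-mer seed index over a germline reference
#'
#' Precomputes, for every k-mer of every reference segment, the segment it
#' comes from and its 1-based position.  [assign_segments()] looks contig
#' k-mers up in this index to find candidate segments and seed diagonals
#' before running the banded local aligner.
#'
#' @param reference Germline tibble (see [make_germline_reference()]).
#' @param k Seed length (default 12, the default `min_seed`).
#' @return An opaque index object (environment-backed) reusable across
#'   contigs.
#' @export
kmer_index <- function(reference, k = 12L) {
  validate_germline(reference, require_both = FALSE)
  k <- as.integer(k)
  seqs <- reference$sequence
  lens <- nchar(seqs)
  kmers <- character(0); seg <- integer(0); pos <- integer(0)
  for (i in which(lens >= k)) {
    p <- seq_len(lens[i] - k + 1L)
    kmers <- c(kmers, substring(seqs[i], p, p + k - 1L))
    seg <- c(seg, rep.int(i, length(p)))
    pos <- c(pos, p)
  }
  env <- list2env(split(seq_along(kmers), kmers), hash = TRUE,
                  size = max(length(kmers), 29L))
  structure(list(env = env, seg = seg, pos = pos, k = k,
                 reference = reference,
                 is_v = reference$segment_type == "V"),
            class = "kmer_index")
}

# project a 1-based reference anchor position onto contig coordinates
# through a banded alignment; positions outside the aligned range are
# extrapolated along the alignment ends (valid when no indels lie beyond)
project_anchor <- function(aln, anchor_pos) {
  if (is.na(aln$r_start)) return(NA_integer_)
  map <- aln$ref_to_query
  if (anchor_pos >= aln$r_start && anchor_pos <= aln$r_end) {
    q <- map[anchor_pos]
    if (!is.na(q)) return(q)
    mapped <- which(!is.na(map[seq_len(anchor_pos)]))
    if (length(mapped) == 0) return(NA_integer_)
    left <- max(mapped)
    return(map[left] + (anchor_pos - left))
  }
  if (anchor_pos < aln$r_start) {
    return(aln$q_start - (aln$r_start - anchor_pos))
  }
  aln$q_end + (anchor_pos - aln$r_end)
}

# align the top candidate segments of one type (base-R hot path); ties
# break on score, then longer aligned span, then smaller segment_id
best_segment_hit <- function(contig, index, qp, seg, rp, q_limit = NULL,
                             band = 16L, top_n = 3L) {
  if (length(seg) == 0) return(NULL)
  counts <- table(seg)
  cand <- as.integer(names(sort(counts, decreasing = TRUE)))
  cand <- cand[seq_len(min(length(cand), top_n))]
  sub <- if (is.null(q_limit)) contig else substr(contig, 1L, q_limit)
  if (!nzchar(sub)) return(NULL)
  ref <- index$reference
  best <- NULL
  for (si in cand) {
    sel <- seg == si
    diags <- qp[sel] - rp[sel]
    d0 <- as.integer(stats::median(diags))
    band_eff <- as.integer(min(max(band, diff(range(diags)) + 8L), 48L))
    aln <- .align_banded(sub, ref$sequence[si], d0, band_eff)
    if (is.na(aln$q_start)) next
    span <- aln$r_end - aln$r_start + 1L
    id <- ref$segment_id[si]
    if (is.null(best) ||
        aln$score > best$score ||
        (aln$score == best$score && span > best$span) ||
        (aln$score == best$score && span == best$span && id < best$id)) {
      best <- list(score = aln$score, span = span, id = id, aln = aln,
                   seg = si)
    }
  }
  best
}

# internal workhorse: plain-list variant of assign_segments()
.assign_segments <- function(contig, index, min_seed = 12L, band = 16L,
                             seed_step = 3L) {
  k <- index$k
  L <- nchar(contig)
  if (L < min_seed) abort("contig shorter than `min_seed`.")

  qp <- seq.int(1L, L - k + 1L, by = seed_step)
  if (qp[length(qp)] != L - k + 1L) qp <- c(qp, L - k + 1L)
  km <- substring(contig, qp, qp + k - 1L)
  hit_lists <- lapply(km, get0, envir = index$env, inherits = FALSE)
  n_hits <- lengths(hit_lists)
  ei <- unlist(hit_lists, use.names = FALSE)
  out <- list(v_call = NA_character_, j_call = NA_character_,
              v_score = NA_real_, j_score = NA_real_,
              v_anchor = NA_integer_, j_anchor = NA_integer_)
  if (is.null(ei) || length(ei) == 0) return(out)

  h_qp <- rep.int(qp, n_hits)
  h_seg <- index$seg[ei]
  h_rp <- index$pos[ei]
  is_v <- index$is_v[h_seg]
  ref <- index$reference

  j_best <- best_segment_hit(contig, index, h_qp[!is_v], h_seg[!is_v],
                             h_rp[!is_v], band = band)
  q_limit <- NULL
  if (!is.null(j_best)) {
    out$j_call <- j_best$id
    out$j_score <- j_best$aln$score
    out$j_anchor <- project_anchor(j_best$aln,
                                   ref$anchor_pos[j_best$seg])
    q_limit <- max(j_best$aln$q_start + 2L, min_seed)
  }

  keep_v <- is_v & (if (is.null(q_limit)) TRUE else h_qp <= q_limit)
  v_best <- best_segment_hit(contig, index, h_qp[keep_v], h_seg[keep_v],
                             h_rp[keep_v], q_limit = q_limit, band = band)
  if (!is.null(v_best)) {
    out$v_call <- v_best$id
    out$v_score <- v_best$aln$score
    out$v_anchor <- project_anchor(v_best$aln,
                                   ref$anchor_pos[v_best$seg])
  }
  out
}

#' Assign the best-matching V and J germline segments to a contig
#'
#' Finds exact k-mer seeds shared between the contig and the reference,
#' extends the top candidate segments of each type by banded affine local
#' alignment (match +2, mismatch -2, gap open -5, gap extend -2), and
#' returns the best-scoring V and J together with the conserved anchor
#' codon positions projected onto contig coordinates.  The V segment is
#' searched only 5' of the start of the J alignment.  Ties break on
#' higher score, then longer aligned span, then lexicographically
#' smallest `segment_id`.
#'
#' @param contig A nucleotide string (length >= `min_seed`).
#' @param index A [kmer_index()] (or a germline tibble, which is indexed
#'   on the fly).
#' @param min_seed Seed k-mer length; contigs shorter than this error.
#' @param band Half-width of the alignment band around the seed diagonal.
#' @param seed_step Query k-mer stride (every `seed_step`-th k-mer is
#'   looked up).
#' @return A one-row tibble with `v_call`, `j_call`, `v_score`,
#'   `j_score`, `v_anchor`, `j_anchor` (1-based contig positions, NA on
#'   failure).  Both calls NA means no seed matched (annotation failure).
#' @export
assign_segments <- function(contig, index, min_seed = 12L, band = 16L,
                            seed_step = 3L) {
  if (!inherits(index, "kmer_index")) index <- kmer_index(index, min_seed)
  tibble::as_tibble(.assign_segments(contig, index, min_seed = min_seed,
                                     band = band, seed_step = seed_step))
}
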