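#' Build a per-sample clonotype table from rearrangements
#'
#' Aggregates `duplicate_count` over clonotype keys: V call, J call and
#' the junction at nucleotide (`key_mode = "nt"`) or amino-acid
#' (`key_mode = "aa"`) resolution, and derives frequencies.
#'
#' @param rearrangements AIRR-style tibble (see [annotate_repertoire()]).
#' @param key_mode Junction resolution for the clonotype key.
#' @param sample_id,group Optional labels attached to the table.
#' @return Tibble with `sample_id`, `group`, `v_call`, `j_call`,
#'   `junction` (nt mode only), `junction_aa`, `count`, `frequency`.
#' @export
build_clonotype_table <- function(rearrangements, key_mode = c("nt", "aa"),
                                  sample_id = NA_character_,
                                  group = NA_character_) {
  key_mode <- match.arg(key_mode)
  if (!is.data.frame(rearrangements) || nrow(rearrangements) == 0) {
    abort("`rearrangements` must be a non-empty table.")
  }
  keys <- if (key_mode == "nt") c("v_call", "j_call", "junction") else
    c("v_call", "j_call", "junction_aa")
  grouped <- rearrangements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)))
  out <- if (key_mode == "nt") {
    dplyr::summarise(grouped,
                     junction_aa = dplyr::first(.data$junction_aa),
                     count = sum(.data$duplicate_count), .groups = "drop")
  } else {
    dplyr::summarise(grouped,
                     count = sum(.data$duplicate_count), .groups = "drop")
  }
  out <- dplyr::mutate(out, frequency = .data$count / sum(.data$count))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id, group = group),
                   out)
}

#' Shannon entropy of clonotype frequencies (nats)
#'
#' `H = -sum(p * log(p))`; zero frequencies are dropped and the vector is
#' renormalised, so raw counts are accepted.
#'
#' @param frequencies Non-negative vector with a positive sum.
#' @param base Logarithm base (default `exp(1)`, i.e. nats; use 2 for
#'   bits).
#' @return Entropy, a single number in `[0, log(richness)]`.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # log(2)
#' @export
shannon_entropy <- function(frequencies, base = exp(1)) {
  if (length(frequencies) == 0) abort("`frequencies` must be non-empty.")
  if (any(is.na(frequencies)) || any(frequencies < 0)) {
    abort("`frequencies` must be non-negative.")
  }
  p <- frequencies[frequencies > 0]
  if (length(p) == 0) abort("`frequencies` must have a positive sum.")
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Gini coefficient of a frequency vector
#'
#' Mean absolute difference form
#' `G = sum_ij |x_i - x_j| / (2 n^2 mu)`: scale-invariant, 0 for a
#' perfectly even vector, `(n-1)/n` when a single category holds all
#' mass.
#'
#' @param x Non-negative vector with a positive sum.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini_coefficient(c(3, 1)) # 0.25
#' @export
gini_coefficient <- function(x) {
  if (length(x) == 0 || any(is.na(x)) || any(x < 0) || sum(x) <= 0) {
    abort("`x` must be a non-negative vector with a positive sum.")
  }
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(x))
}

#' Highly expanded clones (HECs)
#'
#' A clonotype is a HEC when its frequency strictly exceeds `threshold`
#' (default 0.1%, reading "more than 0.1%" literally: a frequency of
#' exactly 0.001 is not a HEC).
#'
#' @param clonotypes Clonotype tibble with a `frequency` column.
#' @param threshold HEC frequency threshold in `(0, 1)`.
#' @return List with `hec` (the qualifying rows), `hec_count` and
#'   `hec_cum_freq`.
#' @export
detect_hec <- function(clonotypes, threshold = 0.001) {
  check_number(threshold, "threshold", lower = 0, upper = 1,
               allow_upper = FALSE)
  if (threshold <= 0) abort("`threshold` must lie in (0, 1).")
  hec <- clonotypes[clonotypes$frequency > threshold, ]
  list(hec = hec, hec_count = nrow(hec),
       hec_cum_freq = sum(hec$frequency))
}

#' V/J segment and V-J pair usage
#'
#' Usage frequencies are weighted by read counts, matching repertoire
#' figures whose axes show "frequencies of reads".
#'
#' @param clonotypes Clonotype tibble with `v_call`, `j_call`, `count`.
#' @return List with `v_freqs`, `j_freqs`, `vj_pairs` (long tibbles of
#'   read-weighted frequencies, each summing to 1), `top_vj_pair`
#'   (c(v, j)) and `top_vj_freq`.
#' @export
vj_usage <- function(clonotypes) {
  if (!is.data.frame(clonotypes) || nrow(clonotypes) == 0) {
    abort("`clonotypes` must be non-empty.")
  }
  total <- sum(clonotypes$count)
  v_freqs <- clonotypes |>
    dplyr::count(.data$v_call, wt = .data$count, name = "reads") |>
    dplyr::mutate(frequency = .data$reads / total)
  j_freqs <- clonotypes |>
    dplyr::count(.data$j_call, wt = .data$count, name = "reads") |>
    dplyr::mutate(frequency = .data$reads / total)
  vj_pairs <- clonotypes |>
    dplyr::count(.data$v_call, .data$j_call, wt = .data$count,
                 name = "reads") |>
    dplyr::mutate(frequency = .data$reads / total) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  list(v_freqs = v_freqs, j_freqs = j_freqs, vj_pairs = vj_pairs,
       top_vj_pair = c(vj_pairs$v_call[1], vj_pairs$j_call[1]),
       top_vj_freq = vj_pairs$frequency[1])
}

#' Public clonotypes shared across samples
#'
#' A clonotype key is public when it occurs in at least two distinct
#' samples.  Following the convergent-recombination argument, the default
#' key is the amino-acid junction alone; `key_mode = "nt"` uses the
#' nucleotide junction.
#'
#' @param clonotypes Combined clonotype tibble covering >= 2 samples
#'   (must have `sample_id` and the junction columns).
#' @param key_mode Junction resolution for the sharing key.
#' @return List of class `sharing_summary` with `core_count` (number of
#'   public keys), `petal_counts` (per-sample private-key counts),
#'   `pairwise_overlap` (symmetric matrix of shared-key counts whose
#'   diagonal is per-sample richness) and `public_keys`.
#' @export
public_clonotypes <- function(clonotypes, key_mode = c("aa", "nt")) {
  key_mode <- match.arg(key_mode)
  keyvar <- if (key_mode == "aa") "junction_aa" else "junction"
  samples <- unique(clonotypes$sample_id)
  if (length(samples) < 2) abort("need clonotypes from >= 2 samples.")

  occ <- dplyr::distinct(clonotypes,
                         .data$sample_id, key = .data[[keyvar]])
  per_key <- occ |> dplyr::count(.data$key, name = "n_samples")
  public_keys <- per_key$key[per_key$n_samples >= 2]

  petal_counts <- occ |>
    dplyr::filter(!(.data$key %in% public_keys)) |>
    dplyr::count(.data$sample_id, name = "private") |>
    dplyr::right_join(tibble::tibble(sample_id = samples),
                      by = "sample_id") |>
    dplyr::mutate(private = dplyr::coalesce(.data$private, 0L)) |>
    dplyr::arrange(match(.data$sample_id, samples))

  sets <- split(occ$key, factor(occ$sample_id, levels = samples))
  n <- length(samples)
  ov <- matrix(0L, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) {
    ov[i, i] <- length(sets[[i]])
    for (j in seq_len(n)[-seq_len(i)]) {
      ov[i, j] <- ov[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }

  structure(list(core_count = length(public_keys),
                 petal_counts = petal_counts,
                 pairwise_overlap = ov,
                 public_keys = public_keys,
                 key_mode = key_mode),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d public (%s) keys across %d samples\n",
              x$core_count, x$key_mode, nrow(x$petal_counts)))
  invisible(x)
}

#' @method tidy sharing_summary
#' @export
tidy.sharing_summary <- function(x, ...) {
  dplyr::mutate(x$petal_counts, core_count = x$core_count)
}

#' Per-sample diversity and clonality summary
#'
#' Composes richness, Shannon entropy (nats), clone- and V-J-level Gini
#' coefficients, HEC statistics and the top V-J pair into one record.
#'
#' @param clonotypes One sample's clonotype tibble.
#' @param hec_threshold HEC frequency threshold.
#' @return One-row tibble: `sample_id`, `group`, `richness`, `entropy`,
#'   `gini_clone`, `gini_vj`, `hec_count`, `hec_cum_freq`, `top_v`,
#'   `top_j`, `top_vj_freq`.
#' @export
summarize_sample <- function(clonotypes, hec_threshold = 0.001) {
  if (!is.data.frame(clonotypes) || nrow(clonotypes) == 0) {
    abort("`clonotypes` must be non-empty.")
  }
  usage <- vj_usage(clonotypes)
  hec <- detect_hec(clonotypes, hec_threshold)
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(clonotypes))
      clonotypes$sample_id[1] else NA_character_,
    group = if ("group" %in% names(clonotypes))
      clonotypes$group[1] else NA_character_,
    richness = nrow(clonotypes),
    entropy = shannon_entropy(clonotypes$frequency),
    gini_clone = gini_coefficient(clonotypes$frequency),
    gini_vj = gini_coefficient(usage$vj_pairs$frequency),
    hec_count = hec$hec_count,
    hec_cum_freq = hec$hec_cum_freq,
    top_v = usage$top_vj_pair[1],
    top_j = usage$top_vj_pair[2],
    top_vj_freq = usage$top_vj_freq
  )
}

#' Summarise every sample of a combined clonotype table
#'
#' @param clonotypes Combined clonotype tibble with a `sample_id` column.
#' @param hec_threshold HEC frequency threshold.
#' @return Tibble with one [summarize_sample()] row per sample.
#' @export
summarize_repertoire <- function(clonotypes, hec_threshold = 0.001) {
  clonotypes |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(summarize_sample, hec_threshold = hec_threshold) |>
    dplyr::bind_rows()
}
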