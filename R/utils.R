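DNA_BASES <- c("A", "C", "G", "T")

# random DNA strings with the given lengths (vectorised; length 0 -> "")
random_dna <- function(lens) {
  total <- sum(lens)
  out <- character(length(lens))
  if (total == 0) return(out)
  chars <- sample(DNA_BASES, total, replace = TRUE)
  grp <- rep.int(seq_along(lens), lens)
  filled <- vapply(split(chars, grp), paste, character(1), collapse = "")
  out[lens > 0] <- filled
  out
}

# reverse complement of plain character vectors
rev_comp <- function(x) {
  rc <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(rc, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# translate full codons with the standard genetic code (vectorised over
# all codons of all strings at once); trailing partial codons are
# ignored; codons containing N or other ambiguity letters become "X"
translate_nt <- function(x) {
  gc_tab <- Biostrings::GENETIC_CODE
  nc <- nchar(x) %/% 3L
  nc[is.na(nc)] <- 0L
  out <- character(length(x))
  if (sum(nc) == 0) return(out)
  idx <- rep.int(seq_along(x), nc)
  starts <- (sequence(nc) - 1L) * 3L + 1L
  aa <- unname(gc_tab[substring(x[idx], starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  out[unique(idx)] <- vapply(split(aa, idx), paste, character(1),
                             collapse = "")
  out
}

# IMGT-style productivity: in-frame junction, no stop, runs C...F/W
is_productive_junction <- function(junction_nt, junction_aa) {
  in_frame <- nchar(junction_nt) %% 3L == 0L & nchar(junction_nt) > 0L
  ok_aa <- !grepl("*", junction_aa, fixed = TRUE) &
    grepl("^C", junction_aa) & grepl("[FW]$", junction_aa)
  in_frame & ok_aa
}

# decode Sanger Phred+33 quality strings to numeric means
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      (if (allow_upper) x > upper else x >= upper)) {
    abort(sprintf("`%s` must be a number in [%s, %s%s.", name,
                  format(lower), format(upper),
                  if (allow_upper) "]" else ")"))
  }
  invisible(x)
}
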