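# shared small fixtures, built in code at test time

tiny_reference <- function(seed = 101) {
  make_germline_reference(6, 3, seed = seed)
}

# quick clonotype table from counts; junctions made distinct per row
clonotype_fixture <- function(counts, sample_id = "S1", group = NA,
                              v_call = NULL, j_call = NULL,
                              junction_aa = NULL) {
  n <- length(counts)
  tibble::tibble(
    sample_id = sample_id, group = group,
    v_call = v_call %||% rep("TRBV1", n),
    j_call = j_call %||% rep("TRBJ1", n),
    junction = strrep("TGC", seq_len(n)),
    junction_aa = junction_aa %||% strrep("C", seq_len(n)),
    count = counts,
    frequency = counts / sum(counts)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
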