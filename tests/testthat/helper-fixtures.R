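# Small in-code fixtures shared across tests.

make_cells <- function(x, y, labels, slice_id = "s1", mouse_id = "m1",
                       rc_level = "rostral", hemisphere = "ipsi",
                       cell_id = NULL) {
  n <- length(x)
  data.frame(
    cell_id = cell_id %||% sprintf("c%03d", seq_len(n)),
    mouse_id = rep_len(mouse_id, n), slice_id = rep_len(slice_id, n),
    rc_level = rep_len(rc_level, n), hemisphere = rep_len(hemisphere, n),
    x_um = x, y_um = y, labels = rep_len(labels, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-pathway model set with boosted counts for recovery tests
recovery_pathways <- function(ref_count = 2000, alm_count = 400) {
  pw <- default_pathways(c("iRSP", "ALM"))
  pw$iRSP$count_by_rc[] <- ref_count
  pw$ALM$count_by_rc[] <- alm_count
  pw
}
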