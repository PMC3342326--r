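# Small in-code fixtures shared across test files.

# uniformly spaced marker map: `spacing` cM between adjacent markers
make_map <- function(n, spacing = 0.01, chrom = "1", b_freq = 0.5) {
  marker_map(sprintf("m%04d", seq_len(n)), chrom,
             pos_bp = as.integer(seq_len(n) * 1000L),
             pos_cM = (seq_len(n) - 1L) * spacing,
             b_freq = b_freq)
}

make_panel <- function(alleles, spacing = 0.01, b_freq = 0.5,
                       origin = "SIMULATED") {
  haplotype_panel(alleles, make_map(ncol(alleles), spacing, b_freq = b_freq),
                  origin = origin)
}

# i.i.d. Bernoulli panel (no LD) on a dense map
random_panel <- function(n_haps, n_markers, p_b = 0.5, spacing = 0.01) {
  make_panel(matrix(rbinom(n_haps * n_markers, 1L, p_b), nrow = n_haps),
             spacing = spacing, b_freq = p_b)
}

# canonical small segment row for segment_score()
seg_row <- function(hap1_idx, start_idx, end_idx) {
  list(hap1_idx = hap1_idx, start_idx = start_idx, end_idx = end_idx)
}

# compare two segment tables as sets of (unordered id pair, start, end)
segment_key <- function(seg) {
  a <- pmin(seg$hap1_id, seg$hap2_id)
  b <- pmax(seg$hap1_id, seg$hap2_id)
  sort(paste(a, b, seg$start_idx, seg$end_idx))
}
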