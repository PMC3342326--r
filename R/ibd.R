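#' IBD matching parameters
#'
#' Settings of the seed-and-extend pairwise matcher. Defaults follow the
#' stringent configuration appropriate for near-error-free haplotypes read
#' off LOH regions: a minimum match length of 0.4 cM so that short founder
#' segments remain detectable, no tolerated mismatching markers, and short
#' 5-marker seed words for accurate IBD boundaries.
#'
#' @param min_m minimum genetic length of a reported match, cM.
#' @param err_hom allowed mismatching markers within a match (0 = exact).
#' @param bits number of markers per exact-matching seed word.
#' @return list of class `match_params`.
#' @export
match_params <- function(min_m = 0.4, err_hom = 0L, bits = 5L) {
  stopifnot(min_m > 0, err_hom >= 0L, bits >= 1L, bits <= 31L)
  structure(list(min_m = as.numeric(min_m), err_hom = as.integer(err_hom),
                 bits = as.integer(bits)),
            class = "match_params")
}

#' @method print match_params
#' @export
print.match_params <- function(x, ...) {
  cat(sprintf("<match_params> min_m = %g cM, err_hom = %d, bits = %d\n",
              x$min_m, x$err_hom, x$bits))
  invisible(x)
}

segment_table <- function(hap1_idx, hap2_idx, start_idx, end_idx, panel) {
  cm <- panel$markers$pos_cM
  ids <- haplotype_ids(panel)
  df <- data.frame(
    hap1_id = ids[hap1_idx], hap2_id = ids[hap2_idx],
    hap1_idx = as.integer(hap1_idx), hap2_idx = as.integer(hap2_idx),
    start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
    length_cM = cm[end_idx] - cm[start_idx],
    score = rep(NA_real_, length(hap1_idx)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$hap1_id, df$hap2_id, df$start_idx), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Detect pairwise IBD segments in a phased panel
#'
#' Seed-and-extend matcher: markers are partitioned into consecutive words
#' of `bits` markers; haplotype pairs sharing a word value are extended over
#' consecutive identical words and then marker-by-marker at both flanks,
#' and each maximal shared segment of genetic length at least `min_m` cM is
#' reported exactly once per pair. With `err_hom = 0` the output equals the
#' set of maximal identical runs containing at least one fully aligned seed
#' word (see [brute_force_ibd()] for the exhaustive oracle).
#'
#' @param panel a [haplotype_panel()] with at least 2 haplotypes, complete
#'   alleles (run [drop_unreliable_markers()] first) and cM positions.
#' @param params a [match_params()].
#' @return data frame of class `ibd_segments` with columns `hap1_id`,
#'   `hap2_id`, `hap1_idx`, `hap2_idx`, `start_idx`, `end_idx` (inclusive
#'   marker indices), `length_cM` and `score` (NA until scored), sorted by
#'   (hap1_id, hap2_id, start_idx).
#' @export
find_pairwise_ibd <- function(panel, params = match_params()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(params, "match_params"))
  if (nrow(panel$alleles) < 2L)
    stop("panel must contain at least 2 haplotypes")
  if (anyNA(panel$alleles))
    stop("panel has missing alleles; run drop_unreliable_markers() first")
  if (anyNA(panel$markers$pos_cM))
    stop("marker map has no cM positions; attach a genetic map first")
  hits <- .ibd_match_cpp(panel$alleles, panel$markers$pos_cM,
                         params$bits, params$min_m, params$err_hom)
  segment_table(hits$hap1, hits$hap2, hits$start, hits$end, panel)
}

#' Exhaustive pairwise IBD oracle
#'
#' Scans every haplotype pair for maximal runs of identical alleles and
#' reports those of genetic length at least `min_m` cM. Quadratic in panel
#' size and linear in markers; intended for small panels as the independent
#' reference for [find_pairwise_ibd()] (`err_hom` is ignored: runs are
#' exact).
#'
#' @inheritParams find_pairwise_ibd
#' @return Same segment table as [find_pairwise_ibd()], identically sorted.
#' @export
brute_force_ibd <- function(panel, params = match_params()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(params, "match_params"))
  al <- panel$alleles
  cm <- panel$markers$pos_cM
  H <- nrow(al)
  i_out <- integer(0); j_out <- integer(0)
  s_out <- integer(0); e_out <- integer(0)
  for (i in seq_len(H - 1L)) {
    for (j in (i + 1L):H) {
      eq <- al[i, ] == al[j, ]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & (cm[ends] - cm[starts] >= params$min_m)
      if (any(keep)) {
        i_out <- c(i_out, rep.int(i, sum(keep)))
        j_out <- c(j_out, rep.int(j, sum(keep)))
        s_out <- c(s_out, starts[keep])
        e_out <- c(e_out, ends[keep])
      }
    }
  }
  segment_table(i_out, j_out, s_out, e_out, panel)
}
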