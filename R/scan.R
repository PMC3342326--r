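#' Genome scan for significantly recurrent IBD in tumor haplotypes
#'
#' The central fitting function of the package. Given a panel of tumor
#' haplotypes (read off LOH regions) and a reference panel of phased
#' haplotypes from the same population, it (i) estimates B-allele
#' frequencies from the reference, (ii) detects pairwise IBD segments
#' among the tumor haplotypes with the seed-and-extend matcher,
#' (iii) scores each segment by the improbability of its shared alleles
#' and sums scores per SNP, (iv) calibrates a per-SNP Gumbel null by
#' rescanning `n_subsets` random reference subsets of the same size, and
#' (v) converts tumor scores to Gumbel p-values and Benjamini-Hochberg
#' q-values.
#'
#' @param tumor a [haplotype_panel()] of tumor haplotypes.
#' @param reference a [haplotype_panel()] on the same marker scaffold with
#'   at least as many haplotypes as `tumor`.
#' @param params a [match_params()].
#' @param n_subsets number of resampled null subsets (default 100).
#' @param q_threshold significance threshold stored for reporting methods.
#' @param seed integer seed for the null resampling.
#' @return Object of class `ft_scan` with elements `track` (a
#'   [score_track()]), `segments`, `null`, `params`, `q_threshold` and
#'   `call`. Methods: [print.ft_scan()], [summary.ft_scan()],
#'   [plot.ft_scan()], [coef.ft_scan()].
#' @seealso [dash_scan()] for the cluster-plus-Fisher benchmark.
#' @export
ft_scan <- function(tumor, reference, params = match_params(),
                    n_subsets = 100L, q_threshold = 0.01, seed = NULL) {
  stopifnot(inherits(tumor, "haplotype_panel"),
            inherits(reference, "haplotype_panel"))
  if (!identical(tumor$markers$marker_id, reference$markers$marker_id))
    stop("tumor and reference panels are on different marker scaffolds")
  if (nrow(reference$alleles) < nrow(tumor$alleles))
    stop("reference panel is smaller than the tumor panel")
  if (anyNA(tumor$alleles)) {
    keep <- which(colSums(is.na(tumor$alleles)) == 0L)
    if (!length(keep)) stop("no fully observed markers in the tumor panel")
    tumor <- tumor[, keep]
    reference <- reference[, keep]
  }
  mm <- estimate_b_freqs(reference)
  tumor$markers <- mm
  segments <- find_pairwise_ibd(tumor, params)
  cost <- allele_cost_cumsum(tumor$alleles, mm$b_freq)
  segments <- score_segments(segments, cost)
  track <- score_track(mm, per_snp_scores_vec(segments, nrow(mm)))
  null <- build_null(reference, nrow(tumor$alleles), params,
                     n_subsets = n_subsets, seed = seed,
                     b_freq = mm$b_freq)
  track <- score_pvalues(track, null)
  track$q_value <- bh_qvalues(track$p_value)
  structure(list(track = track, segments = segments, null = null,
                 params = params, q_threshold = q_threshold,
                 n_tumor = nrow(tumor$alleles),
                 n_reference = nrow(reference$alleles),
                 call = match.call()),
            class = "ft_scan")
}

#' @method print ft_scan
#' @export
print.ft_scan <- function(x, ...) {
  cat("IBD founder-haplotype scan\n")
  cat(sprintf("  %d tumor haplotypes vs %d reference haplotypes, %d markers\n",
              x$n_tumor, x$n_reference, nrow(x$track)))
  cat(sprintf("  %d pairwise IBD segments (min_m = %g cM, err_hom = %d)\n",
              nrow(x$segments), x$params$min_m, x$params$err_hom))
  sig <- significant_regions(x$track, x$q_threshold)
  cat(sprintf("  %d significant region(s) at q <= %g\n",
              nrow(sig), x$q_threshold))
  invisible(x)
}

#' Summarise an IBD scan
#'
#' Reports the significant regions, segment-length statistics and, when
#' pairwise segments exist, the generation-count estimate implied by their
#' mean genetic length.
#'
#' @param object an `ft_scan`.
#' @param q_threshold threshold overriding the one stored in the scan.
#' @param ... unused.
#' @return list of class `summary.ft_scan`.
#' @export
summary.ft_scan <- function(object, q_threshold = object$q_threshold, ...) {
  regions <- significant_regions(object$track, q_threshold)
  mean_len <- if (nrow(object$segments)) mean(object$segments$length_cM)
              else NA_real_
  out <- list(
    n_tumor = object$n_tumor, n_reference = object$n_reference,
    n_markers = nrow(object$track), n_segments = nrow(object$segments),
    mean_segment_cM = mean_len,
    generations = if (is.na(mean_len)) NA_real_
                  else estimate_generations(mean_len),
    q_threshold = q_threshold, regions = regions
  )
  class(out) <- "summary.ft_scan"
  out
}

#' @method print summary.ft_scan
#' @export
print.summary.ft_scan <- function(x, ...) {
  cat("IBD founder-haplotype scan summary\n")
  cat(sprintf("  haplotypes: %d tumor, %d reference; markers: %d\n",
              x$n_tumor, x$n_reference, x$n_markers))
  cat(sprintf("  pairwise IBD segments: %d (mean length %.2f cM)\n",
              x$n_segments, x$mean_segment_cM))
  if (!is.na(x$generations))
    cat(sprintf("  implied founder age: ~%.1f generations (1/(2L) Morgans)\n",
                x$generations))
  cat(sprintf("  significant regions at q <= %g: %d\n",
              x$q_threshold, nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Per-marker Gumbel null parameters of a scan
#' @param object an `ft_scan`.
#' @param ... unused.
#' @return data frame with `marker_id`, `mu`, `beta`.
#' @export
coef.ft_scan <- function(object, ...) {
  data.frame(marker_id = object$null$marker_id, mu = object$null$mu,
             beta = object$null$beta, stringsAsFactors = FALSE)
}

#' Plot an IBD scan
#'
#' Two stacked panels along the genetic map: the per-SNP IBD score and
#' `-log10` q-value with the significance threshold.
#'
#' @param x an `ft_scan`.
#' @param ... passed to the underlying [plot()] calls.
#' @return Invisibly, `x`.
#' @method plot ft_scan
#' @export
plot.ft_scan <- function(x, ...) {
  tr <- x$track
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$pos_cM, tr$ibd_score, type = "l", xlab = "",
                 ylab = "IBD score", ...)
  graphics::lines(tr$pos_cM, x$null$mu, col = "grey60", lty = 2)
  graphics::plot(tr$pos_cM, -log10(pmax(tr$q_value, 1e-300)), type = "l",
                 xlab = "position (cM)", ylab = "-log10 q", ...)
  graphics::abline(h = -log10(x$q_threshold), col = "red", lty = 2)
  invisible(x)
}
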