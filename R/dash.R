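#' Cluster shared haplotypes in genomic windows
#'
#' Benchmark clustering in the style of haplotype-cluster association
#' methods: the chromosome is tiled into windows of `window_cM`; within
#' each window two haplotypes are connected when a pairwise IBD segment
#' fully spans the window, and clusters are the connected components with
#' at least `min_cluster` members. Clusters with identical member sets in
#' consecutive windows are merged into one cluster spanning the window
#' range.
#'
#' @param segments an `ibd_segments` table from [find_pairwise_ibd()] run
#'   on the combined tumor + reference panel.
#' @param combined_panel the [haplotype_panel()] the segments refer to.
#' @param n_tumor number of tumor haplotypes (the first `n_tumor` rows of
#'   the combined panel).
#' @param min_cluster minimal cluster size (default 2).
#' @param window_cM window width in cM (default 0.2).
#' @return data frame of class `hap_clusters`: `win_start`, `win_end`
#'   (window indices), `start_cM`, `end_cM`, `n_tumor`, `n_reference` and
#'   list-column `members` (haplotype row indices).
#' @export
dash_clusters <- function(segments, combined_panel, n_tumor,
                          min_cluster = 2L, window_cM = 0.2) {
  cm <- combined_panel$markers$pos_cM
  cm0 <- cm - cm[1L]
  n_win <- max(1L, floor((cm0[length(cm0)] + 1e-12) / window_cM))
  empty <- data.frame(win_start = integer(), win_end = integer(),
                      start_cM = numeric(), end_cM = numeric(),
                      n_tumor = integer(), n_reference = integer())
  empty$members <- I(list())
  class(empty) <- c("hap_clusters", "data.frame")
  if (!nrow(segments)) return(empty)
  # windows fully contained in [start, end] of each segment
  s_cm <- cm0[segments$start_idx]
  e_cm <- cm0[segments$end_idx]
  w_first <- pmax(1L, ceiling(s_cm / window_cM - 1e-9) + 1L)
  w_last <- pmin(n_win, floor(e_cm / window_cM + 1e-9))
  keep <- which(w_first <= w_last)
  if (!length(keep)) return(empty)
  n_each <- w_last[keep] - w_first[keep] + 1L
  win <- unlist(lapply(seq_along(keep),
                       function(k) seq.int(w_first[keep[k]],
                                           w_last[keep[k]])))
  h1 <- rep.int(segments$hap1_idx[keep], n_each)
  h2 <- rep.int(segments$hap2_idx[keep], n_each)
  o <- order(win)
  comp <- .window_components_cpp(win[o], h1[o], h2[o],
                                 nrow(combined_panel$alleles))
  # group members by (window, component root)
  grp <- split(comp$hap, paste(comp$win, comp$root, sep = ":"))
  grp <- grp[lengths(grp) >= min_cluster]
  if (!length(grp)) return(empty)
  wins <- as.integer(sub(":.*", "", names(grp)))
  keys <- vapply(grp, paste, character(1L), collapse = ",")
  o <- order(keys, wins)
  wins <- wins[o]; keys <- keys[o]; grp <- grp[o]
  # merge runs of consecutive windows with identical member sets
  new_run <- c(TRUE, keys[-1L] != keys[-length(keys)] |
                 wins[-1L] != wins[-length(wins)] + 1L)
  run_id <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, length(run_id))
  members <- grp[first]
  n_t <- vapply(members, function(m) sum(m <= n_tumor), integer(1L))
  out <- data.frame(win_start = wins[first], win_end = wins[last],
                    start_cM = cm[1L] + (wins[first] - 1L) * window_cM,
                    end_cM = cm[1L] + wins[last] * window_cM,
                    n_tumor = n_t,
                    n_reference = lengths(members) - n_t)
  out$members <- I(unname(members))
  o <- order(out$win_start, out$win_end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_windows") <- n_win
  attr(out, "window_cM") <- window_cM
  class(out) <- c("hap_clusters", "data.frame")
  out
}

#' One-sided Fisher enrichment of a cluster in tumors
#'
#' Hypergeometric upper-tail probability that a cluster of
#' `n_tumor + n_reference` haplotypes drawn from the combined panel would
#' contain at least the observed number of tumor haplotypes — the
#' one-sided Fisher exact test for tumor enrichment of the 2x2 table
#' (in-cluster / out-of-cluster) x (tumor / reference).
#'
#' @param cluster list or row with `n_tumor` and `n_reference` counts.
#' @param n_tumor_total,n_ref_total panel-wide totals.
#' @return p-value.
#' @examples
#' fisher_enrichment(list(n_tumor = 2, n_reference = 0), 2, 2)  # 1/6
#' @export
fisher_enrichment <- function(cluster, n_tumor_total, n_ref_total) {
  k <- cluster$n_tumor
  size <- cluster$n_tumor + cluster$n_reference
  if (any(k > n_tumor_total) || any(cluster$n_reference > n_ref_total))
    stop("cluster counts exceed panel totals")
  ifelse(size == 0L, 1,
         stats::phyper(k - 1L, n_tumor_total, n_ref_total, size,
                       lower.tail = FALSE))
}

#' Cluster-plus-Fisher benchmark scan
#'
#' Frequency-based benchmark for recurrent-haplotype detection: pairwise
#' IBD is detected on the combined tumor + reference panel, shared
#' haplotypes are clustered per window ([dash_clusters()]), each cluster
#' is tested for tumor enrichment with a one-sided Fisher exact test, and
#' q-values (BH across clusters) are projected onto markers as the minimum
#' q of any cluster whose window covers the marker. Unlike the IBD-score
#' scan, the association test ignores haplotype length, which costs power
#' at low prevalence.
#'
#' @inheritParams ft_scan
#' @param window_cM,min_cluster clustering settings, see [dash_clusters()].
#' @return Object of class `dash_scan` with `track` (a [score_track()]
#'   whose `ibd_score` column holds the per-marker cluster count),
#'   `clusters`, `params` and `q_threshold`.
#' @export
dash_scan <- function(tumor, reference, params = match_params(),
                      window_cM = 0.2, min_cluster = 2L,
                      q_threshold = 0.01) {
  stopifnot(inherits(tumor, "haplotype_panel"),
            inherits(reference, "haplotype_panel"))
  if (!identical(tumor$markers$marker_id, reference$markers$marker_id))
    stop("tumor and reference panels are on different marker scaffolds")
  n_t <- nrow(tumor$alleles)
  n_r <- nrow(reference$alleles)
  combined <- haplotype_panel(
    rbind(tumor$alleles, reference$alleles), tumor$markers,
    haplotype_ids = make.unique(c(haplotype_ids(tumor),
                                  haplotype_ids(reference))),
    origin = "TUMOR")
  segments <- find_pairwise_ibd(combined, params)
  clusters <- dash_clusters(segments, combined, n_tumor = n_t,
                            min_cluster = min_cluster,
                            window_cM = window_cM)
  mm <- tumor$markers
  n_mark <- nrow(mm)
  if (nrow(clusters)) {
    clusters$p_value <- fisher_enrichment(clusters, n_t, n_r)
    clusters$q_value <- bh_qvalues(clusters$p_value)
    n_win <- attr(clusters, "n_windows")
    win_q <- rep(1, n_win)
    win_cov <- integer(n_win)
    for (k in seq_len(nrow(clusters))) {
      w <- clusters$win_start[k]:clusters$win_end[k]
      win_q[w] <- pmin(win_q[w], clusters$q_value[k])
      win_cov[w] <- win_cov[w] + 1L
    }
    cm0 <- mm$pos_cM - mm$pos_cM[1L]
    m_win <- pmin(n_win, floor(cm0 / window_cM) + 1L)
    q_marker <- win_q[m_win]
    cov_marker <- win_cov[m_win]
  } else {
    q_marker <- rep(1, n_mark)
    cov_marker <- integer(n_mark)
  }
  track <- score_track(mm, as.numeric(cov_marker),
                       p_value = q_marker, q_value = q_marker)
  structure(list(track = track, clusters = clusters, params = params,
                 window_cM = window_cM, min_cluster = min_cluster,
                 q_threshold = q_threshold, n_tumor = n_t,
                 n_reference = n_r, call = match.call()),
            class = "dash_scan")
}

#' @method print dash_scan
#' @export
print.dash_scan <- function(x, ...) {
  cat("cluster + Fisher benchmark scan\n")
  cat(sprintf("  %d tumor vs %d reference haplotypes; %d clusters\n",
              x$n_tumor, x$n_reference, nrow(x$clusters)))
  nsig <- if (nrow(x$clusters))
    sum(x$clusters$q_value <= x$q_threshold) else 0L
  cat(sprintf("  %d cluster(s) significant at q <= %g\n",
              nsig, x$q_threshold))
  invisible(x)
}

#' @export
summary.dash_scan <- function(object, ...) {
  sig <- significant_regions(object$track, object$q_threshold)
  cat("cluster + Fisher benchmark scan\n")
  cat(sprintf("  clusters: %d; significant marker regions: %d\n",
              nrow(object$clusters), nrow(sig)))
  invisible(list(clusters = object$clusters, regions = sig))
}
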