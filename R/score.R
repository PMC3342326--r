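#' Per-SNP IBD score track
#'
#' One row per marker with the summed IBD score and, once a null has been
#' applied, its Gumbel p-value and Benjamini-Hochberg q-value.
#'
#' @param markers a [marker_map()].
#' @param ibd_score non-negative score per marker.
#' @param p_value,q_value per-marker significance (NA until computed).
#' @return data frame of class `score_track`.
#' @export
score_track <- function(markers, ibd_score, p_value = NA_real_,
                        q_value = NA_real_) {
  validate_marker_map(markers)
  n <- nrow(markers)
  stopifnot(length(ibd_score) == n)
  if (any(ibd_score < 0)) stop("ibd_score must be non-negative")
  df <- data.frame(as.data.frame(markers),
                   ibd_score = as.numeric(ibd_score),
                   p_value = rep_len(as.numeric(p_value), n),
                   q_value = rep_len(as.numeric(q_value), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("score_track", "data.frame")
  df
}

# per-haplotype cumulative allele-cost matrix; cost(h, i) = -2 ln f(H_i)
# with f the clamped population frequency of the allele carried.
allele_cost_cumsum <- function(alleles, b_freq) {
  f <- pmin(pmax(b_freq, FREQ_EPS), 1 - FREQ_EPS)
  cost_b <- -2 * log(f)
  cost_a <- -2 * log(1 - f)
  cost <- t(ifelse(t(alleles) == 1L, cost_b, cost_a))
  t(apply(cost, 1L, cumsum))
}

#' Score of a single pairwise IBD segment
#'
#' The score of a shared segment is minus twice the log-probability of
#' drawing the observed alleles independently at each covered SNP:
#' `S = -sum_i 2 ln f(H_i)`, where `f(H_i)` is the population frequency of
#' the allele carried at SNP i (the B-allele frequency if B, its complement
#' if A), clamped to `[1e-4, 1 - 1e-4]`. A long segment of rare alleles is
#' thus unlikely to be identical by chance and scores high; `S >= 0` always.
#'
#' @param segment one row of an `ibd_segments` table (list or data frame
#'   with `hap1_idx`, `start_idx`, `end_idx`).
#' @param panel the [haplotype_panel()] the segment was found in.
#' @param markers a [marker_map()] with `b_freq` filled (defaults to the
#'   panel's own map).
#' @return Non-negative score.
#' @examples
#' mm <- marker_map(c("a", "b"), "1", c(1L, 2L), pos_cM = c(0, 1),
#'                  b_freq = c(0.5, 0.2))
#' p <- haplotype_panel(rbind(c(1, 1), c(1, 1)), mm)
#' seg <- list(hap1_idx = 1L, start_idx = 1L, end_idx = 2L)
#' segment_score(seg, p)  # -2 (ln 0.5 + ln 0.2) = 4.605
#' @export
segment_score <- function(segment, panel, markers = panel$markers) {
  idx <- segment$start_idx:segment$end_idx
  bf <- markers$b_freq[idx]
  if (anyNA(bf)) stop("b_freq undefined for covered marker(s)")
  f <- pmin(pmax(bf, FREQ_EPS), 1 - FREQ_EPS)
  a <- panel$alleles[segment$hap1_idx, idx]
  -2 * sum(log(ifelse(a == 1L, f, 1 - f)))
}

# vectorized scoring of a whole segment table against a precomputed
# cumulative cost matrix (rows aligned with the panel's haplotypes)
score_segments <- function(segments, cost_cumsum) {
  if (!nrow(segments)) return(segments)
  h <- segments$hap1_idx
  s <- segments$start_idx
  e <- segments$end_idx
  tot <- cost_cumsum[cbind(h, e)] -
    ifelse(s > 1L, cost_cumsum[cbind(h, pmax(s - 1L, 1L))], 0)
  segments$score <- tot
  segments
}

#' Sum segment scores into a per-SNP track
#'
#' The IBD score of SNP i is the sum of the scores of all pairwise IBD
#' segments containing i; markers covered by no segment score 0.
#'
#' @param segments a scored `ibd_segments` table.
#' @param markers the [marker_map()] the indices refer to.
#' @return A [score_track()] with scores only.
#' @export
per_snp_scores <- function(segments, markers) {
  score_track(markers, per_snp_scores_vec(segments, nrow(markers)))
}

per_snp_scores_vec <- function(segments, n_markers) {
  acc <- numeric(n_markers + 1L)
  if (nrow(segments)) {
    if (anyNA(segments$score)) stop("segments must be scored first")
    d <- rowsum(c(segments$score, -segments$score),
                c(segments$start_idx, segments$end_idx + 1L))
    acc[as.integer(rownames(d))] <- d[, 1L]
  }
  # clamp float cancellation noise at uncovered markers
  pmax(cumsum(acc)[seq_len(n_markers)], 0)
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits the type-I extreme value (Gumbel) distribution,
#' `F(x) = exp(-exp(-(x - mu)/beta))`, by maximum likelihood. The scale is
#' solved by damped fixed-point iteration of the profile likelihood
#' equation starting from the method-of-moments value
#' (`beta = s sqrt(6)/pi`, `mu = xbar - gamma beta`); the location then
#' follows in closed form.
#'
#' @param values numeric sample, at least 2 distinct values.
#' @param tol relative convergence tolerance on the scale.
#' @return list `(mu, beta)`.
#' @export
fit_gumbel <- function(values, tol = 1e-10) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 values")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate (constant) sample")
  beta <- s * sqrt(6) / pi
  xb <- mean(x)
  for (iter in 1:200) {
    w <- exp(-(x - min(x)) / beta)
    beta_new <- xb - sum(x * w) / sum(w)
    if (!is.finite(beta_new) || beta_new <= 0) break
    done <- abs(beta_new - beta) <= tol * beta
    beta <- beta_new
    if (done) break
  }
  xm <- min(x)
  mu <- xm - beta * log(mean(exp(-(x - xm) / beta)))
  list(mu = mu, beta = beta)
}

# column-wise ML Gumbel fit for a subsets x markers score matrix;
# degenerate (constant) columns get beta = eps and are flagged.
fit_gumbel_matrix <- function(X, tol = 1e-8, max_iter = 100L,
                              eps = 1e-6) {
  n <- nrow(X)
  xb <- colMeans(X)
  s2 <- colMeans(X^2) - xb^2
  s <- sqrt(pmax(s2, 0) * n / (n - 1L))
  degenerate <- s < .Machine$double.eps^0.5 * (abs(xb) + 1)
  beta <- pmax(s * sqrt(6) / pi, eps)
  xmin <- apply(X, 2L, min)
  Xc <- sweep(X, 2L, xmin)  # shift for exp() stability
  live <- !degenerate
  for (iter in seq_len(max_iter)) {
    if (!any(live)) break
    W <- exp(-sweep(Xc[, live, drop = FALSE], 2L, beta[live], "/"))
    bnew <- xb[live] - colSums(Xc[, live, drop = FALSE] * W) / colSums(W) -
      xmin[live]
    bad <- !is.finite(bnew) | bnew <= 0
    bnew[bad] <- beta[live][bad]
    conv <- abs(bnew - beta[live]) <= tol * beta[live]
    beta[live] <- bnew
    live[live] <- !(conv | bad)
  }
  W <- exp(-sweep(Xc, 2L, beta, "/"))
  mu <- xmin - beta * log(colMeans(W))
  mu[degenerate] <- xb[degenerate]
  beta[degenerate] <- eps
  list(mu = mu, beta = beta, degenerate = degenerate)
}

#' Resampled Gumbel null distribution of per-SNP IBD scores
#'
#' Builds the per-marker null by repeatedly (i) sampling
#' `tumor_panel_size` haplotypes without replacement from the reference
#' panel, (ii) running the pairwise matcher and summing per-SNP scores on
#' the subset, and (iii) fitting a Gumbel distribution marker-by-marker to
#' the resulting subset scores. Because the null subsets are scored with the
#' same matcher, frequency table and score as the tumor set, linkage
#' disequilibrium and local allele-frequency structure are absorbed into
#' the null.
#'
#' @param reference a [haplotype_panel()] of reference haplotypes with cM
#'   positions; must contain at least `tumor_panel_size` haplotypes.
#' @param tumor_panel_size number of haplotypes per null subset (the size
#'   of the tumor set).
#' @param params a [match_params()].
#' @param n_subsets number of resampled subsets (>= 2; 100 by default).
#' @param seed integer seed making the resampling reproducible.
#' @param b_freq optional frequency vector; defaults to frequencies
#'   estimated from `reference` via [estimate_b_freqs()].
#' @return object of class `gumbel_null`: per-marker `mu`, `beta`,
#'   `degenerate` flag, plus `n_subsets` and `subset_size`.
#' @export
build_null <- function(reference, tumor_panel_size, params = match_params(),
                       n_subsets = 100L, seed = NULL, b_freq = NULL) {
  stopifnot(inherits(reference, "haplotype_panel"))
  n_ref <- nrow(reference$alleles)
  if (tumor_panel_size > n_ref)
    stop("reference panel smaller than requested subset size")
  if (n_subsets < 2L) stop("n_subsets must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(b_freq)) b_freq <- estimate_b_freqs(reference)$b_freq
  mm <- reference$markers
  mm$b_freq <- b_freq
  n_mark <- nrow(mm)
  cost <- allele_cost_cumsum(reference$alleles, b_freq)
  scores <- matrix(0, nrow = n_subsets, ncol = n_mark)
  for (b in seq_len(n_subsets)) {
    idx <- sample.int(n_ref, tumor_panel_size)
    sub <- reference[idx, ]
    seg <- find_pairwise_ibd(sub, params)
    if (nrow(seg)) {
      # map subset haplotype rows back to reference cost rows
      seg$hap1_idx <- idx[seg$hap1_idx]
      seg <- score_segments(seg, cost)
      scores[b, ] <- per_snp_scores_vec(seg, n_mark)
    }
  }
  fit <- fit_gumbel_matrix(scores)
  structure(list(marker_id = mm$marker_id, mu = fit$mu, beta = fit$beta,
                 degenerate = fit$degenerate,
                 n_subsets = as.integer(n_subsets),
                 subset_size = as.integer(tumor_panel_size)),
            class = "gumbel_null")
}

#' @method print gumbel_null
#' @export
print.gumbel_null <- function(x, ...) {
  cat(sprintf(
    "<gumbel_null> %d markers; %d subsets of %d haplotypes; %d degenerate\n",
    length(x$mu), x$n_subsets, x$subset_size, sum(x$degenerate)))
  invisible(x)
}

#' Persist / load a Gumbel null as TSV
#' @param null a `gumbel_null` (see [build_null()]).
#' @param path file path.
#' @return Invisibly `path`; `read_gumbel_null()` returns a `gumbel_null`.
#' @export
write_gumbel_null <- function(null, path) {
  df <- data.frame(marker_id = null$marker_id, mu = null$mu,
                   beta = null$beta, degenerate = null$degenerate)
  attrs <- sprintf("# n_subsets=%d subset_size=%d",
                   null$n_subsets, null$subset_size)
  writeLines(attrs, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_gumbel_null
#' @export
read_gumbel_null <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  structure(list(marker_id = as.character(df$marker_id), mu = df$mu,
                 beta = df$beta, degenerate = df$degenerate,
                 n_subsets = meta[1L], subset_size = meta[2L]),
            class = "gumbel_null")
}

#' Gumbel p-values for a score track
#'
#' The p-value of SNP i is the probability, under its fitted null, of a
#' higher IBD score than observed: `p = 1 - exp(-exp(-(S - mu)/beta))`.
#' At degenerate markers (constant null scores) the survival test reduces
#' to an exceedance indicator: p = 0 if the observed score exceeds the
#' constant, else 1.
#'
#' @param track a [score_track()] with scores.
#' @param null a `gumbel_null` on the same marker scaffold.
#' @return The track with `p_value` filled.
#' @export
score_pvalues <- function(track, null) {
  stopifnot(inherits(track, "score_track"), inherits(null, "gumbel_null"))
  if (length(null$mu) != nrow(track) ||
      !identical(as.character(track$marker_id), null$marker_id))
    stop("score track and null are on different marker scaffolds")
  z <- (track$ibd_score - null$mu) / null$beta
  p <- -expm1(-exp(-z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  if (any(null$degenerate))
    p[null$degenerate] <-
      ifelse(track$ibd_score[null$degenerate] >
               null$mu[null$degenerate] + 1e-9, 0, 1)
  track$p_value <- p
  track
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i} p_(j) m / j` mapped back to input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Maximal significant marker runs
#'
#' Returns the maximal runs of consecutive markers whose q-value is at or
#' below the threshold, with bp and cM bounds per chromosome.
#'
#' @param track a [score_track()] with q-values.
#' @param q_threshold significance threshold (default 0.01).
#' @return data frame with one row per region.
#' @export
significant_regions <- function(track, q_threshold = 0.01) {
  stopifnot(inherits(track, "score_track"))
  if (anyNA(track$q_value)) stop("q-values not filled")
  out <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch, , drop = FALSE]
    sig <- t_ch$q_value <= q_threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      i1 <- starts[g]; i2 <- ends[g]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = t_ch$pos_bp[i1], end_bp = t_ch$pos_bp[i2],
        start_cM = t_ch$pos_cM[i1], end_cM = t_ch$pos_cM[i2],
        n_markers = i2 - i1 + 1L,
        min_q = min(t_ch$q_value[i1:i2]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), start_cM = numeric(),
                      end_cM = numeric(), n_markers = integer(),
                      min_q = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age of a founder segment from its mean pairwise IBD length
#'
#' Pairwise IBD segments around a founder mutation have expected genetic
#' length 1/(2n) Morgans after n generations, so the generation count is
#' estimated as `n = 1 / (2 L)` with `L` the mean segment length in
#' Morgans.
#'
#' @param mean_length_cM mean pairwise IBD length in centimorgans.
#' @return Estimated number of generations since the founder.
#' @examples
#' estimate_generations(5.4)  # ~9.26: around nine generations
#' @export
estimate_generations <- function(mean_length_cM) {
  if (!is.numeric(mean_length_cM) || any(mean_length_cM <= 0))
    stop("mean length must be positive")
  1 / (2 * mean_length_cM / 100)
}
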