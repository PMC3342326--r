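#' Configuration of the mosaic haplotype-panel generator
#'
#' The synthetic panel emulates the two features of a real phased
#' reference panel that the resampled null must absorb: a realistic
#' allele-frequency spectrum (founder B-allele probabilities drawn from
#' `freq_law`) and block-wise linkage disequilibrium (every haplotype is a
#' recombinant mosaic of a finite founder pool, with Poisson breakpoints
#' along the genetic map and rare per-marker allele flips playing the role
#' of genotyping error / recurrent mutation).
#'
#' `n_founders` controls the amount of background identity by descent:
#' two haplotypes are co-ancestral over a fraction `1/n_founders` of the
#' genome. The default of 400 founders yields on the order of 0.2 shared
#' segments of at least 0.4 cM per haplotype pair per Morgan, a level
#' typical of an outbred population sample; panels of closely related
#' individuals can be emulated by lowering it.
#'
#' @param n_haplotypes number of haplotypes to generate.
#' @param n_markers number of markers.
#' @param chrom_length_cM chromosome length in cM; markers are uniformly
#'   spaced in cM at 1 cM/Mb.
#' @param n_founders size of the founder haplotype pool (>= 2).
#' @param switch_rate_per_cM founder-switch (recombination) rate.
#' @param flip_rate per-marker allele flip probability.
#' @param freq_min,freq_max bounds of the uniform founder allele-frequency
#'   law.
#' @param seed integer seed; the panel is a deterministic function of the
#'   configuration.
#' @return list of class `panel_gen_config`.
#' @export
panel_gen_config <- function(n_haplotypes = 374L, n_markers = 10000L,
                             chrom_length_cM = 100, n_founders = 400L,
                             switch_rate_per_cM = 1.0, flip_rate = 0.002,
                             freq_min = 0.05, freq_max = 0.95,
                             seed = 1L) {
  stopifnot(n_haplotypes >= 1L, n_markers >= 2L, chrom_length_cM > 0,
            n_founders >= 2L, switch_rate_per_cM > 0,
            flip_rate >= 0, flip_rate < 1,
            0 <= freq_min, freq_min <= freq_max, freq_max <= 1)
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_markers = as.integer(n_markers),
                 chrom_length_cM = as.numeric(chrom_length_cM),
                 n_founders = as.integer(n_founders),
                 switch_rate_per_cM = as.numeric(switch_rate_per_cM),
                 flip_rate = as.numeric(flip_rate),
                 freq_min = as.numeric(freq_min),
                 freq_max = as.numeric(freq_max),
                 seed = as.integer(seed)),
            class = "panel_gen_config")
}

#' Generate a mosaic reference panel
#'
#' Draws per-marker founder allele frequencies from the configured uniform
#' law, builds `n_founders` founder haplotypes by independent Bernoulli
#' draws, and emits each panel haplotype as a founder mosaic: breakpoints
#' follow a Poisson process of rate `switch_rate_per_cM` along the genetic
#' map, the founder is redrawn uniformly at each breakpoint, and each
#' marker is flipped independently with probability `flip_rate`. Markers
#' are uniformly spaced in cM (1 cM/Mb physical scale). Deterministic for
#' a fixed `seed`.
#'
#' @param config a [panel_gen_config()].
#' @return A [haplotype_panel()] with origin `"SIMULATED"`, cM positions
#'   and true founder frequencies in `b_freq`.
#' @export
generate_reference_panel <- function(config) {
  stopifnot(inherits(config, "panel_gen_config"))
  set.seed(config$seed)
  M <- config$n_markers
  span <- config$chrom_length_cM
  pos_cM <- seq(0, span, length.out = M)
  pos_bp <- as.integer(round(pos_cM * 1e6)) + 1L
  freqs <- runif(M, config$freq_min, config$freq_max)
  founders <- matrix(rbinom(config$n_founders * M, 1L,
                            rep(freqs, each = config$n_founders)),
                     nrow = config$n_founders)
  al <- matrix(0L, nrow = config$n_haplotypes, ncol = M)
  for (h in seq_len(config$n_haplotypes)) {
    n_br <- rpois(1L, config$switch_rate_per_cM * span)
    br <- sort(runif(n_br, 0, span))
    founder_of <- sample.int(config$n_founders, n_br + 1L, replace = TRUE)
    seg_of_marker <- findInterval(pos_cM, br) + 1L
    al[h, ] <- founders[cbind(founder_of[seg_of_marker], seq_len(M))]
    if (config$flip_rate > 0) {
      flip <- which(rbinom(M, 1L, config$flip_rate) == 1L)
      al[h, flip] <- 1L - al[h, flip]
    }
  }
  mm <- marker_map(sprintf("snp%05d", seq_len(M)), "1", pos_bp,
                   pos_cM = pos_cM, b_freq = freqs)
  haplotype_panel(al, mm, origin = "SIMULATED")
}

#' Configuration of a planted conserved haplotype
#'
#' @param prevalence fraction of tumor haplotypes carrying the conserved
#'   haplotype, in `(0, 1]`.
#' @param mean_length_cM nominal mean length; per-carrier lengths are drawn
#'   from a Gumbel distribution with location and scale both equal to this
#'   value (reproducing the natural spread of real founder segments), then
#'   clamped to `(0.1 cM, chromosome span]`.
#' @param seed integer seed.
#' @return list of class `plant_config`.
#' @export
plant_config <- function(prevalence, mean_length_cM, seed = 1L) {
  stopifnot(prevalence > 0, prevalence <= 1, mean_length_cM > 0)
  structure(list(prevalence = as.numeric(prevalence),
                 mean_length_cM = as.numeric(mean_length_cM),
                 seed = as.integer(seed)),
            class = "plant_config")
}

# Gumbel(location, scale) sampler
rgumbel <- function(n, location, scale) {
  location - scale * log(-log(runif(n)))
}

#' Plant a conserved founder haplotype into a tumor panel
#'
#' Emulates a founder mutation: a focal genomic location is chosen
#' uniformly on the genetic map, `round(prevalence * n)` carrier
#' haplotypes (always including the first) are selected, and each carrier
#' receives a copy of the first haplotype over a segment containing the
#' focal point. Per-carrier segment lengths are Gumbel-distributed with
#' location and scale equal to `mean_length_cM`, and the focal point sits
#' at a uniform fraction of each segment, clipped to the chromosome.
#'
#' @param tumor_panel a [haplotype_panel()] with cM positions.
#' @param plant a [plant_config()].
#' @return list with `panel` (the modified panel) and `truth`, a list of
#'   class `simulation_truth` carrying the focal cM position, carrier ids,
#'   per-carrier `(start_idx, end_idx)` and the per-marker logical truth
#'   flag (inside the union of planted segments).
#' @export
plant_conserved_haplotype <- function(tumor_panel, plant) {
  stopifnot(inherits(tumor_panel, "haplotype_panel"),
            inherits(plant, "plant_config"))
  set.seed(plant$seed)
  al <- tumor_panel$alleles
  n <- nrow(al)
  cm <- tumor_panel$markers$pos_cM
  span <- cm[length(cm)] - cm[1L]
  if (span <= 0.1) stop("chromosome too short for planting")
  n_carriers <- round(plant$prevalence * n)
  if (n_carriers < 1L) stop("prevalence yields no carriers")
  carriers <- c(1L, if (n_carriers > 1L)
    (2:n)[sample.int(n - 1L, n_carriers - 1L)])
  focal <- runif(1L, cm[1L], cm[length(cm)])
  L <- rgumbel(n_carriers, plant$mean_length_cM, plant$mean_length_cM)
  L <- pmin(pmax(L, 0.1), span)
  u <- runif(n_carriers)
  left <- pmax(cm[1L], focal - u * L)
  right <- pmin(cm[length(cm)], left + L)
  left <- pmax(cm[1L], right - L)
  start_idx <- findInterval(left, cm, left.open = TRUE) + 1L
  end_idx <- findInterval(right, cm)
  start_idx <- pmin(start_idx, end_idx)
  truth_flag <- logical(ncol(al))
  for (k in seq_len(n_carriers)) {
    idx <- start_idx[k]:end_idx[k]
    al[carriers[k], idx] <- al[1L, idx]
    truth_flag[idx] <- TRUE
  }
  panel <- haplotype_panel(al, tumor_panel$markers,
                           haplotype_ids = haplotype_ids(tumor_panel),
                           origin = tumor_panel$origin)
  truth <- structure(list(focal_cM = focal,
                          carrier_idx = carriers,
                          carrier_ids = haplotype_ids(tumor_panel)[carriers],
                          start_idx = start_idx, end_idx = end_idx,
                          truth_flag = truth_flag),
                     class = "simulation_truth")
  list(panel = panel, truth = truth)
}

#' Power / FDR / ROC study with planted conserved haplotypes
#'
#' Replays the planted-haplotype simulation protocol: per replicate, one
#' mosaic population panel is generated and split into a reference half
#' and a tumor half (mirroring the split of one real phased panel into
#' reference and tumor-source sets), a conserved haplotype of the
#' configured mean length and prevalence is planted into the tumor half,
#' and each requested method is run. A replicate counts as detected when
#' at least one marker inside the union of planted segments reaches
#' `q <= q_threshold`; the false discovery rate pools significant markers
#' outside the planted regions over all replicates; ROC points average
#' per-marker TPR/FPR over a grid of q thresholds.
#'
#' @param panel_cfg a [panel_gen_config()]; `n_haplotypes` is the total
#'   population size, of which the first `n_haplotypes - n_tumor` form the
#'   reference panel.
#' @param plant_cfg a [plant_config()]; its seed is re-derived per
#'   replicate from `seed`.
#' @param params a [match_params()].
#' @param n_tumor tumor panel size (default 100).
#' @param n_reps number of replicates.
#' @param n_null_subsets resampled null subsets per scan.
#' @param q_threshold detection threshold (default 0.01).
#' @param methods character subset of `c("foundertracker", "dash")`.
#' @param seed master seed; all per-replicate seeds derive from it.
#' @param roc_thresholds q-threshold grid for the ROC curve.
#' @return list of class `power_study` with per-method `power`, `fdr`,
#'   pooled false/true significant counts, per-replicate detection flags
#'   and the averaged `roc` table.
#' @export
run_power_study <- function(panel_cfg, plant_cfg, params = match_params(),
                            n_tumor = 100L, n_reps = 25L,
                            n_null_subsets = 50L, q_threshold = 0.01,
                            methods = c("foundertracker", "dash"),
                            seed = 1L,
                            roc_thresholds = 10^seq(-6, 0, by = 0.5)) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(panel_cfg, "panel_gen_config"),
            inherits(plant_cfg, "plant_config"), n_reps >= 1L)
  n_ref <- panel_cfg$n_haplotypes - n_tumor
  if (n_ref < n_tumor)
    stop("population must leave a reference half at least as large as the ",
         "tumor half")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_reps),
                      ncol = 3L)
  detected <- matrix(FALSE, nrow = n_reps, ncol = length(methods),
                     dimnames = list(NULL, methods))
  n_false <- setNames(numeric(length(methods)), methods)
  n_sig <- setNames(numeric(length(methods)), methods)
  roc_tp <- roc_fp <- matrix(0, nrow = length(roc_thresholds),
                             ncol = length(methods),
                             dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    cfg <- panel_cfg
    cfg$seed <- rep_seeds[r, 1L]
    pop <- generate_reference_panel(cfg)
    reference <- pop[seq_len(n_ref), ]
    tumor0 <- pop[n_ref + seq_len(n_tumor), ]
    pc <- plant_cfg
    pc$seed <- rep_seeds[r, 2L]
    planted <- plant_conserved_haplotype(tumor0, pc)
    truth <- planted$truth$truth_flag
    for (m in methods) {
      q <- if (m == "foundertracker") {
        scan <- ft_scan(planted$panel, reference, params,
                        n_subsets = n_null_subsets,
                        q_threshold = q_threshold,
                        seed = rep_seeds[r, 3L])
        scan$track$q_value
      } else {
        scan <- dash_scan(planted$panel, reference, params,
                          q_threshold = q_threshold)
        scan$track$q_value
      }
      sig <- q <= q_threshold
      detected[r, m] <- any(sig & truth)
      n_false[m] <- n_false[m] + sum(sig & !truth)
      n_sig[m] <- n_sig[m] + sum(sig)
      for (t in seq_along(roc_thresholds)) {
        s <- q <= roc_thresholds[t]
        roc_tp[t, m] <- roc_tp[t, m] + sum(s & truth) / max(1L, sum(truth))
        roc_fp[t, m] <- roc_fp[t, m] + sum(s & !truth) /
          max(1L, sum(!truth))
      }
    }
  }
  power <- colMeans(detected)
  fdr <- ifelse(n_sig > 0, n_false / n_sig, 0)
  roc <- data.frame(
    q_threshold = rep(roc_thresholds, times = length(methods)),
    method = rep(methods, each = length(roc_thresholds)),
    tpr = as.vector(roc_tp) / n_reps,
    fpr = as.vector(roc_fp) / n_reps
  )
  structure(list(power = power, fdr = fdr, n_false = n_false,
                 n_sig = n_sig, detected = detected, roc = roc,
                 n_reps = n_reps, n_tumor = n_tumor, n_reference = n_ref,
                 plant_cfg = plant_cfg, panel_cfg = panel_cfg,
                 q_threshold = q_threshold, seed = seed),
            class = "power_study")
}

#' @method print power_study
#' @export
print.power_study <- function(x, ...) {
  cat(sprintf(
    "<power_study> %g cM at %.0f%% prevalence; %d tumors vs %d references; %d reps\n",
    x$plant_cfg$mean_length_cM, 100 * x$plant_cfg$prevalence,
    x$n_tumor, x$n_reference, x$n_reps))
  for (m in names(x$power))
    cat(sprintf("  %-14s power = %.3f  FDR = %.2e (q <= %g)\n",
                m, x$power[m], x$fdr[m], x$q_threshold))
  invisible(x)
}
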