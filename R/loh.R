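#' Allele-specific copy-number segments
#'
#' Container for segmented allele-specific copy numbers, one row per
#' (sample, segment): `major_cn` and `minor_cn` are the copy numbers of the
#' more and less abundant parental alleles; they may be fractional when the
#' tumor is contaminated with normal cells.
#'
#' @param sample_id,chrom character vectors.
#' @param start_bp,end_bp 1-based inclusive segment bounds.
#' @param major_cn,minor_cn non-negative copy numbers, `minor_cn <= major_cn`.
#' @return data frame of class `ascn_segments`.
#' @export
ascn_segments <- function(sample_id, chrom, start_bp, end_bp,
                          major_cn, minor_cn) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   major_cn = as.numeric(major_cn),
                   minor_cn = as.numeric(minor_cn),
                   stringsAsFactors = FALSE)
  if (any(df$start_bp > df$end_bp)) stop("start_bp must be <= end_bp")
  if (any(df$minor_cn > df$major_cn + 1e-9))
    stop("minor_cn must not exceed major_cn")
  if (any(df$minor_cn < 0)) stop("copy numbers must be non-negative")
  class(df) <- c("ascn_segments", "data.frame")
  df
}

#' Call LOH segments from allele-specific copy numbers
#'
#' A segment has undergone loss of heterozygosity when the copy number of
#' its minor allele is below 0.5, whatever the copy number of the retained
#' chromosome — this covers classical deletion LOH (1 vs 0), copy-neutral
#' LOH (2 vs 0) and LOH with gain, and tolerates fractional copy numbers
#' from normal-cell contamination.
#'
#' @param segments an [ascn_segments()] table.
#' @param minor_cn_threshold LOH cut-off on the minor copy number
#'   (default 0.5).
#' @return The subset of `segments` that are LOH.
#' @examples
#' seg <- ascn_segments("s1", "17", c(1, 100), c(99, 200),
#'                      major_cn = c(1, 1), minor_cn = c(0, 1))
#' call_loh(seg)  # first segment only
#' @export
call_loh <- function(segments, minor_cn_threshold = 0.5) {
  stopifnot(inherits(segments, "ascn_segments"))
  out <- segments[segments$minor_cn < minor_cn_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recurrent regions of LOH across samples
#'
#' Counts, at every base pair, how many samples have an LOH segment
#' covering it, and returns the maximal intervals where the carrier
#' fraction reaches `min_frequency`. Each region is annotated with the
#' union of samples contributing LOH anywhere within it.
#'
#' @param loh_segments LOH-flagged [ascn_segments()] (from [call_loh()]).
#' @param n_samples total number of samples in the cohort (the frequency
#'   denominator).
#' @param min_frequency minimal carrier fraction in `(0, 1]`; 0.2 is the
#'   usual exploratory setting, 1.0 keeps only regions lost in every sample.
#' @return data frame of class `loh_regions` with columns `chrom`,
#'   `start_bp`, `end_bp`, `frequency` and list-column `carrier_samples`;
#'   `frequency` is the maximum per-bp carrier fraction inside the region.
#' @export
recurrent_loh_regions <- function(loh_segments, n_samples,
                                  min_frequency = 0.2) {
  stopifnot(inherits(loh_segments, "ascn_segments"))
  if (n_samples <= 0L) stop("n_samples must be positive")
  if (min_frequency <= 0 || min_frequency > 1)
    stop("min_frequency must lie in (0, 1]")
  min_count <- ceiling(min_frequency * n_samples - 1e-9)
  res <- list()
  for (ch in unique(loh_segments$chrom)) {
    seg <- loh_segments[loh_segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    # breakpoint sweep over elementary intervals [b_k, b_{k+1} - 1]
    bp <- sort(unique(c(seg$start_bp, seg$end_bp + 1)))
    if (length(bp) < 2L) next
    starts <- bp[-length(bp)]
    ends <- bp[-1L] - 1
    cover <- matrix(FALSE, nrow = length(starts),
                    ncol = length(unique(seg$sample_id)),
                    dimnames = list(NULL, unique(seg$sample_id)))
    for (k in seq_len(nrow(seg)))
      cover[starts >= seg$start_bp[k] & ends <= seg$end_bp[k],
            seg$sample_id[k]] <- TRUE
    count <- rowSums(cover)
    hit <- count >= min_count & count > 0L
    if (!any(hit)) next
    # merge adjacent qualifying elementary intervals into maximal regions
    r <- rle(hit)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (g in which(r$values)) {
      i1 <- idx_start[g]; i2 <- idx_end[g]
      carriers <- colnames(cover)[colSums(cover[i1:i2, , drop = FALSE]) > 0L]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start_bp = starts[i1], end_bp = ends[i2],
        frequency = max(count[i1:i2]) / n_samples,
        stringsAsFactors = FALSE
      )
      res[[length(res)]]$carrier_samples <- I(list(sort(carriers)))
    }
  }
  if (!length(res)) {
    out <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), frequency = numeric())
    out$carrier_samples <- I(list())
  } else {
    out <- do.call(rbind, res)
  }
  rownames(out) <- NULL
  class(out) <- c("loh_regions", "data.frame")
  out
}

#' Infer the retained tumor haplotype from a BAF profile
#'
#' Inside an LOH region only one parental chromosome remains, so the BAF of
#' each SNP sits near 0 (A retained) or 1 (B retained). Fixed thresholds
#' convert the profile to alleles: BAF > 0.65 is called B, BAF < 0.35 is
#' called A, and anything in between (or missing) is flagged unreliable
#' (`NA`).
#'
#' @param baf numeric BAF vector for the markers of `markers` (values in
#'   `[0, 1]` or `NA`).
#' @param markers [marker_map()] for the region (same length as `baf`);
#'   optional, used only for dimension checking.
#' @param b_threshold,a_threshold the two BAF cut-offs.
#' @return Integer allele vector over `{0, 1, NA}`.
#' @examples
#' infer_tumor_haplotype(c(0.92, 0.08, 0.5))  # 1, 0, NA
#' @export
infer_tumor_haplotype <- function(baf, markers = NULL,
                                  b_threshold = 0.65, a_threshold = 0.35) {
  if (!is.null(markers) && length(baf) != nrow(markers))
    stop("baf length does not match marker map")
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("BAF values must lie in [0, 1]")
  out <- rep(NA_integer_, length(baf))
  out[!is.na(baf) & baf > b_threshold] <- 1L
  out[!is.na(baf) & baf < a_threshold] <- 0L
  out
}

#' Drop markers unreliable in any tumor
#'
#' Removes every marker column that carries a missing (unreliable) allele in
#' at least one haplotype, subsetting the marker map in step. IBD matching
#' requires a complete allele matrix, so this is run before
#' [find_pairwise_ibd()].
#'
#' @param panel a [haplotype_panel()].
#' @return The panel restricted to fully observed markers.
#' @export
drop_unreliable_markers <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- colSums(is.na(panel$alleles)) == 0L
  if (!any(keep))
    stop("all markers carry a missing allele in at least one haplotype")
  if (all(keep)) return(panel)
  panel[, which(keep)]
}

#' Reconstruct the haplotype of the chromosome lost by LOH
#'
#' When a matched constitutive (germline) sample is available, comparing
#' its unphased genotypes with the tumor haplotype recovers the lost
#' chromosome: at heterozygous SNPs the lost allele is the one not retained
#' in the tumor; at homozygous SNPs it equals the homozygous allele. A tumor
#' allele absent from the constitutive genotype is an inconsistency and
#' yields a missing call.
#'
#' @param tumor_hap integer alleles over `{0, 1, NA}` (retained chromosome).
#' @param constitutive_genotypes character vector over
#'   `{"AA", "AB", "BB"}` (or `NA`), same length.
#' @return Integer allele vector for the lost chromosome.
#' @examples
#' reconstruct_lost_haplotype(c(1L, 0L, 1L), c("AB", "AA", "AA"))  # 0,0,NA
#' @export
reconstruct_lost_haplotype <- function(tumor_hap, constitutive_genotypes) {
  if (length(tumor_hap) != length(constitutive_genotypes))
    stop("tumor haplotype and constitutive genotypes differ in length")
  g <- toupper(constitutive_genotypes)
  if (!all(g %in% c("AA", "AB", "BA", "BB") | is.na(g)))
    stop("constitutive genotypes must be AA, AB or BB")
  g[g == "BA"] <- "AB"
  out <- rep(NA_integer_, length(tumor_hap))
  het <- !is.na(g) & g == "AB" & !is.na(tumor_hap)
  out[het] <- 1L - tumor_hap[het]
  homA <- !is.na(g) & g == "AA"
  homB <- !is.na(g) & g == "BB"
  out[homA] <- 0L
  out[homB] <- 1L
  # inconsistency: tumor allele not present in the constitutive genotype
  out[homA & !is.na(tumor_hap) & tumor_hap == 1L] <- NA_integer_
  out[homB & !is.na(tumor_hap) & tumor_hap == 0L] <- NA_integer_
  out
}

#' Error rate between two haplotypes
#'
#' Fraction of pairwise-observed positions at which the alleles differ;
#' positions missing in either haplotype are excluded.
#'
#' @param h1,h2 integer allele vectors of equal length.
#' @return Mismatch fraction.
#' @export
haplotype_error_rate <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotypes differ in length")
  ok <- !is.na(h1) & !is.na(h2)
  if (!any(ok)) stop("no pairwise-observed positions to compare")
  mean(h1[ok] != h2[ok])
}

#' Infer per-region tumor haplotype panels from BAF profiles
#'
#' End-to-end composition of the LOH stage: call LOH on the copy-number
#' segments, delineate recurrent LOH regions, and for every region build a
#' tumor haplotype panel from the BAF profiles of the carrier samples.
#'
#' @param baf a list as returned by [read_baf_table()] (`markers` +
#'   markers-x-samples `baf` matrix).
#' @param ascn an [ascn_segments()] table for the same samples.
#' @param min_frequency recurrence threshold, see [recurrent_loh_regions()].
#' @param drop_unreliable drop markers unreliable in any carrier
#'   (default TRUE).
#' @return Named list of [haplotype_panel()] objects, one per recurrent LOH
#'   region, with the region table attached as attribute `"regions"`.
#' @export
infer_haplotype_panels <- function(baf, ascn, min_frequency = 0.2,
                                   drop_unreliable = TRUE) {
  samples <- colnames(baf$baf)
  loh <- call_loh(ascn)
  regions <- recurrent_loh_regions(loh, n_samples = length(samples),
                                   min_frequency = min_frequency)
  if (!nrow(regions)) stop("no LOH regions at min_frequency = ",
                           min_frequency)
  panels <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    in_region <- baf$markers$chrom == regions$chrom[r] &
      baf$markers$pos_bp >= regions$start_bp[r] &
      baf$markers$pos_bp <= regions$end_bp[r]
    mm <- subset_marker_map(baf$markers, which(in_region))
    carriers <- regions$carrier_samples[[r]]
    al <- t(vapply(carriers, function(s)
      infer_tumor_haplotype(baf$baf[in_region, s]),
      integer(sum(in_region))))
    panel <- haplotype_panel(al, mm, haplotype_ids = carriers,
                             origin = "TUMOR")
    if (drop_unreliable) panel <- drop_unreliable_markers(panel)
    panels[[r]] <- panel
  }
  names(panels) <- sprintf("%s:%d-%d", regions$chrom,
                           regions$start_bp, regions$end_bp)
  attr(panels, "regions") <- regions
  panels
}
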