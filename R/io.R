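#' Read a phased haplotype panel
#'
#' Reads phased haplotypes either from an IMPUTE-style `.hap`/`.legend` file
#' pair (one row per SNP in the `.hap` file, one 0/1 column per haplotype;
#' 0 = A, 1 = B) or from a phased VCF. Unphased VCF genotypes (`/` separator)
#' and multi-allelic records are rejected: the panel is strictly binary A/B.
#'
#' @param path path to the `.hap` file, or to the VCF.
#' @param format `"hap_legend"` or `"phased_vcf"`.
#' @param legend_path path to the `.legend` file (required for
#'   `"hap_legend"`); whitespace-delimited with a header whose first two
#'   columns are the marker id and bp position.
#' @param chrom chromosome label for `.hap`/`.legend` input (the legend does
#'   not carry one).
#' @param map optional genetic-map table (see [read_genetic_map()]); when
#'   given, marker cM positions are interpolated with [interpolate_cM()].
#' @param origin panel origin tag, see [haplotype_panel()].
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, format = c("hap_legend", "phased_vcf"),
                                 legend_path = NULL, chrom = "1", map = NULL,
                                 origin = "REFERENCE") {
  format <- match.arg(format)
  panel <- switch(format,
    hap_legend = read_hap_legend(path, legend_path, chrom, origin),
    phased_vcf = read_phased_vcf(path, origin)
  )
  if (!is.null(map)) {
    panel$markers$pos_cM <- interpolate_cM(map, panel$markers$pos_bp)
    validate_marker_map(panel$markers)
  }
  panel
}

read_hap_legend <- function(path, legend_path, chrom, origin) {
  if (is.null(legend_path)) stop("legend_path is required for hap_legend input")
  if (!file.exists(path)) stop("hap file not found: ", path)
  if (!file.exists(legend_path)) stop("legend file not found: ", legend_path)
  leg <- utils::read.table(legend_path, header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(leg) < 2L) stop("legend must have at least id and position columns")
  ids <- as.character(leg[[1L]])
  pos <- as.integer(leg[[2L]])
  if (is.unsorted(pos, strictly = TRUE))
    stop("legend positions must be sorted and strictly increasing")
  hap <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(hap) != length(ids))
    stop(sprintf("hap file has %d rows but legend has %d markers",
                 nrow(hap), length(ids)))
  if (!all(hap %in% c(0L, 1L)))
    stop("hap file entries must be 0 or 1")
  mm <- marker_map(ids, chrom, pos)
  # .hap rows are markers; haplotypes are columns
  haplotype_panel(t(hap), mm, origin = origin)
}

read_phased_vcf <- function(path, origin) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported")
  pos <- as.integer(fix[, "POS"])
  chrom <- as.character(fix[, "CHROM"])
  ids <- as.character(fix[, "ID"])
  ids[is.na(ids) | ids == "."] <-
    paste0(chrom, ":", pos)[is.na(ids) | ids == "."]
  for (ch in unique(chrom))
    if (is.unsorted(pos[chrom == ch], strictly = TRUE))
      stop("VCF positions must be sorted within chromosome ", ch)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype encountered; phased haplotypes (|) are required")
  samples <- colnames(gt)
  n_mark <- nrow(gt)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_mark)
  hap_ids <- character(2L * length(samples))
  for (s in seq_along(samples)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("expected diploid phased genotypes for sample ", samples[s])
    m <- matrix(as.integer(unlist(parts)), nrow = 2L)
    if (any(m > 1L, na.rm = TRUE))
      stop("non-biallelic allele index in genotypes")
    alleles[2L * s - 1L, ] <- m[1L, ]
    alleles[2L * s, ]      <- m[2L, ]
    hap_ids[2L * s - 1L]   <- paste0(samples[s], "_1")
    hap_ids[2L * s]        <- paste0(samples[s], "_2")
  }
  mm <- marker_map(ids, chrom, pos)
  haplotype_panel(alleles, mm, haplotype_ids = hap_ids, origin = origin)
}

#' Write a haplotype panel as `.hap`/`.legend` files
#'
#' Inverse of [read_haplotype_panel()] for the `hap_legend` format; the
#' round trip is lossless for alleles and marker order. Missing alleles are
#' not representable in the 0/1 `.hap` format and raise an error.
#'
#' @param panel a [haplotype_panel()].
#' @param hap_path,legend_path output file paths.
#' @return Invisibly, `hap_path`.
#' @export
write_haplotype_panel <- function(panel, hap_path, legend_path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (anyNA(panel$alleles))
    stop("panel contains missing alleles; drop_unreliable_markers() first")
  leg <- data.frame(id = panel$markers$marker_id,
                    position = panel$markers$pos_bp,
                    a0 = "A", a1 = "B")
  utils::write.table(leg, legend_path, quote = FALSE, row.names = FALSE)
  utils::write.table(t(panel$alleles), hap_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(hap_path)
}

#' Read an IMPUTE-format genetic map
#'
#' Three whitespace-delimited columns with a header: bp position, local
#' recombination rate (cM/Mb) and cumulative genetic position (cM). The
#' cumulative column is authoritative.
#'
#' @param path path to the map file.
#' @return data frame with columns `pos_bp`, `rate_cM_Mb`, `pos_cM`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map not found: ", path)
  m <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(m) < 3L) stop("genetic map needs 3 columns (pos, rate, cM)")
  out <- data.frame(pos_bp = as.numeric(m[[1L]]),
                    rate_cM_Mb = as.numeric(m[[2L]]),
                    pos_cM = as.numeric(m[[3L]]))
  if (is.unsorted(out$pos_bp, strictly = TRUE))
    stop("genetic map positions must be strictly increasing")
  out
}

#' Interpolate genetic positions from a recombination map
#'
#' Piecewise-linear interpolation of cumulative cM against bp. Positions
#' beyond either end of the map are extrapolated with the nearest interval's
#' recombination rate, so the result is monotonically non-decreasing in bp.
#'
#' @param map_table data frame as returned by [read_genetic_map()] (any
#'   data frame with `pos_bp` and `pos_cM` columns works).
#' @param positions_bp bp positions to interpolate at.
#' @return Numeric vector of cM positions.
#' @examples
#' m <- data.frame(pos_bp = c(1e6, 2e6), pos_cM = c(1, 2))
#' interpolate_cM(m, 1.5e6)  # 1.5
#' @export
interpolate_cM <- function(map_table, positions_bp) {
  if (is.null(map_table) || nrow(map_table) == 0L)
    stop("empty genetic map table")
  xb <- map_table$pos_bp
  xc <- map_table$pos_cM
  if (nrow(map_table) == 1L)
    return(rep(xc[1L], length(positions_bp)))
  out <- stats::approx(xb, xc, xout = positions_bp, rule = 2)$y
  # extrapolate beyond map ends with the flanking interval's rate
  lo <- positions_bp < xb[1L]
  hi <- positions_bp > xb[length(xb)]
  if (any(lo)) {
    r <- (xc[2L] - xc[1L]) / (xb[2L] - xb[1L])
    out[lo] <- pmax(0, xc[1L] + (positions_bp[lo] - xb[1L]) * r)
  }
  if (any(hi)) {
    n <- length(xb)
    r <- (xc[n] - xc[n - 1L]) / (xb[n] - xb[n - 1L])
    out[hi] <- xc[n] + (positions_bp[hi] - xb[n]) * r
  }
  out
}

#' Write / read a per-SNP score track
#'
#' Tab-separated with columns `marker_id`, `chrom`, `pos_bp`, `pos_cM`,
#' `ibd_score`, `p_value`, `q_value`, ordered by (chrom, pos_bp).
#'
#' @param track a [score_track()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_score_track <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  df <- as.data.frame(track)
  df <- df[order(df$chrom, df$pos_bp), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_track
#' @export
read_score_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(marker_id = "character",
                                         chrom = "character"))
  mm <- marker_map(df$marker_id, df$chrom, df$pos_bp, df$pos_cM)
  score_track(mm, df$ibd_score, p_value = df$p_value, q_value = df$q_value)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated with header `sample`, `chrom`, `start`, `end`, `major_cn`,
#' `minor_cn` (1-based inclusive bp coordinates).
#'
#' @param path input path.
#' @return data frame of class `ascn_segments` (see [ascn_segments()]).
#' @export
read_ascn_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ascn_segments(df$sample, df$chrom, df$start, df$end,
                df$major_cn, df$minor_cn)
}

#' Read a per-sample B-allele-frequency table
#'
#' Tab-separated with header columns `marker_id`, `chrom`, `pos`, then one
#' BAF column per sample. Empty cells become missing BAF values.
#'
#' @param path input path.
#' @return list with `markers` (a [marker_map()]) and `baf` (markers x
#'   samples numeric matrix).
#' @export
read_baf_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(marker_id = "character",
                                         chrom = "character"))
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(df)))
  baf <- as.matrix(df[, setdiff(names(df), c("marker_id", "chrom", "pos")),
                      drop = FALSE])
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("BAF values must lie in [0, 1]")
  mm <- marker_map(df$marker_id, df$chrom, df$pos)
  rownames(baf) <- mm$marker_id
  list(markers = mm, baf = baf)
}

#' Write pairwise IBD segments as a GERMLINE-style match table
#'
#' @param segments an IBD segment table (see [find_pairwise_ibd()]).
#' @param markers the [marker_map()] the indices refer to.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ibd_segments <- function(segments, markers, path) {
  df <- data.frame(
    hap1 = segments$hap1_id, hap2 = segments$hap2_id,
    chrom = markers$chrom[segments$start_idx],
    start_bp = markers$pos_bp[segments$start_idx],
    end_bp = markers$pos_bp[segments$end_idx],
    start_idx = segments$start_idx, end_idx = segments$end_idx,
    length_cM = segments$length_cM
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
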