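#' Marker scaffold with physical and genetic coordinates
#'
#' A `marker_map` is the ordered scaffold every other object in the package
#' is aligned to: one row per SNP with its identifier, chromosome, physical
#' position (1-based bp), genetic position (cM) and the population frequency
#' of the B allele. Physical positions must be strictly increasing and
#' genetic positions non-decreasing within a chromosome.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome label(s); recycled to the number of markers.
#' @param pos_bp integer-valued physical positions, 1-based.
#' @param pos_cM genetic positions in centimorgans, or `NA` when no genetic
#'   map has been attached yet.
#' @param b_freq B-allele frequencies in `[0, 1]`, or `NA` when unknown.
#' @return A data frame of class `marker_map`.
#' @examples
#' mm <- marker_map(paste0("rs", 1:3), "1", c(100L, 200L, 300L),
#'                  pos_cM = c(0, 0.1, 0.2), b_freq = c(0.5, 0.2, 0.9))
#' @export
marker_map <- function(marker_id, chrom, pos_bp, pos_cM = NA_real_,
                       b_freq = NA_real_) {
  n <- length(marker_id)
  mm <- data.frame(
    marker_id = as.character(marker_id),
    chrom     = rep_len(as.character(chrom), n),
    pos_bp    = as.integer(pos_bp),
    pos_cM    = rep_len(as.numeric(pos_cM), n),
    b_freq    = rep_len(as.numeric(b_freq), n),
    stringsAsFactors = FALSE
  )
  class(mm) <- c("marker_map", "data.frame")
  validate_marker_map(mm)
  mm
}

validate_marker_map <- function(mm) {
  stopifnot(is.data.frame(mm),
            all(c("marker_id", "chrom", "pos_bp", "pos_cM", "b_freq") %in%
                  names(mm)))
  if (anyDuplicated(mm$marker_id))
    stop("marker_id values must be unique")
  for (ch in unique(mm$chrom)) {
    i <- mm$chrom == ch
    if (is.unsorted(mm$pos_bp[i], strictly = TRUE))
      stop("pos_bp must be strictly increasing within chromosome ", ch)
    cm <- mm$pos_cM[i]
    if (!anyNA(cm) && is.unsorted(cm))
      stop("pos_cM must be non-decreasing within chromosome ", ch)
  }
  bf <- mm$b_freq
  if (any(bf < 0 | bf > 1, na.rm = TRUE))
    stop("b_freq must lie in [0, 1]")
  invisible(mm)
}

#' @method print marker_map
#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("<marker_map> %d markers on chromosome(s) %s\n",
              nrow(x), paste(unique(x$chrom), collapse = ", ")))
  if (nrow(x)) {
    span_bp <- x$pos_bp[nrow(x)] - x$pos_bp[1]
    cat(sprintf("  span: %d bp", span_bp))
    if (!anyNA(x$pos_cM))
      cat(sprintf(", %.3f cM", x$pos_cM[nrow(x)] - x$pos_cM[1]))
    cat(sprintf("; b_freq %s\n",
                if (anyNA(x$b_freq)) "not set" else "set"))
    print(utils::head(as.data.frame(x), 4L))
    if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  }
  invisible(x)
}

subset_marker_map <- function(mm, idx) {
  out <- as.data.frame(mm)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_map", "data.frame")
  out
}
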