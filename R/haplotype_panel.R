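#' Panel of phased haplotypes aligned to a marker map
#'
#' A `haplotype_panel` stores one allele per haplotype per marker, with
#' alleles coded `0` (A), `1` (B) and `NA` (missing/unreliable), following
#' the binary A/B convention of Illumina SNP arrays. Rows are haplotypes,
#' columns are the markers of the attached [marker_map()].
#'
#' @param alleles integer matrix (haplotypes x markers) over `{0, 1, NA}`;
#'   `"A"`/`"B"` character matrices are accepted and recoded.
#' @param markers a [marker_map()] with one row per column of `alleles`.
#' @param haplotype_ids unique haplotype identifiers; defaults to the
#'   rownames of `alleles` or `hap1..hapN`.
#' @param origin one of `"TUMOR"`, `"REFERENCE"`, `"SIMULATED"`.
#' @return An object of class `haplotype_panel`.
#' @examples
#' mm <- marker_map(paste0("rs", 1:4), "1", c(1L, 2L, 3L, 4L) * 1000L,
#'                  pos_cM = c(0, 0.5, 1, 1.5))
#' haplotype_panel(rbind(c(0, 1, 0, 1), c(1, 1, 0, 0)), mm)
#' @export
haplotype_panel <- function(alleles, markers, haplotype_ids = NULL,
                            origin = c("TUMOR", "REFERENCE", "SIMULATED")) {
  origin <- match.arg(origin)
  if (is.character(alleles)) {
    ok <- alleles %in% c("A", "B") | is.na(alleles)
    if (!all(ok)) stop("character alleles must be 'A', 'B' or NA")
    alleles <- matrix(match(alleles, c("A", "B")) - 1L, nrow = nrow(alleles))
  }
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L) | is.na(alleles)))
    stop("alleles must be coded 0 (A), 1 (B) or NA")
  validate_marker_map(markers)
  if (ncol(alleles) != nrow(markers))
    stop(sprintf("allele matrix has %d columns but marker map has %d markers",
                 ncol(alleles), nrow(markers)))
  if (is.null(haplotype_ids))
    haplotype_ids <- rownames(alleles)
  if (is.null(haplotype_ids))
    haplotype_ids <- paste0("hap", seq_len(nrow(alleles)))
  haplotype_ids <- as.character(haplotype_ids)
  if (length(haplotype_ids) != nrow(alleles))
    stop("haplotype_ids length does not match number of haplotype rows")
  if (anyDuplicated(haplotype_ids))
    stop("haplotype_ids must be unique")
  dimnames(alleles) <- list(haplotype_ids, markers$marker_id)
  structure(list(alleles = alleles, markers = markers, origin = origin),
            class = "haplotype_panel")
}

#' @method print haplotype_panel
#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d markers (%s)\n",
              nrow(x$alleles), ncol(x$alleles), x$origin))
  nmiss <- sum(is.na(x$alleles))
  if (nmiss) cat(sprintf("  %d missing allele calls\n", nmiss))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' Subset a haplotype panel
#'
#' `panel[i, j]` keeps haplotypes `i` and marker columns `j`, subsetting the
#' marker map in step.
#'
#' @param x a [haplotype_panel()].
#' @param i,j haplotype / marker indices (any standard matrix index form).
#' @param ... unused.
#' @return A `haplotype_panel`.
#' @export
`[.haplotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$alleles))
  if (missing(j)) j <- seq_len(ncol(x$alleles))
  al <- x$alleles[i, j, drop = FALSE]
  mm <- subset_marker_map(x$markers, j)
  # invariants hold by construction on a subset; skip revalidation
  structure(list(alleles = al, markers = mm, origin = x$origin),
            class = "haplotype_panel")
}

#' Haplotype identifiers of a panel
#' @param panel a [haplotype_panel()].
#' @return Character vector of haplotype ids.
#' @export
haplotype_ids <- function(panel) rownames(panel$alleles)

#' Per-marker B-allele frequencies from a reference panel
#'
#' Fills the `b_freq` column of the panel's marker map with the observed
#' fraction of B alleles among non-missing haplotypes at each marker. These
#' empirical frequencies are what the IBD segment score weights rare shared
#' alleles by; estimating them from the reference panel (rather than the
#' tumor set) keeps the tumor scan and its resampled null on one frequency
#' table.
#'
#' @param reference a [haplotype_panel()] with at least 2 haplotypes.
#' @return The panel's [marker_map()] with `b_freq` filled.
#' @examples
#' mm <- marker_map(c("a", "b"), "1", c(1L, 2L), pos_cM = c(0, 1))
#' p <- haplotype_panel(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0)), mm)
#' estimate_b_freqs(p)$b_freq  # 0.5, 0.25
#' @export
estimate_b_freqs <- function(reference) {
  stopifnot(inherits(reference, "haplotype_panel"))
  if (nrow(reference$alleles) < 2L)
    stop("reference panel must contain at least 2 haplotypes")
  nb <- colSums(reference$alleles == 1L, na.rm = TRUE)
  nn <- colSums(!is.na(reference$alleles))
  if (any(nn == 0L))
    stop("marker(s) with all-missing alleles: ",
         paste(reference$markers$marker_id[nn == 0L][1:5], collapse = ", "))
  mm <- reference$markers
  mm$b_freq <- nb / nn
  mm
}
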