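test_that("LOH is called on minor copy number < 0.5 regardless of major", {
  seg <- ascn_segments(
    sample_id = c("s1", "s1", "s1"), chrom = "17",
    start_bp = c(1, 100, 200), end_bp = c(99, 199, 299),
    major_cn = c(1, 1, 2), minor_cn = c(0, 1, 0.3))
  loh <- call_loh(seg)
  # deletion LOH and contaminated copy-neutral/gain LOH kept, het diploid not
  expect_equal(loh$start_bp, c(1, 200))
  expect_equal(loh$minor_cn, c(0, 0.3))
})

test_that("recurrent LOH regions count carriers per base pair", {
  seg <- ascn_segments(paste0("s", 1:3), "1", rep(1000, 3), rep(2000, 3),
                       major_cn = 1, minor_cn = 0)
  r <- recurrent_loh_regions(seg, n_samples = 10, min_frequency = 0.2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$frequency, 0.3)
  expect_equal(r$carrier_samples[[1]], c("s1", "s2", "s3"))
  expect_equal(nrow(recurrent_loh_regions(seg, 10, min_frequency = 0.5)), 0L)
  expect_error(recurrent_loh_regions(seg, 0), "n_samples")
})

test_that("disjoint recurrent intervals match a per-bp counting oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n_samp <- 6L
    rows <- do.call(rbind, lapply(1:12, function(i) {
      s <- sample.int(200, 1)
      data.frame(sample_id = sample(paste0("s", 1:n_samp), 1),
                 start = s, end = s + sample.int(60, 1))
    }))
    # one segment set per sample must be non-overlapping; enforce by
    # keeping the first segment per (sample, overlapping group)
    keep <- rep(TRUE, nrow(rows))
    for (sm in unique(rows$sample_id)) {
      idx <- which(rows$sample_id == sm)
      idx <- idx[order(rows$start[idx])]
      last_end <- -1
      for (i in idx) {
        if (rows$start[i] <= last_end) keep[i] <- FALSE
        else last_end <- rows$end[i]
      }
    }
    rows <- rows[keep, ]
    seg <- ascn_segments(rows$sample_id, "1", rows$start, rows$end, 1, 0)
    got <- recurrent_loh_regions(seg, n_samp, min_frequency = 0.4)
    # oracle: carrier count at every single bp
    minc <- ceiling(0.4 * n_samp - 1e-9)
    bp_count <- sapply(1:300, function(b)
      length(unique(seg$sample_id[seg$start_bp <= b & seg$end_bp >= b])))
    hit <- bp_count >= minc & bp_count > 0
    runs <- rle(hit)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    exp_start <- starts[runs$values]; exp_end <- ends[runs$values]
    expect_equal(got$start_bp, as.numeric(exp_start))
    expect_equal(got$end_bp, as.numeric(exp_end))
    if (nrow(got)) {
      for (k in seq_len(nrow(got))) {
        in_reg <- seg$start_bp <= got$end_bp[k] & seg$end_bp >= got$start_bp[k]
        expect_equal(got$carrier_samples[[k]],
                     sort(unique(seg$sample_id[in_reg])))
      }
    }
  }
})

test_that("BAF thresholds assign B above 0.65, A below 0.35, else missing", {
  h <- infer_tumor_haplotype(c(0.92, 0.08, 0.50, 0.65, 0.35, NA))
  expect_equal(h, c(1L, 0L, NA, NA, NA, NA))
  expect_error(infer_tumor_haplotype(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("markers unreliable in any tumor are dropped with the map", {
  al <- rbind(c(0L, 1L, NA, 1L, 0L),
              c(1L, 1L, 0L, 1L, 0L))
  p <- make_panel(al)
  p2 <- drop_unreliable_markers(p)
  expect_equal(dim(p2), c(2L, 4L))
  expect_equal(p2$markers$marker_id, p$markers$marker_id[-3])
  # identity when complete
  p3 <- make_panel(al[, -3])
  expect_identical(drop_unreliable_markers(p3), p3)
  expect_error(drop_unreliable_markers(make_panel(rbind(NA_integer_, 0L))),
               "all markers")
})

test_that("lost-haplotype reconstruction follows the genotype comparison", {
  expect_equal(reconstruct_lost_haplotype(1L, "AB"), 0L)  # het: other allele
  expect_equal(reconstruct_lost_haplotype(0L, "AA"), 0L)  # hom: same allele
  expect_equal(reconstruct_lost_haplotype(1L, "AA"), NA_integer_)  # clash
  expect_equal(reconstruct_lost_haplotype(0L, "BB"), NA_integer_)
  expect_error(reconstruct_lost_haplotype(c(0L, 1L), "AB"), "length")
})

test_that("noiseless BAF recovers both parental haplotypes exactly", {
  set.seed(11)
  n <- 500
  hap_kept <- rbinom(n, 1L, 0.5)
  hap_lost <- rbinom(n, 1L, 0.5)
  geno <- c("AA", "AB", "BB")[hap_kept + hap_lost + 1L]
  baf <- ifelse(hap_kept == 1L, 1, 0)  # tumor BAF under pure LOH
  inferred <- infer_tumor_haplotype(baf)
  expect_equal(inferred, hap_kept)
  expect_equal(reconstruct_lost_haplotype(inferred, geno), hap_lost)
})

test_that("noisy BAF inference stays under the expected error rate", {
  set.seed(42)
  n <- 20000
  hap <- rbinom(n, 1L, 0.5)
  baf <- pmin(pmax(ifelse(hap == 1L, 0.95, 0.05) + rnorm(n, 0, 0.05), 0), 1)
  inferred <- infer_tumor_haplotype(baf)
  called <- !is.na(inferred)
  expect_lt(haplotype_error_rate(inferred, hap), 1e-3)
  expect_gt(mean(called), 0.99)  # few markers flagged unreliable
})

test_that("haplotype error rate counts mismatches over compared positions", {
  expect_equal(haplotype_error_rate(rep(1L, 1000), rep(1L, 1000)), 0)
  h1 <- rep(0L, 10000); h2 <- h1; h2[5000] <- 1L
  expect_equal(haplotype_error_rate(h1, h2), 1e-4)
  expect_error(haplotype_error_rate(NA_integer_, 1L), "no pairwise")
})

test_that("panel inference composes LOH calls, regions and BAF thresholds", {
  mm_n <- 40L
  markers <- data.frame(marker_id = sprintf("m%02d", 1:mm_n), chrom = "1",
                        pos = (1:mm_n) * 100L)
  set.seed(3)
  hap <- matrix(rbinom(3L * mm_n, 1L, 0.5), nrow = mm_n)
  baf_mat <- ifelse(hap == 1L, 0.97, 0.03)
  colnames(baf_mat) <- paste0("s", 1:3)
  f <- file.path(tempdir(), "baf.tsv")
  write.table(cbind(markers, baf_mat), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  baf <- read_baf_table(f)
  ascn <- ascn_segments(paste0("s", 1:3), "1", rep(1L, 3),
                        rep(4100L, 3), 1, 0)
  panels <- infer_haplotype_panels(baf, ascn, min_frequency = 1.0)
  expect_length(panels, 1L)
  expect_equal(dim(panels[[1]]), c(3L, mm_n))
  expect_equal(unname(panels[[1]]$alleles), t(hap))
})
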