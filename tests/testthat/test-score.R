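test_that("segment score follows the -2 sum log frequency closed form", {
  mm <- make_map(2, b_freq = c(0.5, 0.2))
  p <- haplotype_panel(rbind(c(1L, 1L), c(1L, 1L)), mm)
  s <- segment_score(seg_row(1L, 1L, 2L), p)
  expect_equal(s, -2 * (log(0.5) + log(0.2)), tolerance = 1e-12)

  p10 <- make_panel(rbind(rep(1L, 10), rep(1L, 10)), b_freq = 0.5)
  expect_equal(segment_score(seg_row(1L, 1L, 10L), p10), 20 * log(2),
               tolerance = 1e-12)

  # all-frequency-1 alleles carry no information (up to the clamp)
  p1 <- make_panel(rbind(rep(1L, 5), rep(1L, 5)), b_freq = 1)
  expect_lt(segment_score(seg_row(1L, 1L, 5L), p1), 0.01)
  expect_gte(segment_score(seg_row(1L, 1L, 5L), p1), 0)

  mm_na <- make_map(2, b_freq = NA_real_)
  p_na <- haplotype_panel(rbind(c(1L, 1L), c(1L, 1L)), mm_na)
  expect_error(segment_score(seg_row(1L, 1L, 2L), p_na), "b_freq")
})

test_that("segment score is additive over partitions and monotone in rarity", {
  set.seed(8)
  p <- random_panel(2, 50, p_b = 0.5)
  p$markers$b_freq <- runif(50, 0.1, 0.9)
  whole <- segment_score(seg_row(1L, 1L, 50L), p)
  parts <- segment_score(seg_row(1L, 1L, 20L), p) +
    segment_score(seg_row(1L, 21L, 50L), p)
  expect_equal(whole, parts, tolerance = 1e-10)

  # making a carried B allele rarer strictly increases the score
  b_marker <- which(p$alleles[1L, ] == 1L)[1L]
  p2 <- p
  p2$markers$b_freq[b_marker] <- p$markers$b_freq[b_marker] / 2
  expect_gt(segment_score(seg_row(1L, 1L, 50L), p2), whole)
})

test_that("per-SNP scores sum covering segments and vanish elsewhere", {
  mm <- make_map(10)
  empty <- find_pairwise_ibd(make_panel(rbind(rep(0L, 10), rep(1L, 10))))
  expect_equal(per_snp_scores(empty, mm)$ibd_score, rep(0, 10))

  seg <- data.frame(hap1_idx = 1L, start_idx = c(2L, 5L),
                    end_idx = c(6L, 8L), score = c(3.0, 4.5))
  tr <- per_snp_scores(seg, mm)
  expect_equal(tr$ibd_score, c(0, 3, 3, 3, 7.5, 7.5, 4.5, 4.5, 0, 0))
  # conservation: total mass equals sum of score x markers covered
  expect_equal(sum(tr$ibd_score), 3 * 5 + 4.5 * 4)

  one <- data.frame(hap1_idx = 1L, start_idx = 3L, end_idx = 7L, score = 7.2)
  expect_equal(unique(per_snp_scores(one, mm)$ibd_score[3:7]), 7.2)
})

test_that("bulk segment scoring matches the per-segment closed form", {
  set.seed(21)
  p <- random_panel(20, 800, p_b = 0.4)
  p$markers$b_freq <- runif(800, 0.05, 0.95)
  al <- p$alleles
  al[4, 101:400] <- al[2, 101:400]
  p$alleles <- al
  seg <- find_pairwise_ibd(p)
  cost <- foundertracker:::allele_cost_cumsum(p$alleles, p$markers$b_freq)
  scored <- foundertracker:::score_segments(seg, cost)
  for (k in seq_len(nrow(scored)))
    expect_equal(scored$score[k], segment_score(scored[k, ], p),
                 tolerance = 1e-9)
  # conservation across the whole track
  tr <- per_snp_scores(scored, p$markers)
  n_mark <- scored$end_idx - scored$start_idx + 1L
  expect_equal(sum(tr$ibd_score), sum(scored$score * n_mark),
               tolerance = 1e-9)
})

test_that("reference B-allele frequencies are per-marker B fractions", {
  p <- make_panel(rbind(c(1L, 1L, 0L), c(1L, 0L, 0L),
                        c(0L, 1L, 0L), c(0L, 1L, 0L)))
  bf <- estimate_b_freqs(p)$b_freq
  expect_equal(bf, c(0.5, 0.75, 0))
})

test_that("Gumbel ML recovers parameters and honors location equivariance", {
  set.seed(123)
  x <- 2 - 1 * log(-log(runif(10000)))  # Gumbel(mu = 2, beta = 1)
  fit <- fit_gumbel(x)
  expect_equal(fit$mu, 2, tolerance = 0.05)
  expect_equal(fit$beta, 1, tolerance = 0.05)

  shifted <- fit_gumbel(x + 10)
  expect_equal(shifted$mu, fit$mu + 10, tolerance = 1e-6)
  expect_equal(shifted$beta, fit$beta, tolerance = 1e-6)

  expect_error(fit_gumbel(rep(3, 10)), "degenerate")
  expect_error(fit_gumbel(1), "at least 2")
})

test_that("Gumbel ML agrees with an independent optimizer", {
  skip_if_not_installed("fitdistrplus")
  set.seed(9)
  x <- 5 - 2 * log(-log(runif(500)))
  fit <- fit_gumbel(x)
  # fitdistrplus looks the d/p functions up by name
  assign("dgumbel", function(x, mu, beta)
    exp(-(x - mu) / beta - exp(-(x - mu) / beta)) / beta,
    envir = globalenv())
  assign("pgumbel", function(q, mu, beta) exp(-exp(-(q - mu) / beta)),
         envir = globalenv())
  withr::defer(rm("dgumbel", "pgumbel", envir = globalenv()))
  ref <- fitdistrplus::fitdist(x, "gumbel",
                               start = list(mu = mean(x), beta = sd(x)))
  expect_equal(fit$mu, unname(ref$estimate["mu"]), tolerance = 1e-3)
  expect_equal(fit$beta, unname(ref$estimate["beta"]), tolerance = 1e-3)
})

test_that("column-wise Gumbel fit matches the scalar fit", {
  set.seed(31)
  X <- cbind(1 - 2 * log(-log(runif(200))),
             -4 + 0.5 * -log(-log(runif(200))) * 1,
             rep(0, 200))  # third column degenerate
  f <- foundertracker:::fit_gumbel_matrix(X)
  s1 <- fit_gumbel(X[, 1]); s2 <- fit_gumbel(X[, 2])
  expect_equal(f$mu[1:2], c(s1$mu, s2$mu), tolerance = 1e-6)
  expect_equal(f$beta[1:2], c(s1$beta, s2$beta), tolerance = 1e-6)
  expect_true(f$degenerate[3])
  expect_equal(f$mu[3], 0)
})

test_that("Gumbel p-values hit the closed-form survival values", {
  mm <- make_map(3, b_freq = 0.5)
  null <- structure(list(marker_id = mm$marker_id, mu = c(5, 5, 5),
                         beta = c(2, 2, 2), degenerate = rep(FALSE, 3),
                         n_subsets = 10L, subset_size = 5L),
                    class = "gumbel_null")
  tr <- score_track(mm, c(5, 1e6, 0))
  tr <- score_pvalues(tr, null)
  expect_equal(tr$p_value[1], 1 - exp(-1), tolerance = 1e-12)
  expect_lt(tr$p_value[2], 1e-12)   # far right tail
  expect_gt(tr$p_value[3], 0.9)     # far left tail
  bad <- score_track(make_map(2), c(0, 0))
  expect_error(score_pvalues(bad, null), "scaffold")
})

test_that("degenerate null markers reduce to an exceedance test", {
  mm <- make_map(2, b_freq = 0.5)
  null <- structure(list(marker_id = mm$marker_id, mu = c(0, 0),
                         beta = c(1e-6, 1e-6), degenerate = c(TRUE, TRUE),
                         n_subsets = 10L, subset_size = 5L),
                    class = "gumbel_null")
  tr <- score_pvalues(score_track(mm, c(3, 0)), null)
  expect_equal(tr$p_value, c(0, 1))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  # hand computation: sorted (0.001, 0.04, 0.2, 0.9), m = 4
  expect_equal(bh_qvalues(p), c(0.004, 0.2666667, 0.08, 0.9),
               tolerance = 1e-6)
  expect_error(bh_qvalues(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("significant regions are maximal q-threshold runs", {
  mm <- make_map(4)
  tr <- score_track(mm, rep(1, 4), p_value = 1,
                    q_value = c(0.5, 0.005, 0.005, 0.5))
  r <- significant_regions(tr, 0.01)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_bp, mm$pos_bp[2])
  expect_equal(r$end_bp, mm$pos_bp[3])
  expect_equal(r$n_markers, 2L)

  tr$q_value <- rep(0.5, 4)
  expect_equal(nrow(significant_regions(tr, 0.01)), 0L)
  tr$q_value <- c(0.001, 0.5, 0.001, 0.001)
  expect_equal(nrow(significant_regions(tr, 0.01)), 2L)
})

test_that("generation count is 1/(2L) Morgans", {
  expect_equal(estimate_generations(5.4), 9.259259, tolerance = 1e-6)
  expect_equal(round(estimate_generations(5.4)), 9)  # around nine
  expect_equal(estimate_generations(50), 1)
  expect_equal(estimate_generations(2), 25)
  expect_error(estimate_generations(0), "positive")
})

test_that("null construction is deterministic and validates inputs", {
  ref <- generate_reference_panel(
    panel_gen_config(n_haplotypes = 20, n_markers = 600,
                     chrom_length_cM = 6, n_founders = 8, seed = 77))
  n1 <- build_null(ref, 8, n_subsets = 10, seed = 42)
  n2 <- build_null(ref, 8, n_subsets = 10, seed = 42)
  expect_identical(n1, n2)
  n3 <- build_null(ref, 8, n_subsets = 10, seed = 43)
  expect_false(identical(n1$mu, n3$mu))
  expect_error(build_null(ref, 25, n_subsets = 10), "smaller")
  expect_error(build_null(ref, 8, n_subsets = 1), "at least 2")
  expect_true(all(n1$beta > 0))
})

test_that("reference subsets score as typical draws from their own null", {
  # p-values of fresh subsets of the reference should be near-uniform
  set.seed(555)
  # a closely related panel so every marker sees IBD mass in every subset
  # and the per-marker score distribution is continuous
  cfg <- panel_gen_config(n_haplotypes = 60, n_markers = 2500,
                          chrom_length_cM = 25, n_founders = 30,
                          seed = 404)
  ref <- generate_reference_panel(cfg)
  null <- build_null(ref, 25, n_subsets = 60, seed = 11)
  bf <- estimate_b_freqs(ref)$b_freq
  cost <- foundertracker:::allele_cost_cumsum(ref$alleles, bf)
  # score fresh subsets; collect p at widely spaced markers to limit
  # serial correlation along the chromosome
  probe <- seq(100, 2400, by = 230)
  pvals <- c()
  for (b in 1:40) {
    idx <- sample.int(60, 25)
    seg <- find_pairwise_ibd(ref[idx, ])
    seg$hap1_idx <- idx[seg$hap1_idx]
    seg <- foundertracker:::score_segments(seg, cost)
    sc <- foundertracker:::per_snp_scores_vec(seg, 2500)
    tr <- score_pvalues(score_track(ref$markers, sc), null)
    pvals <- c(pvals, tr$p_value[probe])
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
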