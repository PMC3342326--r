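test_that("mosaic panel generation is deterministic and founder-faithful", {
  cfg <- panel_gen_config(n_haplotypes = 30, n_markers = 1000,
                          chrom_length_cM = 10, n_founders = 5,
                          switch_rate_per_cM = 1e-9, flip_rate = 0,
                          seed = 21)
  p <- generate_reference_panel(cfg)
  p2 <- generate_reference_panel(cfg)
  expect_identical(p$alleles, p2$alleles)  # fixed seed, bitwise identical

  # without switches or flips every haplotype copies one founder; with 5
  # founders and 30 haplotypes some founder is copied twice, and those
  # copies are identical across all markers
  d <- as.matrix(dist(p$alleles, method = "manhattan"))
  diag(d) <- NA
  expect_true(any(d == 0, na.rm = TRUE))
})

test_that("pairwise identity matches the frequency-law expectation", {
  cfg <- panel_gen_config(n_haplotypes = 40, n_markers = 10000,
                          chrom_length_cM = 100, seed = 5)
  p <- generate_reference_panel(cfg)
  pairs <- combn(40, 2)
  sel <- pairs[, sample(ncol(pairs), 120)]
  ident <- mean(sapply(seq_len(ncol(sel)), function(k)
    mean(p$alleles[sel[1, k], ] == p$alleles[sel[2, k], ])))
  # E[f^2 + (1-f)^2] for f ~ U(0.05, 0.95): 1 - 2(E f - E f^2)
  ef <- 0.5; ef2 <- 0.0675 + 0.25
  expect_equal(ident, 1 - 2 * (ef - ef2), tolerance = 0.02)
})

test_that("planted haplotypes share the focal point and the first sample", {
  cfg <- panel_gen_config(n_haplotypes = 50, n_markers = 5000,
                          chrom_length_cM = 50, seed = 31)
  tum <- generate_reference_panel(cfg)
  pl <- plant_conserved_haplotype(tum, plant_config(1.0, 5, seed = 4))
  tr <- pl$truth
  expect_equal(length(tr$carrier_idx), 50L)
  expect_true(1L %in% tr$carrier_idx)
  cm <- tum$markers$pos_cM
  for (k in seq_along(tr$carrier_idx)) {
    s <- tr$start_idx[k]; e <- tr$end_idx[k]
    # segment contains the focal location
    expect_lte(cm[s], tr$focal_cM + 0.011)
    expect_gte(cm[e], tr$focal_cM - 0.011)
    # carrier equals sample 1 over its segment
    expect_equal(pl$panel$alleles[tr$carrier_idx[k], s:e],
                 pl$panel$alleles[1L, s:e])
  }
})

test_that("carrier counts round the prevalence and reject zero", {
  cfg <- panel_gen_config(n_haplotypes = 100, n_markers = 2000,
                          chrom_length_cM = 20, seed = 13)
  tum <- generate_reference_panel(cfg)
  pl <- plant_conserved_haplotype(tum, plant_config(0.02, 2, seed = 1))
  expect_length(pl$truth$carrier_idx, 2L)
  pl7 <- plant_conserved_haplotype(tum, plant_config(0.07, 2, seed = 1))
  expect_length(pl7$truth$carrier_idx, 7L)
  expect_error(plant_conserved_haplotype(tum, plant_config(0.004, 2)),
               "no carriers")
})

test_that("clamped Gumbel lengths keep the expected mean", {
  set.seed(19)
  L <- foundertracker:::rgumbel(10000, 5, 5)
  L <- pmin(pmax(L, 0.1), 100)
  gamma <- 0.5772156649
  expect_equal(mean(L), 5 * (1 + gamma), tolerance = 0.03 * 5 * (1 + gamma))
})

test_that("power study is reproducible and degenerates sanely", {
  cfg <- panel_gen_config(n_haplotypes = 60, n_markers = 1500,
                          chrom_length_cM = 15, n_founders = 60)
  pc <- plant_config(0.25, 3)
  s1 <- run_power_study(cfg, pc, n_tumor = 20L, n_reps = 2L,
                        n_null_subsets = 10L,
                        methods = "foundertracker", seed = 88)
  s2 <- run_power_study(cfg, pc, n_tumor = 20L, n_reps = 2L,
                        n_null_subsets = 10L,
                        methods = "foundertracker", seed = 88)
  expect_identical(s1$power, s2$power)
  expect_identical(s1$n_false, s2$n_false)
  expect_identical(s1$roc, s2$roc)

  # a single carrier leaves nothing for pairwise IBD to find: the panel is
  # untouched and detection reduces to the (near-zero) false-positive rate
  tum1 <- generate_reference_panel(
    panel_gen_config(n_haplotypes = 20, n_markers = 1500,
                     chrom_length_cM = 15, seed = 3))
  pl1 <- plant_conserved_haplotype(tum1, plant_config(0.05, 3, seed = 2))
  expect_identical(pl1$panel$alleles, tum1$alleles)
  # reference large enough that every marker sees IBD mass in the null
  cfg_lone <- panel_gen_config(n_haplotypes = 120, n_markers = 2000,
                               chrom_length_cM = 20, n_founders = 60)
  lone <- run_power_study(cfg_lone, plant_config(0.025, 3), n_tumor = 40L,
                          n_reps = 2L, n_null_subsets = 20L,
                          methods = "foundertracker", seed = 5)
  expect_equal(unname(lone$power["foundertracker"]), 0)

  # ROC rates are proper rates
  expect_true(all(s1$roc$tpr >= 0 & s1$roc$tpr <= 1))
  expect_true(all(s1$roc$fpr >= 0 & s1$roc$fpr <= 1))
  expect_error(run_power_study(cfg, pc, n_tumor = 40L, n_reps = 1L),
               "reference half")
})

test_that("a strong planted signal is detected in a small study", {
  cfg <- panel_gen_config(n_haplotypes = 90, n_markers = 3000,
                          chrom_length_cM = 30, n_founders = 200)
  st <- run_power_study(cfg, plant_config(0.4, 5), n_tumor = 30L,
                        n_reps = 3L, n_null_subsets = 20L,
                        methods = c("foundertracker", "dash"), seed = 7)
  expect_equal(unname(st$power["foundertracker"]), 1)
  expect_equal(unname(st$power["dash"]), 1)
})
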