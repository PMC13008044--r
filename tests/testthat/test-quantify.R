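# Replicate aggregation, the Livak and Pfaffl formulas, and the
# per-sample quantification driver.

test_that("replicate aggregation applies the both-replicates exclusion rule", {
  # both replicates above the L1 reference cutoff: excluded
  agg <- aggregate_replicates(c(31.0, 30.5), ct_cutoff = 30.25)
  expect_true(agg$excluded)
  expect_true(is.na(agg$mean_ct))
  # one-sided failure: the passing replicate is used alone, flagged
  agg <- aggregate_replicates(c(29.9, 31.0), ct_cutoff = 30.25)
  expect_false(agg$excluded)
  expect_equal(agg$mean_ct, 29.9)
  expect_equal(agg$n_used, 1L)
  expect_true(agg$flagged)
  # clean duplicates
  agg <- aggregate_replicates(c(20.0, 20.4))
  expect_equal(agg$mean_ct, 20.2)
  expect_false(agg$flagged)
  # undetermined counts like above-cutoff
  expect_true(aggregate_replicates(c(NA_real_, NA_real_))$excluded)
})

test_that("the Livak formula reproduces the delta-delta-CT ratios", {
  expect_identical(livak_level(25, 20, 25, 20), 100) # sample == calibrator
  expect_equal(livak_level(26, 20, 25, 20), 50)
  expect_equal(livak_level(24, 20, 25, 20), 200) # > 100% is preserved
  expect_error(livak_level(NA_real_, 20, 25, 20), "not computable")
})

test_that("the Pfaffl formula applies per-assay efficiency corrections", {
  # target one cycle late at E = 0.9, reference unchanged: 100 / 1.9
  expect_equal(pfaffl_level(26, 25, 0.9, 20, 20, 0.85), 100 / 1.9)
  expect_equal(pfaffl_level(25, 25, 0.77, 20, 20, 0.93), 100)
  expect_error(pfaffl_level(26, 25, 1.9, 20, 20, 0.85), "e_me")
})

test_that("Pfaffl collapses to Livak at 100% efficiencies", {
  set.seed(14)
  for (i in 1:200) {
    cts <- runif(4, 15, 35)
    expect_equal(pfaffl_level(cts[1], cts[3], 1, cts[2], cts[4], 1),
                 livak_level(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-12)
  }
})

test_that("noise-free unbiased simulation quantifies to the generating truth", {
  pair <- test_assay_pair(e = 0.9)
  ms <- seq(0.05, 1, by = 0.05)
  groups <- list(list(label = "grid", n = length(ms),
                      methylation = function(p) ms))
  tbl <- simulate_cohort(groups, list(pair$msp, pair$mip),
                         sim_config(ct_noise_sd = 0))
  truth <- attr(tbl, "truth")
  # efficiency-corrected quantification is exact for any shared E
  res <- quantify_samples(tbl, test_config("PFAFFL", e = 0.9))
  i <- match(res$sample_id, truth$sample_id)
  expect_equal(res$methylation_pct, 100 * truth$true_methylation[i],
               tolerance = 1e-6)
  # Livak is exact when every assay doubles perfectly
  pair2 <- test_assay_pair(e = 1.0)
  tbl2 <- simulate_cohort(groups, list(pair2$msp, pair2$mip),
                          sim_config(ct_noise_sd = 0))
  res2 <- quantify_samples(tbl2, test_config("LIVAK"))
  i <- match(res2$sample_id, truth$sample_id)
  expect_equal(res2$methylation_pct, 100 * truth$true_methylation[i],
               tolerance = 1e-6)
})

test_that("status conventions: ZERO_SIGNAL, EXCLUDED, missing calibrator", {
  pair <- test_assay_pair(e = 0.9)
  groups <- list(list(label = "g", n = 2, methylation = function(p) c(0, 0.5)))
  tbl <- simulate_cohort(groups, list(pair$msp, pair$mip),
                         sim_config(ct_noise_sd = 0))
  res <- quantify_samples(tbl, test_config("PFAFFL"))
  z <- res[res$sample_id == "g_001", ]
  expect_equal(z$status, "ZERO_SIGNAL")
  expect_equal(z$methylation_pct, 0)
  # push both reference replicates above an artificial cutoff -> EXCLUDED
  ref_ct <- tbl$ct[tbl$assay_id == "Ref" & tbl$sample_id == "g_002"]
  res2 <- quantify_samples(tbl, test_config("PFAFFL",
                                            cutoff_ref = min(ref_ct) - 0.1))
  expect_equal(res2$status[res2$sample_id == "g_002"], "EXCLUDED")
  expect_true(is.na(res2$methylation_pct[res2$sample_id == "g_002"]))
  # calibrator must be present
  expect_error(quantify_samples(tbl[tbl$sample_id != "CAL", ],
                                test_config("PFAFFL")),
               "calibrator")
})

test_that("AUTO pairs require and use a formula choice", {
  pair <- test_assay_pair(e = 0.9)
  tbl <- simulate_cohort(list(list(label = "g", n = 2, methylation = 0.5)),
                         list(pair$msp, pair$mip),
                         sim_config(ct_noise_sd = 0))
  cfg <- test_config("AUTO")
  expect_error(quantify_samples(tbl, cfg), "AUTO")
  std_cfg <- sim_config(ct_noise_sd = 0)
  ch <- select_formula(simulate_dilution_series(pair$msp, config = std_cfg),
                       simulate_dilution_series(pair$mip, config = std_cfg))
  res <- quantify_samples(tbl, cfg, choices = list("Me|Ref" = ch))
  expect_equal(unique(res$formula), "LIVAK")
})

test_that("quantification is invariant to input row order", {
  pair <- test_assay_pair(e = 0.9)
  tbl <- simulate_cohort(list(list(label = "g", n = 6,
                                   methylation = methylation_dist(0.6, 0.1))),
                         list(pair$msp, pair$mip),
                         sim_config(seed = 8, ct_noise_sd = 0.1))
  res1 <- quantify_samples(tbl, test_config("PFAFFL"))
  set.seed(1)
  shuffled <- tbl[sample(nrow(tbl)), ]
  res2 <- quantify_samples(shuffled, test_config("PFAFFL"))
  expect_equal(res1, res2)
})

test_that("CT noise propagates multiplicatively at the predicted magnitude", {
  # duplicate wells with CT noise sd 0.1 on all four reactions give
  # sd(ddCT) = 0.1 * sqrt(4/2), hence an ln-scale error of about
  # ln(2) * 0.141 = 0.098 under Livak; the calibrator's contribution is
  # shared across samples, so draw each sample with its own calibrator
  pair <- test_assay_pair(e = 1.0)
  lnerr <- vapply(1:120, function(s) {
    tbl <- simulate_cohort(list(list(label = "g", n = 1, methylation = 0.5)),
                           list(pair$msp, pair$mip),
                           sim_config(seed = s, ct_noise_sd = 0.1))
    log(quantify_samples(tbl, test_config("LIVAK"))$methylation_pct / 50)
  }, 0)
  predicted <- log(2) * 0.1 * sqrt(4 / 2)
  expect_equal(mean(lnerr), 0, tolerance = 0.03)
  expect_gt(sd(lnerr), 0.5 * predicted)
  expect_lt(sd(lnerr), 1.5 * predicted)
})
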