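# The mechanistic generator: per-well template accounting, dilution series,
# mixture panels and cohorts.

noise_free <- function(seed = 1, n_replicates = 2L) {
  sim_config(seed = seed, ct_noise_sd = 0, n_replicates = n_replicates)
}

test_that("a fully methylated sample amplified by MIP matches the closed form", {
  a <- assay_spec("Ref", "MIP", "LINE1", e_meth = 0.9)
  s <- sample_spec("fm", 1, 200)
  w <- simulate_well(s, a, noise_free())
  n0 <- 200 * repeat_copies_per_pg("LINE1") * 0.1
  expect_equal(w$ct, closed_form_ct(n0, 0.9, a$threshold_copies),
               tolerance = 1e-9)
})

test_that("copy conservation holds without conversion losses", {
  # invert the closed form: recovered n0 must equal mass x copies x fraction
  a <- assay_spec("Ref", "MIP", "ALU", e_meth = 0.87)
  s <- sample_spec("fm", 1, 157.3, bisulfite_recovery = 1,
                   conversion_failure = 0)
  w <- simulate_well(s, a, noise_free())
  n0 <- a$threshold_copies / (1 + 0.87)^w$ct
  expect_equal(n0, 157.3 * repeat_copies_per_pg("ALU") * 0.1,
               tolerance = 1e-6)
})

test_that("an unmethylated sample gives no MSP signal without cross-reactivity", {
  a <- assay_spec("Me", "MSP", "LINE1", e_meth = 0.9)
  s <- sample_spec("um", 0, 200)
  expect_true(is.na(simulate_well(s, a, noise_free())$ct))
  # with cross-reactivity the unmethylated pool is amplifiable
  ax <- assay_spec("Mex", "MSP", "LINE1", e_meth = 0.9,
                   cross_reactivity = 0.01)
  expect_false(is.na(simulate_well(s, ax, noise_free())$ct))
})

test_that("a biased MIP assay shifts the mixture CT toward the faster allele", {
  s <- sample_spec("half", 0.5, 200)
  biased <- assay_spec("R1", "MIP", "LINE1", e_meth = 0.80, e_unmeth = 0.95)
  slow <- assay_spec("R2", "MIP", "LINE1", e_meth = 0.80, e_unmeth = 0.80)
  ct_biased <- simulate_well(s, biased, noise_free())$ct
  ct_slow <- simulate_well(s, slow, noise_free())$ct
  expect_lt(ct_biased, ct_slow)
  expect_equal(ct_biased,
               brute_force_ct(0.5, 0.5, 0.80, 0.95,
                              biased$threshold_copies /
                                (200 * repeat_copies_per_pg("LINE1") * 0.1)),
               tolerance = 0.01)
})

test_that("noise-free dilution series is exactly log-linear", {
  a <- assay_spec("Ref", "MIP", "LINE1", e_meth = 1.0)
  std <- simulate_dilution_series(a, config = noise_free())
  fit <- lm(ct ~ log10(input_mass_pg), data = std)
  expect_equal(unname(coef(fit)[2]), -1 / log10(2), tolerance = 1e-9)
})

test_that("dilution series validates masses and covers the default grid", {
  a <- assay_spec("Ref", "MIP", "LINE1", e_meth = 0.9)
  expect_error(simulate_dilution_series(a, masses_pg = numeric(0)))
  expect_error(simulate_dilution_series(a, masses_pg = c(100, 0)),
               "positive")
  std <- simulate_dilution_series(a, config = noise_free())
  expect_setequal(unique(std$input_mass_pg),
                  c(1000, 250, 62.5, 15.625, 3.125))
  expect_equal(nrow(std), 10)
})

test_that("mixture panel validates levels and emits the calibrator", {
  pair <- test_assay_pair()
  expect_error(simulate_mixture_panel(pair$msp, pair$mip,
                                      levels_pct = c(-1, 50)),
               "\\[0, 100\\]")
  pan <- simulate_mixture_panel(pair$msp, pair$mip, config = noise_free())
  truth <- attr(pan, "truth")
  expect_true("CAL" %in% truth$sample_id)
  expect_equal(sort(truth$true_methylation),
               sort(c(0, 0.125, 0.25, 0.5, 0.75, 1, 1)))
  # one well per sample x assay x replicate
  expect_equal(nrow(pan), 7 * 2 * 2)
})

test_that("seeded simulation is bit-reproducible and noise 0 deterministic", {
  pair <- test_assay_pair()
  cfg <- sim_config(seed = 99, ct_noise_sd = 0.1)
  p1 <- simulate_mixture_panel(pair$msp, pair$mip, config = cfg)
  p2 <- simulate_mixture_panel(pair$msp, pair$mip, config = cfg)
  expect_identical(p1, p2)
  d1 <- simulate_dilution_series(pair$mip, config = noise_free(1))
  d2 <- simulate_dilution_series(pair$mip, config = noise_free(2))
  expect_equal(d1$ct, d2$ct) # no noise: seed irrelevant
})

test_that("mass-dependent conversion failure raises dCT(MIP - MSP) with input", {
  # the saturating failure converts part of the unmethylated pool into
  # MSP-amplifiable signal; at higher input mass the failure fraction grows,
  # the MSP CT drops relative to the MIP CT and dCT = CT(MIP) - CT(MSP)
  # increases
  pair <- test_assay_pair()
  cf <- saturating_conversion_failure(f_max = 0.15, K = 5000)
  dct_at <- function(mass) {
    s <- sample_spec("s", 0.9, mass, conversion_failure = cf)
    simulate_well(s, pair$mip, noise_free())$ct -
      simulate_well(s, pair$msp, noise_free())$ct
  }
  dcts <- vapply(c(200, 1000, 5000, 50000), dct_at, 0)
  expect_true(all(diff(dcts) > 0))
  # at m = 1 there is no unmethylated pool to misread: no effect
  s1 <- sample_spec("fm1", 1, 50000, conversion_failure = cf)
  s0 <- sample_spec("fm0", 1, 50000, conversion_failure = 0)
  expect_equal(simulate_well(s1, pair$msp, noise_free())$ct,
               simulate_well(s0, pair$msp, noise_free())$ct)
})

test_that("cohort generator enforces group structure", {
  pair <- test_assay_pair()
  expect_error(simulate_cohort(list(list(label = "g", n = 0,
                                         methylation = 0.5)),
                               list(pair$msp, pair$mip)),
               "'n'")
  expect_error(simulate_cohort(list(list(label = "a", n = 3,
                                         methylation = 0.5),
                                    list(label = "b", n = 4,
                                         methylation = 0.5)),
                               list(pair$msp, pair$mip), paired = TRUE),
               "equal")
})

test_that("paired groups with identical distributions are exactly matched", {
  pair <- test_assay_pair()
  groups <- list(list(label = "a", n = 10,
                      methylation = methylation_dist(0.7, 0.05)),
                 list(label = "b", n = 10,
                      methylation = methylation_dist(0.7, 0.05)))
  tbl <- simulate_cohort(groups, list(pair$msp, pair$mip),
                         noise_free(5), paired = TRUE)
  truth <- attr(tbl, "truth")
  expect_equal(truth$true_methylation[truth$group == "a"],
               truth$true_methylation[truth$group == "b"])
  res <- quantify_samples(tbl, test_config("PFAFFL"))
  cmp <- compare_two_groups(res$methylation_pct[res$group == "a"],
                            res$methylation_pct[res$group == "b"],
                            paired = TRUE)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$test_name, "degenerate")
})
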