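# Independent oracles and shared builders for the test suite.

# Brute-force threshold cycle: accumulate both template pools cycle by
# cycle and interpolate the crossing log-linearly between integer cycles.
# Deliberately independent of the root-finding in mixture_ct().
brute_force_ct <- function(n_m, n_u, e_m, e_u, q, max_cycles = 2000L) {
  total_prev <- n_m + n_u
  stopifnot(total_prev > 0, q > total_prev)
  for (cyc in seq_len(max_cycles)) {
    n_m <- n_m * (1 + e_m)
    n_u <- n_u * (1 + e_u)
    total <- n_m + n_u
    if (total >= q) {
      return(cyc - 1 + (log(q) - log(total_prev)) /
               (log(total) - log(total_prev)))
    }
    total_prev <- total
  }
  stop("threshold not reached")
}

# One MSP + one MIP LINE-1 assay pair; equal allele efficiencies unless a
# MIP gap is requested (e_meth kept at `e`, e_unmeth lowered by `mip_gap`).
test_assay_pair <- function(e = 0.9, mip_gap = 0, e_msp = e) {
  list(msp = assay_spec("Me", "MSP", "LINE1", e_meth = e_msp),
       mip = assay_spec("Ref", "MIP", "LINE1", e_meth = e,
                        e_unmeth = e - mip_gap))
}

test_config <- function(formula = "PFAFFL", e = 0.9, e_msp = e,
                        cutoff_me = NA, cutoff_ref = NA) {
  run_config(
    data.frame(assay_id = c("Me", "Ref"), role = c("MSP", "MIP"),
               element = "LINE1", efficiency = c(e_msp, e),
               ct_cutoff = c(cutoff_me, cutoff_ref)),
    calibrator_id = "CAL",
    pairs = data.frame(element = "LINE1", target_assay = "Me",
                       reference_assay = "Ref", formula = formula))
}

# Small deterministic well table for IO tests.
make_wells <- function(n = 8, seed = 42) {
  set.seed(seed)
  data.frame(
    sample_id = rep(sprintf("s%02d", seq_len(n / 2)), each = 2),
    assay_id = "Me", replicate = rep(1:2, n / 2),
    ct = round(runif(n, 18, 32), 4),
    input_mass_pg = 200, group = "test",
    stringsAsFactors = FALSE)
}
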