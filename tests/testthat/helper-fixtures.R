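# Shared fixtures, generated in code. All randomness is seed-fixed.

# Small strong-signal cohort used by several recovery tests.
strong_cohort <- function(seed = 42) {
  simulate_cohort(cohort_config(seed = seed))
}

# Null cohort: no latent-factor coupling anywhere.
null_cohort_config <- function(seed) {
  cohort_config(n_subjects = 16, grid_dims = c(20, 24, 20),
                signal_beta = 0, loadings = rep(0, 17), seed = seed)
}

# Run preprocessing (full-sample residualization) on a cohort.
preprocess_fixture <- function(cohort, residualize = TRUE) {
  preprocess_cohort(cohort$volumes, cohort$mask,
                    ages = cohort$demographics$age,
                    voxel_size_mm = cohort$config$voxel_size_mm,
                    residualize = residualize)
}

# Published group-comparison rows (mean, SD, n = 16 per group) used to
# check the summary-statistics t-test path.
published_rows <- function() {
  data.frame(
    measure = c("Age", "ROCF_copy", "CBTT_bwd", "DST_fwd"),
    m1 = c(25.56, 30.38, 36.81, 56.81),
    s1 = c(16.94, 6.21, 32.44, 27.26),
    n1 = 16,
    m2 = c(23.75, 26.81, 20.38, 28.38),
    s2 = c(11.77, 8.36, 21.36, 12.50),
    n2 = 16,
    p_published = c(0.728, 0.181, 0.101, 0.001),
    stringsAsFactors = FALSE)
}
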