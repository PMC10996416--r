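# Small hand-built datasets used across test files.

# Six cases, one finding, two readers, hand-countable confusion cells.
toy_six_cases <- function() {
  study_dataset(tibble::tibble(
    case_id = paste0("c", 1:6),
    finding = "pneumothorax",
    truth       = c(1L, 1L, 1L, 0L, 0L, 0L),
    radiologist = c(1L, 0L, 1L, 0L, 1L, 0L),
    ai          = c(1L, 1L, NA, 0L, 0L, 0L)
  ))
}

# Random rectangular dataset for property tests (no unavailable calls);
# operating points themselves are drawn at random, deterministically in seed.
random_dataset <- function(n_cases, seed, prevalence = 0.3) {
  pars <- withr::with_seed(seed, runif(6))
  cfg <- sim_config(n_cases,
                    prevalence = prevalence,
                    se_a = 0.2 + 0.7 * pars[1], sp_a = 0.8 + 0.2 * pars[2],
                    se_b = 0.2 + 0.7 * pars[3], sp_b = 0.8 + 0.2 * pars[4],
                    dep_pos = pars[5], dep_neg = pars[6],
                    seed = seed + 1)
  simulate_dataset(cfg)
}
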