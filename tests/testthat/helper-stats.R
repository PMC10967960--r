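# simulated cohort fixtures for the statistics layer

sim_table <- function(mus, n, seed, weeks = 4) {
  set.seed(seed)
  cohorts <- c("MsDx", "MsDxF", "control")
  do.call(rbind, lapply(seq_along(mus), function(i) {
    tibble::tibble(animal = paste0(cohorts[i], seq_len(n)),
                   eye = "RE", week = weeks, cohort = cohorts[i],
                   y = rnorm(n, mus[i]))
  }))
}

make_corr_table <- function(x, y, week_x = 2, week_y = 24) {
  n <- length(x)
  rbind(
    tibble::tibble(animal = paste0("a", 1:n), eye = "RE", week = week_x,
                   cohort = "MsDx", iop_mmHg = x, vit_rpe = NA_real_),
    tibble::tibble(animal = paste0("a", 1:n), eye = "RE", week = week_y,
                   cohort = "MsDx", iop_mmHg = NA_real_, vit_rpe = y))
}
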