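# Memoized default pipeline run shared by the acceptance checks, plus the
# profile simulator used for the statistical-calibration checks.

.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.run_cache$out)) {
    .run_cache$out <- suppressMessages(run_pipeline(sim_config()))
  }
  .run_cache$out
}

# Two-category profile data across 4 communities x 4 months with
# community and month-within-community random intercepts; `shift` is the
# planted between-category difference in residual-SD units. Categories
# are balanced within strata (each stratum draw carries one observation
# of each category) so the category contrast is orthogonal to the random
# intercepts — the appropriate design for calibration checks.
sim_profiles <- function(n_per_cat = 20, shift = 0, seed = 1,
                         sd_comm = 0.5, sd_month = 0.5) {
  set.seed(seed)
  comms <- paste0("C", 1:4)
  b_comm <- stats::setNames(stats::rnorm(4, 0, sd_comm), comms)
  b_cm <- matrix(stats::rnorm(16, 0, sd_month), 4, 4,
                 dimnames = list(comms, 1:4))
  community <- sample(comms, n_per_cat, replace = TRUE)
  month <- sample(1:4, n_per_cat, replace = TRUE)
  stratum <- b_comm[community] + b_cm[cbind(community, month)]
  rbind(
    data.frame(community = community, month_index = month,
               category = "alpha",
               value = stratum + stats::rnorm(n_per_cat)),
    data.frame(community = community, month_index = month,
               category = "beta",
               value = shift + stratum + stats::rnorm(n_per_cat)))
}
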