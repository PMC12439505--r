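# Shared fixtures, all generated in code.

# Small balanced two-group cohort.
small_cohort <- function(n_normal = 5, n_mpird = 5, noise_sd = 0.2,
                         seed = 42, recordings = 2L,
                         between_participant_sd = 0.25) {
  co <- generate_cohort(cohort_config(
    n_normal = n_normal, n_mpird = max(n_mpird, 1L),
    recordings_per_participant = recordings,
    params = waveform_params(noise_sd = noise_sd),
    between_participant_sd = between_participant_sd, seed = seed))
  if (n_mpird == 0) {
    keep <- co$meta$diagnosis == "normal"
    co <- perg_cohort(co$meta[keep, , drop = FALSE],
                      co$samples[keep, , drop = FALSE])
  }
  co
}

# Deterministic two-tone test trace used against frozen reference
# coefficients (20 Hz + 45 Hz, inside the 1-100 Hz band).
two_tone_trace <- function() {
  t_s <- perg_time_grid() / 1000
  sin(2 * pi * 20 * t_s) + 0.5 * sin(2 * pi * 45 * t_s)
}

random_trace <- function() rnorm(256)

# All coefficient addresses of a decomposition's deepest-level
# representation.
all_addresses <- function(decomp) {
  c(unlist(lapply(seq_len(decomp$level), function(d) {
    sprintf("D%d-%d", d, seq_along(decomp$details[[d]]))
  })),
    sprintf("A%d-%d", decomp$level, seq_along(decomp$approximation)))
}
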