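# small cohort configurations used across tests
small_config <- function(n = 100, seed = 1, ...) {
  cohort_config(n_cases = n, seed = seed, ...)
}

# noiseless, fully rhythmic configuration (deterministic expression)
noiseless_config <- function(n = 200, seed = 1, arrhythmic = 0, ...) {
  cohort_config(
    n_cases = n, seed = seed,
    oscillator_nr1d1 = gene_oscillator(mesor = 1.4, amplitude = 1.2,
                                       acrophase = 6, noise_sd = 0),
    oscillator_bmal1 = gene_oscillator(mesor = 0, amplitude = 1.2,
                                       acrophase = 18, noise_sd = 0),
    arrhythmic_fraction = arrhythmic, ...)
}

# flat-oscillator (true null) configuration: no rhythm in either gene
flat_config <- function(n = 120, seed = 1, noise_sd = 0.5) {
  cohort_config(
    n_cases = n, seed = seed,
    oscillator_nr1d1 = gene_oscillator(mesor = 1.4, amplitude = 0,
                                       acrophase = 6, noise_sd = noise_sd),
    oscillator_bmal1 = gene_oscillator(mesor = 0, amplitude = 0,
                                       acrophase = 18, noise_sd = noise_sd))
}

# composition consisting purely of chronic head-injury deaths
all_chronic_composition <- function() {
  comp <- default_composition()
  comp$causes$prob <- ifelse(comp$causes$cause_subcategory == "head_injury",
                             1, 0)
  comp$head_injury_chronic_prob <- 1
  comp
}

# brute-force minimal circular covering arc, for cross-checking
# tightest_window: try every point as the arc start
brute_force_arc <- function(times) {
  t <- sort(times %% 24)
  best <- NULL
  for (s in t) {
    span <- max((t - s) %% 24)
    if (is.null(best) || span < best$length)
      best <- list(start = s, end = (s + span) %% 24, length = span)
  }
  best
}
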