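# Shared signal fixtures, generated in code.

# Continuous 1 Hz tone plus a 6 Hz tone gated on over the middle third:
# the classic intermittency signal that provokes mode mixing in plain EMD.
gated_two_tone <- function(seed, n = 1000, fs = 100) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  ph <- runif(2, 0, 2 * pi)
  a <- runif(1, 0.2, 0.5)
  gate <- as.numeric(t >= max(t) / 3 & t < 2 * max(t) / 3)
  hi <- a * gate * sin(2 * pi * 6 * t + ph[2])
  list(x = sin(2 * pi * 1 * t + ph[1]) + hi, hi = hi, t = t)
}

# A compact labeled window set: EEMD windows of a small synthetic cohort.
small_cohort_windows <- function(n_subjects = 2, activities = c("resting", "drinking"),
                                 seed = 1, n_ensembles = 100) {
  cohort <- generate_cohort(n_subjects,
                            lapply(activities, activity_profile),
                            seed = seed, body_parts = "lower_arm",
                            axes = "roll")
  sets <- lapply(seq_along(cohort$recordings), function(i) {
    pre <- preprocess_signal(cohort$recordings[[i]]$mixed)
    d <- eemd(pre, eemd_config(n_ensembles = n_ensembles,
                               seed = seed + i * 1000))
    windows_from_decomposition(d, recording_id = i,
                               activity = cohort$manifest$activity[i])
  })
  ws <- bind_window_sets(sets)
  ws$subjects <- cohort$manifest$subject[ws$meta$recording]
  ws
}
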