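# Synthetic hand-arm orientation recordings: Parkinsonian tremor (3-10 Hz)
# riding on voluntary movement (< 3 Hz) plus sensor noise, linear drift and
# occasional missing samples, at the study's 100 Hz sampling rate.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' `(arguments, seed)` without disturbing the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Activity profile for the simulator
#'
#' Describes one of the four recorded actions: resting (limbs on armrests),
#' outstretching, wing posture, and drinking (a dynamic reach-and-return
#' task). Static actions last 10 s; drinking is longer because it covers four
#' reach-drink-return cycles. Voluntary motion is band-limited below 3 Hz,
#' tremulous motion to 3-10 Hz.
#'
#' Amplitudes are free parameters of the simulator (the clinical study reports
#' no amplitude statistics); defaults are chosen once as clinically plausible
#' hand-orientation excursions in degrees, with drinking given the strongest,
#' most distinct tremor (kinetic + postural) and the largest voluntary sweep.
#'
#' @param name one of `"resting"`, `"outstretching"`, `"wing"`, `"drinking"`.
#' @param duration_s recording length in seconds (10 for the static actions;
#'   drinking must be at least 10).
#' @param voluntary_amplitude_deg peak amplitude of the voluntary component.
#' @param tremor_amplitude_deg peak amplitude of the tremulous component.
#' @param noise_std_deg standard deviation of additive white sensor noise.
#' @param drift_slope_deg_per_s slope of the additive linear drift.
#' @param missing_fraction fraction of interior samples replaced by `NA`
#'   (must be below 0.2).
#' @param voluntary_band_hz,tremor_band_hz frequency bands (Hz) of the two
#'   components; fixed by the problem definition, exposed for inspection.
#'
#' @return A list of class `activity_profile`.
#' @export
#' @examples
#' activity_profile("resting")
activity_profile <- function(name = c("resting", "outstretching", "wing", "drinking"),
                             duration_s = NULL,
                             voluntary_amplitude_deg = NULL,
                             tremor_amplitude_deg = NULL,
                             noise_std_deg = 0.1,
                             drift_slope_deg_per_s = 0.1,
                             missing_fraction = 0.01,
                             voluntary_band_hz = c(0, 3),
                             tremor_band_hz = c(3, 10)) {
  name <- match.arg(name)
  defaults <- list(
    resting       = list(dur = 10, vol = 0.5, trem = 2.5),
    outstretching = list(dur = 10, vol = 1.0, trem = 2.0),
    wing          = list(dur = 10, vol = 1.0, trem = 1.5),
    drinking      = list(dur = 12, vol = 12.0, trem = 4.0))[[name]]
  if (is.null(duration_s)) duration_s <- defaults$dur
  if (is.null(voluntary_amplitude_deg)) voluntary_amplitude_deg <- defaults$vol
  if (is.null(tremor_amplitude_deg)) tremor_amplitude_deg <- defaults$trem
  if (duration_s <= 0)
    stop("activity_profile: duration_s must be positive")
  if (name == "drinking" && duration_s < 10)
    stop("activity_profile: drinking duration must be >= 10 s")
  if (missing_fraction < 0 || missing_fraction >= 0.2)
    stop("activity_profile: missing_fraction must lie in [0, 0.2)")
  if (voluntary_amplitude_deg < 0 || tremor_amplitude_deg < 0 ||
      noise_std_deg < 0)
    stop("activity_profile: amplitude and noise parameters must be >= 0")
  structure(list(name = name, duration_s = duration_s,
                 voluntary_band_hz = voluntary_band_hz,
                 tremor_band_hz = tremor_band_hz,
                 voluntary_amplitude_deg = voluntary_amplitude_deg,
                 tremor_amplitude_deg = tremor_amplitude_deg,
                 noise_std_deg = noise_std_deg,
                 drift_slope_deg_per_s = drift_slope_deg_per_s,
                 missing_fraction = missing_fraction),
            class = "activity_profile")
}

#' The four default activity profiles
#' @return named list of [activity_profile()] objects.
#' @export
default_profiles <- function() {
  acts <- c("resting", "outstretching", "wing", "drinking")
  stats::setNames(lapply(acts, activity_profile), acts)
}

#' Generate the voluntary motion component
#'
#' A random superposition of 3-6 sinusoids with frequencies drawn uniformly in
#' \[0.2, 2.5\] Hz and random phases, peak-scaled to the profile amplitude.
#' For the drinking action a slow raised-cosine reach-and-return trajectory
#' (four cycles over the recording) carries a smaller sinusoid mixture, so the
#' action is dynamic and multi-phase rather than postural.
#'
#' @param profile an [activity_profile()].
#' @param seed integer seed; the generator is a pure function of
#'   `(profile, seed)`.
#' @param fs sampling rate in Hz.
#' @return An [orientation_signal()] with at least 95% of periodogram power
#'   below 3 Hz.
#' @export
generate_voluntary <- function(profile, seed, fs = 100) {
  stopifnot(inherits(profile, "activity_profile"))
  n <- round(profile$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- profile$voluntary_amplitude_deg
  if (amp == 0)
    return(orientation_signal(numeric(n) + 0, fs = fs,
                              meta = list(activity = profile$name,
                                          component = "voluntary")))
  x <- with_local_seed(seed, {
    k <- sample(3:6, 1)
    freqs <- runif(k, 0.2, 2.5)
    phases <- runif(k, 0, 2 * pi)
    weights <- runif(k, 0.3, 1)
    mix <- rowSums(sapply(seq_len(k), function(i)
      weights[i] * sin(2 * pi * freqs[i] * t + phases[i])))
    if (profile$name == "drinking") {
      cyc <- 4 / profile$duration_s  # four reach-and-return cycles
      reach <- 0.5 * (1 - cos(2 * pi * cyc * t))
      amp * reach + 0.25 * amp * mix / max(abs(mix))
    } else {
      amp * mix / max(abs(mix))
    }
  })
  orientation_signal(x, fs = fs,
                     meta = list(activity = profile$name,
                                 component = "voluntary"))
}

#' Generate the tremulous motion component
#'
#' An amplitude- and frequency-modulated tone: carrier drawn uniformly in
#' \[3.5, 9\] Hz (unless given), slow sinusoidal frequency wobble of +/- 0.3 Hz,
#' and 10-50% amplitude modulation, emulating the varying tremor frequencies
#' and amplitudes seen across patients and activities. The instantaneous
#' frequency stays inside the 3-10 Hz tremor band.
#'
#' @inheritParams generate_voluntary
#' @param carrier_hz tremor carrier frequency; `NULL` draws one from the seed.
#' @param am_depth amplitude-modulation depth in \[0, 1\]; `NULL` draws from
#'   \[0.1, 0.5\]. Use 0 for an unmodulated tone.
#' @param fm_dev_hz peak frequency deviation of the slow wobble (0 disables).
#' @return An [orientation_signal()] with at least 95% of periodogram power in
#'   3-10 Hz. The drawn carrier is stored in `meta$carrier_hz`.
#' @export
generate_tremor <- function(profile, seed, fs = 100, carrier_hz = NULL,
                            am_depth = NULL, fm_dev_hz = 0.3) {
  stopifnot(inherits(profile, "activity_profile"))
  n <- round(profile$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- profile$tremor_amplitude_deg
  if (amp == 0)
    return(orientation_signal(numeric(n) + 0, fs = fs,
                              meta = list(activity = profile$name,
                                          component = "tremor")))
  drawn <- with_local_seed(seed, {
    f0 <- if (is.null(carrier_hz)) runif(1, 3.5, 9) else carrier_hz
    d <- if (is.null(am_depth)) runif(1, 0.1, 0.5) else am_depth
    fm_rate <- runif(1, 0.05, 0.3)
    am_rate <- runif(1, 0.1, 0.5)
    ph <- runif(3, 0, 2 * pi)
    finst <- f0 + fm_dev_hz * sin(2 * pi * fm_rate * t + ph[1])
    phase <- 2 * pi * cumsum(finst) / fs
    env <- (1 + d * sin(2 * pi * am_rate * t + ph[2])) / (1 + d)
    list(x = amp * env * sin(phase + ph[3]), carrier = f0)
  })
  orientation_signal(drawn$x, fs = fs,
                     meta = list(activity = profile$name, component = "tremor",
                                 carrier_hz = drawn$carrier))
}

#' Generate one synthetic recording
#'
#' Builds `mixed = voluntary + tremor + white noise + linear drift`, then
#' replaces `missing_fraction` of the interior samples with `NA` markers
#' (endpoints are never corrupted, so interpolation never extrapolates). The
#' uncorrupted ground-truth components are retained.
#'
#' @inheritParams generate_voluntary
#' @param carrier_hz optional fixed tremor carrier (otherwise drawn).
#' @param meta provenance tags merged into every channel's metadata.
#' @return A list of class `synthetic_recording` with elements `mixed`,
#'   `voluntary_truth`, `tremor_truth` (all [orientation_signal()]s of equal
#'   length), `profile`, and `seed`.
#' @export
#' @examples
#' rec <- generate_recording(activity_profile("resting"), seed = 1)
#' length(rec$mixed$values)  # 10 s at 100 Hz -> 1000
generate_recording <- function(profile, seed, fs = 100, carrier_hz = NULL,
                               meta = list()) {
  stopifnot(inherits(profile, "activity_profile"))
  sub <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  vol <- generate_voluntary(profile, sub[1], fs = fs)
  trem <- generate_tremor(profile, sub[2], fs = fs, carrier_hz = carrier_hz)
  n <- length(vol$values)
  t <- (seq_len(n) - 1) / fs
  corrupt <- with_local_seed(sub[3], {
    noise <- rnorm(n, 0, profile$noise_std_deg)
    n_miss <- round(profile$missing_fraction * n)
    miss_idx <- if (n_miss > 0) sample(2:(n - 1), n_miss) else integer(0)
    list(noise = noise, miss_idx = miss_idx)
  })
  mixed <- vol$values + trem$values + corrupt$noise +
    profile$drift_slope_deg_per_s * t
  mixed[corrupt$miss_idx] <- NA_real_
  meta$activity <- profile$name
  structure(list(
    mixed = orientation_signal(mixed, fs = fs, meta = meta),
    voluntary_truth = orientation_signal(vol$values, fs = fs, meta = meta),
    tremor_truth = orientation_signal(trem$values, fs = fs,
                                      meta = c(meta, trem$meta["carrier_hz"])),
    profile = profile, seed = seed), class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording: %s, %d samples @ %g Hz, seed %d>\n",
              x$profile$name, length(x$mixed$values), x$mixed$fs, x$seed))
  invisible(x)
}

#' Generate a cohort of synthetic recordings
#'
#' Emulates the clinical acquisition layout: `n_subjects` patients each
#' performing every activity in `profiles`, measured on each combination of
#' `body_parts` and `axes`. Each subject draws an individual tremor carrier
#' frequency (uniform in 3.5-9 Hz) and amplitude scale, giving inter-subject
#' variability; every recording's seed is recorded in the manifest.
#'
#' @param n_subjects number of simulated patients (>= 1).
#' @param profiles list of [activity_profile()]s (default: all four actions).
#' @param seed master seed; all per-subject and per-recording draws derive
#'   from it deterministically.
#' @param body_parts,axes character vectors defining the recorded channels
#'   (default 3 x 3 = 9 channels as in the clinical setup; pass a single
#'   element of each for compact cohorts).
#' @param fs sampling rate in Hz.
#' @return A list with `recordings` (list of `synthetic_recording`) and
#'   `manifest` (data frame: one row per recording with subject, activity,
#'   body part, axis, seed, carrier frequency and amplitude parameters).
#' @export
generate_cohort <- function(n_subjects, profiles = default_profiles(), seed = 1,
                            body_parts = c("lower_arm", "upper_arm", "palm"),
                            axes = c("roll", "pitch", "yaw"), fs = 100) {
  if (n_subjects < 1) stop("generate_cohort: n_subjects must be >= 1")
  if (length(profiles) == 0) stop("generate_cohort: empty profile list")
  n_rec <- n_subjects * length(profiles) * length(body_parts) * length(axes)
  draws <- with_local_seed(seed, list(
    carrier = runif(n_subjects, 3.5, 9),
    amp_scale = runif(n_subjects, 0.7, 1.3),
    rec_seed = sample.int(.Machine$integer.max - 1L, n_rec)))
  recordings <- vector("list", n_rec)
  manifest <- vector("list", n_rec)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (p in seq_along(profiles)) {
      prof <- profiles[[p]]
      prof$tremor_amplitude_deg <- prof$tremor_amplitude_deg * draws$amp_scale[s]
      prof$voluntary_amplitude_deg <- prof$voluntary_amplitude_deg * draws$amp_scale[s]
      for (bp in body_parts) {
        for (ax in axes) {
          i <- i + 1L
          rec <- generate_recording(
            prof, draws$rec_seed[i], fs = fs, carrier_hz = draws$carrier[s],
            meta = list(subject = s, body_part = bp, axis = ax))
          recordings[[i]] <- rec
          manifest[[i]] <- data.frame(
            recording = i, subject = s, activity = prof$name,
            body_part = bp, axis = ax, seed = draws$rec_seed[i],
            carrier_hz = draws$carrier[s],
            tremor_amplitude_deg = prof$tremor_amplitude_deg,
            voluntary_amplitude_deg = prof$voluntary_amplitude_deg,
            noise_std_deg = prof$noise_std_deg,
            drift_slope_deg_per_s = prof$drift_slope_deg_per_s,
            missing_fraction = prof$missing_fraction,
            duration_s = prof$duration_s)
        }
      }
    }
  }
  list(recordings = recordings, manifest = do.call(rbind, manifest))
}

#' Write a synthetic recording to CSV
#'
#' Writes the mixed channel as `<stem>.csv` (columns `t,value`, missing
#' samples as empty cells) with a JSON sidecar of provenance and profile
#' parameters; optionally the two ground-truth components as
#' `<stem>_voluntary.csv` / `<stem>_tremor.csv`.
#'
#' @param recording a `synthetic_recording`.
#' @param stem output path stem (no extension).
#' @param truths also write the ground-truth components?
#' @return character vector of files written, invisibly.
#' @export
write_recording <- function(recording, stem, truths = TRUE) {
  files <- paste0(stem, ".csv")
  df <- data.frame(t = signal_time(recording$mixed),
                   value = recording$mixed$values)
  write.csv(df, files, row.names = FALSE, na = "")
  side <- c(recording$mixed$meta,
            unclass(recording$profile), list(seed = recording$seed,
                                             fs = recording$mixed$fs))
  jsonlite::write_json(side, paste0(files, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (truths) {
    for (comp in c("voluntary", "tremor")) {
      f <- paste0(stem, "_", comp, ".csv")
      sig <- recording[[paste0(comp, "_truth")]]
      write.csv(data.frame(t = signal_time(sig), value = sig$values), f,
                row.names = FALSE, na = "")
      files <- c(files, f)
    }
  }
  invisible(files)
}
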