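## Synthetic participants: paired force-plate + LFP sessions with a known
## neural-to-gait coupling, used to validate the full pipeline without any
## patient data. The generator emulates: an initial motionless baseline,
## alternating stepping at ~0.8 Hz whose amplitude follows a slowly varying
## vigor a(t) in [0, 1], a 1/f^chi aperiodic LFP background that drifts
## across visits, band-limited oscillations with burst-like envelopes, and a
## configurable coupling of one band's envelope to the stepping vigor.

#' Synthetic session specification
#'
#' Defaults are the generator's stated world: 100 s tasks (task protocol
#' length), 0.8 Hz cadence, 800 N body weight, positive unit-strength
#' high-beta coupling, aperiodic exponent 1.5 drifting by +0.25 per visit.
#'
#' @param seed integer RNG seed.
#' @param duration_s task duration in seconds.
#' @param weight_N body weight in newtons.
#' @param cadence_hz stepping rate.
#' @param baseline_s initial motionless segment (weight estimation).
#' @param coupling_band band name from [frequency_bands()] whose envelope is
#'   modulated by vigor.
#' @param coupling_sign +1 (more vigor, more band amplitude) or -1.
#' @param coupling_strength ratio of modulated to baseline band amplitude
#'   (0 = no coupling).
#' @param aperiodic_exponent 1/f slope chi of the LFP background.
#' @param noise_sd white measurement noise on the LFP (signal units).
#' @param force_noise_N white measurement noise on each plate.
#' @param osc_amplitudes named baseline amplitudes of the band oscillations.
#' @param env_mod fractional burst-envelope fluctuation (sd of the slow
#'   multiplicative envelope noise).
#' @param lfp_fs,force_fs native sampling rates (422 / 100 Hz).
#' @return a `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(seed = 0L, duration_s = 100, weight_N = 800,
                           cadence_hz = 0.8, baseline_s = 5,
                           coupling_band = "high_beta", coupling_sign = 1,
                           coupling_strength = 1,
                           aperiodic_exponent = 1.5, noise_sd = 0.2,
                           force_noise_N = 2,
                           osc_amplitudes = c(alpha = 0.5, low_beta = 0.4,
                                              high_beta = 0.5, low_gamma = 0.3),
                           env_mod = 0.3, lfp_fs = 422, force_fs = 100) {
  spec <- list(seed = as.integer(seed), duration_s = duration_s,
               weight_N = weight_N, cadence_hz = cadence_hz,
               baseline_s = baseline_s, coupling_band = coupling_band,
               coupling_sign = coupling_sign,
               coupling_strength = coupling_strength,
               aperiodic_exponent = aperiodic_exponent, noise_sd = noise_sd,
               force_noise_N = force_noise_N, osc_amplitudes = osc_amplitudes,
               env_mod = env_mod, lfp_fs = lfp_fs, force_fs = force_fs)
  stopifnot(spec$duration_s > 0, spec$weight_N > 0, spec$cadence_hz > 0,
            spec$coupling_strength >= 0, spec$lfp_fs > 0, spec$force_fs > 0)
  osc_f <- c(alpha = 10, low_beta = 16, high_beta = 28, low_gamma = 50)
  if (!spec$coupling_band %in% c(names(osc_f), "none")) {
    stop(sprintf("coupling_band must be one of %s or 'none'",
                 paste(names(osc_f), collapse = ", ")))
  }
  spec$osc_freqs <- osc_f
  class(spec) <- "synthetic_spec"
  spec
}

## slowly varying unit-sd noise: 2 Hz low-passed white noise, renormalized
slow_noise <- function(n, fs, cutoff = 2) {
  z <- stats::rnorm(n + round(2 * fs))
  f <- butter_design(2, cutoff / (fs / 2), "low")
  z <- iir_apply(f, z)[-seq_len(round(2 * fs))]  # drop start-up transient
  z / stats::sd(z)
}

#' Ground-truth stepping vigor profile
#'
#' A smoothed random walk min-max mapped to `[0, 1]`, held at 0 during the
#' motionless baseline with a 1 s ramp after the start cue.
#'
#' @param spec a [synthetic_spec()] (uses the current RNG stream).
#' @param fs sampling rate of the returned profile.
#' @return numeric vector of length `duration_s * fs`.
#' @export
generate_vigor <- function(spec, fs = spec$force_fs) {
  n_sec <- ceiling(spec$duration_s) + 4L
  w <- cumsum(stats::rnorm(n_sec))
  w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
  w <- w[!is.na(w)]
  w <- (w - min(w)) / (max(w) - min(w) + 1e-12)
  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  a <- stats::approx(seq_along(w) - 1, w, xout = pmin(tt, length(w) - 1),
                     rule = 2)$y
  ramp <- pmin(pmax((tt - spec$baseline_s) / 1, 0), 1)
  a * ramp
}

#' Generate a synthetic force-plate session
#'
#' Alternating plate loading at the stepping cadence with amplitude `a(t)`:
#' `L(t) = (W/2) (1 + a(t) s(t)) + ripple`, `R(t) = (W/2)(1 - a(t) s(t)) +
#' ripple`, where `s(t)` is a smoothed square-ish alternation and the small
#' independent per-plate ripple makes the two plates non-complementary (so
#' the merge/mirror logic is exercised on realistic traces). The first
#' `baseline_s` seconds are motionless at half weight per plate.
#'
#' @param spec a [synthetic_spec()].
#' @param vigor optional externally supplied vigor profile at `force_fs`
#'   (defaults to [generate_vigor()] under the spec seed).
#' @return list with `force` (2-channel [recording()], newtons), `vigor`.
#' @export
generate_forces <- function(spec, vigor = NULL) {
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$force_fs)
  if (is.null(vigor)) vigor <- generate_vigor(spec)
  stopifnot(length(vigor) == n)
  tt <- (seq_len(n) - 1) / spec$force_fs
  s <- tanh(3 * sin(2 * pi * spec$cadence_hz * tt))
  W <- spec$weight_N
  ripple_sd <- 0.01 * W
  rippleL <- ripple_sd * slow_noise(n, spec$force_fs, cutoff = 3)
  rippleR <- ripple_sd * slow_noise(n, spec$force_fs, cutoff = 3)
  moving <- vigor > 0
  L <- (W / 2) * (1 + vigor * s) + rippleL * moving +
    stats::rnorm(n, sd = spec$force_noise_N)
  R <- (W / 2) * (1 - vigor * s) + rippleR * moving +
    stats::rnorm(n, sd = spec$force_noise_N)
  L <- pmax(L, 0)
  R <- pmax(R, 0)
  force <- recording(rbind(L, R), spec$force_fs,
                     channel_labels = c("FP_L", "FP_R"))
  list(force = force, vigor = vigor)
}

#' Synthesize a 1/f^chi aperiodic background
#'
#' Spectral synthesis: unit-variance Gaussian noise shaped in the frequency
#' domain by `f^(-chi/2)` (flat below 1 Hz), inverse-transformed and
#' rescaled to unit standard deviation.
#'
#' @param n samples.
#' @param fs sampling rate in Hz.
#' @param chi aperiodic exponent (power decays as `1/f^chi`).
#' @return numeric vector, unit sd (uses the current RNG stream).
#' @export
synth_aperiodic <- function(n, fs, chi) {
  nfft <- n
  f <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirrored negative frequencies
  amp <- pmax(f, 1)^(-chi / 2)
  amp[1] <- 0
  ph <- stats::runif(nfft, 0, 2 * pi)
  spec_half <- amp * exp(1i * ph)
  ## enforce Hermitian symmetry for a real signal
  idx <- 2:ceiling(nfft / 2)
  spec_full <- spec_half
  spec_full[nfft + 2 - idx] <- Conj(spec_half[idx])
  if (nfft %% 2 == 0) spec_full[nfft / 2 + 1] <- Re(spec_half[nfft / 2 + 1])
  x <- Re(stats::fft(spec_full, inverse = TRUE)) / nfft
  x / stats::sd(x)
}

#' Generate a synthetic bilateral LFP session
#'
#' Per channel: 1/f^chi aperiodic background + band oscillations (alpha,
#' low-beta, high-beta, low-gamma) with burst-like multiplicative envelopes
#' + white noise. The coupling band's envelope is additionally multiplied by
#' `1 + coupling_sign * coupling_strength * a(t)`. Channels share the vigor
#' but have independent noise, phases and envelopes.
#'
#' @param spec a [synthetic_spec()].
#' @param vigor vigor profile at `force_fs` (aligned with the force session).
#' @return 2-channel [recording()] at `lfp_fs`, labels `STN_L`/`STN_R`.
#' @export
generate_lfp <- function(spec, vigor) {
  set.seed(spec$seed + 104729L)  # distinct stream from the force generator
  fs <- spec$lfp_fs
  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  a_lfp <- stats::approx((seq_along(vigor) - 1) / spec$force_fs, vigor,
                         xout = tt, rule = 2)$y
  chans <- matrix(0, 2, n)
  for (ch in 1:2) {
    x <- synth_aperiodic(n, fs, spec$aperiodic_exponent)
    for (b in names(spec$osc_freqs)) {
      f0 <- spec$osc_freqs[[b]]
      if (f0 >= fs / 2) stop("coupling/oscillation band outside Nyquist")
      env <- pmax(1 + spec$env_mod * slow_noise(n, fs), 0.1)
      if (identical(b, spec$coupling_band)) {
        env <- env * (1 + spec$coupling_sign * spec$coupling_strength * a_lfp)
        if (spec$coupling_sign < 0) env <- pmax(env, 0)
      }
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + spec$osc_amplitudes[[b]] * env * sin(2 * pi * f0 * tt + ph)
    }
    x <- x + stats::rnorm(n, sd = spec$noise_sd)
    chans[ch, ] <- x
  }
  recording(chans, fs, channel_labels = c("STN_L", "STN_R"))
}

#' Generate a full synthetic participant on disk
#'
#' Three visits in chronological order (roles train/validation/test), each a
#' paired LFP + force CSV session; the aperiodic exponent drifts linearly
#' across visits; per-visit seeds derive deterministically from the template
#' seed. Writes a manifest JSON and a ground-truth JSON (vigor profiles,
#' coupling settings).
#'
#' @param spec template [synthetic_spec()].
#' @param visit_months increasing integer vector of length 3.
#' @param out_dir output directory (created).
#' @param participant_id identifier string.
#' @param aperiodic_drift chi increment per visit (default 0.25).
#' @return the `"session_manifest"`, invisibly; files on disk.
#' @export
generate_participant <- function(spec, visit_months = c(3L, 6L, 9L),
                                 out_dir, participant_id = "synthP01",
                                 aperiodic_drift = 0.25) {
  stopifnot(length(visit_months) == 3L, all(diff(visit_months) > 0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  roles <- c("train", "validation", "test")
  visits <- list()
  truth <- list(participant_id = participant_id,
                coupling_band = spec$coupling_band,
                coupling_sign = spec$coupling_sign,
                coupling_strength = spec$coupling_strength,
                weight_N = spec$weight_N, visits = list())
  for (i in 1:3) {
    vspec <- spec
    vspec$seed <- spec$seed + i * 10007L
    vspec$aperiodic_exponent <- spec$aperiodic_exponent +
      (i - 1L) * aperiodic_drift
    fr <- generate_forces(vspec)
    lfp <- generate_lfp(vspec, fr$vigor)
    label <- sprintf("visit%d", i)
    lfp_path <- file.path(out_dir, sprintf("lfp_%s.csv", label))
    force_path <- file.path(out_dir, sprintf("force_%s.csv", label))
    write_recording(lfp, lfp_path)
    write_recording(fr$force, force_path)
    visits[[i]] <- list(visit_label = label,
                        months_since_IP = as.integer(visit_months[i]),
                        lfp_path = lfp_path, force_path = force_path,
                        baseline_interval = c(1, vspec$baseline_s - 0.5),
                        role = roles[i], lfp_fs = vspec$lfp_fs,
                        force_fs = vspec$force_fs, offset_s = 0)
    truth$visits[[i]] <- list(
      visit_label = label, seed = vspec$seed,
      aperiodic_exponent = vspec$aperiodic_exponent,
      vigor_fs = 10,
      vigor = fr$vigor[seq(1, length(fr$vigor), by = spec$force_fs / 10)])
  }
  m <- session_manifest(participant_id, visits)
  write_manifest(m, file.path(out_dir, "manifest.json"))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(m)
}
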