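# Synthetic PERG cohorts. The waveform primitive is a sum of three Gaussian
# bumps at the canonical component latencies: a negative deflection near
# 35 ms (N35), a positive peak near 50 ms (P50) and a negative deflection
# near 95 ms (N95), plus iid Gaussian noise and an optional DC offset. The
# default widths keep essentially all signal energy inside the 1-100 Hz
# acquisition band-pass.

#' Sampling grid of the analysis window
#'
#' @param n_samples Number of samples (256 after padding).
#' @param fs Sampling rate in Hz.
#' @return Times in ms; with the defaults, `(0:255)/1700 * 1000`, spanning
#'   0--150 ms.
#' @export
perg_time_grid <- function(n_samples = 256L, fs = 1700) {
  (seq_len(n_samples) - 1) / fs * 1000
}

#' Waveform parameters for the synthetic PERG generator
#'
#' Amplitudes are in microvolts (the N35/N95 amplitudes are magnitudes of
#' the negative deflections), center times and Gaussian widths in ms. The
#' defaults describe a typical normal trace: P50 of 4 uV at 50 ms flanked by
#' N35 (1 uV, 35 ms) and N95 (5 uV, 95 ms).
#'
#' @param a_n35,a_p50,a_n95 Non-negative bump amplitudes (uV).
#' @param t_n35,t_p50,t_n95 Bump center times (ms), strictly increasing in
#'   (0, 150).
#' @param w_n35,w_p50,w_n95 Positive Gaussian widths (ms).
#' @param noise_sd Standard deviation of the additive white noise (uV).
#' @param drift Constant DC offset (uV).
#' @return Object of class `waveform_params`.
#' @export
waveform_params <- function(a_n35 = 1, a_p50 = 4, a_n95 = 5,
                            t_n35 = 35, t_p50 = 50, t_n95 = 95,
                            w_n35 = 6, w_p50 = 8, w_n95 = 12,
                            noise_sd = 0.2, drift = 0) {
  p <- list(a_n35 = a_n35, a_p50 = a_p50, a_n95 = a_n95,
            t_n35 = t_n35, t_p50 = t_p50, t_n95 = t_n95,
            w_n35 = w_n35, w_p50 = w_p50, w_n95 = w_n95,
            noise_sd = noise_sd, drift = drift)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1)))) {
    stop("all waveform parameters must be finite scalars")
  }
  if (a_n35 < 0 || a_p50 < 0 || a_n95 < 0) stop("amplitudes must be >= 0")
  if (w_n35 <= 0 || w_p50 <= 0 || w_n95 <= 0) stop("widths must be > 0")
  if (!(0 < t_n35 && t_n35 < t_p50 && t_p50 < t_n95 && t_n95 < 150)) {
    stop("center times must satisfy 0 < t_n35 < t_p50 < t_n95 < 150")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(p, class = "waveform_params")
}

# Noise-free component mixture evaluated on an arbitrary time grid (ms).
.waveform_mean <- function(params, t_ms) {
  g <- function(center, width) exp(-0.5 * ((t_ms - center) / width)^2)
  -params$a_n35 * g(params$t_n35, params$w_n35) +
    params$a_p50 * g(params$t_p50, params$w_p50) -
    params$a_n95 * g(params$t_n95, params$w_n95) +
    params$drift
}

#' Generate one synthetic PERG trace
#'
#' Evaluates the three-bump mixture on the sampling grid and adds iid
#' Gaussian noise drawn from the current RNG stream (seed at the caller, or
#' use [generate_cohort()] for a fully reproducible cohort).
#'
#' @param params A [waveform_params()] object.
#' @param n_samples,fs Sampling grid; defaults 256 samples at 1700 Hz.
#' @return Numeric vector of `n_samples` values in uV.
#' @export
generate_waveform <- function(params, n_samples = 256L, fs = 1700) {
  stopifnot(inherits(params, "waveform_params"))
  s <- .waveform_mean(params, perg_time_grid(n_samples, fs))
  if (params$noise_sd > 0) s <- s + rnorm(n_samples, 0, params$noise_sd)
  s
}

#' Cohort configuration for the synthetic generator
#'
#' Defines the two diagnostic groups. Each participant receives a single
#' multiplicative gain (log-normal with unit mean and log-sd
#' `between_participant_sd`) applied to all three bump amplitudes and shared
#' across that participant's recordings, mimicking between-subject amplitude
#' variation while keeping amplitudes positive. Participants in the mpIRD
#' group have the P50 amplitude multiplied by `attenuation_p50` and the N95
#' amplitude by `attenuation_n95`, the macular-predominant loss pattern the
#' analysis is designed to detect.
#'
#' @param n_normal,n_mpird Participant counts (>= 1).
#' @param recordings_per_participant Recordings per participant (two eyes,
#'   alternating RE/LE); default 4, matching roughly four recordings per
#'   participant in a typical clinical visit.
#' @param attenuation_p50,attenuation_n95 Multiplicative amplitude factors in
#'   `[0, 1]` applied to the mpIRD group (defaults 0.3 and 0.6: pronounced
#'   P50 loss, secondary N95 loss).
#' @param between_participant_sd Log-scale sd of the participant gain
#'   (dimensionless; default 0.25, i.e. roughly 25% amplitude variation).
#' @param params Normal-group [waveform_params()].
#' @param eye_gain Named multiplicative gains per eye, default
#'   `c(RE = 1, LE = 1)`; a non-unit value exercises eye-partition
#'   sensitivity analyses.
#' @param seed Integer seed; the cohort is bit-reproducible from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_normal, n_mpird, recordings_per_participant = 4L,
                          attenuation_p50 = 0.3, attenuation_n95 = 0.6,
                          between_participant_sd = 0.25,
                          params = waveform_params(),
                          eye_gain = c(RE = 1, LE = 1), seed = 1L) {
  stopifnot(n_normal >= 1, n_mpird >= 1, recordings_per_participant >= 1,
            attenuation_p50 >= 0, attenuation_p50 <= 1,
            attenuation_n95 >= 0, attenuation_n95 <= 1,
            between_participant_sd >= 0,
            inherits(params, "waveform_params"))
  structure(
    list(n_normal = as.integer(n_normal), n_mpird = as.integer(n_mpird),
         recordings_per_participant = as.integer(recordings_per_participant),
         attenuation_p50 = attenuation_p50, attenuation_n95 = attenuation_n95,
         between_participant_sd = between_participant_sd,
         params = params, eye_gain = eye_gain, seed = as.integer(seed)),
    class = "cohort_config")
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic PERG cohort
#'
#' @param config A [cohort_config()].
#' @return A `perg_cohort`: list with `meta` (one row per recording:
#'   `participant_id`, `visit`, `eye`, `diagnosis`, `age`, `sex`,
#'   `va_logmar`) and `samples`, a recordings x 256 matrix of uV traces,
#'   plus the acquisition constants `fs` and `duration_ms`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, {
    n_rec <- config$recordings_per_participant
    mpird_labels <- c("CRD", "MD", "STGD")
    meta <- list(); traces <- list(); row <- 0L
    groups <- data.frame(
      id = c(sprintf("N%03d", seq_len(config$n_normal)),
             sprintf("P%03d", seq_len(config$n_mpird))),
      group = rep(c("normal", "mpird"), c(config$n_normal, config$n_mpird)))
    for (i in seq_len(nrow(groups))) {
      mpird <- groups$group[i] == "mpird"
      sdlog <- config$between_participant_sd
      gain <- exp(rnorm(1, -sdlog^2 / 2, sdlog))
      base <- config$params
      p <- waveform_params(
        a_n35 = base$a_n35 * gain,
        a_p50 = base$a_p50 * gain * if (mpird) config$attenuation_p50 else 1,
        a_n95 = base$a_n95 * gain * if (mpird) config$attenuation_n95 else 1,
        t_n35 = base$t_n35, t_p50 = base$t_p50, t_n95 = base$t_n95,
        w_n35 = base$w_n35, w_p50 = base$w_p50, w_n95 = base$w_n95,
        noise_sd = base$noise_sd, drift = base$drift)
      diagnosis <- if (mpird) mpird_labels[(i - 1L) %% 3L + 1L] else "normal"
      age <- round(max(5, min(80, rnorm(1, if (mpird) 37 else 27, 16))))
      sex <- sample(c("M", "F"), 1)
      va <- round(max(-0.2, rnorm(1, if (mpird) 0.5 else 0.2, 0.3)), 2)
      for (r in seq_len(n_rec)) {
        eye <- if (r %% 2L == 1L) "RE" else "LE"
        pr <- p
        eg <- unname(config$eye_gain[eye])
        if (!isTRUE(all.equal(eg, 1))) {
          pr <- waveform_params(
            a_n35 = p$a_n35 * eg, a_p50 = p$a_p50 * eg, a_n95 = p$a_n95 * eg,
            t_n35 = p$t_n35, t_p50 = p$t_p50, t_n95 = p$t_n95,
            w_n35 = p$w_n35, w_p50 = p$w_p50, w_n95 = p$w_n95,
            noise_sd = p$noise_sd, drift = p$drift)
        }
        row <- row + 1L
        meta[[row]] <- data.frame(
          participant_id = groups$id[i], visit = 1L, eye = eye,
          diagnosis = diagnosis, age = age, sex = sex, va_logmar = va)
        traces[[row]] <- generate_waveform(pr)
      }
    }
    perg_cohort(do.call(rbind, meta), do.call(rbind, traces))
  })
}

#' Construct a PERG cohort container
#'
#' @param meta data.frame with one row per recording (`participant_id`,
#'   `visit`, `eye`, `diagnosis`, `age`, `sex`, `va_logmar`).
#' @param samples Numeric matrix, one row of samples (uV) per recording.
#' @param fs,duration_ms Acquisition constants.
#' @return Object of class `perg_cohort`.
#' @export
perg_cohort <- function(meta, samples, fs = 1700, duration_ms = 150) {
  samples <- as.matrix(samples)
  if (nrow(meta) != nrow(samples)) {
    stop("meta and samples disagree on the number of recordings")
  }
  rownames(samples) <- NULL
  rownames(meta) <- NULL
  structure(list(meta = meta, samples = samples, fs = fs,
                 duration_ms = duration_ms),
            class = "perg_cohort")
}

#' @export
print.perg_cohort <- function(x, ...) {
  cat(sprintf(
    "<perg_cohort> %d recordings, %d participants, %d samples @ %g Hz\n",
    nrow(x$meta), length(unique(x$meta$participant_id)), ncol(x$samples),
    x$fs))
  print(table(x$meta$diagnosis))
  invisible(x)
}

# Diagnostic group of each recording: normal vs mpird.
cohort_groups <- function(cohort) {
  ifelse(cohort$meta$diagnosis == "normal", "normal", "mpird")
}

#' Monte-Carlo oracle for the common-language effect size
#'
#' Brute-force estimate of the probability that a participant-level feature
#' value from group `a` exceeds one from group `b` (ties count one half).
#' In waveform mode each draw simulates one participant -- gain, then
#' `recordings_per_participant` noisy traces, each decomposed so the energy
#' at `feature` can be averaged across the recordings -- exactly the
#' generative process of [generate_cohort()], but estimated by direct
#' simulation rather than through the feature-table/rank machinery it is
#' used to check. `a` and `b` may instead be functions `f(n)` returning `n`
#' feature draws directly, bypassing the waveform model.
#'
#' @param a,b [waveform_params()] per group, or functions drawing feature
#'   values directly.
#' @param feature Coefficient address, e.g. `"D6-2"` (waveform mode only).
#' @param n_mc Monte-Carlo draws per group.
#' @param seed Integer seed.
#' @param wavelet Mother wavelet used for the energy feature.
#' @param recordings_per_participant,between_participant_sd Participant-level
#'   structure, matching the corresponding [cohort_config()] fields.
#' @return Estimated probability in `[0, 1]`.
#' @export
oracle_cles <- function(a, b, feature = "D6-2", n_mc = 10000L, seed = 1L,
                        wavelet = "sym2", recordings_per_participant = 1L,
                        between_participant_sd = 0) {
  stopifnot(n_mc >= 1)
  draw <- function(side) {
    if (is.function(side)) return(side(n_mc))
    stopifnot(inherits(side, "waveform_params"))
    addr <- parse_index(feature)
    sdlog <- between_participant_sd
    gains <- exp(rnorm(n_mc, -sdlog^2 / 2, sdlog))
    clean <- .waveform_mean(side, perg_time_grid())  # drift included
    f <- wavelet_filter(wavelet)
    lev <- addr$level
    acc <- numeric(n_mc)
    for (r in seq_len(recordings_per_participant)) {
      X <- outer(clean - side$drift, gains) + side$drift
      if (side$noise_sd > 0) {
        X <- X + matrix(rnorm(length(X), 0, side$noise_sd), nrow(X))
      }
      A <- X
      for (d in seq_len(lev)) {
        s <- .dwt_step(A, f$lo, f$hi)
        A <- s$a
        if (d == lev) C <- if (addr$band == "D") s$d else s$a
      }
      acc <- acc + C[addr$position, ]^2
    }
    acc / recordings_per_participant
  }
  .with_seed(seed, {
    va <- draw(a)
    vb <- draw(b)
    r <- rank(c(va, vb))
    u <- sum(r[seq_len(n_mc)]) - n_mc * (n_mc + 1) / 2
    u / (as.numeric(n_mc) * n_mc)
  })
}

#' Write a cohort to the canonical CSV layout
#'
#' One row per recording: the metadata columns followed by sample columns
#' `s0`..`s255` (or however many samples the cohort holds). The file is
#' byte-compatible with [read_cohort()].
#'
#' @param cohort A `perg_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "perg_cohort"))
  s <- as.data.frame(cohort$samples)
  names(s) <- paste0("s", seq_len(ncol(s)) - 1L)
  utils::write.csv(cbind(cohort$meta, s), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
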