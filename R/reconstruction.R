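# Canonical peak measurement and the greedy minimal-index inverse-DWT
# reconstruction: find, per peak, the single coefficient whose lone inverse
# transform best preserves the peak's amplitude and implicit time across
# the normal cohort, then accept one augmenting coefficient only if it cuts
# the weighted error by a large margin.

#' Default canonical peak search windows
#'
#' Milliseconds bracketing the canonical latencies (~35/50/95 ms) with
#' margins consistent with normal PERG morphology.
#'
#' @return Named list of `c(lo, hi)` windows for N35, P50, N95.
#' @export
peak_windows <- function() {
  list(N35 = c(20, 45), P50 = c(40, 70), N95 = c(75, 130))
}

#' Measure the canonical PERG peaks
#'
#' N35 and N95 are the minima of the trace on their search windows, P50 the
#' maximum on its window; ties resolve to the earliest time. The amplitude
#' is the signal value at the extremum (baseline-referenced, so N35/N95
#' amplitudes are typically negative) and the implicit time is the grid
#' time at which it occurs.
#'
#' @param x 256-sample trace.
#' @param fs Sampling rate (Hz).
#' @param windows Search windows, default [peak_windows()].
#' @return data.frame with columns `peak`, `amplitude` (uV),
#'   `implicit_time` (ms), `found`.
#' @export
measure_peaks <- function(x, fs = 1700, windows = peak_windows()) {
  t_ms <- perg_time_grid(length(x), fs)
  out <- lapply(names(windows), function(pk) {
    wdw <- windows[[pk]]
    in_w <- which(t_ms >= wdw[1] & t_ms <= wdw[2])
    if (!length(in_w)) {
      return(data.frame(peak = pk, amplitude = NA_real_,
                        implicit_time = NA_real_, found = FALSE))
    }
    i <- if (pk == "P50") in_w[which.max(x[in_w])] else in_w[which.min(x[in_w])]
    data.frame(peak = pk, amplitude = x[i], implicit_time = t_ms[i],
               found = TRUE)
  })
  do.call(rbind, out)
}

# Peak table for every row of a sample matrix; returns list of matrices
# amplitude[rec, peak], time[rec, peak].
.peaks_matrix <- function(samples, fs, windows) {
  pk_names <- names(windows)
  amp <- matrix(NA_real_, nrow(samples), length(pk_names),
                dimnames = list(NULL, pk_names))
  tim <- amp
  for (i in seq_len(nrow(samples))) {
    p <- measure_peaks(samples[i, ], fs, windows)
    amp[i, ] <- p$amplitude
    tim[i, ] <- p$implicit_time
  }
  list(amplitude = amp, time = tim)
}

#' Reconstruction error of an index set for one canonical peak
#'
#' Every cohort recording is reconstructed from the inverse DWT of the kept
#' coefficient set alone; the peak is measured on both the original and the
#' reconstruction, and the mean absolute errors of amplitude (`v_mae`, uV)
#' and implicit time (`t_mae`, ms) are combined into the weighted MAE
#' `v_mae * t_mae` (uV x ms) that drives the selection.
#'
#' @param cohort Preprocessed `perg_cohort` (normal recordings).
#' @param wavelet Mother wavelet, default `"sym2"` for its symmetric,
#'   near-linear-phase response.
#' @param index_set Character addresses, e.g. `c("D6-2", "A6-3")`.
#' @param peak `"N35"`, `"P50"` or `"N95"`.
#' @param windows Peak search windows.
#' @return data.frame row: `peak`, `index_set`, `v_mae`, `t_mae`,
#'   `weighted`.
#' @export
reconstruction_error <- function(cohort, wavelet = "sym2", index_set, peak,
                                 windows = peak_windows()) {
  stopifnot(inherits(cohort, "perg_cohort"), nrow(cohort$meta) > 0L,
            peak %in% names(windows))
  orig <- .peaks_matrix(cohort$samples, cohort$fs, windows)
  recon <- t(vapply(seq_len(nrow(cohort$samples)), function(i) {
    reconstruct_subset(decompose(cohort$samples[i, ], wavelet), index_set)
  }, numeric(ncol(cohort$samples))))
  rp <- .peaks_matrix(recon, cohort$fs, windows)
  v_mae <- mean(abs(orig$amplitude[, peak] - rp$amplitude[, peak]))
  t_mae <- mean(abs(orig$time[, peak] - rp$time[, peak]))
  data.frame(peak = peak, index_set = paste(index_set, collapse = "+"),
             v_mae = v_mae, t_mae = t_mae, weighted = v_mae * t_mae)
}

#' Greedy minimal-index selection for peak-preserving reconstruction
#'
#' Per canonical peak: (1) every single coefficient in the candidate levels
#' (the sub-100 Hz bands D4, D5, D6 and the deepest approximation) is
#' scored by its one-index weighted MAE over the cohort; (2) the best
#' single is retained; (3) each of the next `n_top - 1` best singles is
#' tried as a partner, and the best pair replaces the single only if its
#' weighted MAE is at most `(1 - improvement)` times the single's --
#' i.e. an improvement of at least 40% by default. Candidates are ordered
#' by weighted MAE, then amplitude MAE, then time MAE, then lower level and
#' position, which keeps the choice deterministic when the weighted product
#' degenerates to zero through a zero time error alone.
#'
#' @param cohort Preprocessed normal-group `perg_cohort`.
#' @param wavelet Mother wavelet, default `"sym2"`.
#' @param candidate_levels Band labels, default `D4, D5, D6` and the
#'   wavelet's deepest approximation.
#' @param improvement Required fractional drop in weighted MAE for the pair
#'   to be accepted, default 0.40.
#' @param n_top Number of top singles eligible as partners, default 5.
#' @param windows Peak search windows.
#' @return Named list (per peak) with `indices` (character), `error` (the
#'   chosen set's error row), `augmented` (logical) and `singles` (the full
#'   ranked single-index score table).
#' @export
select_minimal_indices <- function(cohort, wavelet = "sym2",
                                   candidate_levels = NULL,
                                   improvement = 0.40, n_top = 5L,
                                   windows = peak_windows()) {
  stopifnot(inherits(cohort, "perg_cohort"), nrow(cohort$meta) > 0L)
  n <- ncol(cohort$samples)
  spec <- wavelet_spec(wavelet, n)
  if (is.null(candidate_levels)) {
    candidate_levels <- c("D4", "D5", "D6", paste0("A", spec$max_level))
    candidate_levels <- candidate_levels[
      as.integer(substring(candidate_levels, 2L)) <= spec$max_level]
  }
  addrs <- unlist(lapply(candidate_levels, function(sc) {
    band <- substr(sc, 1L, 1L)
    lev <- as.integer(substring(sc, 2L))
    format_index(band, lev, seq_len(n / 2^lev))
  }))
  decomps <- apply(cohort$samples, 1L, decompose, wavelet = wavelet,
                   simplify = FALSE)
  orig <- .peaks_matrix(cohort$samples, cohort$fs, windows)
  score_set <- function(index_set, peak) {
    recon <- t(vapply(decomps, reconstruct_subset,
                      numeric(n), kept = index_set))
    rp <- .peaks_matrix(recon, cohort$fs, windows)
    v <- mean(abs(orig$amplitude[, peak] - rp$amplitude[, peak]))
    tt <- mean(abs(orig$time[, peak] - rp$time[, peak]))
    data.frame(peak = peak, index_set = paste(index_set, collapse = "+"),
               v_mae = v, t_mae = tt, weighted = v * tt)
  }
  out <- list()
  for (pk in names(windows)) {
    singles <- do.call(rbind, lapply(addrs, score_set, peak = pk))
    ai <- parse_index(addrs)
    ord <- order(singles$weighted, singles$v_mae, singles$t_mae,
                 ai$level, ai$position)
    singles <- singles[ord, , drop = FALSE]
    rownames(singles) <- NULL
    best <- addrs[ord][1L]
    best_err <- singles[1L, ]
    chosen <- best; chosen_err <- best_err; augmented <- FALSE
    partners <- addrs[ord][seq_len(min(n_top, length(addrs)))][-1L]
    if (length(partners)) {
      pair_scores <- do.call(rbind, lapply(partners, function(pa) {
        score_set(c(best, pa), pk)
      }))
      pai <- parse_index(partners)
      pord <- order(pair_scores$weighted, pair_scores$v_mae,
                    pair_scores$t_mae, pai$level, pai$position)
      best_pair <- pair_scores[pord[1L], ]
      if (best_pair$weighted < best_err$weighted &&
          best_pair$weighted <= (1 - improvement) * best_err$weighted) {
        chosen <- c(best, partners[pord[1L]])
        chosen_err <- best_pair
        augmented <- TRUE
      }
    }
    out[[pk]] <- list(indices = chosen, error = chosen_err,
                      augmented = augmented, singles = singles)
  }
  out
}
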