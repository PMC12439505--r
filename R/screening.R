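# Mother-wavelet screening by the energy-to-entropy ratio E/H. A wavelet
# that concentrates signal power into few coefficients has high energy and
# low Shannon entropy, so a high ratio flags decompositions that represent
# the PERG compactly; ratios are averaged recordings -> participant ->
# cohort and bootstrapped at the participant level.

#' Energy of a coefficient vector
#'
#' `E = sum(c_i^2)`, the signal power captured by the coefficients (uV^2).
#'
#' @param coeffs Numeric vector of wavelet coefficients.
#' @return Non-negative scalar.
#' @export
energy <- function(coeffs) {
  if (!all(is.finite(coeffs))) stop("non-finite coefficients")
  sum(coeffs^2)
}

#' Shannon entropy of the coefficient energy distribution
#'
#' Coefficient energies are normalized to probabilities
#' `p_i = c_i^2 / E` and `H = -sum(p_i log p_i)` (natural log, nats), with
#' `0 log 0 = 0`. `H` is 0 for a point mass and `log(N)` for `N` equal
#' magnitudes; it is undefined for an all-zero vector.
#'
#' @param coeffs Numeric vector with at least one nonzero coefficient.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(coeffs) {
  E <- energy(coeffs)
  if (E == 0) stop("entropy undefined for all-zero coefficients")
  p <- coeffs^2 / E
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Energy-to-entropy ratio of one trace
#'
#' Decomposes the trace and computes `E / H` either over all coefficients of
#' the full decomposition (`scope = "overall"`) or restricted to one band,
#' e.g. `"D6"` (detail level 6) or `"A5"` (the level-5 approximation, taken
#' from the cascade's intermediate output when the wavelet decomposes
#' deeper). Scaling the trace by `k` scales the ratio by `k^2`; the ratio is
#' invariant to coefficient permutation and sign.
#'
#' @param x 256-sample trace (or a precomputed `wavelet_decomposition`).
#' @param wavelet Wavelet name; ignored when `x` is already decomposed.
#' @param scope `"overall"` or a band label like `"D4"`, `"A6"`.
#' @return The ratio, or `NA_real_` when the scope does not exist for this
#'   wavelet (level beyond its depth) or when `H = 0` (single-coefficient
#'   point mass), both flagged for exclusion from averages.
#' @export
energy_entropy_ratio <- function(x, wavelet = "sym2", scope = "overall") {
  decomp <- if (inherits(x, "wavelet_decomposition")) x
            else decompose(x, wavelet)
  coeffs <- .scope_coeffs(decomp, scope)
  if (is.null(coeffs)) return(NA_real_)
  E <- energy(coeffs)
  if (E == 0) return(NA_real_)
  H <- shannon_entropy(coeffs)
  if (H == 0) return(NA_real_)
  E / H
}

.scope_coeffs <- function(decomp, scope) {
  if (scope == "overall") {
    return(c(unlist(decomp$details, use.names = FALSE),
             decomp$approximation))
  }
  band <- substr(scope, 1L, 1L)
  lev <- suppressWarnings(as.integer(substring(scope, 2L)))
  if (!band %in% c("A", "D") || is.na(lev)) {
    stop("scope must be \"overall\" or a band label like \"D6\" or \"A5\"")
  }
  if (lev > decomp$level) return(NULL)
  if (band == "D") decomp$details[[paste0("D", lev)]]
  else decomp$approximations[[paste0("A", lev)]]
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the supplied per-participant values with replacement (the
#' participant is the resampling unit) and returns the percentile interval
#' of the resampled means.
#'
#' @param values Per-participant values (>= 1).
#' @param n_boot Number of resamples, default 10000.
#' @param level Coverage, default 0.95.
#' @param seed Optional integer seed for reproducible intervals.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000L, level = 0.95,
                         seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("bootstrap_ci needs at least one value")
  run <- function() {
    draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    means <- colMeans(matrix(values[draws], nrow = n))
    q <- stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                         names = FALSE, type = 7)
    c(lo = q[1], hi = q[2])
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Screen candidate mother wavelets by energy-to-entropy ratio
#'
#' For every wavelet and scope, each recording's ratio is averaged within
#' participant and then across participants (so participants with many
#' recordings do not dominate), with a participant-level percentile
#' bootstrap CI. Per scope, the wavelet with the highest mean ratio is
#' retained; `forced` names are always added (the analysis forces haar for
#' its deep 7-level split and adds coif1 so every family is represented).
#' Exact mean ties are broken by shorter filter length, then by preferring
#' the symmetric near-linear-phase symlet family, then by name.
#'
#' @param cohort Preprocessed `perg_cohort`.
#' @param wavelets Candidate names, default all 20.
#' @param scopes Band scopes to screen, default the sub-100 Hz bands
#'   `D4, D5, D6, A5, A6`.
#' @param n_boot,seed Bootstrap settings (`n_boot = 0` skips the CIs).
#' @param forced Names always retained, default `c("haar", "coif1")`.
#' @param resample_unit `"participant"` (default) or `"recording"`, the
#'   bootstrap resampling unit.
#' @return List with `results` (data.frame: wavelet, scope, mean_ratio,
#'   ci_lo, ci_hi, n_participants, retained) and `retained` (character).
#' @export
screen_wavelets <- function(cohort, wavelets = wavelet_names(),
                            scopes = c("D4", "D5", "D6", "A5", "A6"),
                            n_boot = 10000L, seed = 1L,
                            forced = c("haar", "coif1"),
                            resample_unit = c("participant", "recording")) {
  stopifnot(inherits(cohort, "perg_cohort"), nrow(cohort$meta) > 0L)
  resample_unit <- match.arg(resample_unit)
  pid <- cohort$meta$participant_id
  rows <- list(); k <- 0L
  for (w in wavelets) {
    decomps <- apply(cohort$samples, 1L, decompose, wavelet = w,
                     simplify = FALSE)
    for (sc in scopes) {
      per_rec <- vapply(decomps, energy_entropy_ratio, numeric(1), scope = sc)
      per_part <- tapply(per_rec, pid, mean, na.rm = TRUE)
      per_part <- per_part[is.finite(per_part)]
      unit_vals <- if (resample_unit == "participant") as.numeric(per_part)
                   else per_rec[is.finite(per_rec)]
      mean_ratio <- if (length(per_part)) mean(per_part) else NA_real_
      ci <- if (n_boot > 0L && length(unit_vals)) {
        bootstrap_ci(unit_vals, n_boot = n_boot,
                     seed = seed + k)
      } else c(lo = NA_real_, hi = NA_real_)
      k <- k + 1L
      rows[[k]] <- data.frame(
        wavelet = w, scope = sc, mean_ratio = mean_ratio,
        ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
        n_participants = length(per_part))
    }
  }
  results <- do.call(rbind, rows)
  results$retained <- FALSE
  family_rank <- function(w) {
    match(TRUE, c(grepl("^sym", w), grepl("^db", w), grepl("^coif", w),
                  grepl("^fk", w), TRUE))
  }
  winners <- character(0)
  for (sc in scopes) {
    sub <- results[results$scope == sc & is.finite(results$mean_ratio), ]
    if (!nrow(sub)) next
    best <- sub[sub$mean_ratio == max(sub$mean_ratio), "wavelet"]
    if (length(best) > 1L) {
      ord <- order(vapply(best, function(w) wavelet_filter(w)$length, 1L),
                   vapply(best, family_rank, 1L), best)
      best <- best[ord]
    }
    winners <- c(winners, best[1L])
    results$retained[results$scope == sc & results$wavelet == best[1L]] <- TRUE
  }
  retained <- sort(unique(c(winners, intersect(forced, wavelets))))
  results$retained <- results$retained | results$wavelet %in% retained
  list(results = results, retained = retained)
}
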