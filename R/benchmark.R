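# Benchmarking wavelet indices against the conventional time-domain
# markers: |P50-N35| (macular cone) and |N95-P50| (retinal ganglion cell)
# amplitudes, participant-level Pearson correlations, ROC/AUC by direct
# pair counting, the one-sided >k SD outlier rule, and Tukey five-number
# summaries.

#' Clinical time-domain markers from measured peaks
#'
#' @param peaks A [measure_peaks()] data.frame.
#' @return List with `p50_n35` = |P50 - N35| and `n95_p50` = |N95 - P50|
#'   amplitudes (uV).
#' @export
clinical_markers <- function(peaks) {
  a <- stats::setNames(peaks$amplitude, peaks$peak)
  list(p50_n35 = abs(a[["P50"]] - a[["N35"]]),
       n95_p50 = abs(a[["N95"]] - a[["P50"]]))
}

#' Participant-level Pearson correlation
#'
#' @param x,y Numeric vectors of participant means (>= 3 finite pairs,
#'   non-degenerate).
#' @return Pearson correlation coefficient.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 participants")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' ROC area under the curve by pair counting
#'
#' The probability that a randomly chosen normal value exceeds a randomly
#' chosen mpIRD value, ties counting one half -- evaluated by explicit
#' enumeration of all cross-group pairs, and mathematically identical to
#' `U / (n1 n2)` from [mann_whitney()].
#'
#' @param values Numeric marker values.
#' @param labels Group labels; `"normal"` is the positive class, all other
#'   labels the patient class (logical `TRUE` also marks normal).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  pos <- if (is.logical(labels)) labels else labels == "normal"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  x <- values[pos]; y <- values[!pos]
  d <- outer(x, y, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

#' One-sided outlier filter (leave-self-out)
#'
#' Flags values more than `k` standard deviations above the mean of the
#' *remaining* values: each point is compared against the mean and SD
#' computed with itself left out, so a single extreme value cannot mask
#' itself. One-sided by design -- only unusually large values are removed.
#'
#' @param values Numeric vector (>= 2 values).
#' @param k SD multiplier, default 4.
#' @return Logical vector, `TRUE` for values to keep.
#' @export
outlier_filter <- function(values, k = 4) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  s <- sum(values); ss <- sum(values^2)
  keep <- logical(n)
  for (i in seq_len(n)) {
    m <- (s - values[i]) / (n - 1)
    v <- (ss - values[i]^2 - (n - 1) * m^2) / max(n - 2, 1)
    sd_i <- sqrt(max(v, 0))
    keep[i] <- values[i] <= m + k * sd_i
  }
  keep
}

#' Tukey five-number summary with outliers
#'
#' Quartiles use linear interpolation (type-7 convention, which the fence
#' positions inherit); whiskers extend to the most extreme observations
#' within 1.5 IQR of the quartiles and anything beyond is listed as an
#' outlier.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List with `q1`, `median`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
tukey_summary <- function(values) {
  if (!length(values)) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = values[!inside])
}

#' Mean energy of a pair of indices
#'
#' Combined metric for a detail index and its companion approximation index
#' (e.g. D6-2 with A6-3): the arithmetic mean of the two energies from one
#' recording's energy map.
#'
#' @param emap An [energy_map()] data.frame.
#' @param addr_pair Two coefficient addresses.
#' @return Mean energy (uV^2).
#' @export
combined_index_value <- function(emap, addr_pair) {
  stopifnot(length(addr_pair) == 2L)
  vals <- vapply(addr_pair, function(a) {
    hit <- emap$feature == a
    if (!any(hit)) stop("address ", a, " not present in energy map")
    emap$energy[hit][1L]
  }, numeric(1))
  mean(vals)
}

# Participant-averaged marker and feature values for benchmarking.
.participant_values <- function(cohort, values) {
  pid <- cohort$meta$participant_id
  out <- tapply(values, pid, mean)
  data.frame(participant_id = names(out), value = as.numeric(out))
}

#' Benchmark wavelet indices against the clinical markers
#'
#' Participant-level comparison of selected energy indices with |P50-N35|
#' and |N95-P50|: Pearson correlations within the normal group (after the
#' one-sided >k SD outlier omission on the reference index), ROC/AUC and
#' Mann-Whitney effect size for normal-vs-mpIRD discrimination, and Tukey
#' summaries per group.
#'
#' @param cohort Preprocessed `perg_cohort` containing both groups.
#' @param wavelet Mother wavelet for the indices, default `"sym2"`.
#' @param indices Addresses to benchmark, default `"D6-2"` plus the N95
#'   companion `"D6-3"`.
#' @param combined Optional named list of address pairs evaluated via
#'   [combined_index_value()].
#' @param outlier_reference Address whose participant values drive the
#'   outlier omission (default `"D5-2"`); `NULL` disables it.
#' @param k Outlier SD multiplier.
#' @return List with `correlations` (data.frame), `discrimination`
#'   (data.frame with AUC and r_es per metric) and `tukey` (nested list).
#' @export
benchmark_indices <- function(cohort, wavelet = "sym2",
                              indices = c("D6-2", "D6-3"),
                              combined = list(),
                              outlier_reference = "D5-2", k = 4) {
  stopifnot(inherits(cohort, "perg_cohort"))
  grp <- cohort_groups(cohort)
  nrec <- nrow(cohort$samples)
  emaps <- lapply(seq_len(nrec), function(i) {
    energy_map(decompose(cohort$samples[i, ], wavelet),
               duration_ms = cohort$duration_ms, fs = cohort$fs)
  })
  index_vals <- vapply(indices, function(a) {
    vapply(emaps, function(e) e$energy[e$feature == a][1L], numeric(1))
  }, numeric(nrec))
  comb_vals <- if (length(combined)) {
    vapply(combined, function(pair) {
      vapply(emaps, combined_index_value, numeric(1), addr_pair = pair)
    }, numeric(nrec))
  } else NULL
  markers <- t(vapply(seq_len(nrec), function(i) {
    unlist(clinical_markers(measure_peaks(cohort$samples[i, ],
                                          fs = cohort$fs)))
  }, c(p50_n35 = 0, n95_p50 = 0)))

  metrics <- cbind(index_vals, comb_vals, markers)
  normal <- grp == "normal"

  # outlier omission on the reference index, normal recordings only
  keep_norm <- rep(TRUE, nrec)
  if (!is.null(outlier_reference)) {
    ref <- if (outlier_reference %in% colnames(metrics)) {
      metrics[, outlier_reference]
    } else {
      vapply(emaps, function(e) {
        e$energy[e$feature == outlier_reference][1L]
      }, numeric(1))
    }
    keep_norm[normal] <- outlier_filter(ref[normal], k = k)
  }

  # participant-level correlations in the normal group
  sub <- perg_cohort(cohort$meta[normal & keep_norm, , drop = FALSE],
                     cohort$samples[normal & keep_norm, , drop = FALSE],
                     fs = cohort$fs, duration_ms = cohort$duration_ms)
  corr_rows <- list()
  for (m in setdiff(colnames(metrics), c("p50_n35", "n95_p50"))) {
    mv <- .participant_values(sub, metrics[normal & keep_norm, m])
    for (cm in c("p50_n35", "n95_p50")) {
      cv <- .participant_values(sub, metrics[normal & keep_norm, cm])
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        index = m, marker = cm,
        r_corr = pearson_corr(mv$value, cv$value),
        n = nrow(mv))
    }
  }

  # participant-level discrimination: AUC (pair counting) + r_es
  pid <- cohort$meta$participant_id
  pgrp <- tapply(grp, pid, `[`, 1L)
  disc_rows <- list()
  for (m in colnames(metrics)) {
    pv <- tapply(metrics[, m], pid, mean)
    mw <- mann_whitney(pv[pgrp == "normal"], pv[pgrp == "mpird"])
    es <- effect_sizes(mw$U, mw$z, sum(pgrp == "normal"),
                       sum(pgrp == "mpird"))
    disc_rows[[length(disc_rows) + 1L]] <- data.frame(
      metric = m, auc = roc_auc(as.numeric(pv), pgrp == "normal"),
      r_es = es$r_es, cles = es$cles, p = mw$p)
  }
  tukey <- lapply(stats::setNames(colnames(metrics), colnames(metrics)),
                  function(m) {
    pv <- tapply(metrics[, m], pid, mean)
    list(normal = tukey_summary(as.numeric(pv[pgrp == "normal"])),
         mpird = tukey_summary(as.numeric(pv[pgrp == "mpird"])))
  })
  list(correlations = do.call(rbind, corr_rows),
       discrimination = do.call(rbind, disc_rows),
       tukey = tukey,
       omitted_normal_recordings = sum(normal & !keep_norm))
}
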