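# Participant-level energy-index features and the two-group statistics:
# Mann-Whitney U with a normal approximation, Benjamini-Hochberg FDR
# control, the rank-biserial-style effect size r_es = |z| / sqrt(N), the
# common-language effect size CLES = U / (n1 n2), and greedy Spearman
# pruning of redundant features.

#' Build the participant-level feature table
#'
#' For each retained wavelet, each recording contributes the squared
#' coefficients (energies) at detail levels D4 up to the wavelet's maximum
#' plus the deepest approximation; D1--D3 are dropped because the 1--100 Hz
#' acquisition band-pass leaves them with no physiological content, and
#' shallower approximations are dropped as spectrally redundant with the
#' retained details. Recordings are then averaged within participant so
#' each participant contributes one feature vector regardless of how many
#' recordings they have. Features are named `<wavelet>-<band><level>-<pos>`,
#' e.g. `sym2-D6-2`.
#'
#' @param cohort Preprocessed `perg_cohort`.
#' @param wavelets Retained wavelet names (from [screen_wavelets()] or the
#'   analysis default).
#' @param min_detail_level First detail level kept, default 4.
#' @return data.frame of class `perg_feature_table`: `participant_id`,
#'   `group`, then one numeric column per feature; attribute `feature_info`
#'   maps features to their wavelet, band, level, position and
#'   time-frequency window.
#' @export
build_feature_table <- function(cohort, wavelets, min_detail_level = 4L) {
  stopifnot(inherits(cohort, "perg_cohort"), length(wavelets) >= 1L)
  n <- ncol(cohort$samples)
  X <- t(cohort$samples)                     # samples x recordings
  blocks <- list(); info <- list(); b <- 0L
  for (w in wavelets) {
    spec <- wavelet_spec(w, n)
    f <- wavelet_filter(w)
    A <- X
    for (d in seq_len(spec$max_level)) {
      s <- .dwt_step(A, f$lo, f$hi)
      A <- s$a
      if (d >= min_detail_level) {
        b <- b + 1L
        blocks[[b]] <- s$d^2
        info[[b]] <- data.frame(wavelet = w, band = "D", level = d,
                                position = seq_len(nrow(s$d)))
      }
    }
    b <- b + 1L
    blocks[[b]] <- A^2
    info[[b]] <- data.frame(wavelet = w, band = "A", level = spec$max_level,
                            position = seq_len(nrow(A)))
  }
  E <- do.call(rbind, blocks)                # features x recordings
  info <- do.call(rbind, info)
  feat <- paste0(info$wavelet, "-",
                 format_index(info$band, info$level, info$position))
  pid <- cohort$meta$participant_id
  grp <- cohort_groups(cohort)
  ids <- unique(pid)
  M <- vapply(ids, function(id) rowMeans(E[, pid == id, drop = FALSE]),
              numeric(nrow(E)))
  tab <- data.frame(participant_id = ids,
                    group = grp[match(ids, pid)],
                    t(M), check.names = FALSE)
  names(tab)[-(1:2)] <- feat
  win <- index_window(info$band, info$level, info$position, n_samples = n,
                      duration_ms = cohort$duration_ms, fs = cohort$fs)
  info <- cbind(data.frame(feature = feat, wavelet = info$wavelet),
                win)
  rownames(tab) <- rownames(info) <- NULL
  structure(tab, feature_info = info,
            class = c("perg_feature_table", "data.frame"))
}

#' Mann-Whitney U test (normal approximation)
#'
#' `U` counts the pairs in which the first-group value exceeds the
#' second-group value, ties counting one half, so `U / (n1 n2)` reads
#' directly as the probability that a random first-group value beats a
#' random second-group value. The z-statistic uses the large-sample normal
#' approximation with the midrank tie correction and no continuity
#' correction; the p-value is two-sided.
#'
#' @param x,y Non-empty numeric samples (conventionally normal and mpIRD).
#' @return List with `U`, `z` and `p`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- if (n > 1L) sum(ties^3 - ties) / (n * (n - 1)) else 0
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Effect sizes from a Mann-Whitney result
#'
#' `r_es = |z| / sqrt(N)` with `N = n1 + n2`, and the common-language
#' effect size `CLES = U / (n1 n2)`: the probability that a randomly chosen
#' first-group (normal) observation exceeds a randomly chosen second-group
#' (mpIRD) observation. Both are invariant under strictly monotone
#' transformations of the values.
#'
#' @param U,z Mann-Whitney statistic and z approximation.
#' @param n1,n2 Group sizes.
#' @return List with `r_es` and `cles`.
#' @export
effect_sizes <- function(U, z, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  list(r_es = abs(z) / sqrt(n1 + n2), cles = U / (n1 * n2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) with rejection at
#' `p_adj <= alpha`.
#'
#' @param p P-values in `[0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return List with `p_adj` and logical `reject`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= alpha)
}

#' Group-comparison statistics for every feature
#'
#' Runs [mann_whitney()] (normal vs mpIRD orientation) per feature column,
#' adjusts the two-sided p-values with [bh_adjust()] and attaches both
#' effect sizes and the feature's time-frequency window.
#'
#' @param table A [build_feature_table()] result.
#' @param alpha FDR level.
#' @return data.frame with one row per feature: `feature`, `U`, `z`, `p`,
#'   `p_adj`, `reject`, `r_es`, `cles`, `n_normal`, `n_mpird` and the
#'   window columns.
#' @export
feature_stats <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "perg_feature_table"))
  info <- attr(table, "feature_info")
  feats <- info$feature
  g <- table$group
  n1 <- sum(g == "normal"); n2 <- sum(g == "mpird")
  res <- lapply(feats, function(fname) {
    v <- table[[fname]]
    mw <- mann_whitney(v[g == "normal"], v[g == "mpird"])
    es <- effect_sizes(mw$U, mw$z, n1, n2)
    data.frame(feature = fname, U = mw$U, z = mw$z, p = mw$p,
               r_es = es$r_es, cles = es$cles,
               n_normal = n1, n_mpird = n2)
  })
  out <- do.call(rbind, res)
  adj <- bh_adjust(out$p, alpha)
  out$p_adj <- adj$p_adj
  out$reject <- adj$reject
  out <- merge(out, info[, c("feature", "wavelet", "band", "level",
                             "position", "t_lo", "t_hi", "f_lo", "f_hi")],
               by = "feature", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank features by effect size
#'
#' @param stats A [feature_stats()] data.frame.
#' @return The same rows in descending `r_es` order (stable).
#' @export
rank_features <- function(stats) {
  stats[order(-stats$r_es), , drop = FALSE]
}

#' Prune redundant features by Spearman correlation
#'
#' Features are visited in descending `r_es` (ties: descending CLES, then
#' name) and kept only if their absolute Spearman correlation across
#' participants with every feature already kept stays at or below the
#' threshold -- so of any highly correlated pair, the one with the lower
#' effect size is removed. A constant feature has no defined correlation
#' and is treated as uncorrelated.
#'
#' @param table A [build_feature_table()] result.
#' @param stats Matching [feature_stats()] rows.
#' @param threshold Correlation cutoff, default 0.9 (a pair at exactly 0.9
#'   is kept; removal needs `|rho| > 0.9`).
#' @return Character vector of kept feature names, in visiting order.
#' @export
prune_correlated <- function(table, stats, threshold = 0.9) {
  stopifnot(inherits(table, "perg_feature_table"))
  ord <- order(-stats$r_es, -stats$cles, stats$feature)
  visit <- stats$feature[ord]
  vals <- as.matrix(table[, visit, drop = FALSE])
  rk <- apply(vals, 2L, rank)
  sds <- apply(rk, 2L, stats::sd)
  kept <- character(0)
  for (fname in visit) {
    if (sds[fname] == 0) {            # constant: undefined rho, keep
      kept <- c(kept, fname)
      next
    }
    ok <- TRUE
    for (k in kept) {
      if (sds[k] == 0) next
      rho <- stats::cor(rk[, fname], rk[, k])
      if (abs(rho) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, fname)
  }
  kept
}

#' Restrict a cohort to an eye partition
#'
#' Views for the sensitivity analyses: all recordings, one eye, or each
#' participant's worse eye by visual acuity (higher logMAR) or by the
#' smaller macular-cone amplitude |P50-N35|.
#'
#' @param cohort Preprocessed `perg_cohort`.
#' @param mode `"all"`, `"RE"`, `"LE"`, `"worst_va"` or `"worst_p50n35"`.
#' @return The restricted `perg_cohort`.
#' @export
eye_partition <- function(cohort, mode = c("all", "RE", "LE", "worst_va",
                                           "worst_p50n35")) {
  mode <- match.arg(mode)
  if (mode == "all") return(cohort)
  if (mode %in% c("RE", "LE")) {
    keep <- cohort$meta$eye == mode
  } else {
    score <- if (mode == "worst_va") {
      cohort$meta$va_logmar
    } else {
      -vapply(seq_len(nrow(cohort$samples)), function(i) {
        pk <- measure_peaks(cohort$samples[i, ], fs = cohort$fs)
        clinical_markers(pk)$p50_n35
      }, numeric(1))
    }
    # worse eye = higher score; keep that eye's recordings per participant
    eye_score <- stats::aggregate(
      score,
      by = list(pid = cohort$meta$participant_id, eye = cohort$meta$eye),
      FUN = mean)
    worst <- do.call(rbind, lapply(split(eye_score, eye_score$pid),
                                   function(d) d[which.max(d$x), ]))
    keep <- paste(cohort$meta$participant_id, cohort$meta$eye) %in%
      paste(worst$pid, worst$eye)
  }
  perg_cohort(cohort$meta[keep, , drop = FALSE],
              cohort$samples[keep, , drop = FALSE],
              fs = cohort$fs, duration_ms = cohort$duration_ms)
}
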