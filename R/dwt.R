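# Periodized (circular) orthogonal DWT on dyadic-length traces.
#
# One analysis step maps the current approximation a (length n) to
#   A[k] = sum_m lo[m] a[(2k + L/2 - m) mod n],  m = 0..L-1, k = 0..n/2-1
# (0-based), the standard phase convention of the 'per' extension mode; the
# synthesis step is the adjoint, which for orthonormal filters is the exact
# inverse. Gather-index matrices are memoized per (n, L).

.dwt_cache <- new.env(parent = emptyenv())

.step_index <- function(n, L) {
  key <- sprintf("idx_%d_%d", n, L)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  half <- n %/% 2L
  # idx[m, k] = (2(k-1) + L/2 - (m-1)) mod n, 1-based result
  idx <- outer(seq_len(L) - 1L, 2L * (seq_len(half) - 1L),
               function(m, k2) (k2 + L %/% 2L - m) %% n) + 1L
  .dwt_cache[[key]] <- idx
  idx
}

# One analysis step; X is a vector or an n x m matrix of column traces.
.dwt_step <- function(X, lo, hi) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X); L <- length(lo)
  if (n %% 2L != 0L) stop("periodized step needs even length, got ", n)
  half <- n %/% 2L
  idx <- .step_index(n, L)
  G <- matrix(X[as.vector(idx), , drop = FALSE], nrow = L)
  list(a = matrix(lo %*% G, half, m), d = matrix(hi %*% G, half, m))
}

# Adjoint (= inverse) of one analysis step.
.idwt_step <- function(A, D, lo, hi) {
  A <- as.matrix(A); D <- as.matrix(D)
  half <- nrow(A); n <- 2L * half; L <- length(lo)
  idx <- .step_index(n, L)
  X <- matrix(0, n, ncol(A))
  for (m in seq_len(L)) {
    rows <- idx[m, ]
    X[rows, ] <- X[rows, ] + lo[m] * A + hi[m] * D
  }
  X
}

#' Multilevel periodized wavelet decomposition
#'
#' Decomposes a 256-sample PERG trace (or any dyadic-length vector) with the
#' periodized orthogonal DWT, which treats the trace as circular. The
#' transform is energy preserving (Parseval) and exactly invertible, and
#' level `d` holds exactly `n / 2^d` coefficients.
#'
#' @param x Numeric vector of finite samples with dyadic length.
#' @param wavelet Wavelet name or a [wavelet_spec()].
#' @param level Decomposition depth; defaults to the wavelet's [max_level()].
#' @return Object of class `wavelet_decomposition`: a list with `wavelet`
#'   (the spec), `level`, `details` (list `D1`..`Dlevel`), `approximations`
#'   (list `A1`..`Alevel`, every intermediate lowpass output) and
#'   `approximation`, the deepest one.
#' @export
decompose <- function(x, wavelet, level = NULL) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("trace contains non-finite samples")
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("trace length must be dyadic, got ", n)
  }
  spec <- if (inherits(wavelet, "wavelet_spec")) wavelet else wavelet_spec(wavelet, n)
  if (is.null(level)) level <- spec$max_level
  level <- as.integer(level)
  if (level < 1L || level > log2(n)) stop("invalid decomposition level ", level)
  f <- wavelet_filter(spec$name)
  details <- vector("list", level)
  approximations <- vector("list", level)
  a <- x
  for (d in seq_len(level)) {
    s <- .dwt_step(a, f$lo, f$hi)
    a <- drop(s$a)
    details[[d]] <- drop(s$d)
    approximations[[d]] <- a
  }
  names(details) <- paste0("D", seq_len(level))
  names(approximations) <- paste0("A", seq_len(level))
  structure(
    list(wavelet = spec, level = level, n = n,
         details = details, approximations = approximations,
         approximation = approximations[[level]]),
    class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d samples, level %d\n",
              x$wavelet$name, x$n, x$level))
  invisible(x)
}

# Parse coefficient addresses of the form "D6-2" or "A6-3" (band, level,
# 1-based position) into a data.frame.
parse_index <- function(address) {
  m <- regmatches(address, regexec("^([AD])([0-9]+)-([0-9]+)$", address))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed coefficient address: ",
         paste(address[bad], collapse = ", "),
         " (expected e.g. \"D6-2\" or \"A6-3\")")
  }
  data.frame(band = vapply(m, `[`, "", 2L),
             level = as.integer(vapply(m, `[`, "", 3L)),
             position = as.integer(vapply(m, `[`, "", 4L)))
}

format_index <- function(band, level, position) {
  sprintf("%s%d-%d", band, level, position)
}

# Extract the coefficient values at the given addresses from a decomposition.
.coef_at <- function(decomp, addr) {
  vapply(seq_len(nrow(addr)), function(i) {
    band <- addr$band[i]; lev <- addr$level[i]; pos <- addr$position[i]
    v <- if (band == "D") decomp$details[[paste0("D", lev)]]
         else {
           if (lev != decomp$level) {
             stop("approximation coefficients only exist at the deepest level A",
                  decomp$level, ", requested A", lev)
           }
           decomp$approximation
         }
    if (is.null(v) || pos < 1L || pos > length(v)) {
      stop("invalid coefficient address ", format_index(band, lev, pos))
    }
    v[pos]
  }, numeric(1))
}

#' Inverse DWT of a coefficient subset
#'
#' Reconstructs the trace from the inverse transform with every coefficient
#' outside `kept` zeroed. Because the transform is orthonormal the operation
#' is linear in the kept set: reconstructions of disjoint sets add.
#'
#' @param decomp A [decompose()] result.
#' @param kept Character vector of coefficient addresses such as
#'   `c("D6-2", "A6-3")`; `A` addresses must refer to the deepest level.
#'   An empty vector yields the zero trace; the full set reproduces the input.
#' @return Numeric vector of `decomp$n` samples.
#' @export
reconstruct_subset <- function(decomp, kept) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  details <- lapply(decomp$details, function(v) numeric(length(v)))
  approx <- numeric(length(decomp$approximation))
  if (length(kept)) {
    addr <- parse_index(kept)
    vals <- .coef_at(decomp, addr)  # also validates addresses
    for (i in seq_len(nrow(addr))) {
      if (addr$band[i] == "D") {
        details[[paste0("D", addr$level[i])]][addr$position[i]] <- vals[i]
      } else {
        approx[addr$position[i]] <- vals[i]
      }
    }
  }
  f <- wavelet_filter(decomp$wavelet$name)
  a <- approx
  for (d in rev(seq_len(decomp$level))) {
    a <- drop(.idwt_step(a, details[[d]], f$lo, f$hi))
  }
  a
}

# Full inverse transform.
reconstruct <- function(decomp) {
  f <- wavelet_filter(decomp$wavelet$name)
  a <- decomp$approximation
  for (d in rev(seq_len(decomp$level))) {
    a <- drop(.idwt_step(a, decomp$details[[d]], f$lo, f$hi))
  }
  a
}

#' Time-frequency window of a coefficient index
#'
#' Maps a coefficient address to the time interval and frequency band it
#' covers. At level `d` the `n / 2^d` coefficients tile the analysis window
#' uniformly, so position `k` (1-based) covers
#' `[(k-1) w, k w]` ms with `w = duration_ms * 2^d / n_samples`; integer
#' millisecond bounds are reported with round-half-to-even. Detail level `d`
#' spans the ideal dyadic band `[fs/2^(d+1), fs/2^d]` Hz and the level-`d`
#' approximation spans `[0, fs/2^(d+1)]`; integer hertz bounds are reported
#' with round-half-away-from-zero. Centers are arithmetic midpoints of the
#' unrounded intervals.
#'
#' @param band `"A"` or `"D"` (vectorized, as are the other index arguments).
#' @param level Decomposition level.
#' @param position 1-based coefficient position within the level.
#' @param n_samples,duration_ms,fs Grid constants; defaults are the PERG
#'   acquisition values (256 samples, 150 ms, 1700 Hz).
#' @return data.frame with reported integer bounds `t_lo`, `t_hi` (ms),
#'   `f_lo`, `f_hi` (Hz), exact bounds `t_lo_exact`, `t_hi_exact`, and
#'   midpoints `t_center`, `f_center`.
#' @export
index_window <- function(band, level, position, n_samples = 256L,
                         duration_ms = 150, fs = 1700) {
  k <- length(band)
  if (length(level) != k || length(position) != k) {
    stop("band, level and position must have equal length")
  }
  if (!all(band %in% c("A", "D"))) stop("band must be \"A\" or \"D\"")
  n_cells <- n_samples / 2^level
  if (any(position < 1L | position > n_cells)) {
    bad <- which(position < 1L | position > n_cells)[1]
    stop("position out of range for ", format_index(band[bad], level[bad],
                                                    position[bad]))
  }
  w <- duration_ms * 2^level / n_samples
  t_lo <- (position - 1) * w
  t_hi <- position * w
  f_lo <- ifelse(band == "D", fs / 2^(level + 1), 0)
  f_hi <- ifelse(band == "D", fs / 2^level, fs / 2^(level + 1))
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  data.frame(
    band = band, level = as.integer(level), position = as.integer(position),
    t_lo = round(t_lo), t_hi = round(t_hi),      # round half to even
    f_lo = half_away(f_lo), f_hi = half_away(f_hi),
    t_lo_exact = t_lo, t_hi_exact = t_hi,
    t_center = (t_lo + t_hi) / 2, f_center = (f_lo + f_hi) / 2)
}

#' Energy map (scalogram) of a decomposition
#'
#' One row per coefficient with its squared value (energy, in squared signal
#' units) and the time-frequency window from [index_window()]. Summed
#' energies equal the trace's summed squares (Parseval).
#'
#' @param decomp A [decompose()] result.
#' @param duration_ms,fs Grid constants for the window mapping.
#' @return data.frame with columns `wavelet`, `feature`, `band`, `level`,
#'   `position`, `energy` and the window columns of [index_window()].
#' @export
energy_map <- function(decomp, duration_ms = 150, fs = 1700) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  rows <- lapply(seq_len(decomp$level), function(d) {
    v <- decomp$details[[d]]
    data.frame(band = "D", level = d, position = seq_along(v), coef = v)
  })
  va <- decomp$approximation
  rows[[length(rows) + 1L]] <-
    data.frame(band = "A", level = decomp$level,
               position = seq_along(va), coef = va)
  tab <- do.call(rbind, rows)
  win <- index_window(tab$band, tab$level, tab$position,
                      n_samples = decomp$n, duration_ms = duration_ms, fs = fs)
  out <- cbind(
    data.frame(wavelet = decomp$wavelet$name,
               feature = format_index(tab$band, tab$level, tab$position),
               energy = tab$coef^2),
    win)
  rownames(out) <- NULL
  out
}
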