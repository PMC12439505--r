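#' Supported mother wavelets
#'
#' The candidate set screened by the pipeline: haar, the Daubechies family
#' db2--db8, the near-linear-phase Symlets sym2--sym8, Coiflets coif1--coif2,
#' and the Fejer--Korovkin filters fk4/fk6/fk8. All are orthonormal, so the
#' periodized transform is energy preserving and exactly invertible.
#'
#' @return Character vector of the 20 supported wavelet names.
#' @export
wavelet_names <- function() {
  names(.wavelet_filters)
}

#' Quadrature-mirror filter pair for a mother wavelet
#'
#' @param name Wavelet name, one of [wavelet_names()].
#' @return List with `lo` (scaling / lowpass) and `hi` (wavelet / highpass)
#'   decomposition filters and `length`, the number of taps.
#' @export
wavelet_filter <- function(name) {
  if (length(name) != 1L || !name %in% names(.wavelet_filters)) {
    stop("unknown wavelet '", paste(name, collapse = ","),
         "'; supported: ", paste(names(.wavelet_filters), collapse = ", "))
  }
  lo <- .wavelet_filters[[name]]
  L <- length(lo)
  list(name = name, lo = lo, hi = (-1)^(seq_len(L)) * rev(lo), length = L)
}

#' Maximum admissible decomposition level
#'
#' `floor(log2(n / (L - 1)))` for a filter of `L` taps, the usual rule that
#' stops the cascade before the filter support exceeds the signal. The haar
#' wavelet is deliberately capped at level 7 so that its deepest bands split
#' the 150-ms trace into a 0--75 ms cell (containing P50) and a 75--150 ms
#' cell (containing N95).
#'
#' @param name Wavelet name.
#' @param n_samples Trace length; the pipeline operates on dyadic 256.
#' @return Integer decomposition depth.
#' @export
max_level <- function(name, n_samples = 256L) {
  f <- wavelet_filter(name)
  if (name == "haar") return(7L)
  as.integer(floor(log2(n_samples / (f$length - 1))))
}

#' Wavelet specification
#'
#' @param name Wavelet name.
#' @param n_samples Trace length used to compute the decomposition depth.
#' @return Object of class `wavelet_spec` with fields `name`, `filter_length`
#'   and `max_level`.
#' @export
wavelet_spec <- function(name, n_samples = 256L) {
  f <- wavelet_filter(name)
  structure(
    list(name = name, filter_length = f$length,
         max_level = max_level(name, n_samples)),
    class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s: %d taps, max level %d\n",
              x$name, x$filter_length, x$max_level))
  invisible(x)
}
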