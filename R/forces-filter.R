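#' Zero-phase moving-average filter
#'
#' A length-`kernel` moving average applied forward and then backward
#' (with reflective edge padding of `kernel - 1` samples each side), so
#' the output has no depth lag relative to the input: the
#' cross-correlation with the input peaks at lag zero, constants are
#' preserved exactly, and the gain on a sinusoid is the squared
#' single-pass moving-average gain.
#'
#' @param x Numeric vector of force samples.
#' @param kernel Moving-average length in samples (default 20); must be
#'   between 1 and `length(x)`.
#' @return Filtered numeric vector of the same length.
#' @export
zero_phase_ma <- function(x, kernel = 20) {
  n <- length(x)
  if (kernel < 1) abort("kernel must be >= 1")
  if (kernel > n)
    abort(paste0("kernel (", kernel, ") exceeds trace length (", n, ")"))
  if (kernel == 1) return(as.numeric(x))
  pass <- function(v) {
    k <- kernel
    padded <- c(rev(v[2:k]), v, rev(v[(length(v) - k + 1):(length(v) - 1)]))
    f <- stats::filter(padded, rep(1 / k, k), sides = 1)
    as.numeric(f[(k):(k + length(v) - 1)])
  }
  rev(pass(rev(pass(x))))
}

#' Filter force traces depth-wise per insertion
#'
#' Applies [zero_phase_ma()] to the `force_N` column of a long
#' force-trace table, independently within each insertion (grouping by
#' the metadata columns present among `phantom`, `radius_mm`, `tip`,
#' `rep`).
#'
#' @param traces Tibble with columns `depth_mm`, `force_N` and insertion
#'   metadata.
#' @param kernel Moving-average length in samples.
#' @return The input tibble with `force_N` replaced by the filtered
#'   signal and the raw signal kept in `force_raw_N`.
#' @export
filter_forces <- function(traces, kernel = 20) {
  stopifnot(all(c("depth_mm", "force_N") %in% names(traces)))
  keys <- intersect(c("phantom", "radius_mm", "tip", "rep"), names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$depth_mm, .by_group = TRUE) |>
    dplyr::mutate(force_raw_N = .data$force_N,
                  force_N = zero_phase_ma(.data$force_N, kernel)) |>
    dplyr::ungroup()
}
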