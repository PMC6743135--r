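#' Randomised insertion-experiment design
#'
#' Generates the experiment layout of the calibration study: phantoms
#' are used in sequence, and within each phantom the channel radius
#' order is an independent random permutation; every (phantom, radius)
#' combination is measured for each tip type and repetition. The design
#' is a pure function of its seed.
#'
#' @param radii Channel radii in mm (default the calibration template
#'   radii 20-75 mm).
#' @param phantoms Number of gelatin phantoms (default 10).
#' @param tips Needle tip types (default blunt and sharp).
#' @param reps Repetitions per condition (default 5).
#' @param seed Integer seed (required: reproducibility contract).
#' @return A tibble with columns `phantom`, `order`, `radius_mm`, `tip`,
#'   `rep`, ordered as executed.
#' @export
randomize_design <- function(radii = seq(20, 75, by = 5), phantoms = 10,
                             tips = c("blunt", "sharp"), reps = 5, seed) {
  if (missing(seed)) abort("a seed is required for a reproducible design")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(phantoms), function(ph) {
      order_r <- sample(radii)
      tidyr::expand_grid(order = seq_along(order_r),
                         tip = tips, rep = seq_len(reps)) |>
        dplyr::mutate(phantom = ph, radius_mm = order_r[.data$order]) |>
        dplyr::select("phantom", "order", "radius_mm", "tip", "rep")
    })
  })
}
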