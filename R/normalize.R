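#' Normalize a screen to its untreated non-silencing controls
#'
#' Divides every well's viability by the global mean (or median) of the
#' untreated NS-control wells, putting the screen on a relative-viability
#' scale on which the untreated-control center is 1. A single global
#' constant is used rather than per-plate centering: treated-vs-untreated
#' plate normalization would absorb the drug effect itself and hide true
#' sensitivity differences.
#'
#' All downstream statistics are invariant to a global positive rescaling,
#' so normalization changes no ranking; it exists to make viabilities
#' interpretable and comparable across screens.
#'
#' @param screen A `screen_dataset` (simulated or read from CSV).
#' @param center `"mean"` (default) or `"median"` of the untreated control
#'   wells.
#' @return The screen with viabilities divided by the constant, class
#'   `normalized_screen`, and the constant in `attr(, "norm_constant")`.
#' @examples
#' scr <- simulate_screen(scenario_config(), screen_design(), seed = 1)
#' nrm <- normalize_to_untreated_controls(scr)
#' attr(nrm, "norm_constant")
#' @export
normalize_to_untreated_controls <- function(screen,
                                            center = c("mean", "median")) {
  center <- match.arg(center)
  is_ctl_unt <- screen$kind == "control" & screen$condition == "untreated"
  if (!any(is_ctl_unt)) {
    stop("drug-sensitivity normalization requires untreated NS controls ",
         "on all plates", call. = FALSE)
  }
  v <- screen$viability[is_ctl_unt]
  const <- if (center == "mean") mean(v) else stats::median(v)
  if (!is.finite(const) || const <= 0) {
    stop("normalization constant (", center, " of untreated controls) is ",
         "non-positive", call. = FALSE)
  }
  screen$viability <- screen$viability / const
  attr(screen, "norm_constant") <- const
  attr(screen, "norm_center") <- center
  if (!inherits(screen, "normalized_screen")) {
    class(screen) <- c("normalized_screen", class(screen))
  }
  screen
}
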