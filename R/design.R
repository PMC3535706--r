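#' Plate/well/replicate layout of one screening experiment
#'
#' Describes the physical layout of a drug-sensitivity RNAi screen: a set of
#' library plates, each carrying active-siRNA wells plus non-silencing (NS)
#' control wells, replicated as whole plates in each treatment arm
#' (drug-treated and untreated).
#'
#' @param n_plates Number of distinct library plates (default 10).
#' @param wells_per_plate Wells on each plate (default 96).
#' @param control_wells_per_plate NS-control wells per plate (default 6).
#' @param sirna_wells_per_plate Active-siRNA wells per plate (default 90).
#' @param replicates_per_condition Replicate plates per treatment arm; must
#'   be at least 2 so that two-sample statistics are defined.
#'
#' @return An object of class `screen_design` (a named list).
#' @examples
#' d <- screen_design(replicates_per_condition = 3)
#' d$n_plates * d$sirna_wells_per_plate  # 900 siRNAs under defaults
#' @export
screen_design <- function(n_plates = 10,
                          wells_per_plate = 96,
                          control_wells_per_plate = 6,
                          sirna_wells_per_plate = 90,
                          replicates_per_condition = 3) {
  stopifnot(
    n_plates >= 1,
    sirna_wells_per_plate >= 1,
    control_wells_per_plate >= 1
  )
  if (sirna_wells_per_plate + control_wells_per_plate != wells_per_plate) {
    stop("sirna_wells_per_plate + control_wells_per_plate must equal wells_per_plate",
         call. = FALSE)
  }
  if (replicates_per_condition < 2) {
    stop("replicates_per_condition must be >= 2 (two-sample statistics need ",
         ">= 2 wells per arm)", call. = FALSE)
  }
  structure(
    list(
      n_plates = as.integer(n_plates),
      wells_per_plate = as.integer(wells_per_plate),
      control_wells_per_plate = as.integer(control_wells_per_plate),
      sirna_wells_per_plate = as.integer(sirna_wells_per_plate),
      replicates_per_condition = as.integer(replicates_per_condition)
    ),
    class = "screen_design"
  )
}

#' Total number of distinct siRNAs in a design
#' @param design A `screen_design`.
#' @return Integer count (900 under defaults).
#' @export
n_sirnas <- function(design) {
  design$n_plates * design$sirna_wells_per_plate
}

#' Generative parameters of one simulation scenario
#'
#' Collects the parameters of the generative model for a simulated screen:
#' non-hit wells have viability mean `mu_nh`; sensitizing hits have their
#' mean multiplied by `c1` (> 1) and antagonizing hits by `c2` (< 1); drug
#' treatment multiplies every treated-well mean by `d` (0 < d < 1); NS
#' control wells sit `k`-fold above active wells. Per-well noise is
#' N(mean, sigma^2) when `skewness = 0`, or gamma with the same mean and the
#' requested skewness otherwise. The number of true hits per simulated round
#' is drawn uniformly from `{n_hit_low, ..., n_hit_high}`.
#'
#' @param mu_nh Baseline non-hit viability (arbitrary assay units).
#' @param sigma Per-well noise SD, same units as `mu_nh`.
#' @param c1 Sensitizing hit multiplier (> 1).
#' @param c2 Antagonizing hit multiplier (0 < c2 < 1).
#' @param d Drug-effect multiplier on treated means (0 < d < 1; smaller =
#'   stronger kill).
#' @param k Control-well multiplier (>= 1); controls typically read higher
#'   than transfected wells.
#' @param skewness Gamma skewness s >= 0; 0 selects the normal model.
#' @param n_hit_low,n_hit_high Inclusive bounds of the true-hit count draw.
#' @param n_sims Simulation rounds per scenario.
#' @param seed Optional RNG seed used by [run_scenario()].
#' @param hit_effect `"both"` applies the hit multiplier to treated and
#'   untreated means (so a hit carries an RNAi main effect and an additive
#'   interaction mu*(C-1)*(D-1)); `"treated-only"` applies it to treated
#'   wells only.
#' @param floor_epsilon Viabilities are floored at this small positive value
#'   (viability assays are non-negative and ratio statistics need positive
#'   means); set to `NA` to disable.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(sigma = 0.2, c1 = 7, c2 = 0.15, d = 0.3)
#' @export
scenario_config <- function(mu_nh = 1.0,
                            sigma = 0.2,
                            c1 = 7,
                            c2 = 0.15,
                            d = 0.3,
                            k = 1.1,
                            skewness = 0,
                            n_hit_low = 10L,
                            n_hit_high = 60L,
                            n_sims = 500L,
                            seed = NULL,
                            hit_effect = c("both", "treated-only"),
                            floor_epsilon = 1e-6) {
  hit_effect <- match.arg(hit_effect)
  if (!(mu_nh > 0)) stop("mu_nh must be > 0", call. = FALSE)
  if (!(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (!(c1 > 1)) stop("c1 must be > 1 (sensitizing multiplier)", call. = FALSE)
  if (!(c2 > 0 && c2 < 1)) stop("c2 must be in (0, 1)", call. = FALSE)
  if (!(d > 0 && d < 1)) stop("d must be in (0, 1)", call. = FALSE)
  if (!(k >= 1)) stop("k must be >= 1", call. = FALSE)
  if (!(skewness >= 0)) stop("skewness must be >= 0", call. = FALSE)
  if (!(n_hit_low <= n_hit_high)) {
    stop("n_hit_low must be <= n_hit_high", call. = FALSE)
  }
  if (n_hit_low < 0) stop("n_hit_low must be >= 0", call. = FALSE)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  structure(
    list(
      mu_nh = mu_nh, sigma = sigma, c1 = c1, c2 = c2, d = d, k = k,
      skewness = skewness,
      n_hit_low = as.integer(n_hit_low),
      n_hit_high = as.integer(n_hit_high),
      n_sims = as.integer(n_sims),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      hit_effect = hit_effect,
      floor_epsilon = floor_epsilon
    ),
    class = "scenario_config"
  )
}

# qualitative level -> numeric parameter maps (endpoints of the simulation
# parameter menus; sigma = 0.6 and (C1, C2) = (5, 0.3) remain reachable
# through scenario_config directly)
.noise_map <- c(low = 0.2, moderate = 0.4, strong = 0.8)
.drug_map  <- c(strong = 0.3, moderate = 0.6, weak = 0.8)
.rnai_map  <- list(strong = c(7, 0.15), moderate = c(2, 0.5),
                   weak = c(1.25, 0.8))

#' Build a scenario config from qualitative levels
#'
#' Maps qualitative noise / drug-effect / RNAi-effect levels to numeric
#' generative parameters: noise low/moderate/strong gives sigma 0.2/0.4/0.8;
#' drug strong/moderate/weak gives D 0.3/0.6/0.8 (a smaller multiplier kills
#' more cells); RNAi strong/moderate/weak gives (C1, C2) = (7, 0.15),
#' (2, 0.5), (1.25, 0.8).
#'
#' @param noise One of `"low"`, `"moderate"`, `"strong"`.
#' @param drug One of `"strong"`, `"moderate"`, `"weak"`.
#' @param rnai One of `"strong"`, `"moderate"`, `"weak"`.
#' @param ... Further arguments passed to [scenario_config()] (e.g. `k`,
#'   `n_sims`, `seed`, `skewness`).
#' @return A `scenario_config`.
#' @examples
#' make_scenario("low", "strong", "strong")
#' @export
make_scenario <- function(noise = c("low", "moderate", "strong"),
                          drug = c("strong", "moderate", "weak"),
                          rnai = c("strong", "moderate", "weak"),
                          ...) {
  noise <- match.arg(noise)
  drug <- match.arg(drug)
  rnai <- match.arg(rnai)
  cc <- .rnai_map[[rnai]]
  scenario_config(sigma = .noise_map[[noise]], d = .drug_map[[drug]],
                  c1 = cc[1], c2 = cc[2], ...)
}

#' The nine reference scenarios of the simulation study
#'
#' @return A data frame with columns `scenario`, `noise`, `drug`, `rnai`
#'   covering the nine representative noise / drug / RNAi combinations used
#'   by [sweep_scenarios()] by default.
#' @export
scenario_table <- function() {
  data.frame(
    scenario = 1:9,
    noise = c("low", "moderate", "strong", "low", "low", "moderate",
              "strong", "low", "low"),
    drug  = c("strong", "strong", "strong", "moderate", "weak", "weak",
              "weak", "strong", "strong"),
    rnai  = c("strong", "strong", "strong", "strong", "strong", "strong",
              "strong", "moderate", "weak"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Screen design:", x$n_plates, "plates x", x$wells_per_plate,
      "wells (", x$sirna_wells_per_plate, "siRNA +",
      x$control_wells_per_plate, "NS control ),",
      x$replicates_per_condition, "replicate plates per condition\n")
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: mu_NH=%g sigma=%g C1=%g C2=%g D=%g K=%g skewness=%g hits~U{%d..%d} (%s)\n",
    x$mu_nh, x$sigma, x$c1, x$c2, x$d, x$k, x$skewness,
    x$n_hit_low, x$n_hit_high, x$hit_effect))
  invisible(x)
}
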