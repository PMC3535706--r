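#' Draw the number of true hits for one simulated round
#'
#' The true-hit count of a round is uniform on the integers
#' `{n_hit_low, ..., n_hit_high}` (defaults 10..60, mean 35, out of 900
#' siRNAs).
#'
#' @param config A [scenario_config()].
#' @return A single integer.
#' @export
draw_n_true_hits <- function(config) {
  lo <- config$n_hit_low
  hi <- config$n_hit_high
  if (lo > hi) stop("n_hit_low must be <= n_hit_high", call. = FALSE)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Label which siRNAs are true hits
#'
#' Chooses `n_th` siRNA ids uniformly without replacement and splits them
#' into `ceiling(n_th / 2)` sensitizing and `floor(n_th / 2)` antagonizing
#' hits, so the two directions are balanced to within one.
#'
#' @param n_th Number of true hits.
#' @param design A [screen_design()].
#' @param c1,c2 Hit multipliers recorded in the `multiplier` column
#'   (sensitizing / antagonizing); non-hits get multiplier 1.
#' @return A data frame (the truth table) with one row per siRNA:
#'   `sirna_id`, `label` in {`"non-hit"`, `"sensitizing"`, `"antagonizing"`},
#'   `multiplier`.
#' @export
assign_truth <- function(n_th, design, c1 = NA_real_, c2 = NA_real_) {
  ids <- sirna_ids(design)
  if (n_th > length(ids)) {
    stop("n_th (", n_th, ") exceeds the number of siRNAs (", length(ids), ")",
         call. = FALSE)
  }
  label <- rep("non-hit", length(ids))
  mult <- rep(1, length(ids))
  if (n_th > 0) {
    hit_idx <- sample.int(length(ids), n_th)   # already in random order
    n_sens <- ceiling(n_th / 2)
    sens <- hit_idx[seq_len(n_sens)]
    anta <- hit_idx[setdiff(seq_len(n_th), seq_len(n_sens))]
    label[sens] <- "sensitizing"
    mult[sens] <- c1
    label[anta] <- "antagonizing"
    mult[anta] <- c2
  }
  data.frame(sirna_id = ids, label = label, multiplier = mult,
             stringsAsFactors = FALSE)
}

#' siRNA identifiers of a design
#'
#' Zero-padded ids (`"s0001"` ...) in plate order: siRNA i sits on plate
#' `ceiling(i / sirna_wells_per_plate)`.
#' @param design A `screen_design`.
#' @return Character vector of length [n_sirnas()].
#' @export
sirna_ids <- function(design) {
  n <- n_sirnas(design)
  sprintf("s%04d", seq_len(n))
}

#' Expected viability of one well type
#'
#' Cell means of the generative model. With `hit_effect = "both"` (the
#' default) an active well with hit multiplier C has untreated mean
#' `mu_nh * C` and treated mean `mu_nh * C * d`; control wells have
#' untreated mean `mu_nh * k` and treated mean `mu_nh * d * k`. With
#' `hit_effect = "treated-only"` the hit multiplier enters treated active
#' wells only.
#'
#' @param kind `"active"` or `"control"` (vectorized).
#' @param condition `"treated"` or `"untreated"` (vectorized).
#' @param multiplier Hit multiplier (1 for non-hits; ignored for controls).
#' @param config A [scenario_config()].
#' @return Numeric vector of means.
#' @examples
#' cfg <- scenario_config(d = 0.3, k = 1.1)
#' cell_mean("active", "treated", 7, cfg)    # 2.1
#' cell_mean("control", "treated", 1, cfg)   # 0.33
#' @export
cell_mean <- function(kind, condition, multiplier, config) {
  n <- max(length(kind), length(condition), length(multiplier))
  kind <- rep_len(kind, n)
  condition <- rep_len(condition, n)
  multiplier <- rep_len(multiplier, n)
  treated <- condition == "treated"
  active <- kind == "active"
  m <- rep(config$mu_nh, n)
  if (config$hit_effect == "both") {
    m[active] <- m[active] * multiplier[active]
  } else {
    m[active & treated] <- m[active & treated] * multiplier[active & treated]
  }
  m[!active] <- m[!active] * config$k
  m[treated] <- m[treated] * config$d
  m
}

#' Gamma shape and scale for a target mean
#'
#' In `mode = "skewness"` returns the gamma with mean `mu` and skewness
#' `skewness`: shape `r = 4 / skewness^2` (gamma skewness is `2 / sqrt(r)`)
#' and scale `lambda = mu / r`. In `mode = "moments"` matches a target mean
#' and SD by solving `mu = r * lambda` and `sigma^2 = r * lambda^2`, giving
#' `r = mu^2 / sigma^2`, `lambda = sigma^2 / mu`.
#'
#' @param mu Target mean (> 0).
#' @param skewness Target skewness (> 0; `"skewness"` mode).
#' @param sigma Target SD (> 0; `"moments"` mode).
#' @param mode `"skewness"` or `"moments"`.
#' @return A list with elements `shape` and `scale`.
#' @examples
#' gamma_params(1, skewness = 2)                  # exponential: shape 1
#' gamma_params(1, sigma = 0.5, mode = "moments") # shape 4, scale 0.25
#' @export
gamma_params <- function(mu, skewness = NULL, sigma = NULL,
                         mode = c("skewness", "moments")) {
  mode <- match.arg(mode)
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (mode == "skewness") {
    if (is.null(skewness) || any(skewness <= 0)) {
      stop("skewness must be > 0", call. = FALSE)
    }
    shape <- 4 / skewness^2
    list(shape = shape, scale = mu / shape)
  } else {
    if (is.null(sigma) || any(sigma <= 0)) {
      stop("sigma must be > 0", call. = FALSE)
    }
    list(shape = mu^2 / sigma^2, scale = sigma^2 / mu)
  }
}

# Build the well layout (no viabilities yet): active wells are one row per
# (siRNA, condition, replicate); control wells one row per
# (plate, replicate, condition, control well).
.layout <- function(design) {
  r <- design$replicates_per_condition
  n_si <- n_sirnas(design)
  ids <- sirna_ids(design)
  plate_of <- rep(seq_len(design$n_plates), each = design$sirna_wells_per_plate)
  conds <- c("untreated", "treated")

  act <- data.frame(
    plate = rep(plate_of, times = 2L * r),
    replicate = rep(rep(seq_len(r), each = n_si), times = 2L),
    condition = rep(conds, each = n_si * r),
    kind = "active",
    sirna_id = rep(ids, times = 2L * r),
    stringsAsFactors = FALSE
  )
  nc <- design$control_wells_per_plate
  ctl_block <- expand.grid(
    well = seq_len(nc),
    plate = seq_len(design$n_plates),
    replicate = seq_len(r),
    condition = conds,
    stringsAsFactors = FALSE
  )
  ctl <- data.frame(
    plate = ctl_block$plate,
    replicate = ctl_block$replicate,
    condition = ctl_block$condition,
    kind = "control",
    sirna_id = NA_character_,
    stringsAsFactors = FALSE
  )
  rbind(act, ctl)
}

#' Simulate one drug-sensitivity screen
#'
#' Draws a true-hit count, labels hit siRNAs, and generates every well's
#' viability from the scenario's generative model: normal
#' `N(cell mean, sigma^2)` when `config$skewness == 0`, or a gamma
#' distribution with the same cell mean and the configured skewness
#' otherwise. Viabilities are floored at `config$floor_epsilon`.
#'
#' @param config A [scenario_config()].
#' @param design A [screen_design()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so identical `(config, design, seed)` give identical datasets.
#' @return A data frame of class `screen_dataset` with columns `plate`,
#'   `replicate`, `condition`, `kind`, `sirna_id`, `viability`, carrying the
#'   truth table in `attr(, "truth")` and the generating `config`/`design`
#'   as attributes.
#' @seealso [simulate_screen_gamma()] for the explicit gamma entry point.
#' @export
simulate_screen <- function(config, design = screen_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- .layout(design)
  n_th <- draw_n_true_hits(config)
  truth <- assign_truth(n_th, design, c1 = config$c1, c2 = config$c2)

  mult <- rep(1, nrow(lay))
  act <- lay$kind == "active"
  mult[act] <- truth$multiplier[match(lay$sirna_id[act], truth$sirna_id)]
  means <- cell_mean(lay$kind, lay$condition, mult, config)

  n <- nrow(lay)
  if (config$skewness == 0) {
    v <- stats::rnorm(n, mean = means, sd = config$sigma)
  } else {
    gp <- gamma_params(means, skewness = config$skewness)
    v <- stats::rgamma(n, shape = gp$shape, scale = gp$scale)
  }
  if (is.finite(config$floor_epsilon)) {
    v <- pmax(v, config$floor_epsilon)
  }
  lay$viability <- v
  structure(lay,
            truth = truth, config = config, design = design,
            class = c("screen_dataset", "data.frame"))
}

#' Simulate a screen with gamma-skewed viabilities
#'
#' Identical to [simulate_screen()] but requires `config$skewness > 0`; each
#' well is drawn from a gamma distribution whose mean equals the well's cell
#' mean and whose skewness is `config$skewness` (the variance then follows
#' as `(mean * skewness / 2)^2`).
#'
#' @inheritParams simulate_screen
#' @return A `screen_dataset`; see [simulate_screen()].
#' @export
simulate_screen_gamma <- function(config, design = screen_design(),
                                  seed = NULL) {
  if (config$skewness <= 0) {
    stop("config$skewness must be > 0; use simulate_screen() for the ",
         "normal model", call. = FALSE)
  }
  simulate_screen(config, design, seed)
}

#' Number of true hits attached to a simulated screen
#' @param screen A `screen_dataset` with a truth attribute.
#' @return Integer count of siRNAs labelled sensitizing or antagonizing.
#' @export
n_true_hits <- function(screen) {
  truth <- attr(screen, "truth")
  if (is.null(truth)) stop("screen carries no truth table", call. = FALSE)
  sum(truth$label != "non-hit")
}
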