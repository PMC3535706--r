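#' Select the top-n hit calls for one method
#'
#' Ranks one method's scores on the common sensitizing scale (`sens_score`,
#' larger = more sensitizing) and calls the `ceiling(n_th / 2)` most extreme
#' siRNAs in the sensitizing direction plus the `floor(n_th / 2)` most
#' extreme in the antagonizing direction — the same number of calls as there
#' are true hits, half per direction. Ties are broken by siRNA id for
#' determinism; invalid scores are never selected.
#'
#' @param scores A [score_all()] table restricted to a single method.
#' @param n_th Number of calls to make (the round's true-hit count).
#' @return Character vector of called siRNA ids, with the called direction
#'   for each id in `attr(, "direction")`.
#' @export
select_top_hits <- function(scores, n_th) {
  if (length(unique(scores$method)) > 1) {
    stop("select_top_hits() expects scores for a single method", call. = FALSE)
  }
  sc <- scores[scores$valid & !is.na(scores$sens_score), ]
  if (n_th > nrow(sc)) {
    stop("n_th (", n_th, ") exceeds the number of valid scores (",
         nrow(sc), ")", call. = FALSE)
  }
  if (n_th == 0) {
    out <- character(0)
    attr(out, "direction") <- character(0)
    return(out)
  }
  n_sens <- ceiling(n_th / 2)
  n_anta <- n_th - n_sens
  ord_sens <- order(-sc$sens_score, sc$sirna_id)
  sens_ids <- sc$sirna_id[ord_sens][seq_len(n_sens)]
  ord_anta <- order(sc$sens_score, sc$sirna_id)
  anta_pool <- setdiff(sc$sirna_id[ord_anta], sens_ids)
  anta_ids <- anta_pool[seq_len(n_anta)]
  out <- c(sens_ids, anta_ids)
  attr(out, "direction") <- c(rep("sensitizing", n_sens),
                              rep("antagonizing", length(anta_ids)))
  out
}

#' Confusion counts of a hit-call set against the truth table
#'
#' A called siRNA that is any true hit counts as a true positive regardless
#' of the called direction (hit/non-hit is what the error rates measure);
#' `strict_direction = TRUE` additionally requires the called direction to
#' match the true label, using the direction attribute of
#' [select_top_hits()].
#'
#' @param hits Character vector of called siRNA ids (with optional
#'   `direction` attribute).
#' @param truth Truth table from [assign_truth()] / `attr(screen, "truth")`.
#' @param strict_direction Require direction agreement for a TP.
#' @return A list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(hits, truth, strict_direction = FALSE) {
  unknown <- setdiff(hits, truth$sirna_id)
  if (length(unknown)) {
    stop("hit call(s) not in the truth table: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  is_hit <- truth$label != "non-hit"
  called <- truth$sirna_id %in% hits
  tp_mask <- called & is_hit
  if (strict_direction) {
    dir <- attr(hits, "direction")
    if (is.null(dir)) {
      stop("strict_direction = TRUE requires a direction attribute on hits",
           call. = FALSE)
    }
    called_dir <- dir[match(truth$sirna_id, hits)]
    tp_mask <- tp_mask & truth$label == called_dir
  }
  TP <- sum(tp_mask)
  FP <- sum(called & !is_hit)
  FN <- sum(is_hit) - sum(called & is_hit)
  TN <- sum(!is_hit) - FP
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' False-positive and false-negative rates
#'
#' `FPR = FP / (FP + TN) = 1 - specificity` and
#' `FNR = FN / (TP + FN) = 1 - sensitivity`; `1 - FNR` is the method's
#' power.
#'
#' @param counts Confusion counts from [confusion()].
#' @return A list with fields `FPR` and `FNR`.
#' @export
rates <- function(counts) {
  neg <- counts$FP + counts$TN
  pos <- counts$TP + counts$FN
  if (neg <= 0) stop("FPR undefined: no true non-hits", call. = FALSE)
  if (pos <= 0) stop("FNR undefined: no true hits", call. = FALSE)
  list(FPR = counts$FP / neg, FNR = counts$FN / pos)
}

#' Run one scenario: simulate, score, select, and accumulate error rates
#'
#' For each of `config$n_sims` rounds: draw the true-hit count, simulate a
#' screen, normalize to untreated NS controls, score every siRNA with each
#' method, call the top n_TH hits (half per direction), and record FPR and
#' FNR against the ground truth. Per-round seeds are pre-drawn from
#' `config$seed` so the whole run is reproducible and rounds are
#' independent.
#'
#' @param config A [scenario_config()] (its `n_sims` and `seed` are used).
#' @param design A [screen_design()].
#' @param methods Methods to compare (see [score_all()]).
#' @param center Normalization center, `"mean"` or `"median"`.
#' @param lm_test,welch Passed to [score_all()].
#' @param strict_direction Passed to [confusion()].
#' @return An object of class `scenario_result`: a list with `summary`
#'   (per-method mean FPR/FNR, Monte-Carlo SEs, and rank by mean FNR),
#'   `rounds` (per-round rates), and the generating `config` and `design`.
#' @examples
#' cfg <- make_scenario("low", "strong", "strong", n_sims = 3, seed = 1)
#' run_scenario(cfg, screen_design(replicates_per_condition = 3))$summary
#' @export
run_scenario <- function(config, design = screen_design(),
                         methods = c("fold_change", "t_test", "si", "lm"),
                         center = c("mean", "median"),
                         lm_test = c("chisq", "f"),
                         welch = FALSE,
                         strict_direction = FALSE) {
  center <- match.arg(center)
  lm_test <- match.arg(lm_test)
  n_sims <- config$n_sims
  if (!is.null(config$seed)) set.seed(config$seed)
  round_seeds <- sample.int(.Machine$integer.max, n_sims)

  rounds <- vector("list", n_sims)
  for (b in seq_len(n_sims)) {
    res <- tryCatch({
      scr <- simulate_screen(config, design, seed = round_seeds[b])
      nrm <- normalize_to_untreated_controls(scr, center = center)
      n_th <- n_true_hits(scr)
      scores <- score_all(nrm, methods = methods, lm_test = lm_test,
                          welch = welch)
      truth <- attr(scr, "truth")
      do.call(rbind, lapply(methods, function(m) {
        hits <- select_top_hits(scores[scores$method == m, ], n_th)
        r <- rates(confusion(hits, truth,
                             strict_direction = strict_direction))
        data.frame(round = b, method = m, n_th = n_th,
                   fpr = r$FPR, fnr = r$FNR, stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      stop("scenario round ", b, ": ", conditionMessage(e), call. = FALSE)
    })
    rounds[[b]] <- res
  }
  rounds <- do.call(rbind, rounds)

  summary <- do.call(rbind, lapply(methods, function(m) {
    x <- rounds[rounds$method == m, ]
    data.frame(method = m,
               mean_fpr = mean(x$fpr), mean_fnr = mean(x$fnr),
               mc_se_fpr = stats::sd(x$fpr) / sqrt(nrow(x)),
               mc_se_fnr = stats::sd(x$fnr) / sqrt(nrow(x)),
               stringsAsFactors = FALSE)
  }))
  summary$rank <- rank(summary$mean_fnr, ties.method = "first")
  rownames(summary) <- NULL
  structure(list(summary = summary, rounds = rounds,
                 config = config, design = design),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario result over", x$config$n_sims, "rounds, r =",
      x$design$replicates_per_condition, "replicates/condition\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Sweep a grid of scenarios and replicate levels
#'
#' Runs [run_scenario()] for every (scenario, replicate-level) combination
#' and collects a long results table; the per-method mean-FNR columns as a
#' function of the replicate level are the numeric analogue of the study's
#' FNR-vs-replicates curves, and the per-row method ranking reproduces the
#' recommendation table.
#'
#' @param scenarios Data frame with columns `noise`, `drug`, `rnai` (and
#'   optionally `scenario` labels); defaults to the nine reference
#'   scenarios of [scenario_table()].
#' @param replicates Integer vector of replicate-per-condition levels.
#' @param methods Methods to compare.
#' @param n_sims Simulation rounds per scenario.
#' @param seed Root seed; per-cell seeds are derived deterministically.
#' @param ... Further arguments to [run_scenario()] and [make_scenario()]
#'   (e.g. `k`, `skewness`, `center`).
#' @return A data frame with one row per (scenario, replicates, method):
#'   scenario labels, `mean_fpr`, `mean_fnr`, `mc_se_fpr`, `mc_se_fnr`, and
#'   `rank` (1 = lowest mean FNR within the scenario-replicate cell), plus a
#'   `ranking` summary table (one row per cell, methods in rank order) in
#'   `attr(, "ranking")`.
#' @export
sweep_scenarios <- function(scenarios = scenario_table(),
                            replicates = c(3, 6, 9, 12),
                            methods = c("fold_change", "t_test", "si", "lm"),
                            n_sims = 100, seed = 1, ...) {
  if (nrow(scenarios) == 0 || length(replicates) == 0) {
    stop("scenarios and replicates must be non-empty", call. = FALSE)
  }
  if (is.null(scenarios$scenario)) scenarios$scenario <- seq_len(nrow(scenarios))
  dots <- list(...)
  run_args <- dots[names(dots) %in% names(formals(run_scenario))]
  cfg_args <- dots[names(dots) %in% names(formals(scenario_config))]
  cfg_args$seed <- NULL

  set.seed(seed)
  cells <- expand.grid(si = seq_len(nrow(scenarios)), r = replicates)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))

  out <- vector("list", nrow(cells))
  rank_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    srow <- scenarios[cells$si[i], ]
    r <- cells$r[i]
    cfg <- do.call(make_scenario,
                   c(list(noise = srow$noise, drug = srow$drug,
                          rnai = srow$rnai, n_sims = n_sims,
                          seed = cell_seeds[i]), cfg_args))
    des <- screen_design(replicates_per_condition = r)
    res <- do.call(run_scenario,
                   c(list(config = cfg, design = des, methods = methods),
                     run_args))
    s <- res$summary
    s <- cbind(data.frame(scenario = srow$scenario, noise = srow$noise,
                          drug = srow$drug, rnai = srow$rnai,
                          replicates = r, stringsAsFactors = FALSE),
               s)
    out[[i]] <- s
    rank_rows[[i]] <- data.frame(
      scenario = srow$scenario, noise = srow$noise, drug = srow$drug,
      rnai = srow$rnai, replicates = r,
      ranking = paste(s$method[order(s$rank)], collapse = " > "),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ranking <- do.call(rbind, rank_rows)
  ranking <- ranking[order(ranking$replicates, ranking$scenario), ]
  rownames(ranking) <- NULL
  attr(res, "ranking") <- ranking
  res
}

#' Data-driven diagnostics to guide method choice
#'
#' Estimates, from a screen, the quantities the scenario grid is indexed
#' by: the noise level via the coefficient of variation (`CV = sd/mean`)
#' and variance-to-mean ratio (`VMR = var/mean`) of the untreated wells;
#' the RNAi effect via the per-siRNA `Rc/Cc` ratios; and the drug effect
#' via the control ratio `Cd/Cc`.
#'
#' @param screen A `screen_dataset` or `normalized_screen`.
#' @return A list: `cv`, `vmr` (untreated wells), `rnai_effect` (summary of
#'   per-siRNA Rc/Cc: mean, median, quartiles), `drug_effect` (mean Cd/Cc
#'   over siRNAs).
#' @export
estimate_diagnostics <- function(screen) {
  unt <- screen$viability[screen$condition == "untreated"]
  if (!length(unt)) stop("no untreated wells", call. = FALSE)
  m <- mean(unt)
  cv <- stats::sd(unt) / m
  vmr <- stats::var(unt) / m
  st <- .screen_stats(screen)
  rc_cc <- (st$au$s / st$au$n) / (st$cu$s / st$cu$n)
  cd_cc <- (st$ct$s / st$ct$n) / (st$cu$s / st$cu$n)
  list(cv = cv, vmr = vmr,
       rnai_effect = c(mean = mean(rc_cc),
                       stats::quantile(rc_cc, c(0.25, 0.5, 0.75))),
       drug_effect = mean(cd_cc))
}
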