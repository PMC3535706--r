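#' @importFrom stats pt pchisq pf median var sd rnorm rgamma wilcox.test
NULL

# group sums aligned to 1..nlev integer codes (rowsum drops empty groups;
# re-expand so every siRNA / plate keeps a slot)
.gsum <- function(v, g, nlev) {
  out <- numeric(nlev)
  r <- rowsum(v, g)
  out[as.integer(rownames(r))] <- r
  out
}

# Per-siRNA and per-plate sufficient statistics of a screen: counts, sums
# and sums of squares for the four design cells (active/control x
# treated/untreated). Controls are keyed by plate; each siRNA uses the NS
# wells of its own replicate plates.
.screen_stats <- function(screen) {
  act <- screen$kind == "active"
  a_id <- screen$sirna_id[act]
  ids <- sort(unique(a_id))
  nid <- length(ids)
  gi <- match(a_id, ids)
  a_trt <- screen$condition[act] == "treated"
  av <- screen$viability[act]

  stats_of <- function(v, g) {
    list(n = .gsum(rep(1, length(v)), g, nid),
         s = .gsum(v, g, nid),
         q = .gsum(v * v, g, nid))
  }
  au <- stats_of(av[!a_trt], gi[!a_trt])
  at <- stats_of(av[a_trt], gi[a_trt])

  ctl <- screen$kind == "control"
  cv <- screen$viability[ctl]
  cp <- screen$plate[ctl]
  c_trt <- screen$condition[ctl] == "treated"
  npl <- max(screen$plate)
  cstats <- function(v, g) {
    list(n = .gsum(rep(1, length(v)), g, npl),
         s = .gsum(v, g, npl),
         q = .gsum(v * v, g, npl))
  }
  cu <- cstats(cv[!c_trt], cp[!c_trt])
  ct <- cstats(cv[c_trt], cp[c_trt])

  plate_of <- screen$plate[act][match(ids, a_id)]
  list(ids = ids, plate = plate_of,
       au = au, at = at,
       cu = lapply(cu, function(x) x[plate_of]),
       ct = lapply(ct, function(x) x[plate_of]))
}

#' Cell-mean summaries for one siRNA
#'
#' The four average viabilities that feed the sensitivity index: `Rc`
#' (active siRNA, untreated), `Rd` (active, drug-treated), `Cc` (NS control,
#' untreated), `Cd` (NS control, treated). Control means are taken over all
#' NS wells on the siRNA's own replicate plates.
#'
#' @param screen A `screen_dataset` or `normalized_screen`.
#' @param sirna_id One siRNA identifier.
#' @return A list with elements `Rc`, `Rd`, `Cc`, `Cd`.
#' @export
summarize_cells <- function(screen, sirna_id) {
  st <- .screen_stats(screen)
  i <- match(sirna_id, st$ids)
  if (is.na(i)) stop("unknown siRNA: ", sirna_id, call. = FALSE)
  for (cell in c("au", "at", "cu", "ct")) {
    if (st[[cell]]$n[i] < 1) {
      stop("siRNA ", sirna_id, ": no wells in cell ", cell, call. = FALSE)
    }
  }
  list(Rc = st$au$s[i] / st$au$n[i],
       Rd = st$at$s[i] / st$at$n[i],
       Cc = st$cu$s[i] / st$cu$n[i],
       Cd = st$ct$s[i] / st$ct$n[i])
}

# ---- vectorized method engines (one value per siRNA) ------------------

.fc_scores <- function(st) {
  mu_u <- st$au$s / st$au$n
  mu_t <- st$at$s / st$at$n
  valid <- mu_u > 0
  stat <- rep(NA_real_, length(mu_u))
  stat[valid] <- ifelse(mu_t[valid] > 0, log2(mu_t[valid] / mu_u[valid]),
                        -Inf)
  if (any(!valid)) {
    warning(sum(!valid), " siRNA(s) with non-positive untreated mean; ",
            "fold-change flagged invalid", call. = FALSE)
  }
  list(stat = stat, p = rep(NA_real_, length(stat)), valid = valid,
       sens = -stat)   # more negative log-ratio = more sensitizing
}

.t_scores <- function(st, welch = FALSE) {
  n1 <- st$at$n; n2 <- st$au$n
  m1 <- st$at$s / n1; m2 <- st$au$s / n2
  v1 <- (st$at$q - st$at$s^2 / n1) / (n1 - 1)
  v2 <- (st$au$q - st$au$s^2 / n2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  diff <- m1 - m2           # treated - untreated
  stat <- ifelse(se2 > 0, diff / sqrt(se2),
                 ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(stat), df),
              ifelse(diff == 0, 1, 0))
  valid <- n1 >= 2 & n2 >= 2
  list(stat = stat, p = p, valid = valid,
       sens = -sign(stat) * (1 - p))
}

.si_scores <- function(st) {
  Rc <- st$au$s / st$au$n
  Rd <- st$at$s / st$at$n
  Cc <- st$cu$s / st$cu$n
  Cd <- st$ct$s / st$ct$n
  valid <- Cc > 0
  stat <- rep(NA_real_, length(Rc))
  stat[valid] <- (Rc[valid] / Cc[valid]) * (Cd[valid] / Cc[valid]) -
    Rd[valid] / Cc[valid]
  if (any(!valid)) {
    warning(sum(!valid), " siRNA(s) with non-positive control mean Cc; ",
            "SI flagged invalid", call. = FALSE)
  }
  list(stat = stat, p = rep(NA_real_, length(stat)), valid = valid,
       sens = stat)        # positive SI = sensitizing
}

# Closed-form OLS for the 2x2 factorial. Full model (drug, RNAi,
# interaction) is saturated over the four cells, so RSS_full is the pooled
# within-cell sum of squares; the reduced drug-only model pools the two
# x1 = drug groups. Statistic: (RSS_red - RSS_full) / (RSS_full / (n - 4)),
# referred to chi-square with 2 df (or an exact F(2, n - 4) variant).
.lm_scores <- function(st, lm_test = c("chisq", "f")) {
  lm_test <- match.arg(lm_test)
  within_ss <- function(g) pmax(g$q - g$s^2 / g$n, 0)
  rss_full <- within_ss(st$au) + within_ss(st$at) +
    within_ss(st$cu) + within_ss(st$ct)
  # x1 groups: untreated = active-untreated + control-untreated, etc.
  n0 <- st$au$n + st$cu$n; s0 <- st$au$s + st$cu$s; q0 <- st$au$q + st$cu$q
  n1 <- st$at$n + st$ct$n; s1 <- st$at$s + st$ct$s; q1 <- st$at$q + st$ct$q
  rss_red <- pmax(q0 - s0^2 / n0, 0) + pmax(q1 - s1^2 / n1, 0)
  ntot <- n0 + n1
  df_res <- ntot - 4
  beta3 <- (st$at$s / st$at$n - st$au$s / st$au$n) -
    (st$ct$s / st$ct$n - st$cu$s / st$cu$n)
  delta <- pmax(rss_red - rss_full, 0)
  ok <- rss_full > 0 & df_res > 0
  stat <- ifelse(ok, delta / (rss_full / df_res),
                 ifelse(delta > 0, Inf, 0))
  if (lm_test == "chisq") {
    p <- ifelse(ok, stats::pchisq(stat, df = 2, lower.tail = FALSE),
                ifelse(delta > 0, 0, 1))
  } else {
    p <- ifelse(ok, stats::pf(stat / 2, 2, df_res, lower.tail = FALSE),
                ifelse(delta > 0, 0, 1))
  }
  valid <- st$au$n > 0 & st$at$n > 0 & st$cu$n > 0 & st$ct$n > 0
  list(stat = stat, p = p, valid = valid, beta3 = beta3,
       sens = -sign(beta3) * (1 - p))  # negative interaction = sensitizing
}

.wilcoxon_scores <- function(screen, st) {
  act <- screen[screen$kind == "active", ]
  sp <- split(seq_len(nrow(act)), factor(act$sirna_id, levels = st$ids))
  nid <- length(st$ids)
  stat <- p <- numeric(nid)
  for (i in seq_len(nid)) {
    rows <- sp[[i]]
    trt <- act$viability[rows][act$condition[rows] == "treated"]
    unt <- act$viability[rows][act$condition[rows] == "untreated"]
    exact <- length(trt) <= 10 && length(unt) <= 10
    wt <- suppressWarnings(
      stats::wilcox.test(trt, unt, exact = exact, correct = TRUE))
    stat[i] <- wt$statistic - length(trt) * length(unt) / 2  # centered W
    p[i] <- wt$p.value
  }
  p[is.nan(p)] <- 1   # fully tied samples: no evidence either way
  valid <- st$at$n >= 2 & st$au$n >= 2
  list(stat = stat, p = p, valid = valid,
       sens = -sign(stat) * (1 - p))
}

.method_names <- c("fold_change", "t_test", "si", "lm", "wilcoxon")

.direction_of <- function(sens, valid) {
  d <- ifelse(sens > 0, "sensitizing", ifelse(sens < 0, "antagonizing",
                                              "none"))
  d[!valid | is.na(sens)] <- "none"
  d
}

#' Score every siRNA with the chosen hit-selection methods
#'
#' Computes, per siRNA, any of: `"fold_change"` (log2 treated/untreated mean
#' ratio of the active wells), `"t_test"` (two-sample pooled-variance t of
#' treated vs untreated active wells), `"si"` (sensitivity index
#' `(Rc/Cc)*(Cd/Cc) - Rd/Cc`), `"lm"` (2-df deviance test of the drug-by-
#' RNAi interaction model against the drug-only model, fit to the siRNA's
#' active wells plus the NS-control wells of its plates), and `"wilcoxon"`
#' (rank-sum of treated vs untreated active wells; optional, not part of
#' the default four-method comparison).
#'
#' @param screen A `screen_dataset` or `normalized_screen`.
#' @param methods Character vector from
#'   `c("fold_change", "t_test", "si", "lm", "wilcoxon")`.
#' @param lm_test `"chisq"` (scaled deviance vs chi-square 2 df, default)
#'   or `"f"` (exact F(2, n-4)); the two give identical rankings.
#' @param welch Use the Welch unequal-variance t instead of pooled.
#' @return A data frame with one row per (siRNA, method): `sirna_id`,
#'   `method`, `statistic`, `p_value` (`NA` for fold change and SI),
#'   `direction` in {sensitizing, antagonizing, none}, `valid`, and
#'   `sens_score` — the common-scale ranking score used for two-tailed hit
#'   selection (larger = more sensitizing).
#' @examples
#' scr <- simulate_screen(scenario_config(), seed = 1)
#' head(score_all(normalize_to_untreated_controls(scr)))
#' @export
score_all <- function(screen,
                      methods = c("fold_change", "t_test", "si", "lm"),
                      lm_test = c("chisq", "f"),
                      welch = FALSE) {
  lm_test <- match.arg(lm_test)
  bad <- setdiff(methods, .method_names)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!length(methods)) {
    return(data.frame(sirna_id = character(), method = character(),
                      statistic = numeric(), p_value = numeric(),
                      direction = character(), valid = logical(),
                      sens_score = numeric(), stringsAsFactors = FALSE))
  }
  st <- .screen_stats(screen)
  out <- lapply(methods, function(m) {
    sc <- switch(m,
      fold_change = .fc_scores(st),
      t_test = .t_scores(st, welch = welch),
      si = .si_scores(st),
      lm = .lm_scores(st, lm_test = lm_test),
      wilcoxon = .wilcoxon_scores(screen, st))
    data.frame(sirna_id = st$ids, method = m, statistic = sc$stat,
               p_value = sc$p,
               direction = .direction_of(sc$sens, sc$valid),
               valid = sc$valid, sens_score = sc$sens,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.one_score <- function(screen, sirna_id, method, ...) {
  sc <- score_all(screen, methods = method, ...)
  row <- sc[sc$sirna_id == sirna_id, ]
  if (nrow(row) == 0) stop("unknown siRNA: ", sirna_id, call. = FALSE)
  row
}

#' Log2 fold change of one siRNA
#'
#' `log2(mean treated / mean untreated)` over the siRNA's active wells.
#' A non-positive treated mean gives `-Inf` (ranked most sensitizing); a
#' non-positive untreated mean flags the score invalid.
#'
#' @inheritParams summarize_cells
#' @return A one-row score data frame (see [score_all()]).
#' @export
fold_change <- function(screen, sirna_id) {
  .one_score(screen, sirna_id, "fold_change")
}

#' Two-sample t statistic of one siRNA
#'
#' Pooled-variance Student t of treated vs untreated active wells (sign:
#' treated minus untreated), with a two-sided p-value on `n1 + n2 - 2`
#' degrees of freedom.
#'
#' @inheritParams summarize_cells
#' @param welch Use the Welch unequal-variance form.
#' @return A one-row score data frame (see [score_all()]).
#' @export
t_statistic <- function(screen, sirna_id, welch = FALSE) {
  .one_score(screen, sirna_id, "t_test", welch = welch)
}

#' Sensitivity index of one siRNA
#'
#' `SI = (Rc/Cc) * (Cd/Cc) - Rd/Cc`: the gap between the expected combined
#' RNAi-and-drug effect under multiplicative independence and the observed
#' treated-active viability, on the untreated-control scale. Positive values
#' indicate sensitization, negative antagonism; no p-value is defined.
#'
#' @inheritParams summarize_cells
#' @return A one-row score data frame (see [score_all()]).
#' @export
sensitivity_index <- function(screen, sirna_id) {
  .one_score(screen, sirna_id, "si")
}

#' Drug-by-RNAi interaction test for one siRNA
#'
#' Fits the full linear model
#' `Y = b0 + b1 * drug + b2 * rnai + b3 * drug * rnai` and the reduced
#' drug-only model `Y = b0 + b1 * drug` to the siRNA's active wells plus the
#' NS-control wells of its replicate plates, and tests the 2-df difference
#' with the scaled-deviance statistic
#' `(RSS_reduced - RSS_full) / (RSS_full / (n - 4))`, referred to a
#' chi-square distribution with 2 degrees of freedom (`test = "f"` gives the
#' exact F(2, n-4) version; rankings are identical). A negative fitted
#' interaction coefficient means sensitizing.
#'
#' @inheritParams summarize_cells
#' @param test `"chisq"` (default) or `"f"`.
#' @return A one-row score data frame with the fitted coefficients
#'   `beta0..beta3` attached as columns.
#' @export
lm_interaction_test <- function(screen, sirna_id, test = c("chisq", "f")) {
  test <- match.arg(test)
  st <- .screen_stats(screen)
  i <- match(sirna_id, st$ids)
  if (is.na(i)) stop("unknown siRNA: ", sirna_id, call. = FALSE)
  cells <- c(au = "active untreated", at = "active treated",
             cu = "control untreated", ct = "control treated")
  for (cell in names(cells)) {
    if (st[[cell]]$n[i] < 1) {
      stop("siRNA ", sirna_id, ": design cell '", cells[[cell]],
           "' is empty; the interaction model is singular", call. = FALSE)
    }
  }
  row <- .one_score(screen, sirna_id, "lm", lm_test = test)
  m <- function(g) st[[g]]$s[i] / st[[g]]$n[i]
  row$beta0 <- m("cu")
  row$beta1 <- m("ct") - m("cu")
  row$beta2 <- m("au") - m("cu")
  row$beta3 <- (m("at") - m("au")) - (m("ct") - m("cu"))
  row
}

#' Wilcoxon rank-sum test for one siRNA
#'
#' Rank-sum test of treated vs untreated active wells; exact p for up to 10
#' wells per arm (no ties), normal approximation otherwise. The reported
#' statistic is the rank-sum statistic W centered at `n1 * n2 / 2`, so
#' negative values mean lower treated viability (sensitizing).
#'
#' @inheritParams summarize_cells
#' @return A one-row score data frame (see [score_all()]).
#' @export
wilcoxon_test <- function(screen, sirna_id) {
  .one_score(screen, sirna_id, "wilcoxon")
}
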