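# Hand-built one-siRNA screen from explicit well values, for closed-form
# checks of the per-siRNA statistics.
manual_screen <- function(au, at, cu, ct, id = "s0001", plate = 1L) {
  row_block <- function(v, condition, kind, sid) {
    data.frame(plate = plate, replicate = seq_along(v),
               condition = condition, kind = kind,
               sirna_id = sid, viability = v, stringsAsFactors = FALSE)
  }
  scr <- rbind(
    row_block(au, "untreated", "active", id),
    row_block(at, "treated", "active", id),
    row_block(cu, "untreated", "control", NA_character_),
    row_block(ct, "treated", "control", NA_character_))
  structure(scr, class = c("screen_dataset", "data.frame"))
}

# Small default screen: 2 plates x 10 siRNA wells + 2 controls, fast to
# simulate and score in property loops.
small_design <- function(r = 3) {
  screen_design(n_plates = 2, wells_per_plate = 12,
                control_wells_per_plate = 2, sirna_wells_per_plate = 10,
                replicates_per_condition = r)
}

# Matching hit-count bounds for the 20-siRNA small design.
small_config <- function(...) {
  scenario_config(n_hit_low = 2, n_hit_high = 5, ...)
}

# Brute-force OLS oracle for the interaction test: fits both models with
# lm() and forms the scaled-deviance statistic independently of the
# package's closed-form group-sum path. Controls are the NS wells on the
# siRNA's own plate, as in the package's fit.
lm_oracle <- function(screen, id) {
  is_act <- screen$kind == "active" & !is.na(screen$sirna_id)
  plates <- unique(screen$plate[is_act & screen$sirna_id == id])
  keep <- (screen$kind == "control" & screen$plate %in% plates) |
    (is_act & screen$sirna_id == id)
  d <- screen[keep, ]
  d$x1 <- as.integer(d$condition == "treated")
  d$x2 <- as.integer(d$kind == "active")
  full <- stats::lm(viability ~ x1 * x2, data = d)
  red <- stats::lm(viability ~ x1, data = d)
  rss_full <- sum(stats::resid(full)^2)
  rss_red <- sum(stats::resid(red)^2)
  n <- nrow(d)
  stat <- (rss_red - rss_full) / (rss_full / (n - 4))
  list(stat = stat, p = stats::pchisq(stat, 2, lower.tail = FALSE),
       coef = stats::coef(full))
}
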