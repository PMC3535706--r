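test_that("cell summaries are plain means of the four well groups", {
  flat <- manual_screen(au = c(1, 1), at = c(1, 1), cu = c(1, 1),
                        ct = c(1, 1))
  expect_equal(summarize_cells(flat, "s0001"),
               list(Rc = 1, Rd = 1, Cc = 1, Cd = 1))

  scr <- manual_screen(au = c(0.9, 1.1), at = c(0.2, 0.4),
                       cu = c(1, 1), ct = c(0.5, 0.5))
  expect_equal(summarize_cells(scr, "s0001"),
               list(Rc = 1.0, Rd = 0.3, Cc = 1.0, Cd = 0.5))
  expect_error(summarize_cells(scr, "nope"), "unknown siRNA")
})

test_that("fold change is the log2 treated/untreated mean ratio", {
  eq <- manual_screen(au = c(1, 1.2), at = c(1, 1.2), cu = 1, ct = 1)
  expect_equal(fold_change(eq, "s0001")$statistic, 0)

  scr <- manual_screen(au = c(0.9, 1.1), at = c(0.2, 0.4), cu = 1, ct = 1)
  expect_equal(fold_change(scr, "s0001")$statistic, log2(0.3))

  # under the generative model with no noise, FC = log2(D) for every siRNA,
  # hit or not: the statistic carries no hit information
  cfg <- small_config(mu_nh = 1, sigma = 1e-12, d = 0.3, k = 1.1)
  scr0 <- simulate_screen(cfg, small_design(r = 2), seed = 12)
  sc <- score_all(scr0, methods = "fold_change")
  expect_equal(sc$statistic, rep(log2(0.3), nrow(sc)), tolerance = 1e-5)
})

test_that("t statistic matches the pooled two-sample form", {
  eq <- manual_screen(au = c(1, 2, 3), at = c(1, 2, 3), cu = 1, ct = 1)
  r <- t_statistic(eq, "s0001")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  scr <- manual_screen(au = c(2, 3, 4), at = c(1, 2, 3), cu = 1, ct = 1)
  r <- t_statistic(scr, "s0001")
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  # antisymmetry under swapping the treatment labels
  swapped <- manual_screen(au = c(1, 2, 3), at = c(2, 3, 4), cu = 1, ct = 1)
  r2 <- t_statistic(swapped, "s0001")
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
})

test_that("sensitivity index measures departure from multiplicative effects", {
  flat <- manual_screen(au = 1, at = 1, cu = 1, ct = 1)
  expect_equal(sensitivity_index(flat, "s0001")$statistic, 0)

  # multiplicative independence forces SI = 0
  null <- manual_screen(au = 0.8, at = 0.4, cu = 1, ct = 0.5)
  expect_equal(sensitivity_index(null, "s0001")$statistic, 0)

  sens <- manual_screen(au = 0.9, at = 0.2, cu = 1, ct = 0.5)
  r <- sensitivity_index(sens, "s0001")
  expect_equal(r$statistic, 0.25)
  expect_equal(r$direction, "sensitizing")
})

test_that("SI is centered at zero under the multiplicative null", {
  cfg <- scenario_config(mu_nh = 1, sigma = 0.05, d = 0.3, k = 1.1)
  scr <- simulate_screen(cfg, screen_design(replicates_per_condition = 3),
                         seed = 21)
  truth <- attr(scr, "truth")
  sc <- score_all(scr, methods = "si")
  nh <- sc$statistic[sc$sirna_id %in%
                       truth$sirna_id[truth$label == "non-hit"]]
  expect_lt(abs(mean(nh)), 4 * sd(nh) / sqrt(length(nh)))
})

test_that("interaction test matches a brute-force least-squares oracle", {
  # nested equality: active cells mirror control cells -> statistic 0
  mirror <- manual_screen(au = c(1.0, 1.2), at = c(0.5, 0.7),
                          cu = c(1.0, 1.2), ct = c(0.5, 0.7))
  r <- lm_interaction_test(mirror, "s0001")
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_equal(r$p_value, 1)

  hand <- manual_screen(au = c(1.0, 1.2), at = c(0.1, 0.3),
                        cu = c(1.0, 1.2), ct = c(0.5, 0.7))
  r <- lm_interaction_test(hand, "s0001")
  o <- lm_oracle(hand, "s0001")
  expect_equal(r$statistic, o$stat, tolerance = 1e-8)
  expect_equal(r$p_value, o$p, tolerance = 1e-8)
  expect_equal(unname(unlist(r[c("beta0", "beta1", "beta2", "beta3")])),
               unname(o$coef), tolerance = 1e-8)
  expect_equal(r$beta3, -0.4, tolerance = 1e-12)
  expect_equal(r$direction, "sensitizing")   # negative interaction

  # random screens: closed-form equals generic OLS for every siRNA
  set.seed(31)
  for (rep in 1:5) {
    scr <- simulate_screen(small_config(sigma = 0.4), small_design(),
                           seed = 100 + rep)
    sc <- score_all(scr, methods = "lm")
    for (id in sample(sc$sirna_id, 4)) {
      o <- lm_oracle(scr, id)
      expect_equal(sc$statistic[sc$sirna_id == id], o$stat,
                   tolerance = 1e-8)
    }
  }
})

test_that("F variant of the interaction test ranks identically", {
  scr <- simulate_screen(small_config(), small_design(), seed = 41)
  chisq <- score_all(scr, methods = "lm", lm_test = "chisq")
  f <- score_all(scr, methods = "lm", lm_test = "f")
  # both p-values are monotone decreasing in the shared statistic
  o <- order(chisq$statistic)
  expect_true(all(diff(chisq$p_value[o]) <= 1e-12))
  expect_true(all(diff(f$p_value[o]) <= 1e-12))
  expect_equal(chisq$statistic, f$statistic)  # same scaled deviance
})

test_that("wilcoxon p matches exact rank-sum enumeration", {
  ident <- manual_screen(au = c(1, 1, 1), at = c(1, 1, 1), cu = 1, ct = 1)
  expect_equal(wilcoxon_test(ident, "s0001")$p_value, 1)

  # treated {1,2} vs untreated {3,4}: enumerate all C(4,2) rank splits
  pooled_ranks <- rank(c(1, 2, 3, 4))
  obs_w <- sum(pooled_ranks[1:2]) - 2 * 3 / 2   # Mann-Whitney U of treated
  splits <- combn(4, 2)
  u_all <- apply(splits, 2, function(ix) sum(pooled_ranks[ix]) - 3)
  p_one_sided <- mean(u_all <= obs_w)
  expect_equal(p_one_sided, 1 / 6)

  scr <- manual_screen(au = c(3, 4), at = c(1, 2), cu = 1, ct = 1)
  r <- wilcoxon_test(scr, "s0001")
  expect_equal(r$p_value, 2 * p_one_sided)  # two-sided doubling
  expect_equal(r$direction, "sensitizing")

  swapped <- manual_screen(au = c(1, 2), at = c(3, 4), cu = 1, ct = 1)
  r2 <- wilcoxon_test(swapped, "s0001")
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
})

test_that("score_all covers every (siRNA, method) pair deterministically", {
  scr <- simulate_screen(scenario_config(), screen_design(), seed = 51)
  sc <- score_all(scr, methods = c("fold_change", "t_test", "si", "lm"))
  expect_equal(nrow(sc), 900 * 4)
  expect_true(all(table(sc$method) == 900))
  expect_true(all(!is.na(sc$p_value[sc$method %in% c("t_test", "lm")])))
  expect_true(all(is.na(sc$p_value[sc$method %in% c("fold_change", "si")])))

  empty <- score_all(scr, methods = character(0))
  expect_equal(nrow(empty), 0)

  expect_identical(sc, score_all(scr,
                                 methods = c("fold_change", "t_test",
                                             "si", "lm")))
  expect_error(score_all(scr, methods = "zscore"), "unknown method")
})

test_that("all statistics are invariant to a global rescaling", {
  scr <- simulate_screen(small_config(), small_design(), seed = 61)
  scaled <- scr
  scaled$viability <- scaled$viability * 3.7
  m <- c("fold_change", "t_test", "si", "lm", "wilcoxon")
  a <- score_all(scr, methods = m)
  b <- score_all(scaled, methods = m)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("degenerate inputs produce the documented sentinels", {
  # zero pooled variance, different means -> infinite t with p = 0
  det <- manual_screen(au = c(2, 2), at = c(1, 1), cu = 1, ct = 1)
  r <- t_statistic(det, "s0001")
  expect_equal(r$statistic, -Inf)
  expect_equal(r$p_value, 0)
  # missing design cell -> named singularity error
  scr <- manual_screen(au = 1:2, at = 1:2, cu = 1, ct = 1)
  scr <- scr[!(scr$kind == "control" & scr$condition == "treated"), ]
  expect_error(lm_interaction_test(scr, "s0001"), "control treated")
})

test_that("null p-values of the two-sample tests are calibrated", {
  # no drug effect, no control offset, no hits: every siRNA is null
  cfg <- scenario_config(sigma = 0.2, d = 0.999, k = 1,
                         n_hit_low = 0, n_hit_high = 0)
  des <- screen_design(replicates_per_condition = 6)
  p_t <- unlist(lapply(1:3, function(s) {
    scr <- simulate_screen(cfg, des, seed = 400 + s)
    score_all(scr, methods = "t_test")$p_value
  }))
  expect_gt(length(p_t), 2000)
  ks <- suppressWarnings(stats::ks.test(p_t, "punif"))
  expect_gt(ks$p.value, 0.01)

  # wilcoxon p is discrete (exact rank-sum lattice), so check calibration
  # as a super-uniform rejection rate instead of a KS distance
  scr <- simulate_screen(cfg, des, seed = 410)
  p_w <- score_all(scr, methods = "wilcoxon")$p_value
  rej <- mean(p_w <= 0.05)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / length(p_w)))
})
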