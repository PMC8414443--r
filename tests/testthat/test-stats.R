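# Mixed-model inference: fits, conservative df, EMMs, letters, pseudo-R2.

test_that("zero-variance data reproduce the generating means exactly", {
  eff <- speed_effects()
  ts <- simulate_trial_summary(eff, sd_individual = 0, sd_resid = 0,
                               variable = "speed", seed = 1)
  ts$value <- ts$value + rnorm(nrow(ts), 0, 1e-10)  # lme needs nonzero resid
  m <- swim_lmm(ts, "speed")
  emm <- m$emm_table[order(as.numeric(as.character(m$emm_table$viscosity))), ]
  expect_equal(emm$mean, eff$mean[order(eff$viscosity_cp)], tolerance = 1e-6)
})

test_that("a single individual cannot identify the random effect", {
  ts <- simulate_trial_summary(speed_effects(), seed = 1)
  expect_error(swim_lmm(ts[ts$individual == 1, ], "y"), "two individuals")
  expect_error(swim_lmm(ts, "nonexistent"), "not present")
})

test_that("conservative df reproduce the published design values", {
  des <- paper_design()
  expect_equal(anova_df_conservative(des),
               data.frame(term = "viscosity", df_num = 3, df_den = 29))
  des3 <- merge(des, data.frame(body_position = c("35-55", "55-75", "75-95")))
  df3 <- anova_df_conservative(des3, interaction = TRUE)
  expect_equal(df3$df_den[df3$term == "position"], 10)
  expect_equal(df3$df_num[df3$term == "position"], 2)
  expect_equal(df3$df_den[df3$term == "viscosity"], 114 - 18 - 9)
  # one grouping level reduces to classical ANOVA df: n - v
  one <- data.frame(individual = 1, viscosity_cp = rep(c(1, 5, 10, 40), 5))
  expect_equal(anova_df_conservative(one)$df_den, 20 - 1 - 3)
})

test_that("fitted F tables carry the same df as the counting rule", {
  ts <- simulate_trial_summary(speed_effects(), sd_individual = 0.05,
                               sd_resid = 0.1, variable = "speed", seed = 3)
  m <- swim_lmm(ts, "speed")
  expect_equal(m$f_table$df_num, 3)
  expect_equal(m$f_table$df_den, 29)
  eff <- wave_speed_effects()
  ts2 <- simulate_trial_summary(eff, sd_individual = 0.2,
                                sd_ind_position = 0.15, sd_resid = 0.3,
                                variable = "ws", seed = 3)
  m2 <- swim_lmm(ts2, "ws", interaction = "never")
  ft <- m2$f_table
  expect_equal(ft$df_den[ft$term == "position"], 10)
  rule <- anova_df_conservative(ts2[!is.na(ts2$value), ], interaction = FALSE)
  expect_equal(ft$df_den[match(rule$term, ft$term)], rule$df_den)
})

test_that("balanced EMMs equal cell means; log models back-transform", {
  eff <- speed_effects()
  des <- expand.grid(individual = 1:4, viscosity_cp = c(1, 5, 10, 40),
                     trial = 1:2)
  ts <- simulate_trial_summary(eff, design = des, sd_individual = 0.04,
                               sd_resid = 0.08, variable = "speed", seed = 6)
  m <- swim_lmm(ts, "speed")
  cellmeans <- aggregate(value ~ viscosity_cp, ts, mean)
  emm <- m$emm_table
  emm$viscosity_cp <- as.numeric(as.character(emm$viscosity))
  mm <- merge(emm, cellmeans)
  expect_equal(mm$mean, mm$value, tolerance = 1e-6)
  # log-scale fit recovers the geometric mean, SE reported as a factor
  effr <- data.frame(viscosity_cp = c(1, 5, 10, 40),
                     mean = log(c(11384, 1620, 953, 257)))
  tsr <- simulate_trial_summary(effr, sd_individual = 0.05, sd_resid = 0.1,
                                variable = "re", seed = 2)
  tsr$value <- exp(tsr$value)
  mr <- swim_lmm(tsr, "re", log_transform = TRUE)
  expect_true(all(c("mean", "se_factor") %in% names(mr$emm_table)))
  expect_equal(sort(mr$emm_table$mean, decreasing = TRUE)[1], 11384,
               tolerance = 0.15 * 11384)
  expect_true(all(mr$emm_table$se_factor > 1))
  expect_error(swim_lmm(transform(tsr, value = value - 1e6), "re",
                        log_transform = TRUE), "positive")
})

test_that("Bonferroni correction multiplies by the whole family size", {
  ts <- simulate_trial_summary(speed_effects(), sd_individual = 0.05,
                               sd_resid = 0.1, variable = "speed", seed = 3)
  m <- swim_lmm(ts, "speed")
  pb <- m$letters
  expect_equal(pb$m, choose(4, 2))
  expect_equal(pb$comparisons$p_adj,
               pmin(1, pb$m * pb$comparisons$p.value))
  ts2 <- simulate_trial_summary(wave_speed_effects(), sd_individual = 0.2,
                                sd_ind_position = 0.1, sd_resid = 0.3,
                                variable = "ws", seed = 5)
  m2 <- swim_lmm(ts2, "ws")
  # 3 positions x C(4,2) viscosity pairs + 4 viscosities x C(3,2)
  expect_equal(m2$letters$m, 3 * 6 + 4 * 3)
  expect_true(all(m2$letters$comparisons$p_adj >=
                    m2$letters$comparisons$p.value))
})

test_that("connecting letters follow insert-and-absorb", {
  cells <- c("g1", "g2", "g3")
  pairs <- rbind(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))
  # only pair (1,3) significant -> a, ab, b
  expect_equal(connecting_letters(cells, pairs, c(1, 0.01, 1),
                                  means = c(1, 2, 3)),
               c("a", "ab", "b"))
  # all pairs significant -> all distinct
  expect_equal(connecting_letters(cells, pairs, c(0.01, 0.01, 0.01),
                                  means = c(1, 2, 3)),
               c("a", "b", "c"))
  # nothing significant -> one shared letter
  expect_equal(connecting_letters(cells, pairs, c(1, 1, 1)),
               c("a", "a", "a"))
  # invariant to relabeling: permute cells and means together
  perm <- c(3, 1, 2)
  lt <- connecting_letters(cells[perm],
                           rbind(c("g1", "g2"), c("g1", "g3"), c("g2", "g3")),
                           c(1, 0.01, 1), means = c(1, 2, 3)[perm])
  expect_equal(lt[match(cells, cells[perm])], c("a", "ab", "b"))
})

test_that("letters in fitted models agree with their adjusted p-values", {
  ts2 <- simulate_trial_summary(wave_speed_effects(), sd_individual = 0.2,
                                sd_ind_position = 0.1, sd_resid = 0.3,
                                variable = "ws", seed = 5)
  m2 <- swim_lmm(ts2, "ws", heteroscedastic_by_position = TRUE)
  lt <- m2$letters$letters_by_position
  comp <- m2$letters$comparisons
  comp <- comp[comp$family == "viscosity_within_position", ]
  for (i in seq_len(nrow(comp))) {
    pr <- undulaflow:::parse_pairs(comp$contrast[i],
                                   unique(as.character(lt$viscosity)))
    la <- lt$letters[lt$position == comp$stratum[i] & lt$viscosity == pr[1]]
    lb <- lt$letters[lt$position == comp$stratum[i] & lt$viscosity == pr[2]]
    shares <- length(intersect(strsplit(la, "")[[1]],
                               strsplit(lb, "")[[1]])) > 0
    expect_equal(shares, comp$p_adj[i] >= 0.05)
  }
})

test_that("pseudo-R2 obeys its limiting cases and ordering", {
  eff <- speed_effects()
  ts <- simulate_trial_summary(eff, sd_individual = 1e-9, sd_resid = 1e-9,
                               variable = "speed", seed = 1)
  m <- swim_lmm(ts, "speed")
  expect_equal(unname(m$r2["r2_marginal"]), 1, tolerance = 1e-3)
  expect_equal(unname(m$r2["r2_conditional"]), 1, tolerance = 1e-3)
  flat <- data.frame(viscosity_cp = c(1, 5, 10, 40), mean = 1)
  ts0 <- simulate_trial_summary(flat, sd_individual = 0.1, sd_resid = 0.3,
                                variable = "flat", seed = 4)
  m0 <- swim_lmm(ts0, "flat")
  expect_lt(m0$r2["r2_marginal"], 0.1)
  for (seed in 1:5) {
    tsi <- simulate_trial_summary(eff, sd_individual = 0.07, sd_resid = 0.1,
                                  variable = "speed", seed = seed)
    mi <- swim_lmm(tsi, "speed")
    expect_lte(mi$r2["r2_marginal"], mi$r2["r2_conditional"])
    expect_lte(mi$r2["r2_conditional"], 1)
  }
})

test_that("pseudo-R2 tracks known variance shares", {
  # var_f of the generating means; random and residual chosen so that
  # R2m ~ 0.5 and R2c ~ 0.75 at large n
  eff <- data.frame(viscosity_cp = c(1, 5, 10, 40), mean = c(0, 1, 2, 3))
  var_f <- var(rep(eff$mean, each = 50))
  sd_i <- sqrt(var_f / 2)
  sd_e <- sqrt(var_f / 2)
  des <- expand.grid(individual = 1:10, viscosity_cp = c(1, 5, 10, 40),
                     trial = 1:5)
  r2s <- t(vapply(1:5, function(seed) {
    ts <- simulate_trial_summary(eff, design = des, sd_individual = sd_i,
                                 sd_resid = sd_e, variable = "v", seed = seed)
    swim_lmm(ts, "v")$r2
  }, numeric(2)))
  expect_equal(mean(r2s[, 1]), 0.5, tolerance = 0.07)
  expect_equal(mean(r2s[, 2]), 0.75, tolerance = 0.07)
})

test_that("fixed equal variance weights coincide with the unweighted fit", {
  ts2 <- simulate_trial_summary(wave_speed_effects(), sd_individual = 0.2,
                                sd_ind_position = 0.1, sd_resid = 0.3,
                                variable = "ws", seed = 8)
  d <- data.frame(individual = factor(ts2$individual),
                  viscosity = factor(ts2$viscosity_cp),
                  position = factor(ts2$body_position),
                  value = ts2$value)
  plain <- undulaflow:::fit_lme(value ~ viscosity + position, d,
                                ~ 1 | individual / position, NULL, "REML")
  w <- nlme::varIdent(form = ~ 1 | position,
                      fixed = c("55-75" = 1, "75-95" = 1))
  wfit <- undulaflow:::fit_lme(value ~ viscosity + position, d,
                               ~ 1 | individual / position, w, "REML")
  expect_equal(nlme::fixef(plain), nlme::fixef(wfit), tolerance = 1e-6)
})

test_that("heteroscedastic fits recover per-position residual spread", {
  eff <- wave_speed_effects()
  ts <- simulate_trial_summary(
    eff, sd_individual = 0.1, sd_ind_position = 0.05,
    sd_resid = c("35-55" = 0.1, "55-75" = 0.1, "75-95" = 0.5),
    variable = "ws", seed = 10)
  m <- swim_lmm(ts, "ws", heteroscedastic_by_position = TRUE,
                interaction = "never")
  strata <- m$variance_components$resid_sd_by_stratum
  expect_gt(strata[["75-95"]] / strata[["35-55"]], 2)
})

test_that("swim_lmm methods behave like a fitted model object", {
  ts <- simulate_trial_summary(speed_effects(), sd_individual = 0.05,
                               sd_resid = 0.1, variable = "speed", seed = 3)
  m <- swim_lmm(ts, "speed")
  expect_named(coef(m)[1], "(Intercept)")
  expect_equal(length(predict(m)), nrow(ts))
  expect_equal(length(residuals(m)), nrow(ts))
  expect_s3_class(anova(m), "data.frame")
  expect_output(print(m), "conservative df")
  expect_output(summary(m), "marginal means")
})
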