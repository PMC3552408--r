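# deterministic toy pair: biomass constant per origin so means are exact
toy_pair <- function(pair_id = "A-B", m_local = 1.173, m_foreign = 1,
                     n_fam = 5, blocks = 2, surv_local = 1, surv_foreign = 1) {
  grid <- expand.grid(family_pair = seq_len(n_fam), block = seq_len(blocks),
                      origin = c("local", "foreign"),
                      stringsAsFactors = FALSE)
  grid$row <- 1L; grid$column <- seq_len(nrow(grid))
  grid$seed_weight <- 0.0025
  is_local <- grid$origin == "local"
  grid$germinated <- TRUE
  grid$survived <- ifelse(is_local,
                          seq_len(nrow(grid)) %% 100 < 100 * surv_local,
                          seq_len(nrow(grid)) %% 100 < 100 * surv_foreign)
  grid$biomass <- ifelse(is_local, m_local, m_foreign)
  grid$inflorescences <- ifelse(is_local, 6L, 5L)
  pair_experiment(pair_id, "A", "B", distance_km = 10,
                  local_N = 1000, foreign_N = 500, pots = grid)
}

test_that("differentials compute the percentage difference with the stated sign convention", {
  expect_equal(differentials(toy_pair(m_local = 1, m_foreign = 1),
                             "biomass")$delta_pct, 0)
  # local 1.173 g vs foreign 1.000 g -> +17.3%
  d <- differentials(toy_pair(), "biomass")
  expect_equal(d$delta_pct, 17.3, tolerance = 1e-9)
  expect_false(d$absolute)
  expect_equal(d$log_dist_km, 1)
  expect_equal(d$log_local_N, 3)
})

test_that("swapping the denominator convention follows the exact algebra", {
  d_f <- differentials(toy_pair(), "biomass", denominator = "foreign")
  d_l <- differentials(toy_pair(), "biomass", denominator = "local")
  # local-denominator value equals 100*Delta/mean_local
  expect_equal(d_l$delta_pct,
               100 * (d_f$mean_local - d_f$mean_foreign) / d_f$mean_local)
  # and scale invariance: multiplying all biomass by c changes nothing
  p <- toy_pair(); p$pots$biomass <- p$pots$biomass * 7.3
  expect_equal(differentials(p, "biomass")$delta_pct, d_f$delta_pct)
})

test_that("zero foreign mean falls back to a flagged absolute difference", {
  p <- toy_pair(surv_foreign = 0)
  expect_warning(d <- differentials(p, "survival"), "absolute")
  expect_true(d$absolute)
  expect_equal(d$delta_pct, 1)  # proportions: 1 - 0
})

test_that("single-pair origin F equals the two-sample t^2 closed form", {
  set.seed(31)
  p <- toy_pair(n_fam = 6, blocks = 3)
  p$pots$biomass <- p$pots$biomass + rnorm(nrow(p$pots), 0, 0.05)
  ot <- origin_anova(list(p), "biomass", alpha = 0.05)
  fm <- tapply(ifelse(p$pots$survived, p$pots$biomass, NA),
               interaction(p$pots$family_pair, p$pots$origin),
               mean, na.rm = TRUE)
  grp <- rep(c("foreign", "local"), each = 6)[order(order(names(fm)))]
  tt <- t.test(fm[grepl("local", names(fm))], fm[grepl("foreign", names(fm))],
               var.equal = TRUE)
  expect_equal(ot$anova["origin", "F"], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("origin ANOVA F statistics match a brute-force sums-of-squares oracle", {
  set.seed(32)
  pairs <- lapply(c("A-B", "C-D", "E-F"), function(id) {
    p <- toy_pair(pair_id = id, n_fam = 4, blocks = 3)
    p$pots$biomass <- rlnorm(nrow(p$pots), 0, 0.3)
    p
  })
  ot <- origin_anova(pairs, "biomass")
  fm <- do.call(rbind, lapply(pairs, adaptdiff:::.family_means,
                              trait = "biomass"))
  orc <- oracle_twoway_anova(fm$y, factor(fm$origin), factor(fm$pair_id))
  expect_equal(ot$anova["origin", "F"], orc$F1, tolerance = 1e-9)
  expect_equal(ot$anova["pair", "F"], orc$F2, tolerance = 1e-9)
  expect_equal(ot$anova["origin_x_pair", "F"], orc$F12, tolerance = 1e-9)
})

test_that("empty origin cells are rejected by pair and origin name", {
  p <- toy_pair(pair_id = "A-B")
  p2 <- toy_pair(pair_id = "C-D")
  p2$pots <- p2$pots[p2$pots$origin == "local", ]
  expect_error(pair_experiment("C-D", "C", "D", 1, 10, 10, p2$pots),
               "unbalanced")
  # force past the constructor by removing a whole origin from family means
  expect_error(origin_anova(list(p, structure(p2, class = "pair_experiment")),
                            "biomass"), "C-D")
})

test_that("a planted origin effect is detected and the null keeps type-I error near alpha", {
  reps <- 120
  p_origin <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_pops = 8, n_pairs = 6, families_per_pair = 8,
                      blocks = 4, seed = 700 + i)
    pe <- gen_pair_experiment(cfg)
    p_origin[i] <- origin_anova(pe, "biomass")$anova["origin", "p"]
  }
  rate <- mean(p_origin < 0.034)
  se <- sqrt(0.034 * (1 - 0.034) / reps)
  expect_lt(rate, 0.034 + 3 * se + 0.01)
  # planted effect of ~1 within-family SD (0.3 on the log scale, i.e. +35%)
  # in 3 of 12 pairs at the full design scale -> interaction detected
  eff <- expm1(0.3)
  hits <- 0
  for (i in 1:40) {
    cfg <- sim_config(n_pairs = 12, families_per_pair = 15, blocks = 4,
                      seed = 900 + i,
                      adaptation_effects = list(`1` = list(biomass = eff),
                                                `2` = list(biomass = eff),
                                                `3` = list(biomass = eff)))
    pe <- gen_pair_experiment(cfg)
    ot <- origin_anova(pe, "biomass")
    hits <- hits + (ot$anova["origin_x_pair", "p"] < 0.034)
  }
  expect_gt(hits / 40, 0.8)
})

test_that("stepwise selection recovers an exact single predictor with r2 = 1", {
  set.seed(33)
  rec <- data.frame(delta_pct = 0, log_local_N = rnorm(10),
                    log_foreign_N = rnorm(10), log_dist_km = rnorm(10),
                    env_dist = rnorm(10), qst = runif(10), fst = runif(10))
  rec$delta_pct <- rec$qst
  sw <- suppressWarnings(stepwise_predict(rec))  # lm warns on perfect fit
  expect_identical(sw$selected, "qst")
  expect_equal(sw$r2, 1)
})

test_that("with max_terms = 6 stepwise converges to at most the full OLS fit", {
  set.seed(34)
  n <- 40
  rec <- data.frame(log_local_N = rnorm(n), log_foreign_N = rnorm(n),
                    log_dist_km = rnorm(n), env_dist = rnorm(n),
                    qst = runif(n), fst = runif(n))
  rec$delta_pct <- 2 * rec$log_local_N - 3 * rec$qst + rnorm(n, 0, 0.01)
  sw <- stepwise_predict(rec, max_terms = 6)
  full <- lm(delta_pct ~ log_local_N + log_foreign_N + log_dist_km +
               env_dist + qst + fst, data = rec)
  expect_lte(sw$r2, summary(full)$r.squared + 1e-12)
  expect_true(all(c("log_local_N", "qst") %in% sw$selected))
  # forward AIC agrees with stats::step on the same data
  ref <- step(lm(delta_pct ~ 1, data = rec), direction = "forward",
              scope = formula(full), trace = 0)
  expect_setequal(sw$selected, setdiff(names(coef(ref)), "(Intercept)"))
})

test_that("collinear candidate predictors are refused with a warning", {
  set.seed(35)
  rec <- data.frame(log_local_N = rnorm(10))
  rec$log_foreign_N <- 2 * rec$log_local_N + 1  # exact collinearity
  rec$delta_pct <- rec$log_local_N + rnorm(10, 0, 0.01)
  expect_warning(sw <- stepwise_predict(rec, max_terms = 2), "collinear")
  expect_identical(sw$selected, "log_local_N")
})

test_that("data generated from the planted plane are recovered by stepwise regression", {
  set.seed(36)
  x <- runif(12, 2, 5)       # log10 local population size
  y <- runif(12, 0.05, 0.6)  # pairwise Q_ST
  rec <- data.frame(delta_pct = -20.03 + 4.17 * x + 68.2 * y + rnorm(12, 0, 1),
                    log_local_N = x, log_foreign_N = runif(12, 2, 5),
                    log_dist_km = runif(12, 0, 2.8), env_dist = runif(12),
                    qst = y, fst = runif(12, 0, 0.1))
  sw <- stepwise_predict(rec)
  expect_setequal(sw$selected, c("log_local_N", "qst"))
  est <- sw$coefficients; se <- sw$se
  expect_lt(abs(est[["log_local_N"]] - 4.17), 2 * se[["log_local_N"]])
  expect_lt(abs(est[["qst"]] - 68.2), 2 * se[["qst"]])
  expect_true(sw$significant)
})
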