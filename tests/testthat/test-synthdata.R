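test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_pops = 5, fams_per_pop = 6, obs_per_fam = 2,
                    n_pairs = 3, families_per_pair = 4, seed = 42)
  expect_identical(gen_traits(cfg), gen_traits(cfg))
  expect_identical(gen_genotypes(cfg), gen_genotypes(cfg))
  expect_identical(gen_environment(cfg), gen_environment(cfg))
  expect_identical(gen_pair_experiment(cfg), gen_pair_experiment(cfg))
  cfg2 <- sim_config(n_pops = 5, fams_per_pop = 6, obs_per_fam = 2,
                     n_pairs = 3, families_per_pair = 4, seed = 43)
  expect_false(identical(gen_traits(cfg), gen_traits(cfg2)))
  # generators do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_traits(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the default transplant design produces the full factorial of pots", {
  pe <- gen_pair_experiment(sim_config(seed = 2))
  expect_length(pe, 12L)
  expect_identical(sum(vapply(pe, function(p) nrow(p$pots), 0L)), 1440L)
  for (p in pe[1:3]) {
    tab <- table(p$pots$family_pair, p$pots$block, p$pots$origin)
    expect_true(all(tab == 1L))
  }
})

test_that("trait truth records carry the implied Q_ST under each variant", {
  cfg <- sim_config(n_pops = 4, fams_per_pop = 5, obs_per_fam = 2,
                    trait_specs = list(t = list(V_B = 0, V_fam = 0.2,
                                                V_res = 0.8, h2_true = 0.5)),
                    seed = 3)
  tr <- attr(gen_traits(cfg), "truth")$t
  expect_equal(tr$qst_true$heritability_scaled, 0)
  # V_B chosen so that truth is exactly 1/3 under the default formula
  cfg2 <- sim_config(n_pops = 4, fams_per_pop = 5, obs_per_fam = 2,
                     trait_specs = list(t = list(V_B = 1, V_fam = 0.25,
                                                 V_res = 0.75, h2_true = 1)),
                     seed = 3)
  tr2 <- attr(gen_traits(cfg2), "truth")$t
  expect_equal(tr2$qst_true$heritability_scaled, 1 / 3)
})

test_that("population-mean variance follows the law of total variance", {
  # var of a population mean = V_B + V_fam/f + V_res/(f*o)
  f <- 6; o <- 3
  V_B <- 0.5; V_fam <- 0.3; V_res <- 0.9
  reps <- 400
  pm <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_pops = 2, fams_per_pop = f, obs_per_fam = o,
                      trait_specs = list(t = list(V_B = V_B, V_fam = V_fam,
                                                  V_res = V_res,
                                                  h2_true = 0.5)),
                      seed = 1000 + i)
    tt <- gen_traits(cfg)
    pm[i] <- mean(tt$t[tt$population == "P01"])
  }
  expected <- V_B + V_fam / f + V_res / (f * o)
  # chi-square CI for a variance estimated from `reps` draws
  ci <- expected * c(qchisq(0.005, reps - 1), qchisq(0.995, reps - 1)) / (reps - 1)
  expect_gt(var(pm), ci[1])
  expect_lt(var(pm), ci[2])
})

test_that("Balding-Nichols genotypes approach panmixia as F -> 0 and track the oracle", {
  cfg0 <- sim_config(n_pops = 4, fams_per_pop = 40, n_loci = 12,
                     bn_F = 1e-6, seed = 6)
  g0 <- gen_genotypes(cfg0)
  th0 <- mean(dist_values(fst_matrix(g0)))
  expect_lt(abs(th0), 0.01)
  # oracle truth is near zero too
  expect_lt(max(attr(g0, "truth")$pairwise_fst), 1e-3)
  # strong divergence: estimates bracket the frequency-level oracle
  diffs <- vapply(1:30, function(s) {
    cfg <- sim_config(n_pops = 2, fams_per_pop = 25, n_loci = 10,
                      alleles_per_locus = 2, bn_F = 0.5, seed = 4000 + s)
    g <- gen_genotypes(cfg)
    fst_pair(g, "P01", "P02") - attr(g, "truth")$pairwise_fst["P01", "P02"]
  }, 0)
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.01)
})

test_that("forcing identical population frequencies gives theta near zero regardless of F", {
  cfg <- sim_config(n_pops = 2, fams_per_pop = 60, n_loci = 10, bn_F = 0.4,
                    seed = 7)
  g <- gen_genotypes(cfg)
  # rebuild pop 2 as a fresh sample from pop 1's realized frequencies
  freqs <- attr(g, "truth")$freqs
  set.seed(8)
  idx2 <- g$population == "P02"
  for (l in seq_along(freqs)) {
    p1 <- freqs[[l]]["P01", ]
    g$a1[idx2, l] <- sample.int(length(p1), sum(idx2), TRUE, p1)
    g$a2[idx2, l] <- sample.int(length(p1), sum(idx2), TRUE, p1)
  }
  expect_lt(abs(fst_pair(g, "P01", "P02")), 0.03)
})

test_that("environment generator separates climate zones but keeps soils a mosaic", {
  cfg <- sim_config(n_pops = 14, climate_zone_split = 0.5, seed = 9)
  env <- gen_environment(cfg)
  zone <- attr(env, "truth")$zone
  clim <- as.data.frame(env)[grep("^clim", env_variables(env), value = TRUE)]
  # a 2-SD zone shift puts the expected between-zone R^2 near 0.5 per variable
  r2 <- vapply(clim, function(v) summary(lm(v ~ zone))$r.squared, 0)
  expect_gt(mean(r2), 0.35)
  # with no zone effect mean R^2 collapses to the chance level ~1/(n-2)
  env0 <- gen_environment(cfg, zone_effect = 0)
  clim0 <- as.data.frame(env0)[grep("^clim", env_variables(env0),
                                    value = TRUE)]
  r20 <- vapply(clim0, function(v) summary(lm(v ~ zone))$r.squared, 0)
  expect_lt(mean(r20), 0.25)
  # geographic vs soil distance: no isolation-by-distance for the mosaic
  rs <- vapply(1:25, function(s) {
    e <- gen_environment(sim_config(n_pops = 10, seed = 100 + s))
    soil <- ordinate(e, grep("^soil", env_variables(e), value = TRUE),
                     retain = 2)
    mantel(geographic_distances(e), env_distance(soil, "soil"),
           n_perm = 99, seed = s)$r
  }, 0)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)
})

test_that("a planted biomass advantage is recovered in the differential", {
  deltas <- vapply(1:60, function(s) {
    cfg <- sim_config(n_pops = 4, n_pairs = 1, families_per_pair = 15,
                      blocks = 4, seed = 2000 + s,
                      adaptation_effects = list(`1` = list(biomass = 0.10)))
    pe <- gen_pair_experiment(cfg)
    differentials(pe[[1]], "biomass")$delta_pct
  }, 0)
  expect_lt(abs(mean(deltas) - 10), 3 * sd(deltas) / sqrt(length(deltas)))
  # and the all-null configuration is centred on zero
  nulls <- vapply(1:60, function(s) {
    cfg <- sim_config(n_pops = 4, n_pairs = 1, families_per_pair = 15,
                      blocks = 4, seed = 3000 + s)
    differentials(gen_pair_experiment(cfg)[[1]], "biomass")$delta_pct
  }, 0)
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(length(nulls)))
})
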