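test_that("diversity matches hand computations", {
  # every individual heterozygous 1/2, n = 10: H_O = 1, p = 0.5,
  # H_E = (20/19)*0.5, A_e = 2, F_IS = 1 - H_O/H_E
  g <- toy_genotypes(rep("a", 10), L1 = rep("1/2", 10))
  d <- diversity(g)
  expect_equal(d$H_O, 1)
  expect_equal(d$H_E, (20 / 19) * 0.5)
  expect_equal(d$A_e, 2)
  expect_equal(d$F_IS, 1 - 1 / ((20 / 19) * 0.5))
  # monomorphic locus: H_O = H_E = 0, A_e = 1, F_IS undefined
  g0 <- toy_genotypes(rep("a", 5), L1 = rep("3/3", 5))
  d0 <- diversity(g0)
  expect_equal(d0$H_O, 0)
  expect_equal(d0$H_E, 0)
  expect_equal(d0$A_e, 1)
  expect_true(is.na(d0$F_IS))
})

test_that("duplicating individuals preserves H_O and A_e and rescales only the bias factor", {
  g <- toy_genotypes(rep("a", 4), L1 = c("1/2", "1/1", "2/2", "1/2"))
  g2 <- toy_genotypes(rep("a", 8), L1 = rep(c("1/2", "1/1", "2/2", "1/2"), 2))
  d <- diversity(g); d2 <- diversity(g2)
  expect_equal(d$H_O, d2$H_O)
  expect_equal(d$A_e, d2$A_e)
  p2 <- sum(c(0.5, 0.5)^2)
  expect_equal(d2$H_E, (16 / 15) * (1 - p2))
})

test_that("theta hits the fixation and null anchors", {
  fixed <- toy_genotypes(rep(c("a", "b"), each = 20),
                         L1 = c(rep("1/1", 20), rep("2/2", 20)))
  expect_equal(fst_pair(fixed, "a", "b"), 1)
  # identical large samples from one frequency vector: theta near 0
  set.seed(4)
  geno <- replicate(200, paste(sample(1:2, 2, TRUE, c(0.6, 0.4)),
                               collapse = "/"))
  same <- toy_genotypes(rep(c("a", "b"), each = 100),
                        L1 = c(geno[1:100], geno[1:100]))
  expect_lt(abs(fst_pair(same, "a", "b")), 0.02)
})

test_that("theta equals the brute-force Weir-Cockerham oracle on printed toy tables", {
  # 2 pops x 5 individuals x 1 biallelic locus
  l1 <- c("1/1", "1/2", "1/2", "2/2", "1/1", "2/2", "2/2", "1/2", "2/2", "2/2")
  g <- toy_genotypes(rep(c("a", "b"), each = 5), L1 = l1)
  orc <- oracle_wc_theta(data.frame(pop = rep(c("a", "b"), each = 5),
                                    a1 = g$a1[, 1], a2 = g$a2[, 1]))
  expect_equal(fst_pair(g, "a", "b"), orc, tolerance = 1e-12)
  # multi-allelic, missing data, two loci
  g2 <- toy_genotypes(rep(c("a", "b"), each = 6),
                      L1 = c("1/3", "2/3", "1/1", "", "3/3", "1/2",
                             "2/2", "2/3", "3/3", "2/2", "", "3/3"),
                      L2 = c("1/2", "1/1", "1/2", "2/2", "1/1", "1/2",
                             "1/2", "2/2", "2/2", "1/2", "2/2", "2/2"))
  orc2 <- oracle_wc_theta(list(
    data.frame(pop = g2$population, a1 = g2$a1[, 1], a2 = g2$a2[, 1]),
    data.frame(pop = g2$population, a1 = g2$a1[, 2], a2 = g2$a2[, 2])))
  expect_equal(fst_pair(g2, "a", "b"), orc2, tolerance = 1e-12)
})

test_that("multi-locus theta is the ratio of sums, not the mean of per-locus ratios", {
  g <- toy_genotypes(rep(c("a", "b"), each = 6),
                     L1 = c(rep("1/1", 6), rep("2/2", 6)),          # theta = 1
                     L2 = c("1/2", "1/1", "1/2", "2/2", "1/2", "1/1",
                            "1/2", "2/2", "1/2", "1/1", "1/2", "2/2"))
  per_locus <- vapply(1:2, function(j) {
    gg <- genotype_table(g$individual, g$population,
                         g$a1[, j, drop = FALSE], g$a2[, j, drop = FALSE])
    fst_pair(gg, "a", "b")
  }, 0)
  combined <- fst_pair(g, "a", "b")
  expect_false(isTRUE(all.equal(combined, mean(per_locus))))
  orc <- oracle_wc_theta(list(
    data.frame(pop = g$population, a1 = g$a1[, 1], a2 = g$a2[, 1]),
    data.frame(pop = g$population, a1 = g$a1[, 2], a2 = g$a2[, 2])))
  expect_equal(combined, orc, tolerance = 1e-12)
})

test_that("theta is invariant to allele relabelling and individual order", {
  cfg <- sim_config(n_pops = 2, fams_per_pop = 12, n_loci = 4, seed = 9)
  g <- gen_genotypes(cfg)
  th <- fst_pair(g, "P01", "P02")
  # relabel alleles (bijection) per locus
  relab <- genotype_table(g$individual, g$population,
                          7L - g$a1, 7L - g$a2)
  expect_equal(fst_pair(relab, "P01", "P02"), th, tolerance = 1e-12)
  set.seed(2)
  ord <- sample(seq_along(g$individual))
  shuf <- genotype_table(g$individual[ord], g$population[ord],
                         g$a1[ord, ], g$a2[ord, ])
  expect_equal(fst_pair(shuf, "P01", "P02"), th, tolerance = 1e-12)
})

test_that("fst_matrix covers all unordered pairs and propagates errors", {
  cfg <- sim_config(n_pops = 5, fams_per_pop = 10, n_loci = 5, seed = 21)
  m <- fst_matrix(gen_genotypes(cfg))
  expect_length(dist_values(m), 10L)
  mono <- toy_genotypes(rep(c("a", "b"), each = 3),
                        L1 = rep("1/1", 6))
  expect_error(fst_matrix(mono), "co-polymorphic")
})

test_that("mean theta increases with the Balding-Nichols divergence parameter", {
  mean_theta <- function(F) {
    mean(vapply(1:12, function(s) {
      cfg <- sim_config(n_pops = 2, fams_per_pop = 25, n_loci = 10,
                        bn_F = F, seed = 300 + s)
      fst_pair(gen_genotypes(cfg), "P01", "P02")
    }, 0))
  }
  th <- vapply(c(0.01, 0.05, 0.15), mean_theta, 0)
  expect_true(all(diff(th) > 0))
})

test_that("linearization applies F/(1-F) elementwise and rejects F = 1", {
  m <- dist_matrix(matrix(c(0, 0.09, 0.09, 0), 2), c("a", "b"), "fst")
  lm_ <- linearize_fst(m)
  expect_equal(lm_["a", "b"], 0.09 / 0.91)
  expect_equal(linearize_fst(dist_matrix(matrix(c(0, 0.5, 0.5, 0), 2),
                                         c("a", "b"), "fst"))["a", "b"], 1)
  neg <- dist_matrix(matrix(c(0, -0.02, -0.02, 0), 2), c("a", "b"), "fst")
  expect_equal(linearize_fst(neg)["a", "b"], -0.02 / 1.02)
  one <- dist_matrix(matrix(c(0, 1, 1, 0), 2), c("a", "b"), "fst")
  expect_error(linearize_fst(one), "a-b")
})

test_that("delta-K reproduces the hand-computed curvature table", {
  mk <- function(mu, sd_target) c(mu - sd_target / sqrt(2), mu + sd_target / sqrt(2))
  trace <- data.frame(K = rep(1:4, each = 2), replicate = rep(1:2, 4),
                      lnL = c(mk(-500, 2), mk(-400, 2), mk(-390, 2),
                              mk(-388, 2)))
  dk <- delta_k(trace)
  expect_equal(dk$table$delta_k[2], 45)  # |-390 + 800 - 500| / 2
  expect_equal(dk$table$delta_k[3], 4)   # |-388 + 780 - 400| / 2
  expect_identical(dk$best_k, 2L)
  expect_false(dk$ambiguous)
  # replicate order is irrelevant
  dk2 <- delta_k(trace[rev(seq_len(nrow(trace))), ])
  expect_equal(dk2$table, dk$table)
})

test_that("linear lnL in K gives zero curvature flagged ambiguous", {
  set.seed(8)
  trace <- data.frame(K = rep(1:5, each = 3), replicate = rep(1:3, 5))
  base <- -100 * trace$K
  noise <- rep(c(-1, 0, 1), 5)  # same within-K spread, exact linear means
  trace$lnL <- base + noise
  dk <- delta_k(trace)
  expect_true(all(dk$table$delta_k[2:4] == 0))
  expect_true(dk$ambiguous)
  expect_error(delta_k(data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                                  lnL = c(0, 0, -1, -1, -2, -2))), "sd")
})
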