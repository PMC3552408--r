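# Independent brute-force oracles used to cross-check the package's
# estimators. These deliberately re-derive everything from first principles
# with plain loops; they never call the implementation they check.

# Weir-Cockerham theta for a genotype table given as a data frame with
# columns pop, a1, a2 (single locus) or a list of such per locus.
oracle_wc_theta <- function(loci) {
  if (is.data.frame(loci)) loci <- list(loci)
  num <- 0; den <- 0
  for (tab in loci) {
    tab <- tab[!is.na(tab$a1) & !is.na(tab$a2), ]
    pops <- unique(tab$pop)
    r <- length(pops)
    n_i <- sapply(pops, function(p) sum(tab$pop == p))
    if (any(n_i == 0)) next
    alleles <- unique(c(tab$a1, tab$a2))
    if (length(alleles) < 2) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        sub <- tab[tab$pop == pops[k], ]
        p_i[k] <- (sum(sub$a1 == al) + sum(sub$a2 == al)) / (2 * nrow(sub))
        h_i[k] <- mean(sub$a1 != sub$a2 & (sub$a1 == al | sub$a2 == al))
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

# Balanced nested ANOVA variance components solved from the explicit EMS
# linear system (a pops x f fams x n obs, fully balanced only).
oracle_balanced_components <- function(y, pop, fam) {
  pops <- unique(pop)
  a <- length(pops)
  fams <- unique(paste(pop, fam))
  f <- length(fams) / a
  n <- length(y) / (a * f)
  stopifnot(n == round(n))
  grand <- mean(y)
  ss_pop <- 0; ss_fam <- 0; ss_res <- 0
  for (p in pops) {
    yp <- y[pop == p]
    ss_pop <- ss_pop + length(yp) * (mean(yp) - grand)^2
    for (fm in unique(fam[pop == p])) {
      yf <- y[pop == p & fam == fm]
      ss_fam <- ss_fam + length(yf) * (mean(yf) - mean(yp))^2
      ss_res <- ss_res + sum((yf - mean(yf))^2)
    }
  }
  ms <- c(ss_pop / (a - 1), ss_fam / (a * (f - 1)), ss_res / (a * f * (n - 1)))
  # E[MS] = C %*% (Vpop, Vfam, Vres)
  C <- rbind(c(n * f, n, 1), c(0, n, 1), c(0, 0, 1))
  sol <- solve(C, ms)
  c(V_B = sol[1], V_fam = sol[2], V_res = sol[3])
}

# All permutations of 1..n (n small), for exact Mantel enumeration.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}

# Exact Mantel p by full enumeration (two-tailed), identity included.
mantel_exact_p <- function(a, b) {
  ut <- upper.tri(a)
  x <- a[ut]
  r_obs <- cor(x, b[ut])
  rs <- vapply(all_perms(nrow(a)), function(p) cor(x, b[p, p][ut]), 0)
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Two-way fixed-effects ANOVA sums of squares by explicit cell means
# (balanced origin x pair layout).
oracle_twoway_anova <- function(y, f1, f2) {
  grand <- mean(y)
  n <- length(y)
  m1 <- tapply(y, f1, mean); n1 <- tapply(y, f1, length)
  m2 <- tapply(y, f2, mean); n2 <- tapply(y, f2, length)
  mc <- tapply(y, interaction(f1, f2), mean)
  nc <- tapply(y, interaction(f1, f2), length)
  ss1 <- sum(n1 * (m1 - grand)^2)
  ss2 <- sum(n2 * (m2 - grand)^2)
  sscells <- sum(nc * (mc - grand)^2)
  ss12 <- sscells - ss1 - ss2
  sse <- sum((y - mc[interaction(f1, f2)])^2)
  df1 <- length(m1) - 1; df2 <- length(m2) - 1; df12 <- df1 * df2
  dfe <- n - length(mc)
  list(F1 = (ss1 / df1) / (sse / dfe),
       F2 = (ss2 / df2) / (sse / dfe),
       F12 = (ss12 / df12) / (sse / dfe),
       mse = sse / dfe, dfe = dfe)
}

# Small toy genotype table builder: geno strings like "1/2", "" = missing.
toy_genotypes <- function(pop, ...) {
  loci <- list(...)
  n <- length(pop)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    sp <- strsplit(loci[[j]], "/", fixed = TRUE)
    for (i in seq_len(n))
      if (length(sp[[i]]) == 2) {
        a1[i, j] <- as.integer(sp[[i]][1])
        a2[i, j] <- as.integer(sp[[i]][2])
      }
  }
  colnames(a1) <- colnames(a2) <- names(loci) %||% paste0("L", seq_along(loci))
  genotype_table(paste0("i", seq_len(n)), pop, a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced family-structured trait data with known components.
toy_traits <- function(n_pops, n_fams, n_obs, V_B, V_fam, V_res, seed,
                       mu = 10) {
  set.seed(seed)
  pop <- rep(sprintf("P%02d", 1:n_pops), each = n_fams * n_obs)
  fam <- rep(rep(sprintf("F%02d", 1:n_fams), each = n_obs), n_pops)
  pe <- rnorm(n_pops, 0, sqrt(V_B))[rep(1:n_pops, each = n_fams * n_obs)]
  fe <- rnorm(n_pops * n_fams, 0, sqrt(V_fam))[
    rep(1:(n_pops * n_fams), each = n_obs)]
  y <- mu + pe + fe + rnorm(length(pop), 0, sqrt(V_res))
  trait_table(data.frame(individual = seq_along(pop), population = pop,
                         family = fam, y = y), traits = "y")
}
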