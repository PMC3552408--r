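## Per-locus allele bookkeeping for one set of individuals: returns allele
## counts, heterozygote-carriage counts and sample size (typed individuals).
.locus_tallies <- function(a1, a2) {
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n == 0L)
    return(list(n = 0L, alleles = integer(0), p = numeric(0), h = numeric(0)))
  al <- sort(unique(c(a1[ok], a2[ok])))
  cnt <- vapply(al, function(a) sum(a1[ok] == a) + sum(a2[ok] == a), 0)
  het <- a1[ok] != a2[ok]
  # h[a]: fraction of individuals heterozygous *for* allele a
  h <- vapply(al, function(a)
    mean(het & (a1[ok] == a | a2[ok] == a)), 0)
  list(n = n, alleles = al, p = cnt / (2 * n), h = h)
}

#' Per-population marker diversity
#'
#' Per locus and population: observed heterozygosity `H_O` (fraction of
#' heterozygous individuals), Nei's unbiased expected heterozygosity
#' `H_E = (2n/(2n-1)) (1 - sum p^2)`, effective allele number
#' `A_e = 1 / sum p^2`, and the inbreeding coefficient `F_IS = 1 - H_O/H_E`
#' (undefined at monomorphic loci and excluded from the average). Values are
#' averaged over loci with data.
#'
#' @param g a [genotype_table()].
#' @return data frame, one row per population, columns
#'   `population, n, H_O, H_E, A_e, F_IS`.
#' @export
diversity <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  pops <- unique(g$population)
  out <- lapply(pops, function(p) {
    idx <- g$population == p
    if (!any(idx)) stop_adaptdiff("empty population: ", p)
    ho <- he <- ae <- fis <- numeric(0)
    for (j in seq_len(ncol(g$a1))) {
      t <- .locus_tallies(g$a1[idx, j], g$a2[idx, j])
      if (t$n == 0L) next
      sp2 <- sum(t$p^2)
      ho_j <- mean(g$a1[idx, j][!is.na(g$a1[idx, j])] !=
                   g$a2[idx, j][!is.na(g$a2[idx, j])])
      he_j <- (2 * t$n / (2 * t$n - 1)) * (1 - sp2)
      ho <- c(ho, ho_j); he <- c(he, he_j); ae <- c(ae, 1 / sp2)
      if (he_j > 0) fis <- c(fis, 1 - ho_j / he_j)
    }
    data.frame(population = p, n = sum(idx),
               H_O = mean(ho), H_E = mean(he), A_e = mean(ae),
               F_IS = if (length(fis)) mean(fis) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Weir & Cockerham (1984) per-allele variance components a, b, c for one
## locus across r populations. pops: list of (a1, a2) vectors.
.wc_components <- function(col1, col2, pop) {
  pops <- unique(pop)
  r <- length(pops)
  tal <- lapply(pops, function(p) .locus_tallies(col1[pop == p], col2[pop == p]))
  n_i <- vapply(tal, `[[`, 0L, "n")
  if (any(n_i == 0L)) return(NULL)          # locus untyped in some population
  alleles <- sort(unique(unlist(lapply(tal, `[[`, "alleles"))))
  if (length(alleles) < 2L) return(NULL)    # monomorphic across the set
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- vapply(tal, function(t) {
      k <- match(al, t$alleles); if (is.na(k)) 0 else t$p[k]
    }, 0)
    h_i <- vapply(tal, function(t) {
      k <- match(al, t$alleles); if (is.na(k)) 0 else t$h[k]
    }, 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Pairwise F_ST (Weir-Cockerham theta)
#'
#' Multi-allelic Weir & Cockerham (1984) theta between two populations,
#' combined over loci as the ratio of summed variance components
#' (sum a / sum (a+b+c)), not as a mean of per-locus ratios. Missing
#' genotypes are excluded per locus; loci monomorphic across the pair (or
#' untyped in either population) contribute nothing. The estimator may be
#' slightly negative.
#'
#' @param g a [genotype_table()].
#' @param pop_a,pop_b population labels.
#' @return theta (numeric scalar).
#' @export
fst_pair <- function(g, pop_a, pop_b) {
  sub <- subset_populations(g, c(pop_a, pop_b))
  num <- den <- 0
  used <- 0L
  for (j in seq_len(ncol(sub$a1))) {
    comp <- .wc_components(sub$a1[, j], sub$a2[, j], sub$population)
    if (is.null(comp)) next
    num <- num + comp["a"]
    den <- den + sum(comp)
    used <- used + 1L
  }
  if (used == 0L || den == 0)
    stop_adaptdiff("theta undefined for pair ", pop_a, "-", pop_b,
                   ": no co-polymorphic locus with data in both populations")
  unname(num / den)
}

#' All pairwise theta values as a distance matrix
#'
#' @inheritParams fst_pair
#' @return a `dist_matrix` of kind `"fst"`; P populations give P(P-1)/2
#'   distinct entries.
#' @export
fst_matrix <- function(g) {
  pops <- sort(unique(g$population))
  if (length(pops) < 2L) stop_adaptdiff("need >= 2 populations")
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  pairs <- .pop_pairs(pops)
  for (k in seq_len(nrow(pairs))) {
    th <- fst_pair(g, pairs$a[k], pairs$b[k])
    m[pairs$a[k], pairs$b[k]] <- m[pairs$b[k], pairs$a[k]] <- th
  }
  dist_matrix(m, pops, "fst")
}

#' Rousset linearization F_ST / (1 - F_ST)
#'
#' Elementwise monotone transform used for isolation-by-distance comparisons
#' against geographic distance. Negative estimates pass through.
#'
#' @param m a `dist_matrix` (kind `"fst"`).
#' @return a `dist_matrix` of kind `"custom"`.
#' @export
linearize_fst <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  ones <- which(m == 1 & upper.tri(m), arr.ind = TRUE)
  if (nrow(ones))
    stop_adaptdiff("F_ST = 1 for pair ", rownames(m)[ones[1L, 1L]], "-",
                   colnames(m)[ones[1L, 2L]], ": linearized value infinite")
  if (any(m > 1)) stop_adaptdiff("F_ST values must be < 1")
  dist_matrix(m / (1 - m), rownames(m), "custom")
}

#' Evanno's delta-K from clustering log-likelihood traces
#'
#' Given replicate log-likelihoods `lnL` of a genetic clustering model at
#' successive K, computes
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`
#' (sample sd over replicates) for interior K, and picks `best_k` as its
#' argmax. When the curvature is zero everywhere (lnL linear in K) the choice
#' is flagged ambiguous.
#'
#' @param trace data frame with columns `K`, `replicate`, `lnL`.
#' @return list of class `delta_k`: `table` (per-K means, sds, delta_k),
#'   `best_k`, `ambiguous`.
#' @export
delta_k <- function(trace) {
  need <- c("K", "replicate", "lnL")
  if (!all(need %in% names(trace)))
    stop_adaptdiff("trace needs columns K, replicate, lnL")
  ks <- sort(unique(trace$K))
  if (length(ks) < 3L || any(diff(ks) != 1L))
    stop_adaptdiff("need >= 3 consecutive K values")
  reps <- tapply(trace$lnL, trace$K, length)
  if (any(reps < 2L))
    stop_adaptdiff("need >= 2 replicates at every K")
  mu <- tapply(trace$lnL, trace$K, mean)[as.character(ks)]
  sdv <- tapply(trace$lnL, trace$K, stats::sd)[as.character(ks)]
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2L, length(ks) - 1L)) {
    if (sdv[i] == 0)
      stop_adaptdiff("sd(lnL) = 0 at K = ", ks[i], "; delta-K undefined")
    dk[i] <- abs(mu[i + 1L] - 2 * mu[i] + mu[i - 1L]) / sdv[i]
  }
  interior <- which(!is.na(dk))
  best <- ks[interior[which.max(dk[interior])]]
  ambiguous <- max(dk[interior]) == 0 ||
    sum(dk[interior] == max(dk[interior])) > 1L
  structure(list(
    table = data.frame(K = ks, mean_lnL = as.numeric(mu),
                       sd_lnL = as.numeric(sdv), delta_k = dk),
    best_k = best, ambiguous = ambiguous), class = "delta_k")
}

#' @export
print.delta_k <- function(x, ...) {
  cat("Delta-K cluster-number diagnostic\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best K = %d%s\n", x$best_k,
              if (x$ambiguous) " (ambiguous: flat or tied curvature)" else ""))
  invisible(x)
}
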