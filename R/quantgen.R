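#' Nested variance components by Henderson's method of moments
#'
#' Decomposes one trait into among-population, among-family-within-population
#' and residual components from the unbalanced two-level nested ANOVA
#' (population / family-in-population / residual), equating observed mean
#' squares to their expectations. Negative solutions are truncated to zero.
#' The within-population variance `V_W` is assembled per `vw`: the default
#' `"total"` uses `V_fam + V_res` (total phenotypic variance within
#' populations, the quantity a narrow-sense heritability refers to);
#' `"family"` uses `V_fam` alone.
#'
#' @param tt a [trait_table()].
#' @param trait trait column name.
#' @param vw `"total"` or `"family"`; definition of `V_W`.
#' @return a list of class `variance_decomposition` with components `V_B`,
#'   `V_fam`, `V_res`, `V_W`, counts, and the raw (untruncated) solutions.
#' @export
variance_components <- function(tt, trait, vw = c("total", "family")) {
  vw <- match.arg(vw)
  if (!inherits(tt, "trait_table")) tt <- trait_table(tt)
  if (!trait %in% trait_names(tt)) stop_adaptdiff("unknown trait: ", trait)
  y <- tt[[trait]]
  ok <- !is.na(y)
  y <- y[ok]
  pop <- tt$population[ok]
  fam <- paste(tt$population, tt$family, sep = "\r")[ok]  # families nested in pops
  pops <- unique(pop)
  if (length(pops) < 2L)
    stop_adaptdiff("need >= 2 populations, got ", length(pops))
  fam_per_pop <- tapply(fam, pop, function(f) length(unique(f)))
  single <- names(fam_per_pop)[fam_per_pop < 2L]
  if (length(single))
    stop_adaptdiff("population(s) with a single family: ",
                   paste(single, collapse = ", "))
  N <- length(y)
  a <- length(pops)
  fam_mean <- tapply(y, fam, mean)
  fam_n    <- tapply(y, fam, length)
  fam_pop  <- sub("\r.*$", "", names(fam_mean))
  b <- length(fam_mean)
  pop_sum <- tapply(y, pop, sum)
  pop_n   <- tapply(y, pop, length)
  pop_mean <- pop_sum / pop_n
  grand <- mean(y)

  ss_res <- sum((y - fam_mean[fam])^2)
  ss_fam <- sum(fam_n * (fam_mean - pop_mean[fam_pop])^2)
  ss_pop <- sum(pop_n * (pop_mean - grand)^2)
  df_res <- N - b; df_fam <- b - a; df_pop <- a - 1L

  ms_res <- if (df_res > 0) ss_res / df_res else 0
  ms_fam <- ss_fam / df_fam
  ms_pop <- ss_pop / df_pop

  # EMS coefficients for the unbalanced nested design (Sokal-Rohlf form):
  #   E[MS_res] = Vres
  #   E[MS_fam] = Vres + k1*Vfam
  #   E[MS_pop] = Vres + k2*Vfam + k3*Vpop
  sum_nij2_by_pop <- tapply(fam_n^2, fam_pop, sum)
  k1 <- (N - sum(sum_nij2_by_pop / pop_n[names(sum_nij2_by_pop)])) / df_fam
  k2 <- (sum(sum_nij2_by_pop / pop_n[names(sum_nij2_by_pop)]) -
           sum(fam_n^2) / N) / df_pop
  k3 <- (N - sum(pop_n^2) / N) / df_pop

  v_res_raw <- ms_res
  v_fam_raw <- (ms_fam - ms_res) / k1
  v_pop_raw <- (ms_pop - ms_res - k2 * v_fam_raw) / k3

  if (ss_res + ss_fam + ss_pop == 0)
    warning("zero total variance for trait '", trait,
            "'; all components set to 0")
  V_res <- max(0, v_res_raw)
  V_fam <- max(0, v_fam_raw)
  V_B   <- max(0, v_pop_raw)
  V_W <- if (vw == "total") V_fam + V_res else V_fam
  structure(list(trait = trait, V_B = V_B, V_fam = V_fam, V_res = V_res,
                 V_W = V_W, vw = vw,
                 raw = c(V_B = v_pop_raw, V_fam = v_fam_raw, V_res = v_res_raw),
                 n_pops = a, n_fams = b, n_obs = N),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance components for '%s' (%d pops, %d families, %d obs)\n",
              x$trait, x$n_pops, x$n_fams, x$n_obs))
  cat(sprintf("  V_B = %.4g  V_fam = %.4g  V_res = %.4g  V_W(%s) = %.4g\n",
              x$V_B, x$V_fam, x$V_res, x$vw, x$V_W))
  invisible(x)
}

#' Pairwise Q_ST from variance components
#'
#' Q_ST = V_B / (V_B + 2 V_GW), with the within-population additive genetic
#' variance V_GW assembled per `formula_variant`:
#' * `"heritability_scaled"` (default): V_GW = h^2 * V_W, the trait
#'   heritability times the within-population variance component. Under this
#'   variant the sib model enters only through the variance-component fit.
#' * `"literal_4x"`: V_GW from the family variance component alone, using the
#'   classical sib coefficients — half-sibs share 1/4 of the additive
#'   variance (V_A = 4 V_fam), full-sibs 1/2 (V_A = 2 V_fam); h^2 unused.
#'
#' The result is clamped to `[0, 1]`; when both V_B and V_GW are zero it is
#' defined as 0.
#'
#' @param vc a `variance_decomposition`.
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @param model `"half_sib"` or `"full_sib"`.
#' @param formula_variant see Details.
#' @return Q_ST in `[0, 1]`.
#' @export
qst_pair <- function(vc, h2, model = c("half_sib", "full_sib"),
                     formula_variant = c("heritability_scaled", "literal_4x")) {
  model <- match.arg(model)
  formula_variant <- match.arg(formula_variant)
  stopifnot(inherits(vc, "variance_decomposition"))
  if (!is_number(h2) || h2 < 0 || h2 > 1)
    stop_adaptdiff("h2 must be a number in [0,1]")
  if (vc$V_B < 0 || vc$V_W < 0 || vc$V_fam < 0)
    stop_adaptdiff("negative variance components")
  v_gw <- switch(formula_variant,
    heritability_scaled = h2 * vc$V_W,
    literal_4x = (if (model == "half_sib") 4 else 2) * vc$V_fam)
  denom <- vc$V_B + 2 * v_gw
  if (denom == 0) return(0)
  min(1, max(0, vc$V_B / denom))
}

.pop_pairs <- function(pops) {
  idx <- utils::combn(length(pops), 2L)
  data.frame(a = pops[idx[1L, ]], b = pops[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise Q_ST matrices over all population pairs
#'
#' For every unordered population pair and every trait, fits the two-level
#' nested variance decomposition on the two-population subset and converts it
#' to Q_ST via [qst_pair()]. The mean matrix averages the per-trait Q_ST
#' values present for each pair (traits whose fit fails for a pair are
#' dropped from that pair's average with a warning). P populations yield
#' P(P-1)/2 pairs.
#'
#' @param tt a [trait_table()].
#' @param traits trait names; default all.
#' @param h2 named numeric vector/list, heritability per trait (values in
#'   `[0,1]`); a single unnamed number is recycled.
#' @inheritParams qst_pair
#' @inheritParams variance_components
#' @return list with `per_trait` (named list of `dist_matrix`, kind `"qst"`),
#'   `mean` (`dist_matrix`), `model`, `formula_variant`.
#' @export
qst_matrix <- function(tt, traits = NULL, h2,
                       model = c("half_sib", "full_sib"),
                       formula_variant = c("heritability_scaled", "literal_4x"),
                       vw = c("total", "family")) {
  model <- match.arg(model)
  formula_variant <- match.arg(formula_variant)
  vw <- match.arg(vw)
  if (!inherits(tt, "trait_table")) tt <- trait_table(tt)
  traits <- traits %||% trait_names(tt)
  if (is.list(h2)) h2 <- unlist(h2)
  if (length(h2) == 1L && is.null(names(h2)))
    h2 <- stats::setNames(rep(h2, length(traits)), traits)
  miss <- setdiff(traits, names(h2))
  if (length(miss))
    stop_adaptdiff("no heritability supplied for trait(s): ",
                   paste(miss, collapse = ", "))
  # drop populations that cannot enter any pair
  fam_per_pop <- tapply(tt$family, tt$population,
                        function(f) length(unique(f)))
  drop <- names(fam_per_pop)[fam_per_pop < 2L]
  if (length(drop)) {
    warning("excluding population(s) with < 2 families: ",
            paste(drop, collapse = ", "))
    tt <- trait_table(tt[!tt$population %in% drop, , drop = FALSE],
                      traits = trait_names(tt))
  }
  pops <- sort(unique(tt$population))
  if (length(pops) < 2L) stop_adaptdiff("need >= 2 usable populations")
  pairs <- .pop_pairs(pops)
  P <- length(pops)
  per_trait <- lapply(traits, function(tr) matrix(NA_real_, P, P,
                                                  dimnames = list(pops, pops)))
  names(per_trait) <- traits
  for (k in seq_len(nrow(pairs))) {
    sub <- tt[tt$population %in% c(pairs$a[k], pairs$b[k]), , drop = FALSE]
    sub <- trait_table(sub, traits = trait_names(tt))
    for (tr in traits) {
      q <- tryCatch(
        qst_pair(variance_components(sub, tr, vw = vw), h2 = h2[[tr]],
                 model = model, formula_variant = formula_variant),
        error = function(e) {
          warning("pair ", pairs$a[k], "-", pairs$b[k], ", trait '", tr,
                  "': ", conditionMessage(e))
          NA_real_
        })
      per_trait[[tr]][pairs$a[k], pairs$b[k]] <- q
      per_trait[[tr]][pairs$b[k], pairs$a[k]] <- q
    }
  }
  mean_m <- Reduce(`+`, lapply(per_trait, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, lapply(per_trait, function(m) !is.na(m) + 0))
  diag(mean_m) <- 0
  per_trait <- lapply(per_trait, function(m) {
    diag(m) <- 0
    dist_matrix(m, pops, "qst")
  })
  list(per_trait = per_trait,
       mean = dist_matrix(mean_m, pops, "qst"),
       model = model, formula_variant = formula_variant)
}

#' Concordance of half-sib and full-sib pairwise Q_ST
#'
#' Pearson correlation between the vectorized mean pairwise Q_ST estimates
#' under the half-sib and full-sib models. Under the default
#' `heritability_scaled` variant the two models produce identical values by
#' construction; the `literal_4x` variant (where the sib coefficient enters)
#' is the informative comparison and is the default here.
#'
#' @inheritParams qst_matrix
#' @return list with `r`, `n_pairs`, `degenerate` (TRUE when < 3 pairs).
#' @export
half_full_sib_concordance <- function(tt, traits = NULL, h2,
                                      formula_variant = "literal_4x",
                                      vw = "total") {
  hs <- qst_matrix(tt, traits, h2, model = "half_sib",
                   formula_variant = formula_variant, vw = vw)
  fs <- qst_matrix(tt, traits, h2, model = "full_sib",
                   formula_variant = formula_variant, vw = vw)
  x <- dist_values(hs$mean); y <- dist_values(fs$mean)
  if (length(x) < 3L)
    return(list(r = if (stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_,
      n_pairs = length(x), degenerate = TRUE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_adaptdiff("constant Q_ST vector; correlation undefined")
  list(r = stats::cor(x, y), n_pairs = length(x), degenerate = FALSE)
}
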