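#' One local/foreign transplant population pair
#'
#' Design metadata plus pot-level fitness records for a paired transplant
#' experiment: families from the local and the foreign population grown in
#' local soil, 15 family pairs x 4 blocks x 2 origins per pair by default.
#' Each (family_pair, block, origin) combination must occur exactly once and
#' origins must be balanced within blocks.
#'
#' @param pair_id identifier.
#' @param local_pop,foreign_pop population labels.
#' @param distance_km inter-population distance (> 0).
#' @param local_N,foreign_N reproductive population sizes.
#' @param pots data frame with columns `family_pair`, `block`, `row`,
#'   `column`, `origin` (`"local"`/`"foreign"`), `seed_weight`, `germinated`,
#'   `survived`, `biomass`, `inflorescences`.
#' @return an object of class `pair_experiment`.
#' @export
pair_experiment <- function(pair_id, local_pop, foreign_pop, distance_km,
                            local_N, foreign_N, pots) {
  pots <- as.data.frame(pots, stringsAsFactors = FALSE)
  need <- c("family_pair", "block", "row", "column", "origin", "seed_weight",
            "germinated", "survived", "biomass", "inflorescences")
  miss <- setdiff(need, names(pots))
  if (length(miss))
    stop_adaptdiff("pots table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(pots$origin %in% c("local", "foreign")))
    stop_adaptdiff("origin must be 'local' or 'foreign'")
  if (!is_number(distance_km) || distance_km <= 0)
    stop_adaptdiff("distance_km must be > 0")
  key <- paste(pots$family_pair, pots$block, pots$origin)
  if (anyDuplicated(key))
    stop_adaptdiff("duplicated (family_pair, block, origin) cell(s) in pair ",
                   pair_id)
  bal <- table(pots$block, factor(pots$origin, c("local", "foreign")))
  if (any(bal[, 1L] != bal[, 2L]))
    stop_adaptdiff("origins unbalanced within block(s) in pair ", pair_id)
  structure(list(pair_id = as.character(pair_id),
                 local_pop = as.character(local_pop),
                 foreign_pop = as.character(foreign_pop),
                 distance_km = distance_km,
                 local_N = local_N, foreign_N = foreign_N, pots = pots),
            class = "pair_experiment")
}

#' @export
print.pair_experiment <- function(x, ...) {
  cat(sprintf("Pair %s: local %s (N=%g) vs foreign %s (N=%g), %.1f km, %d pots\n",
              x$pair_id, x$local_pop, x$local_N, x$foreign_pop, x$foreign_N,
              x$distance_km, nrow(x$pots)))
  invisible(x)
}

.trait_pot_values <- function(pots, trait) {
  switch(trait,
    survival = as.numeric(pots$survived),
    biomass = ifelse(pots$survived, pots$biomass, NA_real_),
    inflorescences = ifelse(pots$survived, as.numeric(pots$inflorescences),
                            NA_real_),
    stop_adaptdiff("unknown trait: ", trait))
}

#' Local-vs-foreign fitness differential for one pair
#'
#' `delta_pct = 100 * (mean_local - mean_foreign) / mean_foreign`: positive
#' values indicate local adaptation, negative foreign-genotype advantage.
#' Survival uses family-pooled survival proportions; adult traits (biomass,
#' inflorescences) are averaged over surviving plants. When the foreign mean
#' is zero the percentage is undefined and the absolute difference is
#' reported instead (`absolute = TRUE`). The alternative denominator
#' (`denominator = "local"`) is available because reported percentage
#' conventions differ between studies.
#'
#' @param pair a [pair_experiment()].
#' @param trait `"survival"`, `"biomass"` or `"inflorescences"`.
#' @param qst,fst,env_dist optional predictor values attached to the record.
#' @param denominator `"foreign"` (default) or `"local"`.
#' @return one-row data frame (class `differential_record`): `pair_id`,
#'   `trait`, `delta_pct`, `absolute`, `mean_local`, `mean_foreign`, and the
#'   predictor columns `log_local_N`, `log_foreign_N`, `log_dist_km`,
#'   `env_dist`, `qst`, `fst` (log base 10).
#' @export
differentials <- function(pair, trait, qst = NA_real_, fst = NA_real_,
                          env_dist = NA_real_,
                          denominator = c("foreign", "local")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pair, "pair_experiment"))
  v <- .trait_pot_values(pair$pots, trait)
  loc <- pair$pots$origin == "local"
  if (trait != "survival" &&
      (!any(pair$pots$survived[loc]) || !any(pair$pots$survived[!loc])))
    stop_adaptdiff("pair ", pair$pair_id, ": no surviving plant for one origin")
  m_l <- mean(v[loc], na.rm = TRUE)
  m_f <- mean(v[!loc], na.rm = TRUE)
  den <- if (denominator == "foreign") m_f else m_l
  absolute <- den == 0
  delta <- if (absolute) m_l - m_f else 100 * (m_l - m_f) / den
  if (absolute)
    warning("pair ", pair$pair_id, ": ", denominator,
            " mean is zero; reporting absolute difference")
  out <- data.frame(pair_id = pair$pair_id, trait = trait,
                    delta_pct = delta, absolute = absolute,
                    mean_local = m_l, mean_foreign = m_f,
                    log_local_N = log10(pair$local_N),
                    log_foreign_N = log10(pair$foreign_N),
                    log_dist_km = log10(pair$distance_km),
                    env_dist = env_dist, qst = qst, fst = fst,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_record", "data.frame")
  out
}

## Family-mean responses on the analysis scale used by origin_anova.
.family_means <- function(pair, trait) {
  pots <- pair$pots
  key <- interaction(pots$family_pair, pots$origin, drop = TRUE)
  if (trait == "survival") {
    s <- tapply(pots$survived, key, sum)
    n <- tapply(pots$survived, key, length)
    y <- log((s + 0.5) / (n - s + 0.5))  # empirical logit of pooled counts
  } else {
    v <- .trait_pot_values(pots, trait)
    y <- tapply(v, key, mean, na.rm = TRUE)
    if (trait == "inflorescences") y <- log(y + 1)
  }
  parts <- do.call(rbind, strsplit(names(y), ".", fixed = TRUE))
  data.frame(pair_id = pair$pair_id, family_pair = parts[, 1L],
             origin = parts[, 2L], y = as.numeric(y),
             seed_weight = as.numeric(tapply(pots$seed_weight, key, mean)),
             stringsAsFactors = FALSE)
}

#' Origin x pair tests on family means
#'
#' Fixed-effects two-way ANOVA of family-mean responses with origin,
#' population pair and their interaction. Responses are transformed per
#' trait before averaging enters the ANOVA: biomass is analysed as the family
#' mean of surviving plants, survival as the empirical logit
#' `log((s + 0.5)/(n - s + 0.5))` of family-pooled counts, inflorescence
#' number as `log(mean + 1)`. When `seed_weight_covariate = TRUE`, family
#' means are first residualized on family-mean seed weight. Per-pair
#' local-vs-foreign contrasts use the pooled-error least significant
#' difference at `alpha` (default 0.034, the correlated-traits-adjusted level
#' for three fitness components).
#'
#' @param pair_set list of [pair_experiment()] objects (>= 2).
#' @param trait `"survival"`, `"biomass"` or `"inflorescences"`.
#' @param alpha corrected significance level for per-pair contrasts.
#' @param seed_weight_covariate residualize on seed weight first?
#' @return list of class `origin_test`: `trait`, `anova` (data frame with
#'   df, F, p for origin, pair, origin:pair), `contrasts` (per pair:
#'   `delta_pct`, contrast estimate on the analysis scale, t, p,
#'   `significant`), `alpha`.
#' @export
origin_anova <- function(pair_set, trait, alpha = 0.034,
                         seed_weight_covariate = FALSE) {
  if (inherits(pair_set, "pair_experiment")) pair_set <- list(pair_set)
  if (length(pair_set) < 1L) stop_adaptdiff("empty pair set")
  fm <- do.call(rbind, lapply(pair_set, .family_means, trait = trait))
  cells <- table(fm$pair_id, factor(fm$origin, c("local", "foreign")))
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop_adaptdiff("empty cell: pair ", rownames(cells)[bad[1L]],
                   ", origin ", colnames(cells)[bad[2L]])
  }
  if (seed_weight_covariate)
    fm$y <- stats::residuals(stats::lm(y ~ seed_weight, data = fm))
  fm$origin <- factor(fm$origin, levels = c("local", "foreign"))
  fm$pair_id <- factor(fm$pair_id)
  single_pair <- nlevels(fm$pair_id) == 1L
  form <- if (single_pair) y ~ origin else y ~ origin * pair_id
  fit <- stats::aov(form, data = fm)
  at <- stats::anova(fit)
  rows <- rownames(at)
  pick <- function(nm) {
    i <- match(nm, rows)
    if (is.na(i)) c(df = NA, F = NA, p = NA)
    else c(df = at$Df[i], F = at$`F value`[i], p = at$`Pr(>F)`[i])
  }
  tab <- rbind(origin = pick("origin"),
               pair = pick("pair_id"),
               origin_x_pair = pick("origin:pair_id"))
  mse <- at$`Mean Sq`[match("Residuals", rows)]
  df_res <- at$Df[match("Residuals", rows)]
  # pooled-error LSD contrasts, local - foreign within each pair
  contrasts <- do.call(rbind, lapply(pair_set, function(p) {
    sub <- fm[fm$pair_id == p$pair_id, ]
    ml <- mean(sub$y[sub$origin == "local"])
    mf <- mean(sub$y[sub$origin == "foreign"])
    nl <- sum(sub$origin == "local"); nf <- sum(sub$origin == "foreign")
    se <- sqrt(mse * (1 / nl + 1 / nf))
    tval <- (ml - mf) / se
    pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
    dp <- suppressWarnings(differentials(p, trait))
    data.frame(pair_id = p$pair_id, delta_pct = dp$delta_pct,
               contrast = ml - mf, t = tval, p = pval,
               significant = pval < alpha, stringsAsFactors = FALSE)
  }))
  structure(list(trait = trait, anova = as.data.frame(tab),
                 contrasts = contrasts, alpha = alpha,
                 residual_df = df_res, fit = fit),
            class = "origin_test")
}

#' @export
print.origin_test <- function(x, ...) {
  cat(sprintf("Origin x pair fixed-effects test on family means ('%s')\n",
              x$trait))
  print(round(x$anova, 4))
  sig <- x$contrasts$pair_id[x$contrasts$significant]
  cat(sprintf("pairs with origin contrast significant at alpha = %g: %s\n",
              x$alpha, if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

.aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Forward stepwise AIC regression of fitness differentials on predictors
#'
#' Forward selection from the intercept-only model over the candidate
#' predictors (by default log local population size, log foreign size, log
#' distance, environmental distance, Q_ST and F_ST). At each step the
#' predictor minimizing `AIC = n log(RSS/n) + 2k` (k = fitted coefficients)
#' is added; selection stops at `max_terms` or when no addition lowers the
#' AIC. A candidate whose addition makes the model matrix numerically
#' collinear (condition number > 1e8) is refused with a warning. The final
#' model is an ordinary least-squares fit; the model p-value is the overall
#' F test, judged against `alpha` (default 0.025, Bonferroni 0.05/2 for
#' shared home populations).
#'
#' @param records data frame of differential records (one row per pair) with
#'   a `delta_pct` column and the predictor columns.
#' @param predictors candidate predictor names.
#' @param max_terms maximum number of predictors.
#' @param alpha significance level for the overall model F test.
#' @return list of class `stepwise_fit`: `selected`, `coefficients`, `r2`,
#'   `p_model`, `alpha`, `aic_path`, `fit` (the `lm`), `significant`.
#' @export
stepwise_predict <- function(records,
                             predictors = c("log_local_N", "log_foreign_N",
                                            "log_dist_km", "env_dist",
                                            "qst", "fst"),
                             max_terms = 2L, alpha = 0.025) {
  records <- as.data.frame(records)
  predictors <- intersect(predictors, names(records))
  predictors <- predictors[vapply(predictors, function(p)
    !all(is.na(records[[p]])), TRUE)]
  if (!"delta_pct" %in% names(records))
    stop_adaptdiff("records need a delta_pct column")
  use <- stats::complete.cases(records[c("delta_pct", predictors)])
  records <- records[use, , drop = FALSE]
  n <- nrow(records)
  if (n < 6L) stop_adaptdiff("need >= 6 complete records, got ", n)
  y <- records$delta_pct
  selected <- character(0)
  rss_cur <- sum((y - mean(y))^2)
  aic_cur <- .aic_rss(rss_cur, n, 1L)
  aic_path <- data.frame(step = 0L, added = "(intercept)", aic = aic_cur)
  repeat {
    if (length(selected) >= max_terms) break
    remaining <- setdiff(predictors, selected)
    if (!length(remaining)) break
    cand_aic <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      Xc <- as.matrix(cbind(1, records[c(selected, remaining[i])]))
      if (kappa(Xc, exact = TRUE) > 1e8) {
        warning("refusing collinear predictor '", remaining[i], "'")
        next
      }
      fit_c <- stats::lm.fit(Xc, y)
      cand_aic[i] <- .aic_rss(sum(fit_c$residuals^2), n, ncol(Xc))
    }
    if (all(is.na(cand_aic)) || min(cand_aic, na.rm = TRUE) >= aic_cur) break
    best <- remaining[which.min(cand_aic)]
    selected <- c(selected, best)
    aic_cur <- min(cand_aic, na.rm = TRUE)
    aic_path <- rbind(aic_path, data.frame(step = length(selected),
                                           added = best, aic = aic_cur))
  }
  form <- if (length(selected))
    stats::reformulate(selected, response = "delta_pct")
  else delta_pct ~ 1
  fit <- stats::lm(form, data = records)
  sm <- summary(fit)
  p_model <- if (length(selected))
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  else NA_real_
  structure(list(selected = selected,
                 coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 r2 = sm$r.squared,
                 p_model = unname(p_model),
                 significant = isTRUE(unname(p_model) < alpha),
                 alpha = alpha, aic_path = aic_path, n = n, fit = fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Forward stepwise AIC regression (n =", x$n, ")\n")
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = " + "), "\n")
    cat(sprintf("  R^2 = %.3f, model p = %.4g (alpha = %g)%s\n", x$r2,
                x$p_model, x$alpha,
                if (x$significant) " *" else ""))
    print(round(x$coefficients, 4))
  } else cat("  no predictor improved on the intercept-only model\n")
  invisible(x)
}
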