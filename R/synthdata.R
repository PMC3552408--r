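#' Simulation configuration for the synthetic study system
#'
#' Defaults emulate a fragmented-grassland study system: 15 populations, 25
#' maternal (half-sib) families per population, 4 offspring per family in the
#' common garden; 10 multi-allelic microsatellite-style loci diverged under a
#' Balding-Nichols island model; two climate zones roughly 500 km apart with
#' mosaic (spatially uncorrelated) soil variation; and 12 paired local/foreign
#' transplant experiments of 15 family pairs x 4 blocks x 2 origins each
#' (1440 pots in total).
#'
#' @param n_pops number of populations/sites.
#' @param fams_per_pop maternal families per population (22-30 is realistic;
#'   default 25).
#' @param obs_per_fam offspring measured per family.
#' @param trait_specs named list: per trait, a list with `V_B`, `V_fam`,
#'   `V_res`, `h2_true`, optional `grand_mean`.
#' @param n_loci,alleles_per_locus,bn_F marker simulation: locus count,
#'   alleles per locus, Balding-Nichols divergence.
#' @param n_climate_vars,n_soil_vars,climate_zone_split,collinear_blocks
#'   environment simulation: variable counts, fraction of sites in the
#'   northern zone, and a count of planted perfectly-collinear triplets
#'   appended to the soil variables.
#' @param n_pairs,families_per_pair,blocks transplant design.
#' @param adaptation_effects named list: per pair id, a list of per-trait
#'   effects (`survival` on the logit scale, `biomass` and `inflorescences`
#'   as proportional local advantages, e.g. 0.1 = +10%).
#' @param seed integer; every generator is a pure function of (config, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 15L, fams_per_pop = 25L, obs_per_fam = 4L,
                       trait_specs = list(
                         trait1 = list(V_B = 0.4, V_fam = 0.125, V_res = 0.875,
                                       h2_true = 0.5)),
                       n_loci = 10L, alleles_per_locus = 6L, bn_F = 0.05,
                       n_climate_vars = 8L, n_soil_vars = 8L,
                       climate_zone_split = 0.8, collinear_blocks = 0L,
                       n_pairs = 12L, families_per_pair = 15L, blocks = 4L,
                       adaptation_effects = list(), seed = 1L) {
  stopifnot(n_pops >= 2L, fams_per_pop >= 2L, obs_per_fam >= 1L,
            bn_F > 0, bn_F < 1, climate_zone_split > 0, climate_zone_split <= 1)
  for (tr in names(trait_specs)) {
    ts <- trait_specs[[tr]]
    if (any(unlist(ts[c("V_B", "V_fam", "V_res")]) < 0))
      stop_adaptdiff("negative variance in trait_specs$", tr)
    if (ts$h2_true < 0 || ts$h2_true > 1)
      stop_adaptdiff("h2_true outside [0,1] in trait_specs$", tr)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d pops x %d families x %d obs, ",
                     "%d loci (F = %g), %d transplant pairs (seed %d)\n"),
              x$n_pops, x$fams_per_pop, x$obs_per_fam, x$n_loci, x$bn_F,
              x$n_pairs, x$seed))
  invisible(x)
}

.pop_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Generate family-structured trait data with known variance components
#'
#' Each observation is grand mean + population effect N(0, V_B) + family
#' effect N(0, V_fam) + residual N(0, V_res). The attached `truth` attribute
#' records the generating components, realized effects, and the implied true
#' Q_ST under each formula variant (identical for all pairs since components
#' are homogeneous).
#'
#' @param cfg a [sim_config()].
#' @return a [trait_table()] with attribute `truth`.
#' @export
gen_traits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    pops <- .pop_ids(cfg$n_pops)
    n <- cfg$n_pops * cfg$fams_per_pop * cfg$obs_per_fam
    pop <- rep(pops, each = cfg$fams_per_pop * cfg$obs_per_fam)
    fam <- rep(rep(sprintf("F%02d", seq_len(cfg$fams_per_pop)),
                   each = cfg$obs_per_fam), times = cfg$n_pops)
    df <- data.frame(individual = sprintf("I%05d", seq_len(n)),
                     population = pop, family = fam,
                     stringsAsFactors = FALSE)
    truth <- list()
    for (tr in names(cfg$trait_specs)) {
      ts <- cfg$trait_specs[[tr]]
      mu <- ts$grand_mean %||% 10
      pe <- stats::rnorm(cfg$n_pops, 0, sqrt(ts$V_B))
      fe <- stats::rnorm(cfg$n_pops * cfg$fams_per_pop, 0, sqrt(ts$V_fam))
      res <- stats::rnorm(n, 0, sqrt(ts$V_res))
      fam_idx <- rep(seq_len(cfg$n_pops * cfg$fams_per_pop),
                     each = cfg$obs_per_fam)
      pop_idx <- rep(seq_len(cfg$n_pops),
                     each = cfg$fams_per_pop * cfg$obs_per_fam)
      df[[tr]] <- mu + pe[pop_idx] + fe[fam_idx] + res
      vw <- ts$V_fam + ts$V_res
      truth[[tr]] <- list(
        V_B = ts$V_B, V_fam = ts$V_fam, V_res = ts$V_res,
        h2_true = ts$h2_true,
        pop_effects = stats::setNames(pe, pops),
        qst_true = list(
          heritability_scaled = if (ts$V_B + 2 * ts$h2_true * vw == 0) 0 else
            ts$V_B / (ts$V_B + 2 * ts$h2_true * vw),
          literal_4x_half_sib = if (ts$V_B + 8 * ts$V_fam == 0) 0 else
            ts$V_B / (ts$V_B + 8 * ts$V_fam),
          literal_4x_full_sib = if (ts$V_B + 4 * ts$V_fam == 0) 0 else
            ts$V_B / (ts$V_B + 4 * ts$V_fam)))
    }
    out <- trait_table(df, traits = names(cfg$trait_specs))
    attr(out, "truth") <- truth
    out
  })
}

## Dirichlet draw via independent gammas.
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Frequency-level F_ST between populations of known allele frequencies
#'
#' The large-sample limit of the Weir-Cockerham estimator applied to the true
#' per-population allele frequencies: per allele,
#' `s2 / (pbar (1 - pbar) + s2 / r)` components summed over alleles and loci
#' as a ratio of sums. This is the generator's internal oracle for scoring
#' theta estimates.
#'
#' @param freqs list (loci) of matrices (populations x alleles) of true
#'   frequencies.
#' @return numeric scalar.
#' @export
fst_expected_from_freqs <- function(freqs) {
  num <- den <- 0
  for (P in freqs) {
    r <- nrow(P)
    for (j in seq_len(ncol(P))) {
      p <- P[, j]
      pbar <- mean(p)
      s2 <- sum((p - pbar)^2) / (r - 1)
      num <- num + s2
      den <- den + pbar * (1 - pbar) + s2 / r
    }
  }
  if (den == 0) return(0)
  num / den
}

#' Generate Balding-Nichols diploid genotypes
#'
#' Ancestral allele frequencies are Dirichlet(1,...,1); each population's
#' frequencies are Dirichlet(p (1-F)/F) around the ancestral vector; diploid
#' genotypes are two independent allele draws. The `truth` attribute stores
#' the per-population frequencies and the oracle pairwise frequency-level
#' F_ST matrix from [fst_expected_from_freqs()].
#'
#' @param cfg a [sim_config()].
#' @param n_per_pop individuals sampled per population (default
#'   `fams_per_pop`, one per maternal family).
#' @return a [genotype_table()] with attribute `truth`.
#' @export
gen_genotypes <- function(cfg, n_per_pop = cfg$fams_per_pop) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    pops <- .pop_ids(cfg$n_pops)
    n <- cfg$n_pops * n_per_pop
    a1 <- a2 <- matrix(NA_integer_, n, cfg$n_loci)
    freqs <- vector("list", cfg$n_loci)
    shape <- (1 - cfg$bn_F) / cfg$bn_F
    for (l in seq_len(cfg$n_loci)) {
      anc <- .rdirichlet(rep(1, cfg$alleles_per_locus))
      P <- t(vapply(seq_len(cfg$n_pops),
                    function(i) .rdirichlet(anc * shape),
                    numeric(cfg$alleles_per_locus)))
      rownames(P) <- pops
      freqs[[l]] <- P
      for (i in seq_len(cfg$n_pops)) {
        rows <- (i - 1L) * n_per_pop + seq_len(n_per_pop)
        a1[rows, l] <- sample.int(cfg$alleles_per_locus, n_per_pop,
                                  replace = TRUE, prob = P[i, ])
        a2[rows, l] <- sample.int(cfg$alleles_per_locus, n_per_pop,
                                  replace = TRUE, prob = P[i, ])
      }
    }
    colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(cfg$n_loci))
    g <- genotype_table(sprintf("G%05d", seq_len(n)),
                        rep(pops, each = n_per_pop), a1, a2)
    pairfst <- matrix(0, cfg$n_pops, cfg$n_pops, dimnames = list(pops, pops))
    for (i in seq_len(cfg$n_pops - 1L)) for (j in seq(i + 1L, cfg$n_pops)) {
      f <- fst_expected_from_freqs(lapply(freqs, function(P)
        P[c(i, j), , drop = FALSE]))
      pairfst[i, j] <- pairfst[j, i] <- f
    }
    attr(g, "truth") <- list(freqs = freqs, bn_F = cfg$bn_F,
                             pairwise_fst = pairfst)
    g
  })
}

#' Generate site environments: two climate zones plus mosaic soils
#'
#' Sites are split between a northern and a southern zone ~500 km apart
#' (within-zone scatter spans roughly 0.7-80 km). Climate variables get a
#' zone-level shift (2 SD by default) plus site noise, so climate separates
#' the zones; soil variables are drawn iid per site (a mosaic uncorrelated
#' with geography). `collinear_blocks` appends perfectly collinear triplets
#' (one free variable plus two exact linear copies) to the soil set for
#' exercising the correlation filter.
#'
#' @param cfg a [sim_config()].
#' @param zone_effect climate zone shift in within-zone SD units.
#' @return a [site_environment()] with attribute `truth` (zone membership).
#' @export
gen_environment <- function(cfg, zone_effect = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2L, {
    pops <- .pop_ids(cfg$n_pops)
    n_north <- max(1L, round(cfg$climate_zone_split * cfg$n_pops))
    zone <- rep(c("north", "south"),
                c(n_north, cfg$n_pops - n_north))
    # zone centres ~500 km apart; within-zone jitter up to ~0.4 deg (~45 km)
    lat0 <- ifelse(zone == "north", -35.3, -37.6)
    lon0 <- ifelse(zone == "north", 149.1, 144.9)
    lat <- lat0 + stats::runif(cfg$n_pops, -0.4, 0.4)
    lon <- lon0 + stats::runif(cfg$n_pops, -0.4, 0.4)
    df <- data.frame(site = pops, latitude = lat, longitude = lon,
                     elevation = stats::rnorm(cfg$n_pops, 600, 100),
                     stringsAsFactors = FALSE)
    z <- as.numeric(zone == "south")
    for (k in seq_len(cfg$n_climate_vars))
      df[[sprintf("clim%02d", k)]] <-
        stats::rnorm(cfg$n_pops) + zone_effect * z * sample(c(-1, 1), 1L)
    for (k in seq_len(cfg$n_soil_vars))
      df[[sprintf("soil%02d", k)]] <- stats::rnorm(cfg$n_pops)
    if (cfg$collinear_blocks > 0L)
      for (b in seq_len(cfg$collinear_blocks)) {
        base <- stats::rnorm(cfg$n_pops)
        df[[sprintf("coll%02d_a", b)]] <- base
        df[[sprintf("coll%02d_b", b)]] <- 2 * base + 1
        df[[sprintf("coll%02d_c", b)]] <- -base + 3
      }
    out <- site_environment(df)
    attr(out, "truth") <- list(zone = stats::setNames(zone, pops))
    out
  })
}

#' Generate the paired local/foreign transplant experiment
#'
#' For each of `n_pairs` population pairs: `families_per_pair` family pairs x
#' `blocks` blocks x 2 origins, one pot each (the default design gives
#' 12 x 15 x 4 x 2 = 1440 pots). Germination and survival are Bernoulli with
#' logit-scale origin effects; biomass is log-normal with a proportional
#' (log-additive) origin effect; inflorescence counts are Poisson with a
#' log-scale effect; seed weight is drawn per family. Effects come from
#' `cfg$adaptation_effects[[pair_id]]` (positive = local advantage).
#'
#' @param cfg a [sim_config()].
#' @param env optional [site_environment()] from [gen_environment()] used to
#'   derive pair distances; otherwise distances are drawn log-uniform on
#'   0.7-600 km.
#' @return list of [pair_experiment()] objects with attribute `truth`.
#' @export
gen_pair_experiment <- function(cfg, env = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 3L, {
    pops <- .pop_ids(cfg$n_pops)
    pairs <- vector("list", cfg$n_pairs)
    truth <- list()
    # local populations drawn with replacement (a site can host two pairs),
    # foreign partner always distinct
    for (k in seq_len(cfg$n_pairs)) {
      lp <- sample(pops, 1L)
      fp <- sample(setdiff(pops, lp), 1L)
      pid <- sprintf("%s-%s", lp, fp)
      if (pid %in% names(truth)) pid <- sprintf("%s.%d", pid, k)
      dist_km <- if (!is.null(env)) {
        gd <- geographic_distances(env)
        max(0.7, gd[lp, fp])
      } else exp(stats::runif(1, log(0.7), log(600)))
      eff <- cfg$adaptation_effects[[pid]] %||%
        cfg$adaptation_effects[[as.character(k)]] %||% list()
      e_surv <- eff$survival %||% 0
      e_bio <- eff$biomass %||% 0
      e_inf <- eff$inflorescences %||% 0
      fams <- seq_len(cfg$families_per_pair)
      grid <- expand.grid(family_pair = fams, block = seq_len(cfg$blocks),
                          origin = c("local", "foreign"),
                          stringsAsFactors = FALSE)
      npot <- nrow(grid)
      grid$row <- ((seq_len(npot) - 1L) %% 10L) + 1L
      grid$column <- ((seq_len(npot) - 1L) %/% 10L) + 1L
      sw_fam <- stats::rnorm(2L * cfg$families_per_pair, 2.5, 0.3) / 1000
      fam_key <- grid$family_pair +
        cfg$families_per_pair * (grid$origin == "foreign")
      grid$seed_weight <- pmax(5e-4, sw_fam[fam_key])
      is_local <- grid$origin == "local"
      germ_lin <- stats::qlogis(0.85) + ifelse(is_local, e_surv / 2, 0)
      grid$germinated <- stats::runif(npot) < stats::plogis(germ_lin)
      surv_lin <- stats::qlogis(0.95) + ifelse(is_local, e_surv, 0)
      grid$survived <- grid$germinated &
        (stats::runif(npot) < stats::plogis(surv_lin))
      fam_bio <- stats::rnorm(2L * cfg$families_per_pair, 0, 0.15)
      mlog <- log(1) - 0.3^2 / 2 + fam_bio[fam_key] +
        ifelse(is_local, log1p(e_bio), 0)
      grid$biomass <- ifelse(grid$survived,
                             stats::rlnorm(npot, mlog, 0.3), NA_real_)
      lam <- exp(log(5) + ifelse(is_local, log1p(e_inf), 0))
      grid$inflorescences <- ifelse(grid$survived,
                                    stats::rpois(npot, lam), NA_integer_)
      pairs[[k]] <- pair_experiment(
        pair_id = pid, local_pop = lp, foreign_pop = fp,
        distance_km = dist_km,
        local_N = round(10^stats::runif(1, 2, 5)),
        foreign_N = round(10^stats::runif(1, 2, 5)),
        pots = grid)
      truth[[pid]] <- list(survival = e_surv, biomass = e_bio,
                           inflorescences = e_inf)
    }
    attr(pairs, "truth") <- truth
    pairs
  })
}
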