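#' Pipeline configuration
#'
#' Collects file paths, analysis choices and constants for [run_pipeline()].
#' Any input path may be `NULL`; stages that depend on a missing input are
#' skipped with a logged warning and the remainder of the pipeline completes.
#'
#' @param sites CSV of site coordinates + environment variables.
#' @param traits CSV of family-structured trait observations.
#' @param genotypes genotype file path.
#' @param genotype_dialect `"genepop"` or `"csv"`.
#' @param genotype_pop_labels population names for GenePop blocks (the format
#'   itself carries none); needed for labels to match the site table.
#' @param fitness,design pot-level fitness CSV and pair-design YAML.
#' @param lnl_trace optional CSV (`K, replicate, lnL`) of clustering
#'   log-likelihoods for the delta-K diagnostic.
#' @param h2 named list/vector of per-trait heritabilities, or a YAML path.
#' @param climate_vars,soil_vars environment variable names per group;
#'   defaults: names starting `clim` (plus `elevation`), names starting
#'   `soil`.
#' @param model,formula_variant,vw passed to [qst_matrix()].
#' @param rotation,retain passed to [ordinate()].
#' @param n_perm Mantel permutations.
#' @param alpha_traits per-pair contrast alpha (three correlated fitness
#'   traits).
#' @param alpha_regression overall-model alpha (Bonferroni 0.05/2).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param out_dir output directory for matrices, report and log.
#' @param cache reuse cached stage results keyed on input-file hashes?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sites = NULL, traits = NULL, genotypes = NULL,
                            genotype_dialect = "genepop",
                            genotype_pop_labels = NULL,
                            fitness = NULL, design = NULL, lnl_trace = NULL,
                            h2 = NULL,
                            climate_vars = NULL, soil_vars = NULL,
                            model = "half_sib",
                            formula_variant = "heritability_scaled",
                            vw = "total",
                            rotation = "varimax", retain = "kaiser",
                            n_perm = 10000L,
                            alpha_traits = 0.034, alpha_regression = 0.025,
                            seed = 1L, out_dir = tempfile("adaptdiff_run_"),
                            cache = TRUE) {
  stopifnot(alpha_traits > 0, alpha_traits < 1,
            alpha_regression > 0, alpha_regression < 1)
  for (p in c(sites, traits, genotypes, fitness, design, lnl_trace))
    if (!is.null(p) && !file.exists(p)) stop_adaptdiff("no such file: ", p)
  if (is.character(h2) && length(h2) == 1L && file.exists(h2))
    h2 <- yaml::read_yaml(h2)
  structure(as.list(environment()), class = "pipeline_config")
}

## Stage cache keyed on input-file hashes + parameter values, so matrix
## stages are not recomputed on regression-only reruns over the same inputs.
.stage_cache <- function(cfg, key_parts, compute) {
  if (!isTRUE(cfg$cache)) return(compute())
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- vapply(key_parts, function(p) {
    if (is.character(p) && length(p) == 1L && file.exists(p))
      unname(tools::md5sum(p))
    else paste(deparse(p), collapse = "")
  }, "")
  f <- file.path(cache_dir,
                 paste0(digest_key(paste(parts, collapse = "|")), ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

## tiny stable string key (md5 of the key text via a temp file)
digest_key <- function(s) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Run the full local-adaptation analysis pipeline
#'
#' Sequence mirrors the analysis order: predictor matrices (geographic,
#' environmental composite, soil-only, mean Q_ST, F_ST), all pairwise Mantel
#' tests among the available matrices, marker diversity, the delta-K
#' diagnostic when a likelihood trace is supplied, then per-trait
#' origin-by-pair tests, differentials and stepwise regressions for the
#' transplant pairs. Matrices are written as square CSVs, the report as JSON
#' and the log as plain text under `cfg$out_dir`. Reruns with the same config
#' and inputs are byte-identical (timestamps live only in the log).
#'
#' @param cfg a [pipeline_config()].
#' @return the report, invisibly (a nested list mirroring the JSON).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_adaptdiff("stage '", name, "' failed: ", conditionMessage(e)))
  }
  log_msg("pipeline start, master seed ", cfg$seed)
  matrices <- list()
  report <- list(seed = cfg$seed)

  if (!is.null(cfg$sites)) {
    env <- stage("sites", read_sites(cfg$sites))
    matrices$geographic <- stage("geographic", geographic_distances(env))
    climate <- cfg$climate_vars %||%
      grep("^clim|^elevation$", env_variables(env), value = TRUE)
    soil <- cfg$soil_vars %||%
      grep("^soil|^coll", env_variables(env), value = TRUE)
    env_one <- function(vars, kind) {
      fr <- filter_correlated(env, vars)
      log_msg("env filter (", kind, "): kept ", length(fr$kept), "/",
              length(vars))
      ord <- ordinate(env, fr$kept, rotation = cfg$rotation,
                      retain = cfg$retain)
      log_msg("env ordination (", kind, "): ", ord$n_components,
              " component(s), ",
              sprintf("%.1f%%", ord$explained_variance_pct), " variance")
      list(filter = fr, ordination = ord,
           dist = env_distance(ord, kind))
    }
    if (length(c(climate, soil)) >= 2L) {
      comp <- stage("environmental", env_one(c(climate, soil), "environmental"))
      matrices$environmental <- comp$dist
      report$env_filter <- list(
        kept = comp$filter$kept,
        dropped = comp$filter$dropped$variable,
        n_components = comp$ordination$n_components,
        explained_variance_pct = comp$ordination$explained_variance_pct)
    }
    if (length(soil) >= 2L) {
      so <- stage("soil", env_one(soil, "soil"))
      matrices$soil <- so$dist
    }
  } else log_msg("sites input missing: geographic/environmental stages skipped")

  if (!is.null(cfg$traits)) {
    if (is.null(cfg$h2)) stop_adaptdiff("traits supplied without h2 map")
    qst <- stage("qst", .stage_cache(cfg,
      list(cfg$traits, cfg$model, cfg$formula_variant, cfg$vw,
           paste(unlist(cfg$h2), collapse = ",")),
      function() qst_matrix(read_traits(cfg$traits), h2 = cfg$h2,
                            model = cfg$model,
                            formula_variant = cfg$formula_variant,
                            vw = cfg$vw)))
    matrices$qst <- qst$mean
    log_msg("qst: ", length(qst$per_trait), " trait(s), ",
            nrow(qst$mean) * (nrow(qst$mean) - 1) / 2, " pairs")
  } else log_msg("traits input missing: Q_ST stage skipped")

  if (!is.null(cfg$genotypes)) {
    g <- stage("genotypes",
               read_genotypes(cfg$genotypes, cfg$genotype_dialect,
                              pop_labels = cfg$genotype_pop_labels))
    matrices$fst <- stage("fst", .stage_cache(cfg, list(cfg$genotypes),
                                              function() fst_matrix(g)))
    report$diversity <- stage("diversity", diversity(g))
    report$fst_linearized_max <-
      max(dist_values(linearize_fst(matrices$fst)))
    log_msg("fst: ", nrow(matrices$fst) * (nrow(matrices$fst) - 1) / 2,
            " pairs")
  } else {
    warning("genotype input missing: F_ST-dependent stages skipped")
    log_msg("genotypes input missing: F_ST stages skipped")
  }

  if (!is.null(cfg$lnl_trace)) {
    trace <- utils::read.csv(cfg$lnl_trace)
    dk <- stage("delta_k", delta_k(trace))
    report$delta_k <- list(table = dk$table, best_k = dk$best_k,
                           ambiguous = dk$ambiguous)
  }

  for (nm in names(matrices))
    write_distance_matrix(matrices[[nm]],
                          file.path(cfg$out_dir, paste0(nm, "_dist.csv")))

  # Mantel tests among every pair of available matrices
  if (length(matrices) >= 2L) {
    shared <- Reduce(intersect, lapply(matrices, rownames))
    if (length(shared) < 4L) {
      log_msg("fewer than 4 shared labels across matrices: Mantel skipped")
      report$mantel <- list()
    } else {
    mnames <- names(matrices)
    res <- list()
    for (i in seq_along(mnames)[-length(mnames)])
      for (j in seq((i + 1L), length(mnames))) {
        a <- matrices[[i]]; b <- matrices[[j]]
        a <- dist_matrix(unclass(a)[shared, shared], shared, dist_kind(a))
        b <- dist_matrix(unclass(b)[shared, shared], shared, dist_kind(b))
        key <- paste(mnames[i], mnames[j], sep = "_x_")
        seed_ij <- (cfg$seed * 1000L + i * 31L + j) %% .Machine$integer.max
        m <- stage(paste0("mantel:", key),
                   mantel(a, b, n_perm = cfg$n_perm, seed = seed_ij))
        res[[key]] <- list(r = m$r, p = m$p, n_perm = m$n_perm)
        log_msg("mantel ", key, ": r = ", sprintf("%.4f", m$r),
                ", p = ", sprintf("%.4g", m$p))
      }
    report$mantel <- res
    }
  }

  if (!is.null(cfg$fitness) && !is.null(cfg$design)) {
    pairs <- stage("pairs", read_pair_experiments(cfg$fitness, cfg$design))
    lookup <- function(m, p) {
      if (is.null(m)) return(NA_real_)
      if (!all(c(p$local_pop, p$foreign_pop) %in% rownames(m)))
        return(NA_real_)
      m[p$local_pop, p$foreign_pop]
    }
    fit_out <- list()
    for (tr in c("survival", "biomass", "inflorescences")) {
      recs <- do.call(rbind, lapply(pairs, function(p)
        differentials(p, tr,
                      qst = lookup(matrices$qst, p),
                      fst = lookup(matrices$fst, p),
                      env_dist = lookup(matrices$environmental, p))))
      ot <- stage(paste0("origin_anova:", tr),
                  origin_anova(pairs, tr, alpha = cfg$alpha_traits))
      preds <- c("log_local_N", "log_foreign_N", "log_dist_km",
                 "env_dist", "qst", "fst")
      preds <- preds[vapply(preds, function(p) !anyNA(recs[[p]]), TRUE)]
      sw <- stage(paste0("stepwise:", tr),
                  stepwise_predict(recs, predictors = preds,
                                   alpha = cfg$alpha_regression))
      log_msg("fit ", tr, ": selected {",
              paste(sw$selected, collapse = ", "), "}, R2 = ",
              sprintf("%.3f", sw$r2))
      fit_out[[tr]] <- list(
        differentials = recs,
        anova = cbind(term = rownames(ot$anova), ot$anova),
        contrasts = ot$contrasts,
        regression = list(selected = sw$selected,
                          coefficients = as.list(sw$coefficients),
                          r2 = sw$r2, p_model = sw$p_model,
                          significant = sw$significant))
    }
    report$fitness <- fit_out
  } else log_msg("fitness/design input missing: transplant stages skipped")

  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  log_msg("report written to ", report_path)
  invisible(report)
}
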