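#' Greedy removal of highly correlated environment variables
#'
#' Builds the Pearson correlation matrix of the candidate variables and
#' iteratively removes variables involved in significant correlations
#' (two-tailed t-approximation, default P < 0.001): at each step the variable
#' participating in the largest number of offending pairs is dropped (ties
#' broken by larger mean |r| with its offending partners, then
#' alphabetically), until no offending pair remains. Constant variables are
#' dropped first with reason `"zero variance"`.
#'
#' @param env a [site_environment()] (or plain data frame of numeric columns).
#' @param variables candidate variable names; default: all environment
#'   variables.
#' @param p_threshold significance threshold for removal.
#' @return a list of class `filter_report`: `kept`, `dropped` (data frame
#'   `variable, reason, r, p`), `threshold_p`.
#' @export
filter_correlated <- function(env, variables = NULL, p_threshold = 0.001) {
  X <- as.data.frame(env, stringsAsFactors = FALSE)
  variables <- variables %||% env_variables(env) %||%
    names(X)[vapply(X, is.numeric, TRUE)]
  X <- X[variables]
  if (nrow(X) < 4L)
    stop_adaptdiff("need >= 4 sites to assess correlation significance")
  dropped <- data.frame(variable = character(), reason = character(),
                        r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  const <- variables[vapply(X, function(v) stats::sd(v) == 0, TRUE)]
  for (v in const)
    dropped <- rbind(dropped, data.frame(variable = v, reason = "zero variance",
                                         r = NA_real_, p = NA_real_))
  kept <- setdiff(variables, const)
  cor_p <- function(r, n) {
    # two-tailed p for Pearson r via the t transform; r = +/-1 -> p = 0
    r <- pmin(abs(r), 1 - 1e-15)  # matrix first: pmin keeps dims
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
  n <- nrow(X)
  while (length(kept) > 1L) {
    R <- stats::cor(X[kept])
    P <- cor_p(R, n); diag(P) <- 1
    offending <- P < p_threshold
    if (!any(offending)) break
    counts <- rowSums(offending)
    cand <- which(counts == max(counts))
    if (length(cand) > 1L) {
      mean_absr <- vapply(cand, function(i)
        mean(abs(R[i, offending[i, ]])), 0)
      cand <- cand[mean_absr == max(mean_absr)]
      cand <- cand[order(kept[cand])][1L]
    }
    v <- kept[cand]
    partner <- which.max(abs(R[cand, ]) * offending[cand, ])
    dropped <- rbind(dropped, data.frame(
      variable = v,
      reason = paste0("correlated-with:", kept[partner]),
      r = R[cand, partner], p = P[cand, partner]))
    kept <- setdiff(kept, v)
  }
  structure(list(kept = kept, dropped = dropped, threshold_p = p_threshold),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Variable filter (P < %g): kept %d, dropped %d\n",
              x$threshold_p, length(x$kept), nrow(x$dropped)))
  if (length(x$kept)) cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}

#' Principal-component ordination with varimax rotation
#'
#' PCA on the correlation matrix (variables z-scored internally). Components
#' are retained by the Kaiser rule (eigenvalue > 1) or a fixed count; when
#' more than one component is retained, loadings are varimax-rotated
#' (Kaiser-normalized, convergence tolerance 1e-8, at most 1000 iterations)
#' and site scores are recomputed from the rotated axes. With a single
#' retained component rotation is a no-op.
#'
#' @param env a [site_environment()] or numeric data frame.
#' @param variables variables to ordinate; default all environment variables.
#' @param rotation `"varimax"` or `"none"`.
#' @param retain `"kaiser"` or an integer count of components.
#' @return list of class `ordination`: `scores` (sites x components),
#'   `loadings`, `eigenvalues`, `explained_variance_pct`, `rotation`.
#' @export
ordinate <- function(env, variables = NULL, rotation = c("varimax", "none"),
                     retain = "kaiser") {
  rotation <- match.arg(rotation)
  X <- as.data.frame(env, stringsAsFactors = FALSE)
  variables <- variables %||% env_variables(env) %||%
    names(X)[vapply(X, is.numeric, TRUE)]
  X <- as.matrix(X[variables])
  rn <- if (!is.null(env$site)) env$site else rownames(X)
  if (any(apply(X, 2L, stats::sd) == 0))
    stop_adaptdiff("constant variable(s); filter before ordination")
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  k <- if (identical(retain, "kaiser")) max(1L, sum(eig > 1)) else {
    k0 <- as.integer(retain)
    if (is.na(k0) || k0 < 1L) stop_adaptdiff("retain must be 'kaiser' or a count")
    k0
  }
  if (k > ncol(pc$rotation)) stop_adaptdiff("cannot retain ", k,
                                            " components from ", ncol(pc$rotation))
  if (k >= nrow(X)) stop_adaptdiff("retained components must be < n sites")
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  load <- V %*% diag(pc$sdev[seq_len(k)], k)   # component loadings
  scores <- Z %*% V                            # unrotated scores
  if (rotation == "varimax" && k > 1L) {
    vm <- stats::varimax(load, normalize = TRUE, eps = 1e-8)
    load <- load %*% vm$rotmat
    scores <- scores %*% vm$rotmat
  }
  colnames(load) <- colnames(scores) <- paste0("C", seq_len(k))
  rownames(scores) <- rn
  rownames(load) <- variables
  structure(list(scores = scores, loadings = load,
                 eigenvalues = eig,
                 n_components = k,
                 explained_variance_pct = 100 * sum(eig[seq_len(k)]) / sum(eig),
                 rotation = rotation),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("Ordination: %d component(s) (%s), %.1f%% variance explained\n",
              x$n_components, x$rotation, x$explained_variance_pct))
  invisible(x)
}

#' Environmental distance from rotated factor scores
#'
#' Pairwise Euclidean distance between sites over the retained (rotated)
#' component scores.
#'
#' @param ord an `ordination`.
#' @param kind distance-matrix kind tag (`"environmental"` or `"soil"`).
#' @return a `dist_matrix`.
#' @export
env_distance <- function(ord, kind = "environmental") {
  stopifnot(inherits(ord, "ordination"))
  d <- as.matrix(stats::dist(ord$scores))
  diag(d) <- 0
  dist_matrix(d, rownames(ord$scores), kind)
}
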