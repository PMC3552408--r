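#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a null
#' distribution built by simultaneously permuting the rows and columns of the
#' second matrix (the only valid Mantel null). The second matrix is reordered
#' to the first's labels before testing. The p-value carries the +1
#' correction, `p = (#{extreme} + 1) / (n_perm + 1)`, so it is never zero:
#' two-tailed compares `|r_perm| >= |r_obs|`, `"upper"` uses
#' `r_perm >= r_obs`, `"lower"` the reverse.
#'
#' @param a,b `dist_matrix` objects over the same label set.
#' @param n_perm number of permutations.
#' @param tail `"two"`, `"upper"` or `"lower"`.
#' @param seed integer seed making the permutation stream reproducible.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `tail`, `seed`,
#'   `n` (labels).
#' @export
mantel <- function(a, b, n_perm = 10000L, tail = c("two", "upper", "lower"),
                   seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(inherits(a, "dist_matrix"), inherits(b, "dist_matrix"))
  la <- rownames(a); lb <- rownames(b)
  unshared <- c(setdiff(la, lb), setdiff(lb, la))
  if (length(unshared))
    stop_adaptdiff("label mismatch; unshared: ",
                   paste(unique(unshared), collapse = ", "))
  b <- dist_matrix(unclass(b)[la, la], la, dist_kind(b))
  n <- length(la)
  if (n < 4L) stop_adaptdiff("need >= 4 labels for a Mantel test")
  ut <- upper.tri(a)
  x <- a[ut]
  if (stats::sd(x) == 0 || stats::sd(b[ut]) == 0)
    stop_adaptdiff("zero-variance distance triangle; r undefined")
  r_obs <- stats::cor(x, b[ut])
  bm <- unclass(b)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(x, bm[p, p][ut])
    }, 0)
  })
  extreme <- switch(tail,
    two   = abs(r_perm) >= abs(r_obs) - 1e-12,
    upper = r_perm >= r_obs - 1e-12,
    lower = r_perm <= r_obs + 1e-12)
  structure(list(r = r_obs, p = (sum(extreme) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), tail = tail,
                 seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (n = %d, %s-tailed, %d permutations)\n",
              x$n, x$tail, x$n_perm))
  cat(sprintf("  r = %.4f, p = %.4g\n", x$r, x$p))
  invisible(x)
}
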