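#' Family-structured quantitative trait table
#'
#' Individual-level trait observations with population and maternal-family
#' labels, the input to the variance-component and Q_ST machinery. Family
#' labels must be unique within populations (the same label in two populations
#' denotes two different families and is re-coded internally). Missing trait
#' values are allowed and dropped per trait, not per individual.
#'
#' @param df data frame with columns `individual`, `population`, `family` and
#'   one numeric column per trait.
#' @param traits character vector of trait column names; defaults to all
#'   numeric columns besides the id columns.
#' @return a `trait_table` (a validated data frame with a `traits` attribute).
#' @export
trait_table <- function(df, traits = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("individual", "population", "family")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_adaptdiff("trait table lacks column(s): ", paste(miss, collapse = ", "))
  for (cl in need) df[[cl]] <- as.character(df[[cl]])
  if (is.null(traits))
    traits <- names(df)[vapply(df, is.numeric, TRUE)]
  if (!length(traits)) stop_adaptdiff("no numeric trait columns found")
  bad <- setdiff(traits, names(df))
  if (length(bad)) stop_adaptdiff("unknown trait(s): ", paste(bad, collapse = ", "))
  all_missing <- rowSums(!is.na(df[traits])) == 0L
  if (any(all_missing))
    stop_adaptdiff(sum(all_missing),
                   " individual(s) have no non-missing trait value")
  structure(df, traits = traits, class = c("trait_table", "data.frame"))
}

trait_names <- function(tt) attr(tt, "traits")

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d individuals, %d populations, %d trait(s)\n",
              nrow(x), length(unique(x$population)), length(trait_names(x))))
  cat("  traits:", paste(trait_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname trait_table
#' @param path CSV path with header `individual,population,family,<traits...>`.
#' @export
read_traits <- function(path, traits = NULL) {
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE), traits = traits)
}

#' @rdname trait_table
#' @param tt a `trait_table`.
#' @export
write_traits <- function(tt, path) {
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Site environment table
#'
#' One row per site: coordinates (WGS84 decimal degrees), elevation and an
#' identical set of numeric environmental variables across sites.
#'
#' @param df data frame with columns `site`, `latitude`, `longitude`
#'   (optionally `elevation`) plus numeric environment variables.
#' @return a validated `site_env` data frame with a `variables` attribute.
#' @export
site_environment <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("site", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_adaptdiff("site table lacks column(s): ", paste(miss, collapse = ", "))
  df$site <- as.character(df$site)
  if (anyDuplicated(df$site)) stop_adaptdiff("duplicate site names")
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop_adaptdiff("coordinates outside [-90,90] x [-180,180]")
  vars <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                  c("latitude", "longitude"))
  if (anyNA(df[vars]))
    stop_adaptdiff("missing environmental values; impute or drop before use")
  structure(df, variables = vars, class = c("site_env", "data.frame"))
}

env_variables <- function(env) attr(env, "variables")

#' @rdname site_environment
#' @param path CSV path.
#' @export
read_sites <- function(path) {
  site_environment(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Great-circle distances between sites
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km, reported in km.
#'
#' @param env a `site_env` (or any data frame with `site`, `latitude`,
#'   `longitude`).
#' @return a `dist_matrix` of kind `"geographic"`.
#' @export
geographic_distances <- function(env) {
  if (!inherits(env, "site_env")) env <- site_environment(env)
  n <- nrow(env)
  pts <- cbind(env$longitude, env$latitude)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371008.8) / 1000
  d[abs(d) < 1e-12] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dist_matrix(d, env$site, "geographic")
}
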