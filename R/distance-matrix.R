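#' Labelled symmetric distance matrix
#'
#' The universal currency between pipeline stages: a square symmetric numeric
#' matrix with a zero diagonal, unique labels, and a `kind` tag. Geographic
#' matrices must be nonnegative; `kind = "fst"` matrices may hold slightly
#' negative values (a property of the Weir-Cockerham estimator).
#'
#' @param values square numeric matrix (symmetric within `1e-9`, diagonal 0).
#' @param labels character vector of unique site/population names; defaults to
#'   the matrix dimnames.
#' @param kind one of `"geographic"`, `"environmental"`, `"soil"`, `"qst"`,
#'   `"fst"`, `"custom"`.
#' @return an object of class `dist_matrix`: the matrix with dimnames set and
#'   a `kind` attribute.
#' @examples
#' m <- dist_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("a", "b"))
#' dist_values(m)
#' @export
dist_matrix <- function(values, labels = rownames(values), kind = "custom") {
  kind <- match.arg(kind,
    c("geographic", "environmental", "soil", "qst", "fst", "custom"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_adaptdiff("distance matrix must be square, got ",
                   nrow(values), "x", ncol(values))
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop_adaptdiff("length(labels) != nrow(values)")
  if (anyDuplicated(labels))
    stop_adaptdiff("duplicate labels: ",
                   paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!is.numeric(values) || anyNA(values))
    stop_adaptdiff("distance values must be numeric and non-missing")
  if (max(abs(values - t(values))) > 1e-9)
    stop_adaptdiff("matrix asymmetric beyond 1e-9 tolerance")
  values <- (values + t(values)) / 2  # symmetrize within tolerance
  if (any(diag(values) != 0))
    stop_adaptdiff("diagonal must be exactly zero")
  if (kind == "geographic" && any(values < 0))
    stop_adaptdiff("geographic distances must be nonnegative")
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix (kind = %s): %d labels\n",
              attr(x, "kind"), nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname dist_matrix
#' @param m a `dist_matrix`.
#' @export
dist_values <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  m[upper.tri(m)]
}

dist_kind <- function(m) attr(m, "kind")

#' Read / write distance matrices
#'
#' Square labelled CSV (first column = labels, header = labels) or the square
#' PHYLIP dialect (first line n, then label + n values per row).
#'
#' @param path file path.
#' @param kind passed to [dist_matrix()].
#' @param dialect `"csv"` or `"phylip"`.
#' @return [read_distance_matrix()] a `dist_matrix`;
#'   [write_distance_matrix()] `path`, invisibly.
#' @export
read_distance_matrix <- function(path, kind = "custom", dialect = c("csv", "phylip")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_adaptdiff("no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!identical(labels, colnames(vals)))
      stop_adaptdiff("row labels do not match column header in ", path)
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1L]))
    fields <- lapply(lines[1L + seq_len(n)], function(l)
      strsplit(trimws(l), "\\s+")[[1L]])
    labels <- vapply(fields, `[`, "", 1L)
    vals <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(n)))
  }
  storage.mode(vals) <- "double"
  dist_matrix(vals, labels, kind)
}

#' @rdname read_distance_matrix
#' @param m a `dist_matrix`.
#' @export
write_distance_matrix <- function(m, path, dialect = c("csv", "phylip")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "dist_matrix"))
  if (dialect == "csv") {
    df <- data.frame(label = rownames(m), unclass(m), check.names = FALSE)
    names(df)[1L] <- ""
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i],
                         format(m[i, ], digits = 17, trim = TRUE)),
                       collapse = " "), con)
  }
  invisible(path)
}
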