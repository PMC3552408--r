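#' Diploid multi-allelic genotype table
#'
#' Individuals x loci with population labels. Genotypes are unordered pairs of
#' positive-integer allele codes; a cell is either fully typed (two alleles)
#' or fully missing. Microsatellite-style data: allele codes are arbitrary
#' labels (e.g. fragment lengths), loci may carry many alleles.
#'
#' @param individual,population character vectors, one entry per individual.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes per cell; `NA` in both marks a missing genotype. Column names are
#'   locus names.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(individual, population, a1, a2) {
  individual <- as.character(individual)
  population <- as.character(population)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual)
  if (length(population) != n || nrow(a1) != n || nrow(a2) != n ||
      ncol(a1) != ncol(a2))
    stop_adaptdiff("inconsistent genotype table dimensions")
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- paste0("L", seq_len(ncol(a1)))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop_adaptdiff("non-diploid cell(s): one allele present, one missing (",
                   sum(half), " cell(s))")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop_adaptdiff("allele codes must be positive integers")
  structure(list(individual = individual, population = population,
                 a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals, %d loci, %d population(s)\n",
              length(x$individual), ncol(x$a1), length(unique(x$population))))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

locus_names <- function(g) colnames(g$a1)

n_individuals <- function(g) length(g$individual)

#' Subset a genotype table to selected populations
#' @param g a `genotype_table`.
#' @param pops character vector of population labels to keep.
#' @export
subset_populations <- function(g, pops) {
  missing_pops <- setdiff(pops, unique(g$population))
  if (length(missing_pops))
    stop_adaptdiff("population(s) absent from table: ",
                   paste(missing_pops, collapse = ", "))
  keep <- g$population %in% pops
  genotype_table(g$individual[keep], g$population[keep],
                 g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE])
}

## Allele code width handling for GenePop: 2- or 3-digit alleles, so a
## diploid field is 4 or 6 characters; "0000"/"000000" encodes missing.
.parse_genepop_field <- function(field, line_no) {
  w <- nchar(field)
  if (!w %in% c(4L, 6L))
    stop_adaptdiff("line ", line_no, ": genotype field '", field,
                   "' is not 4 or 6 characters")
  half <- w %/% 2L
  a <- suppressWarnings(as.integer(substr(field, 1L, half)))
  b <- suppressWarnings(as.integer(substr(field, half + 1L, w)))
  if (is.na(a) || is.na(b))
    stop_adaptdiff("line ", line_no, ": non-numeric genotype field '", field, "'")
  if (xor(a == 0L, b == 0L))
    stop_adaptdiff("line ", line_no, ": half-missing genotype '", field, "'")
  if (a == 0L) c(NA_integer_, NA_integer_) else c(a, b)
}

#' Read / write genotype tables
#'
#' Two dialects: GenePop (the de-facto standard for microsatellite data;
#' 2- or 3-digit allele codes, `00`/`000` missing, `Pop` separators) and a
#' lossless CSV with one `a/b` column per locus. GenePop carries no explicit
#' population names, so blocks are labelled `pop_1`, `pop_2`, ... in file
#' order unless `pop_labels` is supplied; the CSV dialect round-trips labels
#' exactly.
#'
#' @param path file path.
#' @param dialect `"genepop"` or `"csv"`.
#' @param pop_labels optional population names for GenePop blocks.
#' @return a `genotype_table`.
#' @export
read_genotypes <- function(path, dialect = c("genepop", "csv"),
                           pop_labels = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_adaptdiff("no such file: ", path)
  if (dialect == "csv") return(.read_genotypes_csv(path))
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) < 3L) stop_adaptdiff("file too short for GenePop: ", path)
  lines <- lines[nonblank]
  line_no <- nonblank  # original numbering for error messages
  pop_rows <- which(tolower(trimws(lines)) == "pop")
  if (!length(pop_rows) || pop_rows[1L] < 3L)
    stop_adaptdiff("no 'Pop' separator found where expected")
  # lines 2..(first Pop - 1): locus names, one per line or comma-separated
  loci <- unlist(strsplit(lines[2:(pop_rows[1L] - 1L)], ","))
  loci <- trimws(loci)
  ind <- character(); pop <- character(); rows1 <- list(); rows2 <- list()
  blocks <- Map(function(s, e) if (s > e) integer() else s:e,
                pop_rows + 1L,
                c(pop_rows[-1L] - 1L, length(lines)))
  for (k in seq_along(blocks)) {
    lab <- if (!is.null(pop_labels)) pop_labels[k] else paste0("pop_", k)
    for (i in blocks[[k]]) {
      parts <- strsplit(lines[i], ",")[[1L]]
      if (length(parts) < 2L)
        stop_adaptdiff("line ", line_no[i], ": expected '<id> , genotypes'")
      id <- trimws(parts[1L])
      fields <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
      if (length(fields) != length(loci))
        stop_adaptdiff("line ", line_no[i], ": ", length(fields),
                       " genotype field(s) for ", length(loci), " loci")
      ab <- vapply(fields, .parse_genepop_field, integer(2), line_no = line_no[i])
      ind <- c(ind, id); pop <- c(pop, lab)
      rows1[[length(rows1) + 1L]] <- ab[1L, ]
      rows2[[length(rows2) + 1L]] <- ab[2L, ]
    }
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  colnames(a1) <- colnames(a2) <- loci
  genotype_table(ind, pop, a1, a2)
}

.read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  need <- c("individual", "population")
  if (!all(need %in% names(df)))
    stop_adaptdiff("genotype CSV needs 'individual' and 'population' columns")
  loci <- setdiff(names(df), need)
  if (!length(loci)) stop_adaptdiff("genotype CSV has no locus columns")
  parse_col <- function(col, locus) {
    out <- matrix(NA_integer_, length(col), 2L)
    has <- nzchar(trimws(col))
    if (any(has)) {
      sp <- strsplit(trimws(col[has]), "/", fixed = TRUE)
      bad <- lengths(sp) != 2L
      if (any(bad))
        stop_adaptdiff("locus ", locus, ": malformed genotype '",
                       col[has][bad][1L], "' (expect 'a/b' or empty)")
      out[has, ] <- t(vapply(sp, function(p) as.integer(p), integer(2)))
    }
    out
  }
  parsed <- lapply(loci, function(l) parse_col(df[[l]], l))
  a1 <- do.call(cbind, lapply(parsed, `[`, , 1L))
  a2 <- do.call(cbind, lapply(parsed, `[`, , 2L))
  colnames(a1) <- colnames(a2) <- loci
  genotype_table(df$individual, df$population, a1, a2)
}

#' @rdname read_genotypes
#' @param g a `genotype_table`.
#' @param digits allele-code width for GenePop (2 or 3).
#' @export
write_genotypes <- function(g, path, dialect = c("genepop", "csv"), digits = 3L) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "genotype_table"))
  if (dialect == "csv") {
    cell <- function(a, b) ifelse(is.na(a), "", paste0(a, "/", b))
    df <- data.frame(individual = g$individual, population = g$population,
                     stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_len(ncol(g$a1)))
      df[[locus_names(g)[j]]] <- cell(g$a1[, j], g$a2[, j])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (!digits %in% c(2L, 3L)) stop_adaptdiff("digits must be 2 or 3")
  if (any(g$a1 >= 10^digits, na.rm = TRUE) || any(g$a2 >= 10^digits, na.rm = TRUE))
    stop_adaptdiff("allele codes too wide for ", digits, "-digit GenePop")
  fmt <- function(a) formatC(ifelse(is.na(a), 0L, a), width = digits, flag = "0")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("adaptdiff genotype export", con)
  writeLines(locus_names(g), con)
  for (p in unique(g$population)) {
    writeLines("Pop", con)
    idx <- which(g$population == p)
    for (i in idx)
      writeLines(paste0(g$individual[i], " ,  ",
                        paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}
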