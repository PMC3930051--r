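#' Construct a dominant band presence/absence matrix
#'
#' The central data container: a binary individuals-by-loci matrix of dominant
#' marker phenotypes (band present = 1, absent = 0, `NA` = not scored), with a
#' population label per individual and optional replicate-pair annotations used
#' for genotyping-error estimation.
#'
#' @param x Integer/logical matrix (individuals x loci) with values 0, 1 or
#'   `NA`. Row names are individual ids, column names are locus names; defaults
#'   are generated when absent.
#' @param population Character vector of population labels, one per row of `x`.
#' @param replicate_of Optional character vector naming, for replicated
#'   individuals, the id of the individual they replicate (`NA` elsewhere).
#' @return An object of class `band_matrix`.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 3)
#' band_matrix(m, population = c("A", "A", "B"))
#' @export
band_matrix <- function(x, population, replicate_of = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(!is.na(x) & x != 0L & x != 1L)) {
    abort("band_matrix values must be 0, 1 or NA")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("L", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) abort("duplicate individual ids")
  population <- as.character(population)
  if (length(population) != nrow(x)) {
    abort("`population` must have one label per individual")
  }
  if (is.null(replicate_of)) replicate_of <- rep(NA_character_, nrow(x))
  replicate_of <- as.character(replicate_of)
  if (length(replicate_of) != nrow(x)) {
    abort("`replicate_of` must have one entry per individual")
  }
  if (any(colSums(!is.na(x)) == 0)) {
    abort("every locus needs at least one non-missing entry")
  }
  structure(
    list(x = x, population = population, replicate_of = replicate_of),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf(
    "<band_matrix> %d individuals x %d loci, %d populations, %d replicate pairs\n",
    nrow(x$x), ncol(x$x), length(unique(x$population)),
    sum(!is.na(x$replicate_of))
  ))
  miss <- mean(is.na(x$x))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$x)

populations <- function(m) unique(m$population)

#' Tidy a band matrix into long format
#'
#' @param x A `band_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `individual`, `population`, `locus`, `band`.
#' @export
tidy.band_matrix <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$x), times = ncol(x$x)),
    population = rep(x$population, times = ncol(x$x)),
    locus = rep(colnames(x$x), each = nrow(x$x)),
    band = as.integer(x$x)
  )
}

#' Read a band matrix from a delimited text file
#'
#' Two dialects are supported. `"plain01"` expects a header row
#' (`individual,population[,replicate_of],<locus names...>`) followed by one
#' row per individual. `"genalex"` expects two leading header rows of counts
#' (as produced by common dominant-marker spreadsheet exports) before the same
#' column header. Missing data are encoded by `missing_codes` (default `-9`
#' or an empty cell).
#'
#' @param path File path.
#' @param dialect `"plain01"` or `"genalex"`.
#' @param sep Field separator, default `","`.
#' @param missing_codes Character vector of codes parsed as missing.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path, dialect = c("plain01", "genalex"),
                             sep = ",", missing_codes = c("-9", "")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  skip <- if (dialect == "genalex") 2L else 0L
  if (length(lines) < skip + 2L) abort("file too short to contain a band matrix")
  lines <- lines[(skip + 1L):length(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  has_rep <- length(header) >= 3 && header[3] == "replicate_of"
  meta_cols <- if (has_rep) 3L else 2L
  loci <- header[-seq_len(meta_cols)]
  if (length(loci) == 0) abort("no locus columns found in header")
  rows <- fields[-1]
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad)) {
    abort(sprintf(
      "ragged row at line %d: %d fields, expected %d",
      bad[1] + 1L + skip, nf[bad[1]], length(header)
    ))
  }
  rec <- do.call(rbind, rows)
  ids <- trimws(rec[, 1])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf(
      "duplicate individual id '%s' at line %d", dup,
      which(ids == dup)[2] + 1L + skip
    ))
  }
  vals <- trimws(rec[, -seq_len(meta_cols), drop = FALSE])
  miss <- matrix(vals %in% missing_codes, nrow(vals))
  ok <- miss | matrix(vals %in% c("0", "1"), nrow(vals))
  if (any(!ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "unknown code '%s' at line %d, locus '%s'",
      vals[!ok][1], idx[1] + 1L + skip, loci[idx[2]]
    ))
  }
  x <- matrix(NA_integer_, nrow(vals), ncol(vals),
    dimnames = list(ids, loci)
  )
  x[!miss] <- as.integer(vals[!miss])
  band_matrix(
    x,
    population = trimws(rec[, 2]),
    replicate_of = if (has_rep) {
      r <- trimws(rec[, 3])
      r[r %in% c(missing_codes, "NA")] <- NA_character_
      r
    } else {
      NULL
    }
  )
}

#' Write a band matrix to a delimited text file
#'
#' @param m A [band_matrix()].
#' @param path Output path.
#' @param dialect,sep,missing_code Output format; see [read_band_matrix()].
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path, dialect = c("plain01", "genalex"),
                              sep = ",", missing_code = "-9") {
  dialect <- match.arg(dialect)
  vals <- matrix(as.character(m$x), nrow(m$x))
  vals[is.na(vals)] <- missing_code
  rep_col <- m$replicate_of
  rep_col[is.na(rep_col)] <- ""
  header <- paste(
    c("individual", "population", "replicate_of", colnames(m$x)),
    collapse = sep
  )
  body <- apply(
    cbind(rownames(m$x), m$population, rep_col, vals), 1,
    paste, collapse = sep
  )
  pre <- character(0)
  if (dialect == "genalex") {
    counts <- table(m$population)
    pre <- c(
      paste(c(ncol(m$x), nrow(m$x), length(counts), as.integer(counts)),
        collapse = sep
      ),
      paste(c("", "", names(counts)), collapse = sep)
    )
  }
  writeLines(c(pre, header, body), path)
  invisible(path)
}
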