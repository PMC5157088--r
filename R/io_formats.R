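# Readers/writers for BED, region-string lists and genome tables.
# Gzip is handled transparently for files ending in ".gz" (reading uses a
# gzfile connection, which also accepts plain text).

# Unopened connection: readLines() opens and closes it itself.
open_text <- function(path) {
  gzfile(path)
}

#' Read a BED3+ file
#'
#' Tab-separated, no header; lines starting with `#`, `track` or
#' `browser` and blank lines are skipped. Rows are returned in file
#' order with no sorting; trailing columns beyond the third are carried
#' opaquely as character columns `V4`, `V5`, ... (rows with fewer extras
#' are padded with `NA`, and [write_bed()] restores the original layout).
#'
#' @param path BED file, optionally gzip-compressed (`.gz`).
#' @return data frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path, call. = FALSE)
  lines <- readLines(open_text(path), warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(empty_regions_df())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("BED line ", lineno[which(bad)[1L]],
         ": non-integer coordinates", call. = FALSE)
  }
  bad <- start < 0 | end <= start
  if (any(bad)) {
    stop("BED line ", lineno[which(bad)[1L]],
         ": empty or inverted interval", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  extra_n <- max(nf) - 3L
  if (extra_n > 0L) {
    for (j in seq_len(extra_n)) {
      out[[paste0("V", j + 3L)]] <- vapply(fields, function(f) {
        if (length(f) >= j + 3L) f[[j + 3L]] else NA_character_
      }, "")
    }
  }
  out
}

#' Write a BED file
#'
#' Tab-separated, no header, newline-terminated; extra columns (anything
#' beyond `chrom`/`start`/`end`) are written verbatim, dropping only the
#' `NA` padding introduced by [read_bed()] on ragged input, so
#' `read_bed(write_bed(x))` round-trips.
#'
#' @param x regions: a data frame from [read_bed()], a `region_set`, or a
#'   character vector of region strings.
#' @param path destination; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (is.character(x) || is.factor(x)) x <- as_region_set(x)
  df <- as.data.frame(x)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    f <- vapply(df[i, , drop = FALSE], function(v) {
      if (is.na(v) && is.character(v)) NA_character_ else as.character(v)
    }, "")
    while (length(f) > 3L && is.na(f[length(f)])) f <- f[-length(f)]
    f[is.na(f)] <- "NA"
    paste(f, collapse = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write region-string list files
#'
#' One region per line, UTF-8; `#`-prefixed comment lines and blank lines
#' are ignored.
#'
#' @param path text file, optionally gzip-compressed.
#' @return `read_regions()`: character vector of region strings, in file
#'   order, validated by [parse_regions()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("cannot read regions file: ", path, call. = FALSE)
  lines <- trimws(readLines(open_text(path), warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_regions(lines)          # validation; value discarded
  lines
}

#' @rdname read_regions
#' @param x regions in any accepted form.
#' @export
write_regions <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(format_regions(as_region_set(x)), con)
  invisible(path)
}

#' Read a genome table file
#'
#' Two tab-separated columns, `chrom<TAB>length`, no header (the classic
#' "genome file" dialect).
#'
#' @param path text file.
#' @return a [genome_table()] data frame.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("cannot read genome file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_table(df)
}

#' Convert between region strings and tabular (BED-style) form
#'
#' Pure structural transforms: coordinates are copied verbatim (region
#' strings and BED share the 0-based half-open convention), rows are
#' never reordered, merged or otherwise modified.
#'
#' @param x regions in any accepted form.
#' @param one_based if `TRUE`, export a 1-based *closed* table
#'   (`start + 1`, `end`) for interoperability with closed-interval range
#'   frameworks; clearly non-default.
#' @return `regions_to_table()`: data frame `chrom`, `start`, `end`;
#'   `table_to_regions()`: character vector of region strings in row
#'   order.
#' @examples
#' regions_to_table("chr1:10-100")
#' @export
regions_to_table <- function(x, one_based = FALSE) {
  df <- as.data.frame(as_region_set(x))[c("chrom", "start", "end")]
  if (one_based) df$start <- df$start + 1L
  df
}

#' @rdname regions_to_table
#' @param rows data frame whose first three columns are chrom/start/end.
#' @export
table_to_regions <- function(rows) {
  format_regions(region_set(rows))
}
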