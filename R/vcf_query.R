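# Minimal VCF reading and tabix-style region extraction.
#
# Coordinate boundary, stated once and loudly: VCF positions and tabix
# query strings are 1-based INCLUSIVE — deliberately different from the
# package's native half-open region strings, because that is the
# convention the indexed-retrieval tools use. query_vcf() therefore
# interprets "1:1000-100000" as POS in [1000, 100000].

#' Read a VCF file (minimal 8-column model)
#'
#' Parses the fixed VCF columns CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' INFO; `##` meta lines and the `#CHROM` header are preserved verbatim,
#' `.` values map to `NA`, and INFO is carried as an opaque string.
#' Genotype (FORMAT/sample) columns, if present, are ignored.
#'
#' @param path VCF file, plain or gzip-compressed.
#' @return list with `header` (character, the meta + `#CHROM` lines) and
#'   `records` (data frame with the 8 fixed columns, in file order).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path, call. = FALSE)
  lines <- readLines(open_text(path), warn = FALSE)
  is_meta <- startsWith(lines, "##")
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) == 0L) {
    stop("not a VCF file (no #CHROM header line): ", path, call. = FALSE)
  }
  hdr_i <- hdr_i[1L]
  header <- lines[seq_len(hdr_i)][is_meta[seq_len(hdr_i)] |
                                  seq_len(hdr_i) == hdr_i]
  body <- lines[-seq_len(hdr_i)]
  lineno <- seq_along(lines)[-seq_len(hdr_i)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- lineno[keep]
  if (length(body) == 0L) {
    return(list(header = header, records = empty_vcf_records()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("VCF line ", lineno[which(nf < 8L)[1L]],
         ": fewer than 8 columns", call. = FALSE)
  }
  col <- function(j) vapply(fields, `[[`, "", j)
  pos <- suppressWarnings(as.integer(col(2L)))
  if (any(is.na(pos))) {
    stop("VCF line ", lineno[which(is.na(pos))[1L]],
         ": non-integer POS", call. = FALSE)
  }
  if (any(pos < 1L)) {
    stop("VCF line ", lineno[which(pos < 1L)[1L]],
         ": POS must be >= 1", call. = FALSE)
  }
  ref <- col(4L)
  if (any(!nzchar(ref))) {
    stop("VCF line ", lineno[which(!nzchar(ref))[1L]],
         ": empty REF allele", call. = FALSE)
  }
  dot_na <- function(v) ifelse(v == ".", NA_character_, v)
  records <- data.frame(
    CHROM = col(1L), POS = pos, ID = dot_na(col(3L)), REF = ref,
    ALT = col(5L), QUAL = suppressWarnings(as.numeric(dot_na(col(6L)))),
    FILTER = dot_na(col(7L)), INFO = col(8L), stringsAsFactors = FALSE)
  list(header = header, records = records)
}

empty_vcf_records <- function() {
  data.frame(CHROM = character(), POS = integer(), ID = character(),
             REF = character(), ALT = character(), QUAL = numeric(),
             FILTER = character(), INFO = character(), stringsAsFactors = FALSE)
}

#' Tabix-style region query over a VCF file
#'
#' Returns the records whose chromosome matches and whose POS falls
#' inside a query window. Query strings follow the tabix convention
#' `chrom:start-end` with 1-based inclusive bounds (see the coordinate
#' note in [read_vcf()]); records hit by several overlapping windows are
#' returned once, in file order. The scan is a plain linear filter over
#' the parsed records — exact by construction, no index required.
#'
#' @param region character vector of tabix-convention query strings.
#' @param path VCF file, plain or gzip-compressed.
#' @param check_chr when `TRUE`, query chromosomes lacking the `"chr"`
#'   prefix are rejected before scanning (guards against naming-convention
#'   mismatches between query and file).
#' @return data frame of matching records (same columns as
#'   `read_vcf()$records`).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' synthetic_vcf(vcf)
#' query_vcf("1:1000-100000", vcf)
#' @export
query_vcf <- function(region, path, check_chr = FALSE) {
  q <- parse_tabix_queries(region, check_chr = check_chr)
  rec <- read_vcf(path)$records
  hit <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(q))) {
    hit <- hit | (rec$CHROM == q$chrom[i] &
                  rec$POS >= q$start[i] & rec$POS <= q$end[i])
  }
  rec[hit, , drop = FALSE]
}

parse_tabix_queries <- function(region, check_chr = FALSE) {
  region <- trimws(as.character(region))
  m <- regmatches(region, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", region))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed tabix query (expected 'chrom:start-end', 1-based inclusive): ",
         paste(sQuote(region[bad]), collapse = ", "), call. = FALSE)
  }
  chrom <- vapply(m, `[[`, "", 2L)
  if (check_chr && any(!grepl("^chr", chrom))) {
    stop("query chromosome lacks 'chr' prefix (check_chr is on): ",
         paste(sQuote(unique(chrom[!grepl("^chr", chrom)])), collapse = ", "),
         call. = FALSE)
  }
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end <- as.numeric(vapply(m, `[[`, "", 4L))
  if (any(start < 1 | end < start)) {
    stop("invalid tabix query window (need 1 <= start <= end)", call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Write VCF records back to a file
#'
#' Re-serializes records under a header, mapping `NA` back to `.`.
#'
#' @param vcf list with `header` and `records`, as from [read_vcf()].
#' @param path destination; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path) {
  rec <- vcf$records
  na_dot <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "."
    v
  }
  qual <- ifelse(is.na(rec$QUAL), ".",
                 format(rec$QUAL, trim = TRUE, scientific = FALSE))
  lines <- c(vcf$header,
             if (nrow(rec)) paste(rec$CHROM, rec$POS, na_dot(rec$ID), rec$REF,
                                  rec$ALT, qual, na_dot(rec$FILTER), rec$INFO,
                                  sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
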