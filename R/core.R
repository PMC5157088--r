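#' regionops: native genomic interval algebra
#'
#' Tools for manipulating genomic regions expressed either as compact
#' region strings (`"chr1:10-100"`) or as BED-style tables. All
#' coordinates are 0-based, half-open `[start, end)` — identical to the
#' BED columns — so a region string and a BED row carry the same numbers.
#'
#' The main entry points are [sort_regions()], [merge_regions()],
#' [sort_and_merge()], [join_left()], [multijoin()], [subtract_regions()],
#' [intersect_regions()], [in_region()], [flank_regions()],
#' [coverage_stats()], [venn_counts()] and [query_vcf()]. A command-line
#' interface over the same operations is provided by [run_cli()] and the
#' `regionops` script installed under `inst/cli`.
#'
#' @name regionops-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Region-string codec
# ---------------------------------------------------------------------------

REGION_RE <- "^([^:[:space:]]+):(-?[0-9]+)-(-?[0-9]+)$"

#' Parse region strings into a coordinate table
#'
#' Parses strings of the form `"chrom:start-end"` (0-based, half-open)
#' into a data frame with columns `chrom`, `start`, `end`. The codec is
#' the exact inverse of [format_regions()].
#'
#' @param x character vector of region strings; surrounding whitespace is
#'   ignored.
#' @return data frame with columns `chrom` (character), `start`, `end`
#'   (integer base pairs).
#' @examples
#' parse_regions(c("chr1:10-100", "chr20:1-5"))
#' @export
parse_regions <- function(x) {
  x <- trimws(as.character(x))
  if (length(x) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(x, regexec(REGION_RE, x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region string (expected 'chrom:start-end'): ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  chrom <- vapply(m, `[[`, "", 2L)
  start <- suppressWarnings(as.numeric(vapply(m, `[[`, "", 3L)))
  end   <- suppressWarnings(as.numeric(vapply(m, `[[`, "", 4L)))
  if (any(start < 0 | end < 0)) {
    i <- which(start < 0 | end < 0)
    stop("negative coordinate in region: ",
         paste(sQuote(x[i]), collapse = ", "), call. = FALSE)
  }
  if (any(end <= start)) {
    i <- which(end <= start)
    stop("empty or inverted interval (end must exceed start): ",
         paste(sQuote(x[i]), collapse = ", "), call. = FALSE)
  }
  check_chrom_names(chrom)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Format a coordinate table as region strings
#'
#' @param x a `region_set`, a data frame with `chrom`/`start`/`end`
#'   columns, or a character vector of region strings (returned as-is
#'   after canonicalization).
#' @return character vector `"chrom:start-end"`, no padding.
#' @examples
#' format_regions(data.frame(chrom = "chr2", start = 10, end = 60))
#' @export
format_regions <- function(x) {
  df <- as_region_set(x)
  if (nrow(df) == 0L) return(character())
  sprintf("%s:%d-%d", df$chrom, df$start, df$end)
}

check_chrom_names <- function(chrom) {
  bad <- !nzchar(chrom) | grepl("[[:space:]:-]", chrom)
  if (any(bad)) {
    stop("invalid chromosome name (empty, or contains whitespace/':'/'-'): ",
         paste(sQuote(unique(chrom[bad])), collapse = ", "), call. = FALSE)
  }
  invisible(chrom)
}

# ---------------------------------------------------------------------------
# region_set
# ---------------------------------------------------------------------------

#' Construct a region set
#'
#' A `region_set` is a data frame of half-open intervals (`chrom`,
#' `start`, `end`) carrying three bookkeeping attributes: an optional
#' `label`, the ordering under which it is sorted (`NA`, `"natural"` or
#' `"lexicographic"`), and whether it is merged (no two intervals on one
#' chromosome overlap or touch).
#'
#' @param x character vector of region strings, a data frame whose first
#'   three columns are chrom/start/end, or an existing `region_set`.
#' @param label optional set name.
#' @param sorted ordering flag recorded on the result (internal use).
#' @param merged mergedness flag recorded on the result (internal use).
#' @return a `region_set`.
#' @examples
#' region_set(c("chr1:10-100", "chr2:40-60"), label = "a")
#' @export
region_set <- function(x, label = NULL, sorted = NA_character_, merged = FALSE) {
  if (inherits(x, "region_set")) {
    df <- x
    if (is.null(label)) label <- attr(x, "label")
    if (is.na(sorted)) sorted <- attr(x, "sorted") %||% NA_character_
    if (!isTRUE(merged)) merged <- isTRUE(attr(x, "merged"))
  } else if (is.character(x) || is.factor(x)) {
    df <- parse_regions(as.character(x))
  } else if (is.data.frame(x)) {
    if (ncol(x) < 3L) stop("a regions data frame needs at least 3 columns", call. = FALSE)
    df <- data.frame(chrom = as.character(x[[1L]]),
                     start = as.integer(x[[2L]]),
                     end = as.integer(x[[3L]]),
                     stringsAsFactors = FALSE)
    check_chrom_names(df$chrom)
    if (any(is.na(df$start) | is.na(df$end))) {
      stop("non-integer coordinates in regions table", call. = FALSE)
    }
    if (any(df$start < 0)) stop("negative coordinate in regions table", call. = FALSE)
    if (any(df$end <= df$start)) {
      stop("empty or inverted interval (end must exceed start)", call. = FALSE)
    }
  } else {
    stop("cannot interpret object of class ", sQuote(class(x)[1L]),
         " as a region set", call. = FALSE)
  }
  new_region_set(df[c("chrom", "start", "end")],
                 label = label, sorted = sorted, merged = isTRUE(merged))
}

new_region_set <- function(df, label = NULL, sorted = NA_character_, merged = FALSE) {
  rownames(df) <- NULL
  structure(df, label = label, sorted = sorted, merged = merged,
            class = c("region_set", "data.frame"))
}

#' @rdname region_set
#' @export
as_region_set <- function(x, label = NULL) {
  if (inherits(x, "region_set") && is.null(label)) x else region_set(x, label = label)
}

#' @rdname region_set
#' @export
is_region_set <- function(x) inherits(x, "region_set")

#' @export
as.character.region_set <- function(x, ...) format_regions(x)

#' @export
print.region_set <- function(x, ...) {
  lab <- attr(x, "label")
  srt <- attr(x, "sorted")
  cat(sprintf("region_set%s: %d interval(s)%s%s\n",
              if (!is.null(lab)) paste0(" ", sQuote(lab)) else "",
              nrow(x),
              if (!is.na(srt)) paste0(", sorted (", srt, ")") else "",
              if (isTRUE(attr(x, "merged"))) ", merged" else ""))
  if (nrow(x) > 0L) print(format_regions(x))
  invisible(x)
}

#' Interval widths in base pairs
#' @param x anything [as_region_set()] accepts.
#' @return integer vector of widths (`end - start`).
#' @export
region_width <- function(x) {
  df <- as_region_set(x)
  df$end - df$start
}

# `%||%` in the style of rlang, for attribute defaults
`%||%` <- function(a, b) if (is.null(a)) b else a

# Return the result in the caller's input format: character in, character out
# (the tabular form is always available via as_region_set()).
restore_format <- function(result, input) {
  if (is.character(input) || is.factor(input)) format_regions(result) else result
}

# ---------------------------------------------------------------------------
# Chromosome orderings
# ---------------------------------------------------------------------------

# Sort keys designed so that byte-wise (C locale / radix) comparison of the
# keys realises the intended ordering. Natural keys: strip an optional
# case-insensitive "chr" prefix, tokenize into digit / non-digit runs,
# zero-pad numeric tokens (numeric tokens order before alphabetic at the same
# position), join with \x01, and append \x02 + the original name so distinct
# names never compare equal ("1" and "chr1" stay distinct chromosomes).
chrom_sort_key <- function(names, ordering = c("natural", "lexicographic")) {
  ordering <- match.arg(ordering)
  if (ordering == "lexicographic" || length(names) == 0L) return(names)
  core <- sub("^[Cc][Hh][Rr]", "", names)
  core[!nzchar(core)] <- names[!nzchar(core)]
  toks <- regmatches(core, gregexpr("[0-9]+|[^0-9]+", core))
  keys <- vapply(toks, function(tk) {
    num <- grepl("^[0-9]+$", tk)
    tk[num] <- paste0("0", formatC(as.numeric(tk[num]), width = 20, flag = "0",
                                   format = "d"))
    tk[!num] <- paste0("1", tolower(tk[!num]))
    paste(tk, collapse = "\x01")
  }, "")
  paste0(keys, "\x02", names)
}

#' Compare two chromosome names under an ordering
#'
#' `"natural"` ordering compares embedded integers numerically (chr2 <
#' chr10) after dropping an optional case-insensitive `"chr"` prefix;
#' `"lexicographic"` is plain byte-wise string comparison. Both are total
#' orders; names are never silently normalized, so `"1"` and `"chr1"`
#' remain distinct.
#'
#' @param a,b single chromosome names.
#' @param ordering `"natural"` or `"lexicographic"`.
#' @return -1, 0 or +1 as `a` sorts before, equal to, or after `b`.
#' @examples
#' compare_chromosomes("chr2", "chr10", "natural")        # -1
#' compare_chromosomes("chr2", "chr10", "lexicographic")  # +1
#' @export
compare_chromosomes <- function(a, b, ordering = c("natural", "lexicographic")) {
  ordering <- match.arg(ordering)
  stopifnot(length(a) == 1L, length(b) == 1L, nzchar(a), nzchar(b))
  if (identical(a, b)) return(0L)
  keys <- chrom_sort_key(c(a, b), ordering)
  if (identical(keys[1L], keys[2L])) return(0L)
  ra <- as.integer(charToRaw(keys[1L]))
  rb <- as.integer(charToRaw(keys[2L]))
  n <- min(length(ra), length(rb))
  d <- ra[seq_len(n)] - rb[seq_len(n)]
  i <- which(d != 0L)
  if (length(i)) {
    if (d[i[1L]] < 0L) -1L else 1L
  } else if (length(ra) < length(rb)) -1L else 1L
}

# Permutation ordering rows of `df` by (chromosome key, start, end), stable.
region_order <- function(df, ordering = c("natural", "lexicographic")) {
  ordering <- match.arg(ordering)
  order(chrom_sort_key(df$chrom, ordering), df$start, df$end, method = "radix")
}

# ---------------------------------------------------------------------------
# Genome tables
# ---------------------------------------------------------------------------

#' Construct a genome table (chromosome lengths)
#'
#' @param x a data frame with chrom/length columns, a named numeric vector
#'   of lengths, or an existing genome table.
#' @return data frame with columns `chrom`, `length`; names unique,
#'   lengths strictly positive.
#' @examples
#' genome_table(c(chr1 = 248956422, chr2 = 242193529))
#' @export
genome_table <- function(x) {
  if (is.data.frame(x)) {
    df <- data.frame(chrom = as.character(x[[1L]]), length = as.numeric(x[[2L]]),
                     stringsAsFactors = FALSE)
  } else if (is.numeric(x) && !is.null(names(x))) {
    df <- data.frame(chrom = names(x), length = as.numeric(x),
                     stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret genome table", call. = FALSE)
  }
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome in genome table", call. = FALSE)
  if (any(is.na(df$length) | df$length <= 0)) {
    stop("genome lengths must be strictly positive", call. = FALSE)
  }
  df
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Validate regions against syntax, a genome, and naming conventions
#'
#' Performs side-effect-free validation and returns a per-interval report;
#' content problems are reported as findings, never thrown.
#'
#' @param x character vector of region strings (malformed strings are
#'   flagged, not thrown) or anything [as_region_set()] accepts.
#' @param genome optional [genome_table()]; when given, intervals on
#'   unknown chromosomes or running past the chromosome end are flagged.
#' @param check_chr when `TRUE`, chromosome names lacking the `"chr"`
#'   prefix are flagged.
#' @return data frame with columns `region`, `pass` (logical), `reason`
#'   (`NA` when passing, else a `"; "`-joined list of findings).
#' @examples
#' validate_regions("1:1000-100000", check_chr = TRUE)
#' @export
validate_regions <- function(x, genome = NULL, check_chr = FALSE) {
  if (!is.null(genome)) genome <- genome_table(genome)
  if (length(x) == 0L || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.frame(region = character(), pass = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  if (is.character(x) || is.factor(x)) {
    txt <- trimws(as.character(x))
    rows <- lapply(txt, function(s) {
      df <- tryCatch(parse_regions(s), error = function(e) conditionMessage(e))
      if (is.character(df)) list(region = s, parsed = NULL, reason = df)
      else list(region = s, parsed = df, reason = character())
    })
  } else {
    df <- as_region_set(x)
    rows <- lapply(seq_len(nrow(df)), function(i) {
      list(region = format_regions(df[i, , drop = FALSE]),
           parsed = df[i, , drop = FALSE], reason = character())
    })
  }
  out <- lapply(rows, function(r) {
    reasons <- r$reason
    if (!is.null(r$parsed)) {
      p <- r$parsed
      if (check_chr && !grepl("^chr", p$chrom)) {
        reasons <- c(reasons, "missing chr prefix")
      }
      if (!is.null(genome)) {
        j <- match(p$chrom, genome$chrom)
        if (is.na(j)) {
          reasons <- c(reasons, "unknown chromosome")
        } else if (p$end > genome$length[j]) {
          reasons <- c(reasons, "end exceeds chromosome length")
        }
      }
    }
    data.frame(region = r$region, pass = length(reasons) == 0L,
               reason = if (length(reasons)) paste(reasons, collapse = "; ")
                        else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
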