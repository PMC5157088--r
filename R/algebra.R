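# Interval set algebra. All operations share the BED convention: 0-based
# half-open [start, end). Two intervals overlap iff they share >= 1 base;
# bookended intervals (prev end == next start) do NOT overlap, but DO merge
# at distance 0 when bookend collapsing is on — the two defaults differ
# deliberately, mirroring the conventions of the classic BED engines.

# Operations that need a sort order use the ordering recorded on the input
# if there is one, else lexicographic (byte-wise) chromosome order — the
# order in which the classic engines emit their results.
default_ordering <- function(rs) {
  s <- attr(rs, "sorted")
  if (!is.null(s) && !is.na(s)) s else "lexicographic"
}

# rbind a list of data frames, tolerating NULL elements and empty lists.
rbind_rows <- function(lst, empty) {
  lst <- lst[!vapply(lst, is.null, logical(1L))]
  if (!length(lst)) return(empty)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

empty_regions_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Sort regions
#'
#' Orders intervals by chromosome (under the requested ordering), then by
#' start, then by end; ties keep their input order. Natural ordering
#' compares embedded integers numerically, so chr2 precedes chr10;
#' lexicographic ordering is plain byte-wise, so chr10 precedes chr2.
#'
#' @param x regions: character vector of region strings, data frame, or
#'   [region_set()]. Character input gives character output.
#' @param ordering `"natural"` or `"lexicographic"`.
#' @return sorted regions in the input's format.
#' @examples
#' sort_regions(c("chr10:50-100", "chr2:10-50"), "natural")
#' @export
sort_regions <- function(x, ordering = c("natural", "lexicographic")) {
  ordering <- match.arg(ordering)
  rs <- as_region_set(x)
  out <- new_region_set(rs[region_order(rs, ordering), , drop = FALSE],
                        label = attr(rs, "label"), sorted = ordering,
                        merged = isTRUE(attr(rs, "merged")))
  restore_format(out, x)
}

#' Merge overlapping (and optionally bookended) regions
#'
#' Collapses each maximal run of intervals on one chromosome whose start
#' lies within `distance` bp of the running end into a single interval
#' spanning the run. With `bookend = TRUE` (the default) equality at the
#' boundary merges, so `chr1:101-200` and `chr1:200-210` collapse while a
#' 1-bp gap (`chr1:210-211` missing) keeps neighbours apart.
#'
#' Input is sorted internally if needed; the output is sorted under the
#' input's recorded ordering, lexicographic otherwise.
#'
#' @inheritParams sort_regions
#' @param distance gap tolerance in bp (default 0: only overlap/bookends).
#' @param bookend merge intervals that exactly touch at the `distance`
#'   boundary.
#' @return merged regions in the input's format.
#' @examples
#' merge_regions(c("chr1:101-200", "chr1:200-210"))
#' @export
merge_regions <- function(x, distance = 0, bookend = TRUE) {
  rs <- as_region_set(x)
  ord_mode <- default_ordering(rs)
  df <- rs[region_order(rs, ord_mode), , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) {
    out <- new_region_set(as.data.frame(df), label = attr(rs, "label"),
                          sorted = ord_mode, merged = TRUE)
    return(restore_format(out, x))
  }
  chrom_run <- cumsum(c(TRUE, df$chrom[-1L] != df$chrom[-n]))
  run_end <- stats::ave(df$end, chrom_run, FUN = cummax)
  prev_end <- c(-Inf, run_end[-n])
  new_chrom <- c(TRUE, chrom_run[-1L] != chrom_run[-n])
  breaks <- if (bookend) df$start > prev_end + distance
            else df$start >= prev_end + distance
  grp <- cumsum(new_chrom | breaks)
  out <- data.frame(
    chrom = df$chrom[!duplicated(grp)],
    start = as.integer(tapply(df$start, grp, min)),
    end = as.integer(tapply(df$end, grp, max)),
    stringsAsFactors = FALSE)
  out <- new_region_set(out, label = attr(rs, "label"), sorted = ord_mode,
                        merged = isTRUE(bookend))
  restore_format(out, x)
}

#' Sort and merge in one step
#'
#' Equivalent to `merge_regions(sort_regions(x, "lexicographic"))`, the
#' usual tandem preprocessing step before joins.
#'
#' @inheritParams sort_regions
#' @return sorted, merged regions in the input's format.
#' @export
sort_and_merge <- function(x) {
  rs <- as_region_set(x)
  attr(rs, "sorted") <- NA_character_   # force the lexicographic default
  restore_format(merge_regions(rs), x)
}

# Internal: merged + sorted copy, plus per-chromosome index for fast lookup.
prep_merged <- function(x, label = NULL) {
  rs <- as_region_set(x, label = label)
  if (!isTRUE(attr(rs, "merged")) || is.na(attr(rs, "sorted") %||% NA_character_)) {
    rs <- merge_regions(rs)
    rs <- as_region_set(rs)
  }
  rs
}

split_by_chrom <- function(df) {
  split(seq_len(nrow(df)), df$chrom)
}

# Indices lo:hi of rows in merged/sorted `b` (restricted to rows `idx`)
# overlapping [s, e); returns integer(0) when none. Overlap = share >= 1 bp.
overlap_run <- function(s, e, b_start, b_end) {
  lo <- findInterval(s, b_end) + 1L          # first b with end > s
  hi <- findInterval(e - 1L, b_start)        # last b with start < e
  if (hi >= lo) lo:hi else integer(0)
}

#' Left outer join of two region sets
#'
#' For each interval of `x` (merged and sorted internally), emits one row
#' per overlapping `y` interval — overlap means at least one shared base,
#' so bookended neighbours do not match — or a single sentinel row
#' (`chr = "."`, `start = end = -1`) when nothing in `y` overlaps.
#'
#' @param x,y regions (any form [as_region_set()] accepts); both are
#'   merged internally before joining.
#' @return data frame with columns `index` (the `x` region string),
#'   `chr`, `start`, `end` describing the matching `y` interval, ordered
#'   by `x`'s sort order then `y` start.
#' @examples
#' b <- example_regions()
#' join_left(b$a, b$b)
#' @export
join_left <- function(x, y) {
  a <- prep_merged(x)
  b <- prep_merged(y)
  bidx <- split_by_chrom(b)
  rows <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    ids <- bidx[[a$chrom[i]]]
    hit <- integer(0)
    if (!is.null(ids)) {
      r <- overlap_run(a$start[i], a$end[i], b$start[ids], b$end[ids])
      hit <- ids[r]
    }
    key <- sprintf("%s:%d-%d", a$chrom[i], a$start[i], a$end[i])
    rows[[i]] <- if (length(hit)) {
      data.frame(index = key, chr = b$chrom[hit], start = b$start[hit],
                 end = b$end[hit], stringsAsFactors = FALSE)
    } else {
      data.frame(index = key, chr = ".", start = -1L, end = -1L,
                 stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows, data.frame(index = character(), chr = character(),
                              start = integer(), end = integer(),
                              stringsAsFactors = FALSE))
}

#' Partition several region sets into atomic cells with membership flags
#'
#' Pools the interval endpoints of all (internally merged) sets per
#' chromosome as breakpoints; each pair of consecutive breakpoints is a
#' candidate cell, and cells covered by at least one set are emitted with
#' an overlap count, a comma-joined list of covering set names, and a 0/1
#' truth column per set. Uncovered gaps are never emitted.
#'
#' @param sets list of 2 or more region sets; names become the set labels
#'   (unnamed lists are labelled `a`, `b`, ...).
#' @return data frame with columns `index` (cell region string),
#'   `n.overlaps`, `names`, then one 0/1 column per set label, in
#'   lexicographic chromosome order then start.
#' @examples
#' b <- example_regions()
#' multijoin(list(a = b$a, b = b$b, c = b$c))
#' @export
multijoin <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("multijoin needs a list of at least 2 region sets", call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- letters[seq_along(sets)]
  }
  ms <- lapply(sets, prep_merged)
  chroms <- unique(unlist(lapply(ms, function(m) m$chrom), use.names = FALSE))
  chroms <- chroms[order(chrom_sort_key(chroms, "lexicographic"), method = "radix")]
  per_chrom <- lapply(chroms, function(ch) {
    sub <- lapply(ms, function(m) m[m$chrom == ch, , drop = FALSE])
    bp <- sort(unique(unlist(lapply(sub, function(s) c(s$start, s$end)),
                             use.names = FALSE)))
    if (length(bp) < 2L) return(NULL)
    cs <- bp[-length(bp)]
    ce <- bp[-1L]
    memb <- vapply(sub, function(s) {
      if (nrow(s) == 0L) return(rep(0L, length(cs)))
      k <- findInterval(cs, s$start)   # last interval with start <= cell start
      cov <- logical(length(cs))
      ok <- k > 0L
      cov[ok] <- s$end[k[ok]] >= ce[ok]
      as.integer(cov)
    }, integer(length(cs)))
    memb <- matrix(memb, nrow = length(cs),
                   dimnames = list(NULL, labels))
    keep <- rowSums(memb) >= 1L
    if (!any(keep)) return(NULL)
    data.frame(index = sprintf("%s:%d-%d", ch, cs[keep], ce[keep]),
               n.overlaps = as.integer(rowSums(memb)[keep]),
               names = apply(memb[keep, , drop = FALSE], 1L,
                             function(m) paste(labels[m == 1L], collapse = ",")),
               memb[keep, , drop = FALSE],
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  empty <- data.frame(index = character(), n.overlaps = integer(),
                      names = character(), stringsAsFactors = FALSE)
  for (l in labels) empty[[l]] <- integer()
  rbind_rows(per_chrom, empty)
}

#' Subtract one region set from another
#'
#' `mode = "whole"` (the default) keeps the intervals of `x` that share no
#' base with `y`, intact — intervals with any overlap are dropped
#' entirely. `mode = "partial"` removes the covered bases, returning the
#' base-level set difference `x \\ y` as maximal intervals.
#'
#' @inheritParams join_left
#' @param mode `"whole"` or `"partial"`.
#' @return regions exclusive to `x`, in the input's format.
#' @examples
#' b <- example_regions()
#' subtract_regions(b$a, b$b)
#' @export
subtract_regions <- function(x, y, mode = c("whole", "partial")) {
  mode <- match.arg(mode)
  a <- prep_merged(x)
  b <- prep_merged(y)
  bidx <- split_by_chrom(b)
  if (mode == "whole") {
    hit <- vapply(seq_len(nrow(a)), function(i) {
      ids <- bidx[[a$chrom[i]]]
      if (is.null(ids)) return(FALSE)
      length(overlap_run(a$start[i], a$end[i], b$start[ids], b$end[ids])) > 0L
    }, logical(1L))
    out <- new_region_set(as.data.frame(a)[!hit, , drop = FALSE],
                          label = attr(a, "label"),
                          sorted = attr(a, "sorted"), merged = TRUE)
    return(restore_format(out, x))
  }
  pieces <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    ids <- bidx[[a$chrom[i]]]
    run <- if (is.null(ids)) integer(0)
           else ids[overlap_run(s, e, b$start[ids], b$end[ids])]
    cur <- s
    keep_s <- integer(0); keep_e <- integer(0)
    for (j in run) {
      if (b$start[j] > cur) {
        keep_s <- c(keep_s, cur); keep_e <- c(keep_e, min(b$start[j], e))
      }
      cur <- max(cur, b$end[j])
    }
    if (cur < e) { keep_s <- c(keep_s, cur); keep_e <- c(keep_e, e) }
    if (length(keep_s)) {
      pieces[[i]] <- data.frame(chrom = a$chrom[i], start = keep_s,
                                end = keep_e, stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(pieces, empty_regions_df())
  out <- new_region_set(out, label = attr(a, "label"),
                        sorted = attr(a, "sorted"), merged = TRUE)
  restore_format(out, x)
}

#' Base-level intersection of two region sets
#'
#' Returns the bases covered by both `x` and `y` (merged internally) as
#' maximal intervals, sorted.
#'
#' @inheritParams join_left
#' @return intersected regions in the format of `x`.
#' @examples
#' b <- example_regions()
#' intersect_regions(b$a, b$b)
#' @export
intersect_regions <- function(x, y) {
  a <- prep_merged(x)
  b <- prep_merged(y)
  bidx <- split_by_chrom(b)
  pieces <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    ids <- bidx[[a$chrom[i]]]
    if (is.null(ids)) next
    run <- ids[overlap_run(a$start[i], a$end[i], b$start[ids], b$end[ids])]
    if (length(run)) {
      pieces[[i]] <- data.frame(
        chrom = a$chrom[i],
        start = pmax(a$start[i], b$start[run]),
        end = pmin(a$end[i], b$end[run]),
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(pieces, empty_regions_df())
  out <- new_region_set(out, sorted = attr(a, "sorted"), merged = TRUE)
  restore_format(out, x)
}

#' Test which intervals overlap a region set
#'
#' For each interval of `x` — in the order given, no sorting — reports
#' whether it shares at least one base with any interval of `y`.
#' Consistent with [join_left()]: `TRUE` exactly where the join row for
#' that interval is non-sentinel.
#'
#' @inheritParams join_left
#' @return logical vector, one element per `x` interval.
#' @examples
#' b <- example_regions()
#' in_region(b$a, b$b)
#' @export
in_region <- function(x, y) {
  a <- as_region_set(x)
  b <- prep_merged(y)
  bidx <- split_by_chrom(b)
  vapply(seq_len(nrow(a)), function(i) {
    ids <- bidx[[a$chrom[i]]]
    if (is.null(ids)) return(FALSE)
    length(overlap_run(a$start[i], a$end[i], b$start[ids], b$end[ids])) > 0L
  }, logical(1L))
}

#' Flanking regions
#'
#' For each interval `[s, e)` emits an upstream flank `[s - upstream, s)`
#' and a downstream flank `[e, e + downstream)`, clipped at position 0 and
#' at the chromosome end when a genome table is supplied; flanks that
#' become empty after clipping are dropped. Flanks are returned on their
#' own, sorted, and are deliberately not merged with the source intervals
#' or with each other.
#'
#' @inheritParams sort_regions
#' @param upstream,downstream flank widths in bp (at least one positive).
#' @param genome optional [genome_table()] used for right clipping.
#' @return flank regions in the input's format.
#' @examples
#' flank_regions("chr1:1-10", upstream = 5, downstream = 5)
#' @export
flank_regions <- function(x, upstream = 0, downstream = 0, genome = NULL) {
  if (upstream < 0 || downstream < 0) {
    stop("flank widths must be non-negative", call. = FALSE)
  }
  if (upstream == 0 && downstream == 0) {
    stop("at least one of upstream/downstream must be positive", call. = FALSE)
  }
  rs <- as_region_set(x)
  if (!is.null(genome)) genome <- genome_table(genome)
  up <- down <- NULL
  if (upstream > 0) {
    up <- data.frame(chrom = rs$chrom, start = pmax(rs$start - upstream, 0),
                     end = rs$start, stringsAsFactors = FALSE)
  }
  if (downstream > 0) {
    down <- data.frame(chrom = rs$chrom, start = rs$end,
                       end = rs$end + downstream, stringsAsFactors = FALSE)
  }
  out <- rbind(up, down)
  if (!is.null(genome) && nrow(out) > 0L) {
    len <- genome$length[match(out$chrom, genome$chrom)]
    cap <- ifelse(is.na(len), Inf, len)
    out$start <- pmin(out$start, cap)
    out$end <- pmin(out$end, cap)
  }
  out <- out[out$end > out$start, , drop = FALSE]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  ord_mode <- default_ordering(rs)
  out <- out[region_order(out, ord_mode), , drop = FALSE]
  out <- new_region_set(out, label = attr(rs, "label"), sorted = ord_mode,
                        merged = FALSE)
  restore_format(out, x)
}

#' Coverage statistics of one or two region sets
#'
#' @inheritParams join_left
#' @param y optional second set.
#' @return list with `total_bp` — summed widths of `merge_regions(x)` —
#'   and `shared_bp` — total width of `intersect_regions(x, y)` (`NA`
#'   when `y` is absent).
#' @examples
#' b <- example_regions()
#' coverage_stats(b$a, b$b)
#' @export
coverage_stats <- function(x, y = NULL) {
  a <- prep_merged(x)
  total <- sum(region_width(a))
  shared <- NA_real_
  if (!is.null(y)) {
    shared <- sum(region_width(as_region_set(intersect_regions(a, y))))
  }
  list(total_bp = as.numeric(total), shared_bp = as.numeric(shared))
}
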