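# Multi-set overlap quantification: the count tables behind 2- to 5-way
# Venn diagrams. Rendering is deliberately left to downstream tools
# (VennDiagram/UpSet-style plotters consume the serialized table).

#' Quantify overlaps among 2-5 region sets
#'
#' Two counting modes over the same partition of the union:
#' \describe{
#'   \item{`feature = "bp"`}{runs [multijoin()] and sums cell widths per
#'     membership signature. The amounts are mutually exclusive and sum
#'     to the width of the union of all sets.}
#'   \item{`feature = "interval"`}{partitions the union into maximal
#'     atomic intervals (the merge of all sets pooled) and assigns an
#'     atomic interval to set S when S covers at least `fraction` of its
#'     width; atomic intervals are counted per signature. Raising
#'     `fraction` can only shrink signatures; atoms whose every coverage
#'     falls below the threshold are dropped.}
#' }
#' `fraction` applies to interval mode only.
#'
#' @param sets named list of 2 to 5 region sets (unnamed lists are
#'   labelled `a`, `b`, ...).
#' @param feature `"bp"` or `"interval"`.
#' @param fraction minimum covered fraction of an atomic interval for
#'   set membership, in (0, 1]; the default `1e-9` makes any shared base
#'   count.
#' @return an `overlap_summary`: list with `labels`, `feature`,
#'   `fraction`, and `counts` — a named numeric vector keyed by
#'   comma-joined membership signature (e.g. `"a"`, `"a,b"`).
#' @examples
#' b <- example_regions()
#' venn_counts(list(a = b$a, b = b$b), feature = "bp")
#' @export
venn_counts <- function(sets, feature = c("bp", "interval"), fraction = 1e-9) {
  feature <- match.arg(feature)
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 5L) {
    stop("venn_counts needs between 2 and 5 region sets", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) labels <- letters[seq_along(sets)]
  names(sets) <- labels
  if (feature == "bp") {
    cells <- multijoin(sets)
    p <- parse_regions(cells$index)
    w <- p$end - p$start
    amounts <- tapply(w, cells$names, sum)
    counts <- as.numeric(amounts)
    names(counts) <- names(amounts)
  } else {
    ms <- lapply(sets, prep_merged)
    pooled <- rbind_rows(lapply(ms, as.data.frame), empty_regions_df())
    atoms <- as_region_set(merge_regions(region_set(pooled)))
    sig <- character(nrow(atoms))
    for (i in seq_len(nrow(atoms))) {
      width <- atoms$end[i] - atoms$start[i]
      memb <- vapply(ms, function(s) {
        sub <- s[s$chrom == atoms$chrom[i], , drop = FALSE]
        if (nrow(sub) == 0L) return(FALSE)
        run <- overlap_run(atoms$start[i], atoms$end[i], sub$start, sub$end)
        if (!length(run)) return(FALSE)
        cov <- sum(pmin(atoms$end[i], sub$end[run]) -
                   pmax(atoms$start[i], sub$start[run]))
        cov >= fraction * width
      }, logical(1L))
      sig[i] <- paste(labels[memb], collapse = ",")
    }
    sig <- sig[nzchar(sig)]
    tab <- table(sig)
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
  }
  structure(list(labels = labels, feature = feature, fraction = fraction,
                 counts = counts),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary: %d sets (%s), feature=%s%s\n",
              length(x$labels), paste(x$labels, collapse = ","), x$feature,
              if (x$feature == "interval")
                sprintf(", fraction=%g", x$fraction) else ""))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.overlap_summary <- function(x, ...) {
  data.frame(signature = names(x$counts), amount = as.numeric(x$counts),
             stringsAsFactors = FALSE)
}

#' Serialize an overlap summary
#'
#' Tab-separated `signature<TAB>amount` rows under a
#' `# feature=<mode> fraction=<f>` comment header, or the same fields as
#' JSON.
#'
#' @param x an `overlap_summary` from [venn_counts()].
#' @param path destination file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_overlap_summary <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c(sprintf("# feature=%s fraction=%g", x$feature, x$fraction),
               paste(names(x$counts), x$counts, sep = "\t"))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(labels = x$labels, feature = x$feature, fraction = x$fraction,
           counts = as.list(x$counts)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
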