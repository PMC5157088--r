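# Independent base-enumeration oracles: represent each chromosome of a
# small coordinate universe as a per-base coverage mask and derive every
# operation from the masks. Deliberately naive — these never share code
# with the sweep-line implementations they check.

oracle_chroms <- c(chrA = 10000, chrB = 10000)

# the mask universe also covers the worked-example chromosomes
oracle_universe <- c(oracle_chroms,
                     c(chr1 = 10000, chr2 = 10000, chr10 = 10000,
                       chr20 = 10000))

as_df <- function(x) {
  df <- as.data.frame(regionops::as_region_set(x))[c("chrom", "start", "end")]
  rownames(df) <- NULL
  df
}

# logical mask per chromosome; base i (1-based) covers [i-1, i)
cov_mask <- function(x, chroms = oracle_universe) {
  df <- as_df(x)
  m <- lapply(chroms, function(size) logical(size))
  for (i in seq_len(nrow(df))) {
    m[[df$chrom[i]]][(df$start[i] + 1L):df$end[i]] <- TRUE
  }
  m
}

mask_to_df <- function(m) {
  out <- lapply(sort(names(m), method = "radix"), function(ch) {
    r <- rle(m[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = as.integer(starts[keep]),
               end = as.integer(ends[keep]), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

oracle_merge <- function(x) mask_to_df(cov_mask(x))

oracle_intersect <- function(x, y) {
  mx <- cov_mask(x); my <- cov_mask(y)
  mask_to_df(Map(`&`, mx, my))
}

oracle_subtract_partial <- function(x, y) {
  mx <- cov_mask(x); my <- cov_mask(y)
  mask_to_df(Map(function(a, b) a & !b, mx, my))
}

oracle_union_bp <- function(...) {
  ms <- lapply(list(...), cov_mask)
  m <- Reduce(function(a, b) Map(`|`, a, b), ms)
  sum(vapply(m, sum, 0))
}

oracle_shared_bp <- function(x, y) {
  sum(vapply(Map(`&`, cov_mask(x), cov_mask(y)), sum, 0))
}

oracle_total_bp <- function(x) sum(vapply(cov_mask(x), sum, 0))

# per-interval overlap test against the mask of y
oracle_in_region <- function(x, y) {
  df <- as_df(x)
  my <- cov_mask(y)
  vapply(seq_len(nrow(df)), function(i) {
    any(my[[df$chrom[i]]][(df$start[i] + 1L):df$end[i]])
  }, logical(1))
}

# check that a cell [start, end) is fully covered by set mask
oracle_cell_covered <- function(mask, chrom, start, end) {
  all(mask[[chrom]][(start + 1L):end])
}

random_pair <- function(seed, n_a = 20, n_b = 15, widths = c(1, 300)) {
  list(a = regionops::random_regions(n_a, oracle_chroms, widths, seed = seed),
       b = regionops::random_regions(n_b, oracle_chroms, widths,
                                     seed = seed + 100000L))
}
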