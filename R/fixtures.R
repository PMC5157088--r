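# Built-in example data: the classic three overlapping demonstration
# region sets on chr1/chr2/chr10/chr20 used throughout the documentation
# and tests, a COSMIC-like synthetic VCF excerpt, and a seeded random
# region generator for property-style testing. Everything here is
# deterministic and constructed in code — no downloads.

#' Example region sets
#'
#' Returns a bundle of small demonstration sets:
#' \describe{
#'   \item{`raw`}{eight unsorted, partially overlapping region strings on
#'     chr1, chr2, chr10 and chr20 (the merge demonstration input).}
#'   \item{`a`}{`merge_regions(raw)` — six disjoint regions, labelled `a`.}
#'   \item{`b`, `c`}{two further merged sets overlapping `a` in
#'     instructive ways (sentinel join rows, bookends, nested overlap).}
#'   \item{`genome`}{a [genome_table()] for the four chromosomes (hg38
#'     lengths), for flank clipping and validation examples.}
#' }
#'
#' @return named list with elements `raw`, `a`, `b`, `c` (character
#'   vectors of region strings, the package's vector currency) and
#'   `genome`.
#' @examples
#' ex <- example_regions()
#' merge_regions(ex$raw)
#' @export
example_regions <- function() {
  raw <- c("chr1:200-210", "chr2:40-60", "chr20:1-5", "chr1:10-100",
           "chr10:50-100", "chr1:101-200", "chr1:211-212", "chr2:10-50")
  a <- merge_regions(raw)
  b <- merge_regions(c("chr1:1-10", "chr1:111-250", "chr1:2000-2010",
                       "chr2:1-5", "chr2:40-60", "chr10:100-150", "chr20:6-10"))
  cc <- merge_regions(c("chr1:1-10", "chr1:20-240", "chr2:1-20", "chr2:30-60",
                        "chr10:110-150", "chr20:7-12"))
  genome <- genome_table(c(chr1 = 248956422, chr2 = 242193529,
                           chr10 = 133797422, chr20 = 64444167))
  list(raw = raw, a = a, b = b, c = cc, genome = genome)
}

#' Seeded random region sets
#'
#' Generates `n` intervals with chromosomes drawn uniformly from
#' `chroms`, widths uniform in `width_range`, and starts uniform over
#' each chromosome (intervals are placed entirely inside the chromosome,
#' with widths clipped to the chromosome length). The caller's RNG state
#' is left untouched; a fixed `seed` reproduces the same set.
#'
#' @param n number of intervals (>= 0).
#' @param chroms named numeric vector or [genome_table()] of chromosome
#'   lengths.
#' @param width_range length-2 integer vector, minimum and maximum width
#'   in bp (minimum >= 1).
#' @param seed integer seed.
#' @return a `region_set`.
#' @examples
#' random_regions(5, c(chr1 = 1000, chr2 = 500), c(10, 50), seed = 1)
#' @export
random_regions <- function(n, chroms, width_range = c(1, 100), seed) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (length(width_range) != 2L || width_range[1L] < 1 ||
      width_range[2L] < width_range[1L]) {
    stop("width_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  g <- genome_table(chroms)
  if (n == 0L) return(new_region_set(empty_regions_df()))
  df <- with_preserved_seed(seed, {
    ci <- sample.int(nrow(g), n, replace = TRUE)
    w <- sample(seq.int(width_range[1L], width_range[2L]), n, replace = TRUE)
    len <- g$length[ci]
    w <- pmin(w, len)
    start <- floor(stats::runif(n, min = 0, max = len - w + 1))
    start <- pmin(start, len - w)        # guard the max = len - w + 1 edge
    data.frame(chrom = g$chrom[ci], start = as.integer(start),
               end = as.integer(start + w), stringsAsFactors = FALSE)
  })
  region_set(df)
}

# Run code under set.seed(seed) and restore the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthetic COSMIC-like VCF fixture
#'
#' Writes a small VCF of coding mutations on chromosome 1 (plus one
#' chromosome-2 decoy): six OR4F5 records at positions 69345-69569
#' inside the window 1:1000-100000, and deterministic `SYNDECOY` records
#' placed outside that window and inside/outside 1:1000000-1100000, so
#' region queries have known exact answers. Entirely synthetic — IDs and
#' annotations imitate the COSMIC column layout, nothing is downloaded.
#' A pre-materialized copy ships as
#' `system.file("extdata", "cosmic_synthetic.vcf", package = "regionops")`.
#'
#' @param path destination; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @examples
#' p <- synthetic_vcf(tempfile(fileext = ".vcf"))
#' nrow(query_vcf("1:1000-100000", p))  # 6
#' @export
synthetic_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(synthetic_vcf_lines(), con)
  invisible(path)
}

synthetic_vcf_lines <- function() {
  rec <- function(chrom, pos, id, ref, alt, info) {
    paste(chrom, pos, id, ref, alt, ".", ".", info, sep = "\t")
  }
  c("##fileformat=VCFv4.1",
    "##source=regionops synthetic fixture (COSMIC-like layout; not real data)",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene name\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Coding strand\">",
    "##INFO=<ID=CDS,Number=1,Type=String,Description=\"CDS annotation\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Peptide annotation\">",
    "##INFO=<ID=CNT,Number=1,Type=Integer,Description=\"Sample count\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    rec(1, 500, "SYNDECOY001", "A", "C",
        "GENE=SYNGENE1;STRAND=+;CDS=c.1A>C;AA=p.T1P;CNT=1"),
    rec(1, 69345, "COSM911918", "C", "A",
        "GENE=OR4F5;STRAND=+;CDS=c.255C>A;AA=p.I85I;CNT=1"),
    rec(1, 69523, "COSM426644", "G", "T",
        "GENE=OR4F5;STRAND=+;CDS=c.433G>T;AA=p.G145C;CNT=1"),
    rec(1, 69538, "COSM75742", "G", "A",
        "GENE=OR4F5;STRAND=+;CDS=c.448G>A;AA=p.V150M;CNT=1"),
    rec(1, 69539, "COSM1343690", "T", "C",
        "GENE=OR4F5;STRAND=+;CDS=c.449T>C;AA=p.V150A;CNT=1"),
    rec(1, 69540, "COSM1560546", "G", "T",
        "GENE=OR4F5;STRAND=+;CDS=c.450G>T;AA=p.V150V;CNT=1"),
    rec(1, 69569, "COSM1599955", "T", "C",
        "GENE=OR4F5;STRAND=+;CDS=c.479T>C;AA=p.L160P;CNT=2"),
    rec(1, 150000, "SYNDECOY002", "G", "A",
        "GENE=SYNGENE2;STRAND=-;CDS=c.90G>A;AA=p.M30I;CNT=1"),
    rec(1, 999999, "SYNDECOY003", "T", "G",
        "GENE=SYNGENE3;STRAND=+;CDS=c.12T>G;AA=p.S4A;CNT=3"),
    rec(1, 1000500, "SYNDECOY004", "C", "T",
        "GENE=SYNGENE4;STRAND=+;CDS=c.33C>T;AA=p.D11D;CNT=1"),
    rec(1, 1050000, "SYNDECOY005", "A", "G",
        "GENE=SYNGENE4;STRAND=+;CDS=c.101A>G;AA=p.K34R;CNT=2"),
    rec(1, 1100000, "SYNDECOY006", "G", "C",
        "GENE=SYNGENE5;STRAND=-;CDS=c.7G>C;AA=p.A3P;CNT=1"),
    rec(1, 1200000, "SYNDECOY007", "T", "A",
        "GENE=SYNGENE6;STRAND=+;CDS=c.55T>A;AA=p.F19I;CNT=1"),
    rec(2, 5000, "SYNDECOY008", "C", "G",
        "GENE=SYNGENE7;STRAND=+;CDS=c.14C>G;AA=p.P5R;CNT=1"))
}
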