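# Frozen expected outputs for the worked example sets (see
# example_regions()): the canonical sort/merge/join/partition results
# that the demonstration sets were designed to produce.

expected_sort_natural <- c(
  "chr1:10-100", "chr1:101-200", "chr1:200-210", "chr1:211-212",
  "chr2:10-50", "chr2:40-60", "chr10:50-100", "chr20:1-5")

expected_sort_lex <- c(
  "chr1:10-100", "chr1:101-200", "chr1:200-210", "chr1:211-212",
  "chr10:50-100", "chr2:10-50", "chr2:40-60", "chr20:1-5")

expected_merged <- c(
  "chr1:10-100", "chr1:101-210", "chr1:211-212", "chr10:50-100",
  "chr2:10-60", "chr20:1-5")

expected_join_ab <- data.frame(
  index = c("chr1:10-100", "chr1:101-210", "chr1:211-212", "chr10:50-100",
            "chr2:10-60", "chr20:1-5"),
  chr = c(".", "chr1", "chr1", ".", "chr2", "."),
  start = c(-1L, 111L, 111L, -1L, 40L, -1L),
  end = c(-1L, 250L, 250L, -1L, 60L, -1L),
  stringsAsFactors = FALSE)

expected_multijoin_abc <- local({
  txt <- c(
    "chr1:1-10      2 b,c   0 1 1",
    "chr1:10-20     1 a     1 0 0",
    "chr1:20-100    2 a,c   1 0 1",
    "chr1:100-101   1 c     0 0 1",
    "chr1:101-111   2 a,c   1 0 1",
    "chr1:111-210   3 a,b,c 1 1 1",
    "chr1:210-211   2 b,c   0 1 1",
    "chr1:211-212   3 a,b,c 1 1 1",
    "chr1:212-240   2 b,c   0 1 1",
    "chr1:240-250   1 b     0 1 0",
    "chr1:2000-2010 1 b     0 1 0",
    "chr10:50-100   1 a     1 0 0",
    "chr10:100-110  1 b     0 1 0",
    "chr10:110-150  2 b,c   0 1 1",
    "chr2:1-5       2 b,c   0 1 1",
    "chr2:5-10      1 c     0 0 1",
    "chr2:10-20     2 a,c   1 0 1",
    "chr2:20-30     1 a     1 0 0",
    "chr2:30-40     2 a,c   1 0 1",
    "chr2:40-60     3 a,b,c 1 1 1",
    "chr20:1-5      1 a     1 0 0",
    "chr20:6-7      1 b     0 1 0",
    "chr20:7-10     2 b,c   0 1 1",
    "chr20:10-12    1 c     0 0 1")
  df <- read.table(text = txt, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("index", "n.overlaps", "names", "a", "b", "c"),
                   check.names = FALSE)
  df$n.overlaps <- as.integer(df$n.overlaps)
  df$a <- as.integer(df$a); df$b <- as.integer(df$b); df$c <- as.integer(df$c)
  df
})

expected_subtract_whole <- c("chr1:10-100", "chr10:50-100", "chr20:1-5")
expected_in_region <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
expected_intersect_ab <- c("chr1:111-210", "chr1:211-212", "chr2:40-60")

expected_cosmic_hits <- data.frame(
  CHROM = rep("1", 6),
  POS = c(69345L, 69523L, 69538L, 69539L, 69540L, 69569L),
  ID = c("COSM911918", "COSM426644", "COSM75742", "COSM1343690",
         "COSM1560546", "COSM1599955"),
  REF = c("C", "G", "G", "T", "G", "T"),
  ALT = c("A", "T", "A", "C", "T", "C"),
  QUAL = rep(NA_real_, 6),
  FILTER = rep(NA_character_, 6),
  INFO = c("GENE=OR4F5;STRAND=+;CDS=c.255C>A;AA=p.I85I;CNT=1",
           "GENE=OR4F5;STRAND=+;CDS=c.433G>T;AA=p.G145C;CNT=1",
           "GENE=OR4F5;STRAND=+;CDS=c.448G>A;AA=p.V150M;CNT=1",
           "GENE=OR4F5;STRAND=+;CDS=c.449T>C;AA=p.V150A;CNT=1",
           "GENE=OR4F5;STRAND=+;CDS=c.450G>T;AA=p.V150V;CNT=1",
           "GENE=OR4F5;STRAND=+;CDS=c.479T>C;AA=p.L160P;CNT=2"),
  stringsAsFactors = FALSE)

# strip region_set attributes / rownames for plain comparisons
plain <- function(x) {
  df <- as.data.frame(x)
  rownames(df) <- NULL
  attr(df, "label") <- NULL
  attr(df, "sorted") <- NULL
  attr(df, "merged") <- NULL
  class(df) <- "data.frame"
  df
}
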