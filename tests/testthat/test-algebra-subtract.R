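ex <- example_regions()

test_that("whole-interval subtraction keeps untouched intervals intact", {
  expect_equal(subtract_regions(ex$a, ex$b), expected_subtract_whole)
  expect_equal(subtract_regions(ex$a, ex$b, mode = "whole"),
               expected_subtract_whole)
  expect_equal(subtract_regions(ex$raw, character()), expected_merged)
})

test_that("partial subtraction removes covered bases only", {
  expect_equal(subtract_regions(ex$a, ex$b, mode = "partial"),
               c("chr1:10-100", "chr1:101-111", "chr10:50-100",
                 "chr2:10-40", "chr20:1-5"))
  expect_equal(subtract_regions(ex$raw, character(), mode = "partial"),
               expected_merged)
  # subtracting a superset leaves nothing
  expect_equal(subtract_regions(ex$a, ex$a, mode = "partial"), character())
  for (seed in 1:20) {
    p <- random_pair(seed)
    expect_equal(plain(subtract_regions(p$a, p$b, mode = "partial")),
                 oracle_subtract_partial(p$a, p$b))
  }
})

test_that("whole mode partitions merged a into exclusive and joined", {
  for (seed in 1:15) {
    p <- random_pair(seed + 40)
    am <- format_regions(merge_regions(p$a))
    excl <- subtract_regions(am, p$b)
    hit <- am[in_region(am, p$b)]
    expect_equal(sort(c(excl, hit)), sort(am))
    expect_length(intersect(excl, hit), 0L)
  }
})

test_that("intersection returns the shared bases as maximal intervals", {
  expect_equal(intersect_regions(ex$a, ex$b), expected_intersect_ab)
  expect_equal(intersect_regions(ex$a, ex$a), expected_merged)
  expect_equal(intersect_regions(ex$a, character()), character())
  for (seed in 1:20) {
    p <- random_pair(seed + 70)
    expect_equal(plain(intersect_regions(p$a, p$b)),
                 oracle_intersect(p$a, p$b))
  }
})

test_that("intersection agrees with GenomicRanges on random sets", {
  suppressPackageStartupMessages({
    requireNamespace("GenomicRanges")
    requireNamespace("IRanges")
  })
  for (seed in c(5, 23)) {
    p <- random_pair(seed, n_a = 40, n_b = 40)
    as_gr <- function(x) {
      df <- as.data.frame(x)
      GenomicRanges::reduce(GenomicRanges::GRanges(
        factor(df$chrom, levels = names(oracle_chroms)),
        IRanges::IRanges(df$start + 1L, df$end)))
    }
    ref <- GenomicRanges::intersect(as_gr(p$a), as_gr(p$b))
    got <- plain(intersect_regions(p$a, p$b))
    ord <- order(as.character(GenomicRanges::seqnames(ref)),
                 GenomicRanges::start(ref), method = "radix")
    expect_equal(got$start, GenomicRanges::start(ref)[ord] - 1L)
    expect_equal(got$end, GenomicRanges::end(ref)[ord])
  }
})

test_that("base conservation: partial subtraction plus overlap restores a", {
  for (seed in 1:20) {
    p <- random_pair(seed + 200)
    st <- coverage_stats(p$a, p$b)
    part <- coverage_stats(subtract_regions(p$a, p$b, mode = "partial"))
    expect_equal(part$total_bp + st$shared_bp, st$total_bp)
  }
})

test_that("coverage statistics match the worked example", {
  st <- coverage_stats(ex$a, ex$b)
  expect_equal(st$total_bp, 304)
  expect_equal(st$shared_bp, 120)
  expect_equal(st$shared_bp, oracle_shared_bp(ex$a, ex$b))
  expect_equal(coverage_stats(character())$total_bp, 0)
  expect_true(is.na(coverage_stats(ex$a)$shared_bp))
})

test_that("flanks are emitted per side, clipped, and never merged", {
  fl <- flank_regions(ex$b, upstream = 5, downstream = 5)
  # clipping at position zero shortens the first up-flank
  expect_true("chr1:0-1" %in% fl)
  expect_true("chr1:10-15" %in% fl)
  expect_length(fl, 14)       # 7 intervals x 2 sides, none dropped
  expect_true(all(region_width(fl) <= 5))

  only_down <- flank_regions(ex$b, upstream = 0, downstream = 5)
  expect_length(only_down, 7)
  expect_equal(sum(parse_regions(only_down)$start %in%
                   parse_regions(ex$b)$end), 7L)

  # genome clipping: flank running past the chromosome end is trimmed,
  # and a flank fully outside is dropped
  g <- genome_table(c(chr9 = 100))
  expect_equal(flank_regions("chr9:90-100", 0, 20, genome = g), character())
  expect_equal(flank_regions("chr9:80-95", 0, 20, genome = g), "chr9:95-100")
  expect_equal(flank_regions("chr9:0-10", 5, 0, genome = g), character())

  # exact width when no clipping applies
  fl2 <- flank_regions("chr5:100-200", upstream = 7, downstream = 3)
  expect_equal(fl2, c("chr5:93-100", "chr5:200-203"))
  expect_error(flank_regions(ex$b, 0, 0), "at least one")
})
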