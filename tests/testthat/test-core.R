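test_that("region-string codec parses and round-trips", {
  df <- parse_regions(c("chr1:10-100", "chr20:1-5"))
  expect_equal(df$chrom, c("chr1", "chr20"))
  expect_equal(df$start, c(10L, 1L))
  expect_equal(df$end, c(100L, 5L))
  expect_equal(format_regions(data.frame(chrom = "chr2", start = 10, end = 60)),
               "chr2:10-60")
  expect_equal(format_regions(parse_regions(" chr10:50-100 ")), "chr10:50-100")

  rs <- random_regions(1000, c(chr1 = 1e6, chr2 = 5e5, chrX = 2e5),
                       c(1, 5000), seed = 42)
  expect_identical(plain(region_set(format_regions(rs))), plain(rs))

  expect_equal(parse_regions(character()),
               data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
})

test_that("codec rejects malformed, empty and negative regions distinctly", {
  expect_error(parse_regions("chr1_10_100"), "malformed")
  expect_error(parse_regions("chr1:10"), "malformed")
  expect_error(parse_regions("chr1:100-100"), "empty or inverted")
  expect_error(parse_regions("chr1:100-10"), "empty or inverted")
  expect_error(parse_regions("chr1:-5-10"), "negative")
  expect_error(region_set(data.frame(chrom = "a b", start = 1, end = 2)),
               "chromosome name")
})

test_that("chromosome comparisons implement natural and lexicographic order", {
  expect_equal(compare_chromosomes("chr2", "chr10", "natural"), -1L)
  expect_equal(compare_chromosomes("chr10", "chr2", "natural"), 1L)
  expect_equal(compare_chromosomes("chr10", "chr2", "lexicographic"), -1L)
  for (nm in c("chr1", "chrX", "1", "scaffold_12")) {
    expect_equal(compare_chromosomes(nm, nm, "natural"), 0L)
    expect_equal(compare_chromosomes(nm, nm, "lexicographic"), 0L)
  }
  # numbered chromosomes precede the alphabetic ones; M < X < Y
  nat <- c("chr1", "chr2", "chr10", "chr22", "chrM", "chrX", "chrY")
  shuffled <- nat[c(5, 2, 7, 1, 4, 6, 3)]
  key <- regionops:::chrom_sort_key(shuffled, "natural")
  expect_equal(shuffled[order(key, method = "radix")], nat)
  # no silent prefix normalization: "1" and "chr1" stay distinct
  expect_true(compare_chromosomes("1", "chr1", "natural") != 0L)
})

test_that("both orderings are total orders on random name sets", {
  set.seed(7)
  for (rep in 1:20) {
    names <- unique(replicate(12, paste0(
      sample(c("chr", "ctg", ""), 1),
      paste(sample(c(letters[1:4], 0:9), sample(1:5, 1), replace = TRUE),
            collapse = ""))))
    names <- names[nzchar(names)]
    for (ord in c("natural", "lexicographic")) {
      cmp <- function(x, y) compare_chromosomes(x, y, ord)
      # antisymmetry and determinism
      for (i in seq_along(names)) for (j in seq_along(names)) {
        expect_equal(cmp(names[i], names[j]), -cmp(names[j], names[i]))
      }
      # permutation invariance of the induced sort
      key1 <- regionops:::chrom_sort_key(names, ord)
      perm <- sample(seq_along(names))
      key2 <- regionops:::chrom_sort_key(names[perm], ord)
      expect_equal(names[perm][order(key2, method = "radix")],
                   names[order(key1, method = "radix")])
    }
  }
})

test_that("validate_regions reports findings without throwing", {
  rep1 <- validate_regions("1:1000-100000", check_chr = TRUE)
  expect_false(rep1$pass)
  expect_match(rep1$reason, "missing chr prefix")

  g <- genome_table(c(chr1 = 248956422))
  expect_true(validate_regions("chr1:10-100", genome = g)$pass)
  rep2 <- validate_regions("chr9:10-100", genome = g)
  expect_match(rep2$reason, "unknown chromosome")
  rep3 <- validate_regions("chr1:10-948956422", genome = g)
  expect_match(rep3$reason, "exceeds chromosome length")

  # content errors are findings, not conditions
  rep4 <- validate_regions(c("not-a-region", "chr1:5-2", "chr1:1-10"))
  expect_equal(rep4$pass, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(validate_regions(character())), 0L)
})

test_that("genome tables enforce unique names and positive lengths", {
  expect_error(genome_table(c(chr1 = 10, chr1 = 20)), "duplicate")
  expect_error(genome_table(c(chr1 = 0)), "positive")
  g <- genome_table(data.frame(chrom = "chr1", length = 100))
  expect_equal(g$length, 100)
})

test_that("region_set tracks label, sortedness and mergedness", {
  rs <- region_set(c("chr2:5-9", "chr1:1-4"), label = "demo")
  expect_true(is_region_set(rs))
  expect_equal(attr(rs, "label"), "demo")
  expect_true(is.na(attr(rs, "sorted")))
  srt <- sort_regions(rs, "natural")
  expect_equal(attr(srt, "sorted"), "natural")
  mrg <- merge_regions(rs)
  expect_true(attr(mrg, "merged"))
  expect_equal(region_width(rs), c(4L, 3L))
  expect_output(print(mrg), "2 interval")
})
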