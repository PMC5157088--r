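ex <- example_regions()

test_that("left outer join reproduces the worked example with sentinels", {
  got <- join_left(ex$a, ex$b)
  expect_equal(got, expected_join_ab)
  # bookended neighbours are not matches: chr1:10-100 vs chr1:1-10
  expect_equal(got$chr[got$index == "chr1:10-100"], ".")
})

test_that("joining against an empty set yields only sentinel rows", {
  got <- join_left(ex$a, character())
  expect_equal(got$index, expected_merged)
  expect_true(all(got$chr == "." & got$start == -1L & got$end == -1L))
  expect_equal(nrow(join_left(character(), ex$b)), 0L)
})

test_that("join matches verified by base enumeration on random pairs", {
  for (seed in 1:15) {
    p <- random_pair(seed)
    rows <- join_left(p$a, p$b)
    ma <- cov_mask(p$a); mb <- cov_mask(p$b)
    ai <- parse_regions(rows$index)
    for (i in seq_len(nrow(rows))) {
      left_bases <- (ai$start[i] + 1L):ai$end[i]
      if (rows$chr[i] == ".") {
        expect_identical(c(rows$start[i], rows$end[i]), c(-1L, -1L))
      } else {
        expect_equal(rows$chr[i], ai$chrom[i])
        right_bases <- (rows$start[i] + 1L):rows$end[i]
        expect_gt(length(intersect(left_bases, right_bases)), 0L)
        expect_true(all(mb[[rows$chr[i]]][right_bases]))
      }
    }
    # sentinel structure consistent with in_region over merged a
    am <- merge_regions(p$a)
    sentinel <- tapply(rows$chr == ".", rows$index, all)
    expect_equal(as.vector(sentinel[rows$index[!duplicated(rows$index)]]),
                 !in_region(am, p$b))
  }
})

test_that("multijoin reproduces the 24-cell partition with truth table", {
  got <- multijoin(list(a = ex$a, b = ex$b, c = ex$c))
  expect_equal(got, expected_multijoin_abc)
  # uncovered gaps emit nothing
  expect_false("chr20:5-6" %in% got$index)
  # n.overlaps consistency with names and the 0/1 columns
  expect_equal(got$n.overlaps, got$a + got$b + got$c)
  expect_equal(got$n.overlaps,
               lengths(strsplit(got$names, ",", fixed = TRUE)))
})

test_that("multijoin of a set with itself returns its own intervals", {
  s <- merge_regions(ex$raw)
  got <- multijoin(list(x = s, y = s))
  expect_equal(got$index, expected_merged)
  expect_true(all(got$n.overlaps == 2L))
  expect_true(all(got$names == "x,y"))
})

test_that("multijoin rejects fewer than two sets and defaults labels", {
  expect_error(multijoin(list(a = ex$a)), "at least 2")
  got <- multijoin(list(ex$a, ex$b))
  expect_true(all(unlist(strsplit(got$names, ",")) %in% c("a", "b")))
})

test_that("multijoin tiles the union exactly on random instances", {
  for (seed in 1:10) {
    p <- random_pair(seed + 300)
    cset <- random_regions(10, oracle_chroms, c(1, 300), seed = seed + 600)
    got <- multijoin(list(a = p$a, b = p$b, c = cset))
    cells <- parse_regions(got$index)
    # disjoint and sorted
    for (ch in unique(cells$chrom)) {
      sub <- cells[cells$chrom == ch, ]
      if (nrow(sub) > 1L) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
    # union of cells == union of inputs, base by base
    expect_equal(sum(cells$end - cells$start),
                 oracle_union_bp(p$a, p$b, cset))
    expect_equal(mask_to_df(cov_mask(region_set(cells))),
                 mask_to_df(Reduce(function(x, y) Map(`|`, x, y),
                                   lapply(list(p$a, p$b, cset), cov_mask))))
    # per-cell membership equals the per-base check
    masks <- list(a = cov_mask(p$a), b = cov_mask(p$b), c = cov_mask(cset))
    for (i in seq_len(nrow(cells))) {
      for (lab in c("a", "b", "c")) {
        expect_equal(got[[lab]][i],
                     as.integer(oracle_cell_covered(masks[[lab]],
                                                    cells$chrom[i],
                                                    cells$start[i],
                                                    cells$end[i])))
      }
    }
  }
})

test_that("in_region matches the worked example and the join structure", {
  expect_equal(in_region(ex$a, ex$b), expected_in_region)
  expect_equal(in_region(ex$a, character()), rep(FALSE, 6))
  # order follows the caller's order, unsorted input included
  expect_equal(in_region(c("chr2:10-60", "chr1:10-100"), ex$b),
               c(TRUE, FALSE))
  for (seed in 1:15) {
    p <- random_pair(seed + 50)
    am <- merge_regions(p$a)
    expect_equal(in_region(am, p$b), oracle_in_region(am, p$b))
  }
})
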