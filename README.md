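# regionops

Native genomic interval algebra on BED-style regions, in R.

Comparing sequencing experiments routinely reduces to set arithmetic over
genomic intervals: which promoter regions overlap a peak set, which bases
are exclusive to one callset, how much of the genome is covered by two of
three annotations. The classic way to answer these questions is to shell
out to command-line engines and parse their text output back into R.
`regionops` instead implements the whole algebra natively: every operation
is plain R over plain data frames, so results are reproducible,
inspectable and identical on any platform — no external binaries.

All coordinates follow the BED convention: **0-based, half-open
`[start, end)`**, whether written as a region string `"chr1:10-100"` or as
a BED row `chr1 TAB 10 TAB 100`. Two intervals *overlap* iff they share at
least one base; intervals that merely touch (`prev.end == next.start`,
"bookended") do **not** overlap, but they **do** collapse under merging —
the two defaults differ deliberately, matching the conventions of the
classic BED engines. The one deliberate exception is the VCF layer: tabix
query strings are 1-based inclusive, because that is what
position-indexed retrieval tools use.

## Operations

| function | result |
|---|---|
| `sort_regions(x, ordering)` | natural (`chr2 < chr10`) or lexicographic (`chr10 < chr2`) order |
| `merge_regions(x, distance, bookend)` | collapse overlapping/bookended intervals |
| `sort_and_merge(x)` | the usual tandem preprocessing step |
| `join_left(a, b)` | left outer join; unmatched rows get `.` / `-1` sentinels |
| `multijoin(list(...))` | atomic partition of 2+ sets with a 0/1 truth table |
| `subtract_regions(a, b, mode)` | `"whole"` drops touched intervals intact; `"partial"` removes bases |
| `intersect_regions(a, b)` | shared bases as maximal intervals |
| `in_region(a, b)` | logical overlap test per `a` interval |
| `flank_regions(x, up, down, genome)` | clipped up-/downstream flanks |
| `coverage_stats(a, b)` | total and shared base-pair widths |
| `venn_counts(sets, feature)` | 2–5-way overlap amounts (bp or interval counting) |
| `query_vcf(region, vcf)` | tabix-convention region query over a VCF |
| `read_bed` / `write_bed` / `read_vcf` / `read_genome` | format I/O (gzip transparent) |

Character vectors of region strings go in, character vectors come out;
data-frame and `region_set` inputs return `region_set` tables. A small CLI
(`system.file("cli", "regionops", package = "regionops")`) exposes the
same operations as subcommands (`sort`, `merge`, `join`, `multijoin`,
`subtract`, `query-vcf`, `venn`, `example-data`, ...).

## Worked example

```r
library(regionops)
ex <- example_regions()          # bundled demonstration sets

sort_regions(ex$raw, "natural")
#> [1] "chr1:10-100"  "chr1:101-200" "chr1:200-210" "chr1:211-212"
#> [5] "chr2:10-50"   "chr2:40-60"   "chr10:50-100" "chr20:1-5"

merge_regions(ex$raw)
#> [1] "chr1:10-100"  "chr1:101-210" "chr1:211-212" "chr10:50-100"
#> [5] "chr2:10-60"   "chr20:1-5"
```

Note `chr1:101-200` and `chr1:200-210` collapsed (they touch), while the
1-bp gaps on either side kept `chr1:10-100` and `chr1:211-212` separate.

```r
join_left(ex$a, ex$b)
#>          index  chr start end
#> 1  chr1:10-100    .    -1  -1
#> 2 chr1:101-210 chr1   111 250
#> 3 chr1:211-212 chr1   111 250
#> 4 chr10:50-100    .    -1  -1
#> 5   chr2:10-60 chr2    40  60
#> 6    chr20:1-5    .    -1  -1

in_region(ex$a, ex$b)
#> [1] FALSE  TRUE  TRUE FALSE  TRUE FALSE

subtract_regions(ex$a, ex$b)         # whole-interval mode
#> [1] "chr1:10-100"  "chr10:50-100" "chr20:1-5"

venn_counts(list(a = ex$a, b = ex$b), feature = "bp")
#> overlap_summary: 2 sets (a,b), feature=bp
#>   signature amount
#> 1         a    184
#> 2       a,b    120
#> 3         b    116
```

The three sentinel join rows are `a` intervals sharing no base with `b`
(the first is *bookended* by `b`'s `chr1:1-10` — touching, not
overlapping). The Venn amounts partition the 420 bp union: 184 bp
exclusive to `a`, 116 bp exclusive to `b`, 120 bp shared.

A tabix-style query against the bundled synthetic COSMIC-like VCF:

```r
vcf <- synthetic_vcf(tempfile(fileext = ".vcf"))
query_vcf("1:1000-100000", vcf)[, 1:5]
#>   CHROM   POS          ID REF ALT
#> 2     1 69345  COSM911918   C   A
#> 3     1 69523  COSM426644   G   T
#> 4     1 69538   COSM75742   G   A
#> 5     1 69539 COSM1343690   T   C
#> 6     1 69540 COSM1560546   G   T
#> 7     1 69569 COSM1599955   T   C
```

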