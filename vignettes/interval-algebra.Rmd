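---
title: "Interval algebra on BED-style regions: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval algebra on BED-style regions: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionops)
```

## The model

A genomic region is a half-open interval `[start, end)` on a named
chromosome, with `start >= 0` and `end > start` in base pairs — exactly
the numbers in the first three BED columns, and exactly the numbers in a
region string `"chrom:start-end"`. The package's algebra is ordinary set
algebra over the bases these intervals cover, plus bookkeeping
(sortedness, mergedness, labels) that makes multi-set operations
well-defined.

Three conventions do all the work; everything else follows from them.

**Overlap needs a shared base.** Two intervals overlap iff they share at
least one base: `a.start < b.end && b.start < a.end`. Intervals that
merely touch ("bookended", `a.end == b.start`) share no base and never
count as overlapping in joins, membership tests, subtraction or
intersection.

**Bookends merge anyway.** `merge_regions()` collapses runs of intervals
whose start lies within `distance` (default 0) of the running maximum
end; with `bookend = TRUE` (default) equality at the boundary collapses
too. So `chr1:101-200` + `chr1:200-210` merge into `chr1:101-210`, while
a 1-bp gap (`200-210` vs `211-212`) survives. Overlap and merge defaults
therefore differ deliberately; both mirror the long-standing behaviour
of the classic BED engines, and the worked examples in the test suite
pin each boundary case. The `distance` rule extends uniformly: with gap
tolerance `d`, `bookend` decides whether equality at `start == end + d`
merges.

**Half-open coordinates, one declared exception.** Region strings and
BED tables share the 0-based half-open convention, so conversion between
them copies coordinates verbatim; any ±1 shift would contradict the
merge and join results above when re-imported. The single deliberate
exception is the VCF layer: `query_vcf()` takes tabix-convention
1-based *inclusive* windows, because queries are forwarded in the idiom
of indexed-retrieval tools. The boundary is documented at the function
and the CLI names the argument accordingly; `regions_to_table()` also
offers a clearly-labelled 1-based closed export for closed-interval
range frameworks, never as a default.

## Chromosome orderings

Two total orders over chromosome names are supported:

* **lexicographic** — plain byte-wise comparison (`chr10 < chr2`);
* **natural** — strip an optional case-insensitive `chr` prefix,
  tokenize into digit/non-digit runs, compare numeric tokens as
  integers and alphabetic tokens case-insensitively, numeric before
  alphabetic at the same position (`chr2 < chr10`).

Names are never silently normalized: `"1"` and `"chr1"` are different
chromosomes (equal natural keys fall back to byte comparison), because
silent renaming corrupts joins. For non-numeric chromosomes the natural
rule places `chr1 … chr22 < chrM < chrX < chrY`, the GNU version-sort
convention; this is our convention, chosen once — mixed alphabetic names
have no canonical ordering in the BED world.

`sort_regions()` exposes both orders. Every other operation that sorts
internally (merge, join, multijoin, subtract, intersect, flank) emits
**lexicographic** order by default — the order the classic engines
print — unless the input already carries a recorded ordering, which is
then respected. This is why `sort_and_merge()` is defined as merge after
lexicographic sort. The CLI's `sort` subcommand defaults to natural
order, which is the more readable one at a terminal; the algebra
subcommands keep the lexicographic default so piped output matches the
library exactly.

## The operations, briefly

* `join_left(a, b)` merges both inputs first (unmerged right-hand sets
  would make match multiplicities ambiguous), then emits one row per
  overlapping `b` interval for each `a` interval, or a single sentinel
  row (`.`/`-1`) when none overlaps. Lookups use `findInterval()` over
  the merged, sorted right set: overlapping intervals form a contiguous
  run, found in O(log n).
* `multijoin(sets)` pools all interval endpoints per chromosome as
  breakpoints; consecutive breakpoints bound *cells*, each covered
  entirely or not at all by every input set. Cells covered by at least
  one set are emitted with an overlap count, comma-joined covering
  labels, and a 0/1 column per set. Uncovered gaps are never emitted,
  and cells are never coalesced — with merged inputs equal-signature
  neighbours cannot occur.
* `subtract_regions()` has two first-class modes: `"whole"` (default)
  keeps only `a` intervals with zero overlap, intact — the natural
  notion when intervals are indivisible features; `"partial"` removes
  the covered bases, the natural notion when coverage is what counts.
* `intersect_regions()` returns the base-level intersection as maximal
  intervals. An alternative reading — returning the second set's whole
  intervals that overlap — is already available as the non-sentinel rows
  of `join_left()`, so the base-level form is the one implemented here.
* `flank_regions()` emits up- and downstream flanks separately, clipped
  at 0 and at the chromosome end when a genome table is given, dropping
  flanks that clip to nothing. Flanks are *not* merged with their
  sources or each other: keeping them separate keeps the operation
  invertible and auditable; callers can merge explicitly.
* `venn_counts()` quantifies 2–5-way overlaps. `feature = "bp"` sums
  multijoin cell widths per membership signature, so amounts are
  mutually exclusive and sum to the union width. `feature = "interval"`
  counts atomic intervals (the merge of all sets pooled), assigning an
  atom to a set when the set covers at least `fraction` of its width.
  The coverage fraction applies only in interval mode — a fraction has
  no obvious meaning when the unit being counted is already the base —
  and the default `1e-9` makes any shared base count, in the spirit of
  the minimum-overlap defaults of the underlying engines. The 2-to-5-set
  bound is enforced; that is the range for which Venn output is
  meaningful downstream.

## Numerical and degenerate-input choices

* Zero-width intervals are rejected at construction: membership of an
  empty interval is undefined under the shared-base rule, and no
  standard engine emits them.
* Coordinates are stored as R integers; chromosome-scale values
  (< 2^31) fit comfortably.
* Sort tie-break is `(chromosome, start, end)` ascending, stable
  thereafter, so equal intervals keep input order.
* Empty inputs are identities: merging, sorting or subtracting nothing
  returns an empty set; joining against an empty set returns all
  sentinels; `in_region(x, empty)` is all-`FALSE`.
* Validation (`validate_regions()`) reports findings — malformed
  strings, missing `chr` prefixes, intervals beyond the chromosome end —
  and never throws on content, so it can sweep dirty inputs whole.

## The bundled example data and generators

`example_regions()` reconstructs three small interlocking sets. `raw`
is eight unsorted regions on chr1/chr2/chr10/chr20 whose merge exercises
both the bookend collapse and the 1-bp gap boundary; its pre-merge order
is fixed but scrambled so sorting is non-trivial. Sets `b` and `c` are
pinned by the structure they must produce: every cell signature of the
24-cell three-way partition, the three sentinel rows of the left join,
and the bookended non-overlap at `chr1:10`. The partition acts as a
checksum — the test suite recomputes it and compares cell-by-cell, so
the fixtures are self-verifying.

`random_regions(n, chroms, width_range, seed)` draws chromosomes
uniformly, widths uniform in range, starts uniform within the
chromosome, and restores the caller's RNG state. Property tests run it
against an independent base-enumeration oracle: coordinates are kept
below 10^4 so each chromosome is a small coverage mask and every
operation can be recomputed base by base. The default property-suite
shape (hundreds of instances, 12–20 intervals per set, widths up to a
few hundred bp) yields dense overlap structure — many partial overlaps,
containments and bookends per instance — which is what stresses the
sweep logic; the suite finishes in well under a minute.

`synthetic_vcf()` writes a deterministic COSMIC-like VCF: six coding
mutations at known positions inside `1:1000-100000`, plus fixed decoys
outside that window, inside a second window, and on another chromosome,
so every region query has an exact expected answer. It is synthetic
throughout — the layout imitates COSMIC, the content does not come from
it.

What the synthetic data does *not* emulate: real chromosome counts and
lengths, strand, empirical interval-length distributions, clustered
(non-uniform) feature placement, or VCF genotype columns. Passing tests
show the algebra is exact under its stated conventions — which is the
claim at stake for deterministic set arithmetic — not that any
biological inference downstream is valid.

## Known limitations

* Strand-aware operations, closest-feature/distance queries, window
  operations and coverage histograms are out of scope.
* The VCF layer is the minimal 8-column model: no genotype columns, no
  `.tbi`/bgzf virtual-offset indexing — queries scan linearly, which is
  exact and fast at the scale this package targets. Records hit by
  several overlapping query windows are returned once (deduplicated, in
  file order); tools differ on this, so it is stated here.
* BED extra columns are opaque payload: operations that rebuild
  intervals (merge, subtract, intersect) drop them; operations that only
  reorder (sort) keep them.
* GFF/GTF parsing and construction of external range-framework objects
  are out of scope; `regions_to_table()` output converts readily.
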