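---
title: "Duplex consensus calling with barcode error correction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling with barcode error correction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dureunite)
```

## The problem

Duplex sequencing (DS) detects sequence variants at frequencies far below
the raw error rate of the sequencer by tagging both strands of every input
DNA fragment with random 12-mer barcodes. All reads descending from one
strand of one molecule share a tag pair and are collapsed into a
single-strand consensus sequence (SSCS); the two complementary SSCSs of a
molecule are then cross-checked into a duplex consensus sequence (DCS).
PCR and sequencing errors appear as minority "polymorphisms" within a
family and are voted away.

The weak point of the scheme is the barcode itself: it is sequenced like
any other base, so roughly `24 * e` of reads (tag length 24, per-base
error rate `e`, plus PCR errors accumulated during amplification) carry a
corrupted tag. Such reads fail the exact-match grouping, fall out of their
family — usually as unusable singletons — and are discarded. `dureunite`
implements the rescue: find all pairs of observed tags within a small
substitution distance, cluster them, pick one representative per cluster,
and rewrite the read families before consensus calling.

## Tag model

A molecule's two tags `a` and `b` appear as `a + b` on reads from one
strand and `b + a` on reads from the other. `canonical_tag()` normalises
the pair to the lexicographically smaller of the two concatenations and
keeps the observed arrangement as an `order` flag (`ab`/`ba`); ties
(`a == b`) resolve to `ab`. This makes family grouping a plain sort on
`(canonical_tag, order, mate)` and makes the two strands of one molecule
share a single key. The constant linker between tag and insert is removed
by fixed length (`linker_len`, default 5), not by sequence match: the
linker is synthesised, ligated and sequenced like the tag, so its identity
carries no information the length does not.

## Approximate tag matching

The matcher (`find_tag_matches()`) must find every pair of distinct
24-mers within substitution (Hamming) distance `d` of each other,
considering both arrangements of every tag:

$$D_{ij} = \sum_{k=1}^{2L} [x_{ik} \neq x_{jk}], \qquad
  d(i, j) = \min\big(D(c_i, c_j),\ D(c_i, \mathrm{swap}(c_j))\big).$$

Substitution-only distance is the right metric here: tags are synthesised
at fixed length and the dominant error processes (polymerase
misincorporation, base miscalls) substitute rather than insert or delete.
Rather than the quadratic all-vs-all scan, the matcher uses k-mer
partitioning: a pair within distance `d` must agree exactly on at least
one of `d + 1` disjoint blocks of the tag, so tags are bucketed by (block
index, block content) over both arrangements and only co-bucketed
candidates are verified. The result is exactly the brute-force pair set
(the test suite proves equality against an independent `O(n^2)` oracle)
at a small fraction of the cost. `min_mapq` and `max_pos_offset` exist as
de-noising filters for pluggable external aligner backends and have no
effect on the exact matcher, which reports unambiguous pairs at offset 0.

## Clustering and canonical selection

Matches form an undirected graph over tags (`build_barcode_graph()`,
components via igraph); each connected component is taken to be one
molecule plus its error derivatives. Transitive chains merge (A–B, B–C
join even if `d(A, C) > d`): this follows from the component formulation
and in practice keeps multi-error derivatives attached through
intermediate single-error tags. Per component one representative is
elected (`select_canonical()`): by default the tag backing the most read
pairs, alternatively the tag with the highest degree. Ties break by the
other criterion and then by the lexicographically smallest tag, so output
is deterministic; a tag containing `N` never outranks an all-real-base
tag, since an `N` is by construction an error. Applying the map
(`apply_correction()`) rewrites tags, flips the `ab`/`ba` flag for
records whose raw tag matched the swapped arrangement of the
representative, and conserves the record count exactly.

## Consensus model

`call_consensi()` votes per aligned column with three tunables, whose
defaults are the reference pipeline settings:

* `cons_thres = 0.7` — minimum fraction of surviving votes the winning
  symbol needs; below it the column is masked `N`. A tie for the majority
  is also `N`.
* `min_reads = 3` — minimum family size for any consensus.
* `qual_thres = 25` (PHRED) — bases below this quality do not vote; gaps
  always vote. A column whose votes are all discarded yields `N`.

A winning gap emits nothing (a deletion): gap-as-vote keeps column
semantics uniform instead of special-casing indels. Duplex merging
(`call_dcs()`) pairs `(ab, mate 1)` with `(ba, mate 2)` and vice versa —
the two groups that read the same fragment strand — and masks any
disagreement or `N` as `N` rather than introducing IUPAC ambiguity codes,
which downstream variant callers would count as variants. DCS qualities
are a constant PHRED 40 placeholder, since the model assigns none.

Families whose reads all share one length are column-stacked directly (a
family has no indel signal in that case); mixed-length families go through
a center-star multiple alignment around the longest read using pairwise
global alignment (match +1, mismatch −1, gap −2 per base) from Biostrings.
The engine sits behind `align_family()` and is pluggable; ungapping any
MSA row always recovers its input read.

## Parallel execution

Consensus jobs run through `ordered_parallel_map()`: a queue of
`workers * queue_mult` jobs (default multiplier 8) is kept in flight and
results are collected strictly in submission order, so fast workers stay
busy while a slow family aligns and the output is byte-identical for any
worker count. Families are processed in lexicographic tag order for the
same reason. Worker invariance holds because consensus calling uses no
randomness; the test suite checks `workers = 1` against `workers = 4`.

## The simulator

`run_simulation()` generates a full synthetic duplex experiment so that
every downstream claim can be scored against a known truth:

1. **Fragmentation** — `n_fragments` error-free fragments of exactly
   `frag_len` (default 400) bases, uniform start and strand, from a
   supplied or random reference.
2. **Tag synthesis** — i.i.d. uniform bases (25% each), 12-mers by
   default.
3. **Strand split** — each of the family's reads goes to the `ab` or `ba`
   strand molecule with a fair coin. The `ab` molecule is
   `alpha + linker + fragment + revcomp(linker) + revcomp(beta)`; the
   `ba` molecule is its reverse complement.
4. **PCR genealogy** — per strand, the family's reads start at the root
   molecule; at cycle `c` a node replicates with probability
   `1 / 1.05^(c-1)` (efficiency decay; cycle 1 always fires), reads split
   between the two daughters with a fair coin, and *each daughter*
   receives fresh `Binomial(length, 0.001)` substitutions that all its
   descendants inherit — every molecule created by a replication is a new
   synthesis event. 25 cycles by default.
5. **Sequencing** — mate 1 is the first 100 bases of the molecule, mate 2
   the first 100 of its reverse complement, each with i.i.d. substitution
   errors at the same rate and flat PHRED 40 qualities.
6. **Truth log** — one record per read and mate: fragment, true tags,
   strand, and every injected error as `position:source` (`pcr`/`seq`,
   0-based read coordinates).

Everything is driven by R's RNG, so a fixed `rng_seed` reproduces the
output byte-for-byte.

### Family sizes

The reads-per-molecule distribution of a duplex experiment is an empirical
quantity governed by input DNA amount and amplification; published
barcode-list data show it is dominated by singleton and near-singleton
families, with consensus-forming families sitting in a tail whose median
is around a dozen reads. The packaged default
(`family_size_distribution()`) reproduces this shape as a mixture:
80% geometric (p = 0.5; mode at 1) plus 20% discrete log-normal
(`meanlog = log(12)`, `sdlog = 0.7`), truncated to `[1, 200]`. The mixture
weight was fixed once so that about one simulated fragment in nine yields
a duplex consensus without error correction, matching the reference
experiment's reported yield fraction; it was not adjusted afterwards. Any
user table of `(size, weight)` pairs can replace it
(`read_family_size_distribution()`).

### What the simulator does not model

Indels, chimeric fragments, GC-biased amplification, quality-score decay
along the read, and adapter read-through are all absent. Passing tests on
simulated data therefore demonstrate the correctness of the grouping,
matching, clustering and voting machinery under a substitution-only error
process — not performance on real libraries, where the MSA engine and the
trimmer carry more of the load.

## Evaluation semantics

`classify_corrections()` scores a correction map per observed family
(distinct raw canonical tag, counted once): corrected into the family of
its own source molecule → true positive; corrected elsewhere → false
positive; uncorrected and not an original tag → false negative;
uncorrected original tag → true negative. "Its own molecule's family" is
deliberately evaluated at the fragment level rather than as base-identity
with the original tag: when an error derivative happens to out-vote the
original tag in the canonical election, reads mapped onto it are still
correctly reunited, and counting that as an error would misstate what the
correction got wrong. The exact-identity variant of every count remains
computable from `truth_families()`, which exposes each observed tag's
majority true tag and fragment.

`per_base_error_rate()` compares every DCS base positionally with the
fragment it descends from. A DCS mate reads either the fragment prefix or
the reverse-complement prefix depending on the lexicographic orientation
of its tag, so both candidates are compared and the matching one scored.
By default an `N` counts as a difference from the input (consensus
abstention is still lost signal); the rate with `N` positions excluded
from numerator and denominator is reported alongside, and on simulated
data essentially all differences are `N` maskings rather than miscalled
bases.

## QC tools

`min_edit_distance_profile()` samples `sample_n` tags (default 1000 — a
sample this size estimates the profile as well as the full set) and finds
each sampled tag's minimum distance to every other observed tag, querying
both arrangements; a spike at distance 1 diagnoses uncorrected barcode
errors, and correction at `max_dist = 1` empties that bin exactly.
`family_size_histogram()` counts families by size per
`(tag, order, mate)` key. `trim_read_pairs()` removes N-dense 5' ends of
consensus reads: a 10-base window slides from the 5' end with stride 1
(the conservative reading of the published parameters), the read survives
from the first window whose `N` fraction does not exceed 0.3 — "exceeds"
is strict, so a window at exactly 0.3 passes — minus any leading `N`s,
and a pair is dropped whole if either mate falls under 75 bases. Reads
shorter than the window are judged as a single whole-read window.

## Numerical and degenerate-input choices

* All string ordering uses C-locale radix sorts; ties everywhere break
  lexicographically, so every stage is deterministic.
* Vote fractions are compared with `>=` in double precision.
* `max_dist = 0` produces the identity correction; empty inputs propagate
  as empty tibbles rather than errors except where a contract forbids them
  (empty families, empty distributions, record-misaligned FASTQ pairs).
* Positions are 0-based half-open internally (truth-log error
  coordinates); user-facing tables are plain tibbles.
* Reads shorter than `tag_len + linker_len` are dropped and counted, not
  fatal.

## Problem sizes

The test suite exercises the full pipeline on a fixed-seed 10,000-fragment
simulation (plus many small constructed fixtures); the reproduction script
`scripts/acceptance.R` uses 40,000 fragments, the desk-scale version of
the reference experiment, which runs in well under a minute. Both sizes
are package choices that keep the stochastic quantities (recall, yield
gain, error rates) stable to well within their comparison tolerances.

## Known limitations

* Substitution-only matching cannot rescue tags with indels; such reads
  stay singletons.
* The canonical election can be won by an error derivative in small
  families; the correction still reunites the molecule's reads (and is
  scored accordingly), but the reported family tag then differs from the
  original synthesis.
* The center-star MSA is adequate for the shallow, low-divergence
  families duplex data produce; it is not a general-purpose aligner, and
  an external engine can be plugged in behind `align_family()` where
  indel-rich data demand one.
* Consensus error rates on simulated data are dominated by `N` masking
  from PCR errors shared by part of a family; their absolute level is
  sensitive to the family-size distribution and to the granularity of the
  error-injection model, both of which are only partially constrained by
  the published description (see the calibration note above).
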