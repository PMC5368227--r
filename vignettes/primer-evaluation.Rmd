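---
title: "In silico evaluation of degenerate 16S rRNA gene primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico evaluation of degenerate 16S rRNA gene primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerscout)
```

## The problem

Amplicon surveys of bacterial communities stand or fall with the PCR
primers used to amplify the 16S rRNA gene: a primer pair that fails to bind
a lineage's conserved flanking regions renders that lineage invisible. As
reference databases grow, primer pairs designed years ago need periodic
re-evaluation against current references. `primerscout` implements the
standard in-silico workflow for this: locate each degenerate primer's best
binding site on every reference sequence, score it with a 3'-weighted
mismatch/gap penalty, aggregate per-taxon coverage and non-coverage tables,
and predict amplicons and their length distributions for primer pairs. A
synthetic reference generator with exactly known ground truth makes every
stage of the pipeline testable at desk scale.

## The scoring model

A binding site is scored by the weighted penalty

$$S = 0.40\,mm_{\overline{3'}} + 1.00\,mm_{3'} + 1.00\,gap_{\overline{3'}}
      + 3.00\,gap_{3'} + 3.00\,[\text{final base mismatches}]$$

where the 3' region is the final `three_prime_len` bases of the primer
(default 5). Mismatches near the 3' terminus impair polymerase extension
far more than 5' mismatches, hence the asymmetric weights and the extra
terminal-base penalty. A sequence is counted *covered* (amplifiable) by a
primer when its best site scores at most `hit_threshold` (default 1.0); a
pair covers a sequence when **both** primers pass on that same sequence
with the forward site strictly 5' of the reverse site — not when the
marginal coverages merely overlap.

The alternative *total-mismatch* (`tp`) score is the unit-weight count of
all mismatches plus gaps, with no positional weighting and no terminal
penalty. Both scores are computed for every hit; `scoring_config(method =)`
selects which one the coverage calculations threshold. Their divergence is
diagnostic: a single terminal 3' mismatch scores 4.0 weighted (not covered
at threshold 1.0) but 1.0 total-mismatch (covered), so taxa whose defects
are concentrated at the 3' terminus appear uncovered only under the
weighted method. With the default weights the reverse can also happen: two
non-3' mismatches score 0.8 weighted (covered) but 2.0 total-mismatch (not
covered). The invariant "tp non-coverage never exceeds weighted
non-coverage" therefore holds only when every per-category weight is at
least 1, and the test suite asserts it only under such a configuration.

### Matching semantics for ambiguity codes

Primer positions carry IUPAC ambiguity codes. A template position matches
a primer position iff the template code's base set is a **subset** of the
primer code's set: a concrete template base matches iff the primer admits
it, and an ambiguous template base (`N` in a database sequence) never
matches a narrower primer code. This is the conservative choice — an `N` in
the reference may well be a base the primer does not cover — and database
ambiguity codes are rare enough that the choice barely moves coverage.
RNA `U` is converted to `T` at ingest and matching is case-insensitive.

## The binding-site search

The search minimises the weighted score over all placements:

1. a vectorised scan of every ungapped offset;
2. when a gapped placement could possibly beat the ungapped optimum
   (i.e. the ungapped best exceeds the cheapest single-gap penalty), an
   exact fitting-alignment dynamic program over the whole template — primer
   global, template ends free — with an explicit gap-count dimension
   (0..`max_gaps`, default 2).

The DP therefore returns the true minimum over *all* offsets and *all*
placements of at most `max_gaps` indels; the test suite proves this by
exhaustive enumeration (every deletion subset, every insertion multiset,
every offset) on hundreds of random primer/template pairs. We chose the
full DP over a banded refinement around promising offsets because at
primer lengths of 17–21 nt the DP is cheap, needs no band-width heuristic,
and is provably exhaustive.

Design choices that shape the alignment space:

* **The 3' terminal base must be base-paired.** No gap is ever placed at
  the final primer position. An unpaired 3' terminus cannot prime
  extension, and allowing a terminal deletion would let every terminal
  mismatch (4.0) be re-scored as a terminal gap (3.0), emptying the
  terminal penalty of meaning. Internal gaps, including the slot between
  the last two primer bases, remain allowed.
* **Gap classification.** A deletion (primer base unaligned) takes the gap
  weight of that primer position; an insertion (extra template base
  between primer positions *i* and *i+1*) takes the weight of position
  *i+1*. A gap never triggers the terminal-base penalty; that penalty
  applies only to an aligned base-base mismatch at the final position.
* **Ties** prefer (1) the lower score, (2) ungapped over gapped
  placements, (3) the site closest to the primer's E. coli reference
  coordinates when the template spans them, then (4) the leftmost site.
  The result is deterministic for fixed inputs.
* **Reverse primers** are matched against the reverse complement of the
  template; coordinates are mapped back to the plus strand, so all
  reported sites and amplicons are in plus-strand 1-based inclusive
  coordinates.
* **Truncated templates** (shorter than the primer) are flagged, carry an
  infinite score, and are excluded from coverage denominators by default
  (`truncated_policy = "exclude"`); `"miss"` counts them as non-covered
  instead. Reference fragments that do not span a primer locus otherwise
  depress coverage for reasons unrelated to primer quality.

## Amplicon prediction

For a primer pair, at most one amplicon per record is emitted: the
best-scoring site pair with both scores within threshold and the forward
site 5' of the reverse site. The amplicon spans the forward primer's 5'
end through the plus-strand image of the reverse primer's 5' end, primer
sites included. For 341f (E. coli 341–357) and 785r (785–805) this is
805 − 341 + 1 = 465 nt. Note that published primer tables often quote the
difference of the primer *name* coordinates (785 − 341 = 444) as the
"amplicon size"; the package always reports coordinate-derived lengths and
does not attempt to match such columns.

`length_distribution()` bins amplicon lengths per taxon. Its motivating
use case is the length polymorphism in many Alphaproteobacteria, which
carry short deletions between the 341f and 785r sites (E. coli ~454–485):
on a mixed community these produce a second amplicon peak shifted by the
deletion length, and the per-taxon histogram attributes the shorter mode
to the lineage carrying it.

## The synthetic reference generator

`simulate_reference_set()` emulates exactly the features of a curated
16S reference set that this pipeline consumes: records of 16S-like length
(default 1200–1600 nt), a semicolon-delimited taxonomy per record, and one
concrete realisation of every primer's binding site planted at its
E. coli coordinates (so coordinate conventions are exercised end to end).
Per taxon, a quota of records receives one defect:

| defect | weighted score | tp score |
|---|---|---|
| `non3p_mismatch` | 0.40 | 1 |
| `threep_mismatch` (3', not terminal) | 1.00 | 1 |
| `terminal_mismatch` | 4.00 | 1 |
| `double_mismatch` (non-3' + 3') | 1.40 | 2 |
| `site_gap` (1-nt deletion in the site) | 1.00 | 1 |
| `deletion` (between the sites) | 0 | 0 |

Planting is deterministic — the first `round(defect_frac * n)` records by
index — so the expected coverage of every taxon under every method follows
in closed form and is written to a truth manifest; `stochastic = TRUE`
switches to Bernoulli planting, with the manifest recording realised
counts. Mismatch substitutions use the first base (A<C<G<T order) outside
the primer's set at that position; planting a mismatch against an `N`
primer position is refused, since no base can mismatch it.

A uniform random background of ~1.4 kb frequently contains spurious
windows scoring below a planted defect (a terminal mismatch scores 4.0,
and a random window with seven non-3' mismatches scores 2.8). The
generator therefore *repairs* the background: any window whose score
approaches the planted site's expected score is re-randomised (a fast
ungapped pre-pass, then an exact loop using the full search), until the
planted site is provably the best site with exactly its closed-form score
and terminal-base flag. This is what makes the truth manifest exact rather
than approximate, at the cost of a background that is random *conditional
on* containing no competing binding site. One caveat documented here: a
primer whose final two bases realise identically (e.g. a 3' terminus
`...CC`) can always dodge a planted terminal mismatch via an internal
deletion that re-pairs the terminus; terminal-mismatch defects should
target primers without such a repeat (the packaged 341f and 68f are safe).

What the generator deliberately does **not** emulate: phylogenetic
correlation between records (backgrounds are independent), compositional
bias, alignment-column structure, chimeras, or sequencing error. Passing
the recovery tests therefore demonstrates correctness of the scoring,
search and aggregation machinery — not that any real database will show
these coverage values. Full-scale evaluation against a real reference
release (~600k sequences) uses the same `run_evaluation()` entry point
with a FASTA path instead of a synthetic block and is a matter of CPU
hours, not of different code.

## Coverage aggregation

`coverage_by_taxon()` groups records at a requested rank of the
semicolon-delimited taxonomy path (`domain`, `phylum`, ...). Records with
missing or too-shallow taxonomy fall into an `Unclassified` bucket rather
than failing. Within each primer-or-pair the row set conserves records
(taxon totals sum to the denominator-policy total), coverage is monotone
non-decreasing in the threshold, and a parent rank's coverage equals the
size-weighted mean of its children's — all three are asserted as
properties in the test suite. Percentages are written with two decimals in
TSV reports and at full precision in JSON.

## qPCR efficiency

For wet-lab validation of a primer pair, the package includes the standard
dilution-series calibration: `fit_standard_curve()` fits Cq against
log10(template quantity) by least squares and converts the slope to
percent amplification efficiency, $E = (10^{-1/slope} - 1) \times 100$,
with 100% corresponding to a slope of $-1/\log_{10} 2 \approx -3.32$
(perfect doubling per cycle). `tidy()` and `glance()` methods expose the
fit in the usual tabular forms.

## Numerical and scale choices

Scores are small sums of the weights (multiples of 0.05 under the
defaults), so floating-point comparisons use a 1e-9 tolerance — far below
the score quantum. Test problem sizes were chosen so the whole suite runs
in a few minutes: synthetic sets of 40–250 records for recovery tests,
200 random pairs (primers ≤ 12 nt, templates ≤ 60 nt) for the
enumeration-equivalence proof, ten seeds for the round-trip property. The
packaged demo evaluation uses 40 records across five phyla with defect
rates chosen to mirror the qualitative weak spots reported for these
primer pairs (terminal 68f mismatches in Chlorobi and Bacteroidetes,
terminal 341f mismatches in Armatimonadetes, and the Alphaproteobacteria
deletion).

## Known limitations

* No thermodynamics: scores are positional mismatch counts, not ΔG or Tm
  models, matching the convention of the coverage-evaluation tools this
  package follows.
* One amplicon per record: multi-site (off-target) templates emit only the
  best-scoring product; this is appropriate for marker-gene references,
  not whole genomes.
* The `tp` score is computed on the site that minimises the *weighted*
  score; a site minimising the total-mismatch count directly could in
  principle differ, but at these primer lengths the best site is almost
  always shared.
* Exact reproduction of published full-database coverage figures depends
  on details the original tools do not document (ambiguity-code handling,
  gap parameters, denominator policy for fragments); the configurable
  policies here bracket those choices but cannot guarantee digit-level
  agreement.
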