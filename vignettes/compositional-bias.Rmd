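---
title: "Annotating compositionally biased regions by binomial P-value minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating compositionally biased regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flpsr)
```

## The model

A compositionally biased (CB) region is a sequence tract enriched for a
subset of residue types, anywhere on the continuum from a concentrated
"low-complexity" run (poly-Q, SR-rich) to a long mild skew. `flpsr`
scores a candidate window of length $w$ containing $k$ occurrences of a
residue set with summed background frequency $p$ by the binomial upper
tail

$$P(X \ge k), \qquad X \sim \mathrm{Binomial}(w, p),$$

and annotates, per residue type, the subinterval minimizing this tail
probability. The null is an i.i.d. background: each position carries
residue $r$ independently with probability $p_r$ taken from a background
composition (a whole-database table, a user file, or — for DNA — the
uniform $1/4$ per base). No multiple-testing correction is applied: the
raw tails are the reported quantities, matching how such P-values are
conventionally printed for this method, and should be read as ranking
scores rather than calibrated error rates.

All probabilities are carried as $\log_{10} P$ end to end. Proteome
scans routinely produce regions with $P < 10^{-300}$; linear-space
arithmetic would underflow. Each tail is summed term by term from
$i = w$ down to $i = k$ with pairwise log-add-exp — smallest terms
first, so cancellation is bounded — with binomial coefficients from
log-gamma. Against an exact-summation oracle the error is below
$10^{-14}$ in $\log_{10}$ for all $k \le w \le 200$ (the acceptance
report measures this).

## The pipeline and its parameters

Four stages per sequence, controlled by `scan_params()`:

* **Quick scan.** Windows of length `m` (residues, default 15) slide at
  the precision mode's step, plus one window flush with the sequence end
  so a stride can never skip a terminal bias. A window is *kept* for
  residue $r$ when its tail probability is below the mode's baseline
  $P_0$. The modes are `fast` ($P_0 = 10^{-3}$, step 3), `medium`
  ($10^{-2}$, step 2) and `thorough` ($10^{-1}$, step 1): a higher
  baseline keeps more and longer runs of windows, admitting subtler
  (often multi-residue) skews at the cost of runtime and output volume.
  Kept windows chain into candidate contigs; a residue with no kept
  window is not pursued further.
* **Minimize.** For each pursued residue the tail probability is
  minimized over subintervals with length in `[m, M]` (`M` default 500
  residues). Minimization is exhaustive, so the reported optimum is
  exactly the brute-force one; after the optimum is excluded, its flanks
  are searched recursively, so several disjoint tracts of one residue
  are all found. Ties on the raw tail resolve to the candidate whose
  *trimmed* tail is lowest, then the longest, then the leftmost
  interval (see "Numerical choices").
* **Merge.** Single-residue regions overlapping by at least one position
  group transitively. Each group is re-minimized over its union extent
  with the pooled residue set: success probability $\sum_r p_r$ and the
  pooled count. This reproduces the characteristic behaviour that a
  strong single bias plus co-located weaker ones yields a joint region
  of essentially the strong region's extent with a far lower P-value
  (e.g. `{P}` + `{Y}` + `{Q}` giving `{PYQ}`). The single-residue inputs
  are retained in the output alongside the merged region. The merged
  extent may exceed `M`: the length cap expresses how far a *search* is
  allowed to grow a single-residue window, not a bound on what merging
  overlapping evidence may produce.
* **Trim + output.** A region forced to minimum length `m` can carry
  flanking residues outside its biasing set; these are sheared off both
  ends and the tail recomputed on the shorter window (it can only
  fall — the count is unchanged). Longer optima are already flush, so
  trimming is a no-op for them. Regions passing the output threshold
  `t` (default $10^{-3}$, linear scale) are reported sorted by start
  position then tail probability.

Output rows carry the *bias signature* — the biasing residues in
precedence order (ascending single-residue tail within the region, ties
alphabetical) inside curly brackets, e.g. `{KRQ}` — a *bias class*, and
the *enrichment*: the fraction of region residues that are biasing
divided by the biasing set's summed background frequency. Protein bias
classes come from a packaged table of Taylor-Venn property sets
(hydrophobic, polar, small, tiny, aliphatic, aromatic, charged,
positive, negative) plus the intersection categories glx, tiny_polar and
polar_aromatic; the label with the smallest membership containing the
residue set wins, with `mixed` as fallback. The table ships as a
plain-text file (`extdata/protein_classes.txt`) and is user-replaceable:
the literature fixes the rule and the label vocabulary but not the exact
memberships, so they are pinned in one documented place. DNA biases fold
into the eight strand-paired classes ({A}—{T}, {G}—{C}, {AT}, {GC},
{AC}—{GT}, {AG}—{CT}, {ATC}—{ATG}, {ACG}—{CGT}); a set and its base
complement are one class, and the two three-base classes read as
strand-specific depletions of a single base.

Unknown residues (`X` for protein, `N` for DNA, with rarer ambiguity
codes collapsed onto them at parse time) can never be biasing. By
default they still occupy window positions, diluting any bias that spans
them; with the ignore-unknowns flag (`-k`) they are removed from both
the count and the window length. The same conservatism applies in
`compute_composition()`: unknowns are excluded from the numerator but,
by default, kept in the denominator, so computed background frequencies
are slight underestimates (and the table is allowed to sum to slightly
under 1 in that case).

## Domain filtering and discontinuous regions

Some CB regions are discontinuous — a structured domain sits in the
middle of a bias. `apply_domain_filter()` removes annotated domains
either by *excision* (spans deleted; shorter sequence) or *masking*
(spans replaced by the unknown letter; length preserved), recording the
original-coordinate spans in the record and on the FASTA name line as
`#FILTERED start-end id[,...]#` (the literature states that positions
are labelled on the name line without fixing a syntax; this package
defines one and tests reader and writer as inverses). After scanning an
excised sequence, `remap_regions()` restores original coordinates; a
region spanning an excision is reported as one interval with its outer
extent plus the list of excluded spans, rather than split — matching how
a bias flanking an excised domain is naturally presented as a single
discontinuous region. Conservation is testable and tested: the residues
a remapped region claims (extent minus excluded spans) are exactly those
the same scan attributes on the concatenated non-domain sequence.

## The synthetic-data generator

`generate_sequence()` draws background positions i.i.d. from a
composition table and implants tracts per `implant_spec()`: at each
implant position, with probability equal to the tract's concentration a
residue is drawn uniformly from the implant's residue set, otherwise
from the background. Defaults across the test suite follow the stated
evaluation world: tracts of length 25 at 80% concentration in length-600
uniform-background sequences for recovery (200 of them, threshold
$10^{-5}$, ±5 residues of boundary tolerance per end); uniform
backgrounds because they make the per-window false-positive rate exactly
computable for the quick-scan calibration check. What the generator does
*not* emulate: residue autocorrelation of real proteomes, tandem repeat
structure, length- and composition-coupling between regions, or
phylogenetic redundancy. A green recovery test therefore establishes
correct mechanics at a realistic signal strength, not performance on any
particular database; the published database-scale censuses depend on
versioned downloads and are deliberately out of the desk-scale test
world (an optional, clearly marked network script covers the worked
case study).

## Numerical choices

* **Trim-then-threshold.** The output threshold is applied to the
  *trimmed* tail: a minimum-length optimum whose raw tail just misses
  `t` but passes after shearing non-contributing ends is reported. The
  region invariant ("every reported region has $P \le t$") refers to the
  final region, and only this ordering makes exhaustive-search
  equivalence exact on borderline cases.
* **Tie-breaks.** Exact ties on the raw tail (common on DNA, where
  counts are coarse) resolve by lowest trimmed tail, then longest, then
  leftmost interval. The trimmed tail is mirror-invariant, which is what
  makes annotation of a reverse-complemented sequence mirror exactly
  under a uniform base background; a purely positional tie-break would
  break that symmetry. A pathological mass tie (thousands of exactly
  equal minima) is truncated deterministically.
* **Precision modes and counts.** The quick scan *gates* residues;
  minimization itself never depends on how kept windows happened to
  chain into contigs. This keeps found regions stable across modes, so
  region counts grow (weakly) from fast through medium to thorough — the
  published direction — because a higher baseline can only admit more
  residues. The window-offset sets of step 3 and step 2 are not nested,
  so window-level nesting cannot hold in general; count monotonicity is
  the invariant that is both true and tested.
* **Degenerate inputs.** A residue with background frequency 0 (or
  $\ge 1$) is untestable and silently skipped by the scanner;
  `log_binom_tail()` itself refuses $p \in \{0, 1\}$. Sequences shorter
  than `m` yield an empty annotation, not an error. Empty FASTA records
  and out-of-alphabet characters are hard errors naming the record and
  position.
* **Short output style.** `long` prints every region; `oneline` one
  summary row per sequence. The third style, `short`, is defined here as
  the lowest-P region per overlap footprint — the natural digest when
  the long output lists a merged region together with its single-residue
  parts. The reference naming was adopted without a published content
  specification for this style, so the choice is documented prominently.

## Limitations

The i.i.d. binomial null ignores residue autocorrelation, so repetitive
but unbiased sequence (e.g. exact tandem repeats of a diverse motif) is
not flagged — by design; complexity-based tools serve that purpose.
Reported P-values are not corrected for the number of windows tested.
Exhaustive minimization makes `thorough` mode quadratic in sequence
length up to `M`; database-scale runs should use `fast`, exactly as the
original tool advises. The packaged protein class memberships and the
default Swiss-Prot-wide composition are fixed, documented choices —
analyses sensitive to either should supply their own files.
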