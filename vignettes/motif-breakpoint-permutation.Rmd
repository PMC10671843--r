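---
title: "Degenerate-motif enrichment at breakpoints: model and methods"
author: "dsbmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate-motif enrichment at breakpoints: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbmotifs)
```

## The question and the model

The PRDM9 zinc-finger array binds a degenerate 13-bp DNA motif,
`CCNCCNTNNCCNC`, and thereby positions meiotic double-strand breaks. The
analysis implemented here asks whether concrete variants of that motif are
over-represented in fixed-width windows centered on somatic
structural-variant breakpoints — and, if so, which variants.

The inference is a *region-randomization permutation test*. Given a window
set $W$ (one window per breakpoint) and a hit set $H$ (every occurrence of
one motif variant), the observed statistic is the count-once overlap

$$s_{\mathrm{obs}} = \#\{\, w \in W : w \cap H \neq \emptyset \,\},$$

i.e. the number of windows containing at least one occurrence. Counting
each window at most once makes the statistic insensitive to stacks of
overlapping occurrences inside a single window. The null model re-places
every window independently and uniformly over the genome and recomputes
the statistic $n$ times, yielding $s_1,\dots,s_n$, from which

$$z = \frac{s_{\mathrm{obs}} - \bar{s}}{\mathrm{sd}(s)},
\qquad
p = \frac{1 + \#\{ s_i \geq s_{\mathrm{obs}}\}}{n+1}$$

(for the `greater` side; mirrored for `less`). The +1 smoothing keeps
$p > 0$ and gives the floor $p_{\min} = 1/(n+1)$.

Key modelling assumptions, stated plainly:

* **Uniform placement null.** A window is equally likely at every valid
  genomic start; chromosomes are weighted by their number of valid starts
  and placements overlapping the assembly gap mask are rejected. No
  GC-matching, chromatin or replication-timing covariates enter the null —
  enrichment relative to *sequence-uniform* placement is what is tested.
* **Windows are exchangeable.** Randomizing windows (rather than motif
  hits) treats the breakpoint windows as the query set; they are the
  smaller, length-homogeneous set. The opposite assignment is available
  via `randomize = "hits"` and gives the same observed statistic.
* **Independence across windows.** Windows are randomized independently
  and may land on top of each other, exactly as `randomizeRegions()`
  documents.

## Coordinates and containers

Externally the package speaks BED: 0-based, half-open, so touching
intervals do not overlap. Internally regions are `GRanges` (1-based,
closed), the container every Bioconductor tool understands; the two
conventions describe identical base-pair sets and `readBed()`/`writeBed()`
convert exactly. A "breakpoint position" from a BED interval is the
midpoint `floor((start+end)/2)` — breakpoint records may arrive as 1-bp
points or wider junction intervals, and the midpoint rule is this
package's convention (inputs do not state one).

The `GenomeAssembly` class carries chromosome order (input order, never
lexicographic), optional sequence over `A/C/G/T/N`, and a gap mask
covering exactly the maximal `N` runs. Any IUPAC ambiguity code in input
sequence is conservatively masked to `N`: a degenerate genome position can
then never count as a motif match, and randomized regions never land
across it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width` | 100 and 500 bp | total window width; the breakpoint sits at the center, `[p - w/2, p + w/2)`. Edge windows are clipped, not dropped, so the number of windows never silently changes. |
| `nPerm` | 1000 | permutations per test. 1000 makes the attainable floor `1/1001` print as 0.001, the conventional reporting resolution for this analysis. |
| `alternative` | `auto` | resolved to `greater` when the observed count is at least the null mean, else `less`. |
| `strandMode` | `forward` | motif occurrences on the given strand only, matching a plain `matchPattern` workflow; `both` reports reverse-complement matches on forward coordinates and deduplicates. |
| significance rule | `p < 0.05` and `|z| > 3` | the raw per-combination flag; BH q-values per (label × width) stratum are reported in a separate column and never enter the flag. |
| `maxShift`, `step` | `5w`, `w/2` | local z-score displacement grid. |

Windows are never merged, even for breakpoints closer than the width:
each breakpoint contributes one region, and the count-once statistic keeps
duplicated windows meaningful. Motif hits are likewise never merged, which
matters only for hit-set randomization, not for the window statistic.

## The synthetic generator

`generateGenome()` draws i.i.d. bases with $P(G)=P(C)=\mathrm{gc}/2$ and
plants `nPlantedSites` non-overlapping copies of one concrete variant at
uniform positions; `generateBreakpoints()` places each breakpoint, with
probability `enrichmentFraction`, uniformly within `proximityDistance` bp
of a random planted site, else uniformly on the genome. True origins
(`enriched`) and planted positions are recorded so tests can condition on
them.

The reference geometry used by the calibration and power checks is
2 × 2.5 Mb at GC 0.41 (the genome-wide GC of human DNA, a reasonable
single default for a background model), 300 planted copies of
`CCACCATCACCAC` — the one expansion of the degenerate motif that the
screening stage is expected to single out — and 60 breakpoints. The
multi-label fixture (`makeStudyFixture()`) writes four sets of
150/170/230/170 breakpoints on a 3 × 2 Mb genome, echoing the relative
sizes of a four-cancer breakpoint study at desk scale, with per-label
enrichment 0.5 as a middle-of-the-road signal strength.

Two deliberate realism limits:

* background *chance* occurrences of the motif are **not** removed — real
  genomes are full of them, and the test must stay powerful despite them
  (at GC 0.41, a 4-mer like `CCAC` occurs roughly every 400 bp by chance);
* breakpoints are single coordinates, not paired junction ends, and no
  structural-variant mechanism, chromatin state or replication timing is
  simulated. Passing tests therefore demonstrate the statistical machinery
  is correct and calibrated under a sequence-uniform world, not that any
  particular biological confounder is handled.

## Numerical choices and degenerate inputs

* **Empty hit set** (or any null with `sd = 0`): the z-score is reported
  as `NA` with a warning rather than ±∞; the p-value stays valid
  (`p = 1` for an empty hit set). The local z-score refuses an undefined
  parent.
* **Determinism.** Every test accepts a seed; the screen derives one seed
  per (variant, label, width) combination by a stable 31-bit string hash
  of the base seed and the combination identity (`comboTestSeed()`), so a
  single combination re-run in isolation reproduces its row bit-exactly
  and whole screens serialize byte-identically.
* **Ties in nearest-feature annotation** go to the smaller feature start;
  distance is |window midpoint − feature start|, the feature start being
  the TSS coordinate under BED convention.
* **Interval too long to place** (longer than every chromosome's largest
  un-masked stretch) is a hard error rather than an infinite rejection
  loop.
* **Clipped shifted windows** in the displacement profile that leave the
  chromosome entirely simply cannot overlap (they contribute 0), matching
  the clipping convention of window construction.

## Calibration facts the test suite establishes

The suite (and `scripts/acceptance.R`) verifies, at the reference
geometry:

* overlap counting agrees with a brute-force all-pairs oracle on dozens of
  randomized instances;
* on a 30-bp toy instance with length-2 windows the permutation null is
  within total-variation 0.01 of the exactly enumerated
  Binomial$(3, q)$ placement law at $n = 20{,}000$;
* under the null generator (enrichment 0) the fraction of 400 replicates
  with $p < 0.05$ is about 0.03 — *conservative* rather than exact,
  because the null statistic at this geometry has mean ≈ 0.4 and its
  discreteness leaves no rejection region near 0.05 (attainable p-values
  jump from ≈ 0.33 to ≈ 0.065 to ≈ 0.008);
* a planted enrichment of 0.8 reaches the p floor with $z > 3$, the
  local-z profile peaks at zero displacement and collapses beyond one
  window width, and median z is monotone in the enrichment fraction.

Problem sizes throughout (a few Mb, hundreds of sites, $n$ of 200–1000)
are chosen as comfortable desk-scale settings where these distributional
checks are tight; the machinery itself is size-agnostic.

## Known limitations

* The uniform-placement null is the classical one for this analysis but is
  liberal wherever breakpoints and motifs share large-scale covariates
  (GC, repeats, accessibility); a circular-rotation or covariate-matched
  null is out of scope.
* Forward-strand scanning is the default; for the palindrome-poor default
  motif, both-strand scanning roughly doubles hit counts and is one flag
  away.
* The raw significance rule (`p < 0.05`, `|z| > 3`) reproduces the
  screening convention it mirrors; with 1024 variants it implies tens of
  expected false flags per screen, which is why the BH q-value column and
  the pooled per-variant summaries (`summarizeSignificance()`) are
  emitted alongside.
* Whether a variant must be significant in one or in all breakpoint sets
  is a reporting choice, not a statistical one; both pooled readings are
  provided.
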