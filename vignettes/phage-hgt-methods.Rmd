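---
title: "Detecting phage-mediated gene transfer between endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage-mediated gene transfer between endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehgt)
```

## The problem

Obligate intracellular bacteria such as *Wolbachia* rarely meet unrelated
bacteria, so horizontal gene transfer (HGT) into their genomes was long
assumed to be negligible. Temperate phages are the loophole: a prophage that
excises, packages flanking or cargo genes, and lysogenizes a different
strain moves DNA between lineages that never touch. Detecting such an event
from genome sequences alone requires several *independent* lines of
evidence, because any one signal has mundane explanations:

1. **Divergence ratios.** If a prophage moved recently between two host
   strains, the two prophage copies are much less diverged than resident
   prophages of the same family, and no more diverged than the host strains'
   own orthologs. Nucleotide identity and synonymous divergence (dS) are
   compared between three gene groups — the candidate prophage pair, the
   candidate versus the recipient's resident prophages, and host
   orthologs — with Mann–Whitney U tests.
2. **Composition.** Cargo acquired from foreign DNA keeps an alien GC
   signature for a long time; cumulative GC-profile segmentation flags
   compositionally distinct segments at the prophage's ends.
3. **Attachment sites.** An actively excising phage leaves a recombination
   fingerprint: a core sequence shared by attL, attR, attB and attP,
   spanning each junction, sometimes flanked by inverted-repeat arms.
4. **Parsimony.** On the host phylogeny, vertical descent of the shared
   prophage would require multiple independent losses; a single transfer is
   more parsimonious when the loss count is high.
5. **Copy number.** qPCR copy ratios above one for phage (and packaged
   flanking) genes relative to single-copy host genes show that the region
   replicates extrachromosomally, i.e. is part of the virion.

The package implements each stage as a tidy, tibble-first function, and a
seeded synthetic-data generator that emulates the statistical structure of
all five signals, so the whole pipeline is testable offline.

## Synonymous divergence (Nei–Gojobori 1986)

The divergence clock is the original (equal-weight) Nei–Gojobori
estimator. For each codon, the synonymous site count is the fraction of
admissible single-base changes that preserve the amino acid, summed over
the three positions; changes that create stop codons are excluded from both
numerator and denominator. Between two codons differing at $k$ positions,
synonymous/nonsynonymous step counts are averaged over all $k!$ orderings,
excluding orderings that pass through a stop (if *every* ordering does, the
unrestricted average is used and flagged). With $p_S = S_d/S$, the
Jukes–Cantor correction gives

$$ d_S = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3} p_S \right), $$

undefined (and flagged, never silently `NaN`) when $p_S \ge 3/4$. Variance
comes from a codon-column bootstrap (default 1000 replicates, seed
recorded); replicates where the statistic is undefined are dropped and
counted.

```{r ng86}
fit <- ng86("TTTGGGAAA", "TTTGGAAAA")
tidy(fit)
```

Two choices deserve a note. "Nei–Gojobori" sometimes means the modified
(Zhang) variant; the original equal-weight variant is implemented and named
in the output, since that is what mainstream distance software computes by
default. Codon columns containing gaps, ambiguity codes, or stop codons are
dropped pairwise; consequently ng86 expects in-frame alignments, and gap
runs whose lengths are not multiples of three can shift the frame of what
follows. The pairs produced by the pipeline's ortholog step are
substitution-only and unaffected; a codon-aware aligner is out of scope.

## Alignment, trimming, orthologs, homology search

Pairwise global alignment is Needleman–Wunsch with affine gaps
(match +2, mismatch −3, gap open 5, extend 2; a gap of length $k$ costs
$5 + 2k$), delegated to Biostrings and verified in the tests against
exhaustive enumeration of all alignments for short inputs. Identity is
reported over ungapped columns by default. A simplified conserved-block
filter stands in for the classical trimming step: columns at or above a gap
fraction of 0.5 are removed, surviving runs shorter than 10 columns or
below 50% identity are dropped. Exact behaviour of the classical tool is
explicitly not promised; the paper-level quantities (group mean identities
and dS) are insensitive to this at the precision compared.

Ortholog pairing is reciprocal best hit on trimmed identity (ties: longer
aligned length, then lexicographic id). The homology screen is a seeded
local search (11-mer seeds, one ungapped X-drop extension per diagonal,
both strands). E-values follow the Karlin–Altschul form
$E = KmN e^{-\lambda S}$ with $\lambda$ solved exactly from the scoring
scheme's moment equation; $K$ is a fixed calibration constant (0.1) rather
than the full iterative series, because the screen only uses the *ranking*
of hits and a broad cutoff ($10^{-5}$), which a constant $K$ cannot
disturb. Raising the cutoff never removes a presence call (tested).

## Compositional segmentation

The cumulative profile walks the sequence scoring +1 for A/T, −1 for G/C
(0 for ambiguity codes); the detrended profile's interior extrema mark
compositional boundaries. Segmentation is recursive binary splitting: the
candidate cut maximising a two-proportion z statistic on GC fractions is
accepted iff it reaches the halting threshold (default 7) and both sides
keep the minimum segment length (default 100 bp) — both knobs match the
cited profile tool's user-facing parameters, while the merit function is a
z statistic rather than the tool's exact quadratic divergence, so
equivalent qualitative behaviour (validated on planted inserts), not
bit-identical breakpoints, is the promise. The candidate argmax is
restricted to cuts leaving both sides at least the minimum length, which is
how the "minimum length to segment" knob reads in practice and avoids
spurious early stops. Because early global cuts are noisy when several
change points exist, a refinement pass re-localises each boundary using
only its two adjacent segments, iterated to a fixed point; this is the
standard companion of binary segmentation and is what brings boundary
errors on a 0.35-vs-0.60 GC contrast to a few tens of bases. Segments
whose GC differs from the genome background by at least `alien_delta`
(default 0.05) are flagged alien.

```{r seg}
g <- simulate_genome_with_insert(seed = 3)
segs <- segment_genome(g$seq)
call_alien_segments(segs, genome_gc = gc_fraction(g$seq))
```

## Attachment sites

`att_context()` derives the four junction sequences from a prophage and
its flanks; `build_attP()` is the circularized-phage junction (3' end
joined to 5' start). The core is defined as the longest string occurring in
all four sequences with an occurrence overlapping each junction — the
recombination-crossover semantics, not mere presence. Cores of length one
are admissible (observed in real systems), so "overlap" counts a string
touching either junction-adjacent base. Ties are broken by the occurrence
closest to the junction, then lexicographically, making the search
deterministic.

Inverted-repeat arms are searched abutting the core (an optional `max_gap`
allows a few intervening bases), with Hamming mismatches only (no indels,
for determinism), scanning arm lengths from long to short: longest arm
wins, then fewest mismatches, then smallest gap. Anchoring the arms at the
core is deliberate: integrase arms sit directly beside the core, and a
free-floating search over a 200 bp window would drown in chance
reverse-complement matches at any usable arm length.

## Statistical spine

The Mann–Whitney U statistic is computed from rank sums (midranks under
ties); the p-value is exact by enumeration when the combined sample is at
most 20 and tie-free, otherwise a tie-corrected normal approximation with
continuity correction. The exact path is verified against full enumeration
of labelings for all group sizes up to 6, and the approximation's type-I
error at $\alpha = 0.05$ is checked by simulation. When every observation
is tied the statistic carries no evidence and p is reported as 1.

Dollo loss counting assumes a single gain above the carriers' most recent
common ancestor and returns the number of maximal carrier-free subtrees
inside that clade — the minimum number of independent losses vertical
descent would require. It is verified against brute-force minimisation
over all loss placements on random trees of up to 8 leaves (a random
sample of topologies; exhaustive topology enumeration grows factorially
and adds nothing at this tree size).

qPCR standard curves are least-squares fits of Ct against log10 copies;
amplification efficiency is $10^{-1/\text{slope}} - 1$. Plate effects are
removed by rescaling each plate so its calibrator mean matches the
cross-plate calibrator mean — a documented stand-in for the unpublished
normalisation the field cites. Copy ratios are tested per replicate with a
one-sample two-tailed t-test against the expected single-lysogen ratio
of 1.

The verdict classifier is a pure function of the recorded statistics:
`recent_transfer` requires (i) candidate-pair identity significantly above
the candidate-vs-resident identity (two-tailed MWU, default $p < 0.01$,
the significance level the divergence-ratio argument rests on), (ii)
candidate identity not significantly *below* host-ortholog identity
(one-sided MWU at 0.05) or candidate mean dS at or below the host mean,
and (iii) at least 2 Dollo losses when a tree is supplied. Failing (i)
gives `vertical_or_ancient`; anything else is `indeterminate`. All
thresholds are configuration, and the full evidence record (including a
pseudo-replication note: gene-level observations within one genome pair
are not independent) is always emitted.

## What the generator emulates — and what it does not

`simulate_study()` builds two single-contig genomes realizing the three
divergence groups: host orthologs at dS 0.10, a transferred candidate
prophage pair at dS 0.07, and two resident prophages at dS 0.27 relative
to the candidate — the regime reported for the canonical
donor/recipient comparison this pipeline formalises. Defaults of 12 host
genes and 8 phage genes of ~300 nt (plus 2 alien cargo genes at GC 0.60 on
a GC 0.35 backbone, the att core ATGA with 7 bp inverted-repeat arms, and
a toy 8-leaf host phylogeny on which the two carriers require 3 losses)
keep a full pipeline run to a few seconds while leaving every test
well-powered; these sizes are the package's chosen simulation conditions
and are stated here once. qPCR data are generated from the implied Ct
curve (10-fold standards from $10^3$ to $10^7$ copies in triplicate — the
field's standard plate design, and what makes the efficiency recover
within the reported 96.6–104.4% band under realistic Ct noise) with true
ratios 2.90, 3.21, 2.45 (phage and packaged flanks versus host) and 1.01
(host control).

Sequence evolution is substitution-only and purely synonymous by default:
a Poisson number of synonymous single-base changes with expectation
$S \cdot p_S^{target}$, where $p_S^{target}$ inverts the Jukes–Cantor
correction. This makes dS the only divergence axis, matching the use of
the synonymous rate as the transfer clock. Two consequences are worth
knowing. Repeated hits at the same site make the realized $p_S$ fall
slightly below the target at higher divergences, so recovered dS is mildly
conservative (about 5% low at dS 0.1, more at 0.3); the realized $p_S$ is
recorded in the truth object so nothing needs re-deriving. And real
genomes add everything the generator omits: indels, recombination,
selection on nonsynonymous sites, codon-usage heterogeneity, rearranged
gene orders and assembly artefacts. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the model's
assumptions — not that real annotations are clean.

The attachment-site generator plants arms on the phage ends only (so attB
carries no arms, as in a real un-integrated site), constrains the
junction-adjacent flank bases so the planted core cannot extend across a
junction by chance, and resamples flanks until the planted core is the
*unique* maximal junction-spanning common string — otherwise "planted
core" would be ill-defined for short cores and 100% recovery would be an
accident of tie-breaking.

## Numerical choices and degenerate inputs

* Leftmost argmax on segmentation ties; lexicographic tie-breaks in core
  and RBH searches: every search is deterministic.
* Single-base-class sequences (GC fraction 0 or 1) return one segment
  without attempting a split; sequences shorter than twice the minimum
  segment length are rejected.
* Saturated divergences (p at or above 3/4) are flagged, not propagated
  as `NaN`; bootstrap replicates that saturate are dropped and counted,
  with a warning past 50%.
* A noiseless copy-ratio vector has zero variance; the t statistic is
  reported as 0 (p = 1) at the expected ratio and unbounded otherwise.
* Pseudogenes and length-non-multiple-of-3 or internal-stop CDSs are kept
  in the data model but excluded from codon analysis with a logged
  reason; ambiguous bases are stored, dropped from codon columns, and
  neutral in composition.
* All randomness flows through explicit seeds; bootstrap seeds are
  recorded in the result objects.

## Problem sizes used by the tests and the acceptance script

Parameter recovery uses 100 gene pairs of 999 nt at dS 0.10 with
1000-replicate bootstraps; segmentation uses 20 planted-insert and 50
homogeneous 10 kb genomes; att-core recovery uses 100 seeded fixtures
(including the ATGA core); MWU calibration uses 1000 two-group draws of
30 each; the end-to-end null uses 100 simulated studies with all groups
at dS 0.10; Dollo is checked on 60 random trees of 3–8 leaves against the
brute-force oracle. These sizes were chosen so each property is tested
with useful power on a single core.

## Known limitations

* No codon-aware alignment and no indel evolution; ng86 trusts its input
  frame.
* The homology screen is a teaching-grade seeded search: no gapped
  extension, no two-hit heuristics, constant K. It is not a BLAST
  replacement beyond the screening role it plays here.
* The verdict classifier inherits the gene-level pseudo-replication of
  the underlying test design; it reports it rather than correcting it.
* Transfer *direction* is not inferred — a positive verdict reads
  "directly or indirectly transferred", nothing more.
* Plate normalisation is calibrator scaling; if the calibrator itself
  varies biologically across plates, the correction absorbs that
  variation too.
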