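---
title: "Detecting genomic catastrophes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic catastrophes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shatterscan)
```

# Scope

Tumor genomes can acquire structural complexity through single catastrophic
events rather than gradual accumulation: chromothripsis (one-off chromosome
shattering and random religation), breakage-fusion-bridge cycles (BFB;
iterated telomere loss, sister-chromatid fusion and anaphase breakage), and
double-minute chromosomes (DM; circular extrachromosomal amplicons that can
carry oncogenes). `shatterscan` detects these processes from three standard
somatic inputs — SNVs (VCF), SV breakpoint pairs with orientations and
evidence counts (BEDPE dialect), and allele-specific copy-number segments
(TSV) — plus sequencing reads for telomere content. A synthetic cohort
generator with truth labels makes every detector testable without access to
patient data, which for the study design this package implements is
controlled-access.

This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic studies do and do
not demonstrate.

# Copy-number state model

Integer total copy number (CN) and major-allele fraction (maf) classify each
segment:

| state | rule |
|---|---|
| loss | CN 0–1 |
| neutral | CN 2, maf < 0.9 |
| cn_loh | CN 2, maf ≥ 0.9 (copy-neutral loss of heterozygosity) |
| gain | CN 3–5 |
| amplified | CN ≥ 6 |

The 0.9 heterozygosity cutoff is a deliberate tolerance: at realistic tumor
cellularity (~70%), BAF-derived allele fractions of truly heterozygous
segments are noisy, while cnLOH segments sit at maf ≈ 1. The cutoff is
exposed (`het_maf`) on `chromothripsis_criteria()` and
`classify_cn_state()`.

# High-confidence SV filtering and typing

A call is high-confidence when it has at least two evidence classes
(discordant pairs, split reads, soft clipping) with any support, or one
class with ≥ 10 reads; no support in the matched normal; and breakend
region coverage ≤ 1000 (removing high-coverage repeat artifacts). The filter
is a total function returning the first failed clause as the reject reason,
and it is monotone: more tumor support never demotes a call, more normal
support never rescues one.

Typing integrates breakend orientations with CN context through a
first-match-wins decision table: translocation (interchromosomal) →
deletion (head–tail join whose two breakends match the two boundaries of a
loss segment within ± 30 kb) → tandem duplication (tail–head join
boundary-matched to a gained/amplified segment) / duplication (tail–head
join overlapping a gained segment without boundary match) → fold-back
inversion (same-orientation join, breakend separation ≤ 30 kb, with a CN
state step within ± 30 kb of the join) → amplified inversion (both
breakends inside amplified segments) → inversion → intrachromosomal.
Fold-back must precede plain inversion in the table or it is unreachable.
The ± 30 kb window is the array-resolution matching tolerance used
consistently everywhere a breakend is compared with a segment boundary
(including the amplicon graph); the fold-back span cap reuses it in the
absence of a stated span, since fold-back junctions map within amplified
regions at short range. The split between fold-back (short span + CN step)
and amplified inversion (amplified-segment membership) is this package's
operationalization — the source material does not define the two
operationally — and both labels count as "inversion-family" wherever a
detector needs inversions.

# Chromothripsis

A chromosome is called chromothriptic when five criteria hold jointly:

1. **Breakpoint clustering** — one-sample Kolmogorov–Smirnov test of
   breakend positions against Uniform(0, length), asymptotic p < 0.001.
   Each breakend of an intrachromosomal SV counts once; a translocation
   contributes its one breakend on the chromosome.
2. **Oscillation** — ≥ 10 switches between adjacent segments' total CN.
3. **Few states** — 2 or 3 distinct total-CN levels on the chromosome,
   read as the count of distinct integer CN values.
4. **Retained heterozygosity** — every segment at the modal higher CN level
   (the "retained" state of the oscillation) is heterozygous (maf < 0.9);
   segments at the minimum level ("lost") are exempt. Missing allele data
   makes the verdict indeterminate (`NA`), never negative.
5. **Random joins** — chi-square goodness-of-fit (df = 3) of the four
   orientation-pair counts against uniformity, p ≥ 0.001; fewer than 8
   joins is indeterminate and fails the criterion. This is the simplest
   faithful operationalization of join-randomness; segment-order
   permutation tests were considered and rejected as answering a different
   question (fragment order rather than junction geometry).

The array-only screen (`detect_chromothripsis_array_only()`) uses criteria
2–4 only, supporting CN-array cohorts without sequencing.

All five flags are reported per chromosome; the composite verdict is
asserted (at run time) to equal their conjunction. The package flags every
chromosome independently and lets the report list all positives, since "one
or few chromosomes" is not quantified in the source design.

# Breakage-fusion-bridge

BFB is called on a chromosome when (i) a terminal run of loss-state
segments spans ≥ 1 Mb (telomeric loss), (ii) an amplified segment (CN ≥ 6)
begins within 1 Mb of that run, and (iii) at least 2 inversion-family SVs
have both breakends inside the contiguous amplified region. The 1 Mb spans
are artifact defaults (configurable via `bfb_criteria()`); the source
material states no spans. Both chromosome ends are tested, so the detector
is mirror-symmetric (p-arm and q-arm events are equivalent).

# Kataegis

Per chromosome, intermutation distances (IMDs) are computed on sorted,
deduplicated positions, and the log10(IMD) series is segmented by exact
piecewise constant fitting (PCF) with penalty c = 25 and minimum segment
length kmin = 2. A focus is a run of ≥ 6 consecutive mutations, contained
in one segment, whose raw (untransformed) mean IMD is ≤ 1,000 bp; the
longest qualifying run per segment is taken and disjoint runs are reported
separately. Three numerical choices deserve explanation:

* **log10 scale.** A penalty of 25 is meaningless against raw distances
  spanning 10^0–10^8; on the log scale the penalty is commensurate with the
  squared separation (~3 log-units) between focus-density and
  background-density IMDs. Whether the original analysis segmented raw or
  transformed IMDs is not recoverable from the text; log10 is this
  package's documented choice, and both parameters are configurable
  (`kataegis_params()`).
* **Containing-run qualification.** The qualifying test applies to the
  longest contained run rather than the whole segment, because with
  kmin = 2 the exact optimum will absorb a single flanking background
  mutation into a focus segment whenever isolating it would cost a
  boundary; the absorbed ~10^4–10^6 bp linking distance would otherwise
  disqualify a genuine cluster by inflating the segment mean.
* **Exactness.** `pcf_segment()` is an O(n²) dynamic program returning the
  exact penalized optimum (ties broken toward fewer segments, then earlier
  boundaries); the suite verifies it against exhaustive enumeration over
  all segmentations for series up to n = 20.

Focus counts map to a per-genome burden label: none (0), occasional (1–9),
numerous (≥ 10).

The 96-context spectrum (`spectrum_matrix()`) uses pyrimidine-normalized
substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) × 5′ base × 3′ base,
indexed `16·sub + 4·idx(5′) + idx(3′)`; enumeration of all 192 raw
combinations collapses onto exactly 96 classes, two strands each.

# Telomere content

A read is telomeric iff it contains `TTAGGG` × 3 or `CCCTAA` × 3 as a
contiguous substring (case-insensitive; `N` breaks a match; a read counts
at most once). Degenerate telomeric variants are deliberately not matched.
Counts are normalized by mean genomic coverage — an input parameter, since
read sets alone cannot supply genome-wide base coverage — and the
tumor/normal ratio of normalized counts reports somatic telomere change
(< 1 = shortening).

# Amplicon reconstruction

Amplified segments become graph nodes with two ports (left/right end). An
SV becomes an edge when each breakend matches a fragment end within ± 30 kb
with the compatible orientation (head ⇒ left end, tail ⇒ right end).
Candidate double minutes are simple cycles in which every fragment is
traversed through opposite ports and consecutive orientations agree with
the SV ports. The search is exhaustive with a 12-fragment cap — real DMs
reconstructed this way have ~6 fragments, and exactness beats scalability
at that size. Cycles are canonical (rotated to the lowest fragment id,
reported up to reflection), validated by an independent port-consistency
re-check, and all overlapping cycles are reported (no model selection among
alternatives, which the source narrative does not specify). The test suite
proves oracle equivalence against an independent edge-subset enumeration:
a k-fragment cycle uses exactly k SV edges with both ports of every
involved fragment at degree 1 and single-component closure.

# Genome subtyping

≥ 450 high-confidence SVs ⇒ `unstable`; otherwise any chromosome with ≥ 5
breakends at ≥ 3× the genome-wide breaks/Mb rate ⇒ `complex_localized`;
otherwise `scattered`. "Expected" breaks/Mb is the same genome's own rate,
and the 3× rule counts breakends (double-strand break ends), not events.

# The synthetic cohort generator

`sim_params()` defines the reference study conditions; `simulate_sample()`
is deterministic given its seed. Defaults: 22 chromosomes × 100 Mb;
chromothripsis shattering 30 fragments between CN states {2, 3} with
retention probability 0.5; BFB with 5 Mb telomeric loss, a 4 Mb CN-8
amplicon and 20 fold-back inversions; kataegis foci of 8 mutations over
4 kb on a 1/Mb background; a 2.5 Mb six-fragment CN-8 double minute spread
over 3 chromosomes; scattered background SVs at 0.03/Mb (≈ 66 per genome,
within the scattered-subtype burden); tumor/normal read mixtures at 74× and
39× coverage with telomeric fractions 0.01/0.02. Evidence counts are drawn
so ~95% of simulated SVs pass the confidence filter and the rest exercise
each reject path; DM junction SVs always pass (they model validated
junctions, and one failing junction would break the planted circle rather
than degrade it gracefully).

The generator's contract is **clear-margin truth**: every planted event
must be detectable at the package's default criteria, and every unplanted
chromosome must be negative. Several design decisions exist purely to honor
that contract, and they are the generator's definition of the phenomena —
not tuning knobs:

* **Localized shattering.** The shattered region occupies a fraction
  (default 0.15) of the chromosome, placed in the distal q arm (relative
  position 0.60–0.92 − span). A whole-chromosome partition would spread
  breakpoints uniformly and no clustering test could, even in principle,
  flag it; the real events are arm-confined concentrations. The distal
  placement bounds the worst-case KS deviation at ~0.4 even after
  background-breakend dilution.
* **Retry-until-criterion.** Stochastic constructions that must meet hard
  thresholds are redrawn up to 100 times, then error: the retained/lost
  assignment until ≥ 10 switches and ≥ 9 retained fragments (so the event
  has ≥ 8 joins, the join-randomness minimum); join orientations until the
  uniformity test gives p ≥ 0.01; and, at the sample level, each planted
  chromothriptic chromosome until KS clustering p ≤ 10⁻⁴ and
  join-randomness p ≥ 0.01 hold on the chromosome's full high-confidence
  SV complement, background included. A draw that fails to exhibit the
  defining features of the phenomenon is not a valid planting.
* **Kataegis context.** Foci are spread over distinct chromosomes when
  possible, kept ≥ 10 Mb apart otherwise, placed in the interior [0.2, 0.8]
  of the chromosome, and background SNVs within 10 kb of a focus are
  dropped. Each rule protects the identifiability of the planted truth:
  foci closer than ~7 Mb merge into one PCF segment whose interstitial
  background disqualifies both; a focus with ≤ 1 background mutation on one
  side cannot anchor its segment boundary under kmin = 2; and a background
  mutation inside a focus changes the cluster's true mutation count.

**What passing these studies shows — and does not.** The generator emulates
the geometry and statistics the detectors test (oscillation, clustering,
join orientation, focus spacing, motif content), not sequencing physics: no
read-level noise, no alignment artifacts, no segmentation error in the CN
input, no purity/ploidy distortion, and CN profiles are exact integers.
Truth recovery on these cohorts validates the logic and the statistics of
the detectors; it does not measure their sensitivity on real WGS, where the
upstream callers dominate error. The negative-control side (zero false
positives across ~1,000 event-free chromosomes per study) is similarly a
statement about the decision rules, not about artifact robustness.

# Study sizes

The packaged studies (test suite and `scripts/acceptance.R`) use: 50
samples × 1–3 chromothriptic chromosomes (≈ 100 positives, ≈ 1,000
negatives); 50 BFB samples plus the three single-ingredient ablations
(no inversions, CN-3 neighbor, no telomeric loss); 100 SNV sets with 0–5
planted foci on an 8 × 50 Mb genome plus 20 sets of 5-mutation
sub-threshold clusters; 1,000 uniform and 100 clustered chromosomes for KS
calibration at n = 50 breakpoints (asymptotic null rejection ≈ 0.04); 200
random series (n ≤ 20) against the exhaustive PCF oracle; 50 random port
graphs (≤ 12 fragments) against the edge-subset cycle oracle plus the
planted single- and three-chromosome DMs; a 500-combination evidence-filter
sweep; and 10,000-read telomere mixtures at fractions 0, 0.02 and 0.2.

# Known limitations

* Temporal ordering of co-occurring catastrophes (e.g. BFB following
  chromothripsis) is out of scope; the per-chromosome verdicts are
  marginal.
* The amplicon search distinguishes circular topology, not DM from HSR —
  that distinction requires cytogenetics.
* `heterozygosity_retained()` reduces a chromosome to one modal retained
  level; profiles with two genuinely retained levels at different maf are
  summarized conservatively.
* The KS clustering test conditions on ≥ 5 breakends and uses the
  asymptotic p-value; with very few SVs per chromosome the detector is
  intentionally insensitive rather than anti-conservative.
* Telomere counting requires the exact tandem triple motif; variant
  telomeric repeats are not counted, so absolute content is underestimated
  in genomes rich in degenerate repeats (the tumor/normal ratio is less
  affected).
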