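---
title: "Models and methods behind ribomethr"
author: "ribomethr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribomethr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomethr)
```

## The measurement principle

Ribose 2'-O-methylation (Nm) renders the phosphodiester bond immediately 3'
of the modified residue resistant to mild alkaline hydrolysis. When total
RNA is randomly fragmented under alkaline conditions and the fragment ends
are sequenced deeply, read ends become a per-bond cleavage counter: bonds 3'
of methylated riboses accumulate *fewer* 5'/3' read ends than their
neighborhood. The local deficit is quantitative — to first order, the
fraction of molecules methylated at a residue (the stoichiometry $f$)
equals the fractional depletion of end counts at its bond.

`ribomethr` implements this protection-score analysis end to end, together
with the two companion analyses used to interpret an rRNA methylation
repertoire: box C/D snoRNA guide assignment (which snoRNA directs each
methylation) and low-dNTP primer-extension confirmation (an orthogonal,
non-sequencing read-out).

## The protection score

Let $n_i$ be the end count of bond $i$ (joining residues $i$ and $i+1$):

$$n_i = \text{fivePrimeEnds}[i+1] + \text{threePrimeEnds}[i],$$

both terms reading out cleavage of the same bond. With a window of $l = 6$
flanking bonds per side and linear-taper weights $w_j = (l + 1 - j)/l$, the
local baseline is

$$B_i = \tfrac12\!\left(
  \frac{\sum_{j=1}^{l} w_j\, n_{i-j}}{\sum_{j=1}^{l} w_j} +
  \frac{\sum_{j=1}^{l} w_j\, n_{i+j}}{\sum_{j=1}^{l} w_j}
\right),$$

and the methylation score is $s_i = 1 - n_i / B_i$, clamped into $[0,1]$.
Flanks outside the bond range are excluded with weight renormalization.
Under the protection model the expected end count at a site with
stoichiometry $f$ is $(1-f)$ times its neighborhood baseline, so
$\mathbb{E}[s_i] \approx f$; the acceptance suite verifies recovery within
$\pm 0.05$ across $f \in \{0, 0.25, 0.5, 0.75, 1\}$.

Numerical and robustness choices:

* **Missing-data guards.** A score is reported missing rather than wrong:
  at positions with fewer than `min_neighbors = 3` usable flanks per side
  (sequence ends) and wherever $B_i <$ `min_local_ends` $= 10$ (coverage too
  thin for a stable ratio). Degenerate inputs never raise exceptions in
  scoring.
* **Clamping.** Over-cleaved positions would score negative; they are
  clamped to 0 because the downstream logic (cutoffs in $[0,1]$) has no use
  for negative stoichiometries. Clamping inflates the score of truly
  unmethylated positions by roughly $\sigma/\sqrt{2\pi} \approx 0.02$ at
  default depth — well inside the $\pm 0.05$ recovery contract.
* **Both end types are summed** (5' at $i+1$, 3' at $i$); a `ends =
  "five_prime"` switch restricts to 5' ends for chemistries with biased
  3'-end capture.
* **Exact depth invariance.** The score is a ratio, so multiplying every
  count by a constant changes nothing; this is tested to $10^{-12}$.

Site calling is threshold-based, mirroring the cutoff logic of the
repertoire it reimplements rather than a hypothesis test: a position is
*detected* when its score reaches `detection_threshold = 0.30` in at least
75% of a stage's replicates for at least one stage, and *hypomethylated*
when a mean score falls strictly below `cutoff = 0.75`. Both thresholds
were chosen to be conservative on synthetic nulls (no false detections at
default depth) and are arguments, not constants.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every quantitative contract is verified.

**Fragmentation.** Each of `molecules` template molecules (default 20000)
has every internal bond $b$ cleaved independently with probability
$p_0 (1 - f(b))$, $p_0 = 0.03$; fragments with length in $[20, 50]$ are
retained, emulating a protocol tuned to ~20-30 nt fragments (the window is
deliberately a bit wider so baseline estimation sees mild coverage
waviness). Per-molecule simulation makes end conservation an exact
identity — the number of retained fragments equals both end-count totals —
which the tests assert as equalities, not approximations. A cleavage
probability high enough that the expected fragment length falls below
`min_len` warns rather than errors.

**Embryo series.** Six developmental stages (2, 10, 16, 23, 32, 45) with
four individually "sequenced" embryos each. Replicate embryos perturb the
stage truth by a truncated-Gaussian deviate (`replicate_noise = 0.02`);
biological replicate variance is not published for this design, so the
default is small, consistent with the tight replicate clustering the
profiled series shows. All randomness fans out from one root seed through
`derive_seed()` (a deterministic label hash), so any single (stage,
replicate) is reproducible in isolation.

The packaged demonstration series (`demo_stage_design()`) places 40 sites
on a synthetic 1800-nt rRNA — about one site per 45 nt, matching the site
density of the real repertoire (103 sites across ~6 kb of rRNA) — covering
four behavior classes: robust ($f = 0.95$), constitutively hypomethylated
($f = 0.45$), stage-45-only hypomethylated ($0.9 \to 0.45$), and monotone
developmental ramps ($f$ moving by 0.2 between consecutive stages, both
directions). The ramps give consecutive stages a real signature;
the site count matters because profile clustering estimates correlations
across sites, and a series with too few sites under-determines them: with
only ~20 sites the flat cut occasionally merged the two earliest stages
while splitting a noisy replicate, which is a statement about information
content, not about the clustering method.

**RT-stop profiles.** Reverse transcriptase starts at a primer position and
walks 3'→5'; opposite residue $i$ it terminates with probability
$f(i)\,s(\text{condition}) + 0.002$, where $s(\text{low}) = 0.8$ and
$s(\text{regular}) = 0.05$. The cDNA 3' end of a stop is recorded one
nucleotide 3' of the pausing residue (`stop_offset = 1`, configurable to
0). Sampling uses the exact inverse-transform of the stop distribution, so
a profile costs $O(L + \text{depth})$.

**Guide transcriptomes.** For each target site, one transcript shaped like
a guide-finder report: 4 leading nt, C box `GUGAUGA`, a 20-nt spacer, a
12-nt guide exactly antisense to the rRNA window dictated by the +5 rule,
D box `CUGA`, 2 trailing nt. Two construction details make the round trip
exact rather than merely likely: the spacer contains no U (so no spurious
C- or D-box motif can arise in it, and a 20-nt spacer keeps any chance
`CUGA` inside the guide below the 30-nt box-separation floor), and the
spacer's last nine nucleotides are chosen to mismatch — neither
Watson-Crick nor wobble — any leftward extension of the guide/rRNA duplex,
so the embedded 12-mer is the unique best duplex at every scanned guide
length. Each finished transcript is additionally verified by re-scanning
it against the references, and its spacer resampled in the rare case a
chance near-antisense repeat elsewhere would recruit spacer nucleotides
into a longer, higher-scoring duplex; the round-trip guarantee is thus by
construction, for any seed. Decoys are random sequences constructed greedily so that every
12-nt window keeps Hamming distance ≥ 3 from the antisense of every rRNA
12-mer (position-by-position selection with vectorized distance profiles
and local backtracking; rejection sampling cannot work here, since a random
12-mer sits within distance 2 of *some* antisense window of a 6-kb
reference about 20% of the time).

What the generator does **not** model: sequencing error, ligation/GC bias,
PCR duplication, sequence- or structure-dependent cleavage heterogeneity,
and paired-end structure (alignments are ingested as single fragments).
Passing tests therefore demonstrate correctness of the inference given the
protection chemistry, not robustness to library artifacts.

## Guide search and the +5 rule

The search is a deterministic motif-plus-duplex model: C box `RUGAUGA`
(≤ 1 mismatch, R = A/G) upstream of an exact D box `CUGA` separated by
30-200 nt, optional internal D' box (`CUGA` ≤ 1 mismatch), and for each
box a guide of length 10-21 ending immediately 5' of it, scored against
every rRNA window (Watson-Crick +1, G·U wobble +0.5, mismatch −2, at most
one mismatch per duplex). The predicted target is the rRNA residue paired
with the 5th guide nucleotide counted upstream from the box — equivalently
the 5th window position from its 5' end — and every emitted candidate
stores enough coordinates for the tests to recompute this independently.
Candidate score = duplex score + box bonuses (C +5, D +3, D' +2) − 2 per
C-box mismatch, reported at ≥ 12.

Site assignment follows the repertoire's own selection logic: the
highest-scoring candidate per site, ties broken by the best free-end-gap
pairwise alignment (match +1, mismatch −1, gap −2) against a supplied
ortholog set, remaining ties by (transcript, span) order so output is
byte-deterministic. Terminal-stem scoring is deliberately omitted from the
default score; wobble pairs count half, a choice the source material leaves
open.

## Low-dNTP primer-extension confirmation

The decision rule is literal: a site is confirmed when its normalized
low-dNTP stop signal strictly exceeds `min_fold` times the regular-dNTP
signal; a site surveyed by several primers is confirmed if any survey
confirms it, and un-surveyed sites are reported as such rather than
failing. `confirm_by_primer_extension()` defaults to `min_fold = 1` — the
rule as stated for gel band intensities. For *count* data the two
conditions share a Poisson background (~20 stops per position at depth
10,000 with the default 0.002/nt background), and two equal-rate Poisson
draws satisfy a strict ">" about half the time; fold 2 still confirms ~2%
of null positions, while fold 3 brings this to ~0.1%. `batch_validate()`
therefore defaults to `min_fold = 3`, which loses nothing on real signal
(a half-methylated site under low dNTP exceeds its regular signal
~15-fold). Primer placement matters in batch designs: an intervening
methylated residue between primer and target terminates most low-dNTP
extensions before they reach the target, so simulated surveys place each
primer downstream of its site but upstream of the next methylated residue,
as an interleaved oligo panel does. No background subtraction is applied.

## Packaged catalog fixtures

`xl_site_catalog()`, `xl_stage_scores()` and `xl_snorna_assignments()`
ship a distilled 103-site repertoire (34/2/67 sites on 18S/5.8S/28S, 15
novel, 23 validated, 10 constitutive and 12 stage-45-only hypomethylated
sites, 49 novel guide candidates) over synthetic stand-in reference
sequences; all individually named residues and all counts follow the
published repertoire, while filler positions, per-stage score values and
counterpart labels of unnamed sites are generated (`data-raw/make_fixtures.R`,
filenames carry `_synthetic`). The fraction of hypomethylated sites is
reported under three readings — overall mean, all stages below cutoff,
any stage below cutoff — because "percent hypomethylated" is ambiguous
between them; on the packaged fixture they are 9.7%, 9.7% and 21.4%.

## Problem sizes and determinism

The quantitative contracts run at desk scale: stoichiometry recovery at
20,000 molecules × 10 seeds on a 2-kb reference; the clustering analog at
20 seeded runs of the full 6 × 4 series; guide round trips with 5 embedded
guides against 50 decoys over the ~6-kb reference set; primer-extension
checks at depth 10,000 over ~1,300 null positions. These sizes were chosen
so the whole suite re-runs in minutes while leaving every contract
comfortably determined; all of them are arguments to the corresponding
functions, not constants. Identical seeds reproduce every output file byte
for byte (manifest timestamps excluded by design — the manifests record
seeds, parameters and counts only).

## Known limitations

* The protection score is a first-order estimator; closely spaced sites
  (within one scoring window, 6 nt) bias each other's baselines and are
  not deconvolved.
* Alignment ingestion trusts the aligner: no MAPQ filtering or soft-clip
  correction beyond CIGAR-aware end computation, and clipped reads can
  break the end-conservation identity (they are counted and logged).
* The guide model is a motif heuristic, not a thermodynamic or
  probabilistic model; it is calibrated only on the synthetic round trip
  and is expected to under-call non-canonical guides on real transcripts.
* Replicate noise is modeled as independent truncated-Gaussian
  perturbation of stoichiometry; real embryo-to-embryo covariance
  structure is unknown and unmodeled.
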