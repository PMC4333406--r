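---
title: "Screening promoters for paired HZA and GATA enhancer elements"
author: "hzascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening promoters for paired HZA and GATA enhancer elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzascreen)
```

## The biology and the computational problem

In *C. elegans*, several genes that respond to high dietary zinc —
the metallothioneins *mtl-1* and *mtl-2* and the CDF zinc transporters
*cdf-2* and *ttm-1b* — share a 15-bp promoter motif, the **high zinc
activation (HZA) element** (core consensus 5'-CANAAAC-3'), which sits
within 20 bp of a **GATA element** (TGATAA), the binding site of the
intestinal GATA factor ELT-2. The two elements act as a module: the GATA
element confers intestine-specific expression and the HZA element confers
zinc responsiveness. Because the module is compact and its spacing
constrained, it can be used as a genome-wide *predictor* of novel
zinc-inducible genes.

`hzascreen` implements that screen as a reusable, fully testable pipeline:

1. **Motif elicitation** (`discoverMotif`) — deterministic EM (OOPS/ZOOPS)
   over a small set of co-regulated promoters, seeded from every substring.
2. **Weight-matrix machinery** (`buildPWM`, `scoreScheme`,
   `nullDistribution`, `cutoffForPvalue`) — probability matrices with exact
   per-window null score distributions and p-value cutoffs.
3. **Region extraction** (`extractUpstreamRegions`) — upstream intergenic
   sequence per gene, up to 20 kb, in the translation-start coordinate
   convention (the A of ATG is +1, the preceding base is −1; no offset 0).
4. **Scanning and pairing** (`scanRegions`, `pairElements`,
   `screenGenome`) — both-strand scans and HZA+GATA co-occurrence under an
   edge-gap constraint, with optional cis-regulatory-module (CRM)
   containment and ATG-distance filters.
5. **Conservation** (`globalAlign`, `elementConservation`) — PWM-guided
   localization of an element in an ortholog promoter plus global
   alignment identity.
6. **Synthetic benchmarking** (`syntheticStudy`) — seeded genomes with
   planted modules and a truth table, so every claim above is testable
   offline.

## The occurrence model behind `discoverMotif`

Each sequence is modelled as i.i.d. background (0-order, estimated from
the input) except for at most one motif occurrence. Under **ZOOPS**, a
sequence carries a site with prior probability $\gamma$ (default 0.9 —
input promoters are chosen *because* they share regulation, so a site is
expected), placed uniformly over the usable windows of both strands;
**OOPS** fixes $\gamma = 1$. The complete-data likelihood is maximised by
EM with a Dirichlet pseudocount prior on motif columns (default 0.25 per
base). Two details matter in practice:

* **The monotone quantity is the penalized log-likelihood.** With a
  pseudocount the M-step is a MAP update, so the raw likelihood ratio can
  dip by a rounding-sized amount between iterations; the objective that is
  provably nondecreasing — and that `llTrace` records and the convergence
  test uses — is the log-likelihood ratio plus the Dirichlet log-prior of
  the motif columns.
* **Seeding and determinism.** Every distinct W-mer of the input (both
  strands when enabled) becomes a near-indicator start (0.7 on the seed
  base, 0.1 elsewhere). Seeds are ranked by a single E-step evaluation of
  the seed model; the top 20 are refined to convergence
  ($\Delta < 10^{-6}$, at most 200 iterations), and the best converged
  log-likelihood ratio wins, with ties broken by lexicographically
  smallest consensus and then seed order. After convergence the fitted
  matrix is additionally restarted shifted by ±1 and ±2 columns and a
  strictly better register is kept: EM is phase-ambiguous, and a
  coincidentally conserved flanking base can otherwise lock the motif one
  base off. Everything is deterministic given the input and configuration.

The ranking statistic is the converged log-likelihood ratio against the
background-only model. It is deliberately called `significance`, **not**
an E-value: it orders motifs of the same width on the same data, and no
claim of calibrated type-I error is attached to it.

A known identifiability limit, visible in the recovery benchmarks: with
six planted copies at a 10% per-base mutation rate, a dataset occasionally
arises in which an adjacent background column is better conserved than a
heavily mutated edge column of the planted register. The shifted register
then has genuinely higher likelihood, and no likelihood-based method
recovers the planted phase. This is why consensus-recovery criteria are
stated as ≥13/15 positions in ≥18/20 replicates rather than exact
recovery.

## Exact p-values instead of inherited cutoffs

Classic matrix scanners ship "default cutoff scores" that are hard to
reproduce. Here a matrix is discretised onto an integer lattice
($\mathrm{round}(g \ln(p_b/q_b))$, granularity $g = 1000$ units per
natural-log-odds unit, bounding the per-window rounding error at
$W/2g = 0.0075$ log-odds for $W = 15$), and the exact distribution of the
window score of a background W-mer is obtained by column-by-column
convolution. The cutoff for a per-window, per-strand p-value $\alpha$ is
the smallest achievable lattice score with exceedance $\le \alpha$; the
test suite checks the convolution bit-for-bit against exhaustive $4^W$
enumeration. Windows containing N are skipped, all overlapping hits are
reported (pairing decides downstream), and a hit's offset is always the
5'-most base of the window in transcription orientation, on either
strand.

Two different defaults are used by the screen, and the asymmetry is
deliberate:

* `alphaHza = 1e-4` — the 15-bp HZA matrix carries enough information for
  this to be attainable.
* `alphaGata = 1e-3` — the fallback GATA matrix (`gataMatrix()`) has only
  6 informative positions, so the rarest possible window under a uniform
  background has probability $4^{-6} \approx 2.4\times10^{-4}$. A $10^{-4}$
  per-window cutoff is *arithmetically unattainable* for any matrix whose
  only signal is a 6-bp core: `cutoffForPvalue` would warn and return an
  impassable score, and the screen would be vacuously empty. At $10^{-3}$
  the cutoff admits exactly the full-core matches. Users supplying a real
  12-position GATA matrix can tighten `alphaGata`.

## The screen criteria

`screenGenome` composes: extraction (≤ 20 kb, truncated at the nearest
gene body on either strand or the chromosome end) → both-strand scans →
pairing with **nearest-edge gap ≤ 20 bp**. The edge convention (bases
strictly between the windows; negative when they overlap) is forced by the
founder modules, whose separations run from highly overlapping to 12 bp
apart. All four strand-orientation combinations are kept, a gene may
contribute several pairs, and the candidate gene list is the deduplicated
row set. Strict mode adds two filters: both windows fully contained in a
single supplied CRM interval (BED in genomic coordinates or a per-gene
ATG-relative table), and module distance — measured at the module's most
ATG-distal base — ≤ 1.5 kb. Relaxed mode (co-occurrence + spacing only) is
always a superset of strict mode on the same inputs.

Where wording differs between "less than 20 bp" and "≤ 20 bp" in the
source material, the screen implements ≤ 20 (configurable via `maxGap`).

## What the synthetic generator emulates — and what it does not

`syntheticStudy()` builds one chromosome of 50 genes (default), each
preceded by its own intergenic region of 500–5000 bp of i.i.d. background
(uniform by default), with 20% of genes receiving a planted module: an
HZA word sampled from the built-in HZA-like matrix, the GATA word TGATAA,
independent element strands, an edge gap drawn from 0–20 bp, and a module
ATG distance drawn from 59–450 bp (59 bp is the closest module observed
among real candidates; 450 keeps any module inside the shortest default
intergenic region). Everything is reproducible from a single seed, and the
truth table is re-extractable from the emitted FASTA/GFF3 byte-for-byte.

The **built-in HZA-like matrix** (`hzaMatrix()`) is a synthetic stand-in,
because the real 15-bp matrix is published only as a logo: 12 positions
carry their consensus base at probability 0.95 — matching the published
description of the zinc-responsive matrix as having twelve
high-frequency positions — the CANAAAC core's N position is uniform, and
the two outermost positions are moderately informative (0.55), mirroring
the reported loss of edge-position significance in the cadmium-refined
variant. An exact-DP power calculation at these values puts the
probability that a sampled site passes the $10^{-4}$ cutoff at 0.986,
so the planted-recovery benchmark (≥95% gene-level sensitivity) probes
the pipeline rather than the information content of an under-specified
matrix. The two stand-in matrices are labelled as such in their names
and documentation.

Genes are all placed on the + strand in the generated studies. The
generator exposes no gene-strand option on purpose: with mixed strands,
divergently transcribed neighbours share one intergenic region, a planted
module then lies in *both* genes' promoters, and the truth table becomes
ambiguous. Minus-strand extraction, reverse-complement scanning and the
offset conventions are instead exercised by dedicated two-strand fixtures
in the test suite.

Real promoters differ from this generator in ways that matter: base
composition is not uniform (and is AT-rich in nematode intergenic DNA),
backgrounds are not 0-order, regulatory regions contain repeats and
multiple co-occurring motifs, and true modules are not planted
independently of context. Passing the synthetic benchmarks therefore
demonstrates correctness of the machinery and its statistical behaviour
under the stated model — not performance on genomic data, which also
depends on the quality of the supplied matrices and CRM intervals.

## Conservation checks

`elementConservation` scans an ortholog promoter on both strands with the
element's matrix, takes the best window, and aligns it to the reference
element with a deterministic Needleman–Wunsch global alignment
(+1/−1 match/mismatch, −2 per gap, ties resolved diagonal-first, then
gap-in-the-second-sequence). Identity is computed over non-gap column
pairs, and "conserved" defaults to identity ≥ 0.8 — a configurable choice:
no published threshold exists for calling these elements conserved, and at
15 bp a 0.8 threshold tolerates the two to three substitutions seen among
real cross-species element alignments. The multiple-alignment step used
historically for this purpose is replaced by localisation + pairwise
alignment because the alignment was only ever used to locate and compare
the element, which this reproduces deterministically.

## Sizes, budgets and numerical choices

The default problem sizes are chosen so a full check runs on a laptop in
about two minutes: 20-replicate screens of 50-gene studies, 20-replicate
EM recovery at 6×600 bp, exhaustive-enumeration oracles at W ≤ 6, and
brute-force scan/pair oracles on ~1000 small random cases. Other
numerical choices collected in one place:

* lattice granularity 1000 (rounding error ≤ W/2000 log-odds);
* pseudocount 0.25 per base for matrices built from sites (and in the EM
  M-step); matrices built directly from probabilities must be strictly
  positive before discretisation;
* PWM text files store six decimals; the reader renormalises columns, so
  round trips agree to 1e-6 per entry;
* EM convergence at $\Delta$(penalized objective) < 1e-6, cap 200
  iterations; seed-model match probability 0.7; shortlist size 20;
* ties everywhere are broken deterministically (offset, then + before −;
  lexicographic consensus; input order).

## Limitations

* The screen's statistical guarantees are per-window; no multiple-testing
  correction across a genome is applied, because the historical procedure
  it reimplements did not apply one. Candidate lists from genome-scale
  scans are enrichment candidates, not calibrated discoveries.
* The fallback GATA matrix is non-canonical (6 informative positions);
  reproducing published candidate counts requires the original
  intestine-enriched GATA matrix and CRM predictions, which are external
  inputs (`readPWM()`, `--crm`).
* Higher-order backgrounds, gapped motifs, motif-width selection and
  cross-motif similarity search are out of scope.
* The ZOOPS/OOPS models assume at most one site per sequence; tandem
  duplicated elements in one promoter are reported only through the
  scanner, not the discovery step.
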