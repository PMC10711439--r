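---
title: "Methods: fingerprinting, searching and validating TnpB/Fanzor pipelines"
author: "fanzortrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting, searching and validating TnpB/Fanzor pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanzortrace)
```

# Scope and design

`fanzortrace` implements the computational core of a comparative analysis
linking eukaryotic Fanzor nucleases to a narrow clade of prokaryotic IS607
TnpBs: motif-fingerprint classification of TnpB-family proteins, iterative
profile search, transposon locus curation, TAM depletion quantification,
TnpA–TnpB co-conservation, and reRNA boundary/pseudoknot analysis. Every
stage is paired with a synthetic-data generator that plants ground truth,
so the whole pipeline is validated end to end on data whose answer is
known. All user-visible coordinates are 1-based and inclusive, the
convention of R and the Bioconductor range infrastructure.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the functions in `R/`,
and `scripts/acceptance.R` recomputes the headline validation quantities
from scratch.

# The fingerprint model

TnpB-family proteins carry an RNase H-fold RuvC nuclease whose D–E–D
catalytic triad is split over three subdomains (RuvC1–3), with a
C-terminal zinc finger (ZF) between RuvC2 and RuvC3. Two features separate
the Fanzor lineage from ordinary TnpBs:

* **RuvC1 class** — Fanzors carry `DPG` where other TnpBs carry `DΦG`
  (Φ ∈ {I, L, F, W, Y, M}). A middle residue outside Φ ∪ {P} is not a
  RuvC1 motif at all.
* **Glutamate placement** — the RuvC2 catalytic glutamate sits either
  six residues upstream of the first ZF cysteine (the *alternative*
  placement, E_alt) or roughly 50 residues upstream (the *canonical*
  placement, E_can).

The full Fanzor fingerprint is the gap-constrained pattern

```
D P G  x(120,160)  E  x{6}  C x x C  x(12,18)  C x x C  x(4,8)  D
```

`classify_fingerprint()` evaluates every combination of RuvC1 motif,
glutamate and ZF placement and reports the best category under
`FANZOR_LIKE > E_ALT_DPHIG > CANONICAL > AMBIGUOUS > INCOMPLETE`.
Decisions taken where the pattern leaves room:

* The long spacer is read as 120–160 residues strictly between the RuvC1
  glycine and the glutamate, matching the paired style of the short
  spacers; both bounds are arguments.
* The canonical window defaults to 35–65 residues upstream of the first
  ZF cysteine (a symmetric band around "~50"); an E at the E_alt offset
  never counts as canonical. `CANONICAL` requires a ZF, a window
  glutamate, and the absence of any E_alt placement; it deliberately does
  not require a RuvC1 spacer, for which no rule exists.
* `AMBIGUOUS` is reserved for sequences carrying both an E_alt and a
  window glutamate without any spacer-complete Fanzor arrangement.
* `X` matches wildcard positions but never the literal C/D/E/G/P/Φ
  anchors — conservative motif calling on low-quality translations.

The classifier is validated against an independent oracle that evaluates
the two full patterns as regular expressions plus the window rule
directly; the two routes agree on 10^4 random and 200 planted proteins
(`scripts/acceptance.R`, `fingerprint_oracle_agreement_pct`).

# Iterative profile search

The discovery phase is modelled desk-scale as a PSSM search rather than a
profile HMM: a position-specific log-odds matrix

$$\mathrm{logodds}_{ia} = \log_2 \frac{(c_{ia} + \beta q_a)/(N_i + \beta)}{q_a}$$

is built from the alignment (pseudocount weight β = 1, uniform background
q = 1/20, columns below 50% occupancy masked), searched against each
candidate by affine-gap local alignment (Gotoh recursion, gap open −8
bits, extend −1 bit, compiled in C++), and hits above an empirical-null
threshold contribute their aligned segment — in profile coordinates, as a
subdomain extraction would — as a new alignment row for the next round.
Five rounds are the default. Inclusion thresholds are recalibrated each
round as the 0.999 quantile of best-hit scores over shuffled decoys
matched for length and composition, standing in for the search tool
defaults the original procedure relied on; hit sets only ever grow, so
monotonicity across rounds is structural. Traceback ties break
diagonal > gap-in-sequence > gap-in-profile, making results deterministic.

The synthetic homolog ladder that exercises this machinery is
*evolutionarily nested*: each lineage's 60% sequence derives from its 80%
sequence, and so on down to 30%. This mirrors how real homolog families
branch and is precisely the regime where augmentation helps — intermediate
hits contribute the derived residues that later, more divergent relatives
share. With independent (star-shaped) rungs the later rounds would add
little. The gain is quantified per run (typically recall at the 40% rung
rises from ~0.5–0.75 in round 1 to ~0.9+ by round 5 at 50 sequences per
rung).

# Transposon curation

* `detect_tsd()` returns the longest exact flank duplication with length
  in [2, 15]; TSDs of this lineage reach 12 nt, and curated calls are
  expected to be clean, so no degeneracy is allowed.
* `detect_tir()` scans the terminal 50 nt windows for the segment pair
  maximising `matches − mismatches` between the left segment and the
  reverse complement of the right one, requiring length ≥ 8 and mismatch
  fraction ≤ 0.2. The balanced score (rather than raw match count) stops
  single chance-complementary bases beyond a repeat's true end from
  dragging the boundary outward; ties prefer the compact placement, then
  segments closer to the termini.
* IS607 boundaries are checked as element-terminal GG dinucleotides at
  both ends — the crossover chemistry fixes GG at the donor and acceptor
  joints, and the empty allele retains a single GG at the junction. The
  element-terminal convention (rather than flank-side) is a convention
  choice; the check is symmetric either way for simulated loci.
* `find_element_copies()` is an ungapped seed-and-extend (16-mer seeds,
  identity ≥ 0.9) with 2 kb flank extension clipped at contig ends —
  adequate for curated desk-scale inputs, not a general aligner.

The locus generator regenerates any draw whose planted TSD or TIR would
be ambiguous (for example a flank base extending the duplication), the
same contract a curator applies when a boundary cannot be pinned down.
Planted TIR mismatches go to interior repeat positions: the repeat
termini are the transposase-critical, conserved positions of real TIRs.

# TAM depletion

TAMs are the `tam_length` (default 6) nucleotides immediately 5' of a
constant target-site anchor, extracted on the anchor's strand with the
reverse complement searched when the forward strand lacks it. Per-sample
frequencies are pseudocounted and depth-normalised,
`f(t) = (n_t + 1)/(N + 4^L)`, and the depletion score is
`log2(f_input/f_output)`, so depleted TAMs score positive and the 5-bit
retention threshold applies as printed. The logo matrix over the retained
set uses unweighted base frequencies, information `I_j = 2 − H_j` bits and
letter heights `f_bj I_j`.

One statistical property of the study conditions deserves note. At
500,000 reads per sample over 4096 TAMs, a TAM depleted 2^6-fold keeps an
expected output count of about 1.9. A 5-bit score then requires an output
count of at most ~3, and `P(Poisson(1.9) ≤ 3) ≈ 0.87` bounds recall from
above regardless of pseudocount; the measured recall of the 5-bit
retained set is ~0.75 with precision ~1.0 (`scripts/acceptance.R`,
`tam_recall`, `tam_precision`). Deeper sequencing or stronger depletion —
real selections are typically far more complete than 64-fold — lifts the
ceiling; the package reports what the stated depth supports. For the same
small-count reason the "score mean ≈ log2(F)" check is asserted at
F = 2^3, where counts are large enough for a 0.2-bit tolerance to be
meaningful.

`norm_cfu()` reports the double/single-antibiotic colony ratio, with
`1/cfu_single` flagged as a detection limit when the double plate is
empty.

# Co-conservation

Percent identity between aligned rows counts only columns where both rows
are non-gap (one-sided gap columns enter neither numerator nor
denominator) — a symmetric, documented convention where the upstream
alignment tool's is unspecified. `trim_columns()` keeps exactly the
columns with non-gap fraction ≥ 0.9 (the stringent gap threshold used
before tree building) and is idempotent. `paired_identities()` emits
TnpA-TnpA and TnpB-TnpB identities for all unordered element pairs with
Pearson/Spearman correlations and a fixed 20×20 histogram over
[0, 100]². All pairs are used; restricting to a cluster subset is the
caller's slice of the pairing table.

The paired-family generator draws one clock per element (uniform 0.1–0.6
substitutions/site, substitution-only so sequences stay trivially
aligned) and lets `coupling` interpolate between a shared TnpA/TnpB clock
(1) and independent clocks (0); the shuffle control permutes only the
TnpB assignment. Coupled simulations at n = 30 give mean Pearson r ≈ 0.92
over 20 seeds; shuffled pairings give mean |r| ≈ 0.15.

# reRNA analysis

Reads map by exact 12-mer seed and full-length extension with ≤ 2
mismatches; placement must be unique, ties are discarded as ambiguous.
The boundary call takes the maximal contiguous run of positions with
coverage ≥ 0.5 × plateau (median non-zero coverage) containing the
coverage maximum — an explicit rule standing in for a visual call; other
qualifying runs are reported as secondary. With endpoint jitter of 1 nt
SD and ≥ 50× depth the half-plateau crossing sits on the planted boundary,
so calls are exact or off by one.

The small-RNA generator emits full-span reads of the planted interval
with Gaussian endpoint jitter — the size-selection regime in which merged
amplicon reads cover the whole small RNA. It does not model partial
fragments, so boundary ramps in real data may be wider than simulated
ones.

Pseudoknot checks pair the five guide-flanking nucleotides against the
apical loop antiparallel (A position i against B position n+1−i), classed
Watson–Crick, G:U wobble, or unpaired; regions are supplied by
annotation, and no folding is performed. Mutation specs follow the
guide-relative convention: −k is k nucleotides 5' of the first guide
position (−1 abuts the guide), +k is the k-th guide nucleotide; the
reference base is verified before substitution, which catches coordinate
misreads. The numbering is anchored at the guide start rather than the
transposon end — the only reading under which positions like −130 (deep
scaffold) and −3 (near guide) are simultaneously sensible — and the guide
region is not trimmed before boundary calling.

# Seeds, determinism and problem sizes

Every generator takes one master seed; records that can be regenerated
(protein decoys, transposon loci) run on per-record child streams,
`child_seed(master, i) = (master·48271 + i·16807) mod (2^31 − 1)`, so
regenerating record i never shifts record j. Read simulators draw i.i.d.
samples from a single stream. `run_pipeline()` derives each stage's seed
from the master seed and writes TSVs with fixed formatting, so reruns are
byte-identical per output file; the manifest records config, output
digests and wall-clock.

Validation problem sizes are chosen to exercise each property at the
scale its statistics need while keeping a full run in minutes: 10^4
random proteins for oracle agreement, 50 sequences per ladder rung over
5 rounds, 110 TSD and 60 TIR loci, 10 TAM replicates at 500,000 reads,
20 co-conservation seeds at 30 elements, and 5 noisy reRNA replicates at
1000 reads.

# Known limitations

* The PSSM replaces a profile HMM: no insert-state emission model, no
  E-values; thresholds are empirical-null quantiles.
* Generators use substitution-only evolution — no indels, no codon
  structure, no sequencing-error model beyond endpoint jitter; passing
  tests demonstrate correct recovery of planted signal under these
  conditions, not robustness to alignment error or indel-rich families.
* TSD detection is exact-match; degenerate duplications are out of scope.
* TAM recall at the stated depth/threshold is Poisson-limited (see
  above); the retained set is precise but incomplete at 64-fold planted
  depletion.
* `find_element_copies()` is ungapped; structural variants within copies
  defeat it.
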