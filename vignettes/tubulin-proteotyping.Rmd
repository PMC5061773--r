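---
title: "Tubulin isotype proteotyping and C-terminal PTM scanning: methods"
author: "tubulinptm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tubulin isotype proteotyping and C-terminal PTM scanning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulinptm)
```

## The problem

Plant α- and β-tubulins (TUA, TUB) form large families of near-identical
paralogs ("isotypes") whose members differ almost exclusively in a short,
acidic, hypervariable C-terminal tail. In woody plants the tail matters
twice over: it is the only region where individual isotypes can be told
apart — by mass spectrometry at the protein level and by short-read mapping
at the transcript level — and it is the canonical substrate of the tubulin
C-terminal post-translational modifications (PTMs) known from animals:
detyrosination (dY, loss of the encoded C-terminal Tyr), non-tyrosination
(dEY, additional loss of the penultimate Glu), and polyglutamylation
(+n × Glu). Lysine-40 acetylation is the one PTM that sits in the
N-terminus instead.

This package implements the complete desk-scale computational pipeline for
that analysis: CNBr reporter-peptide mass prediction, PTM isoform mass
scanning against MALDI-TOF peak lists, label-free isotype quantification,
paralog-resolved transcript quantification with an iterative bait-assembly
reference-correction loop, and seeded simulators that generate all inputs
with known ground truth.

## Reporter peptides and mass arithmetic

CNBr cleaves C-terminal to Met. Because the hypervariable tail of every
tubulin isotype lies downstream of its last conserved Met, CNBr releases
one C-terminal "reporter" peptide per isotype whose singly protonated
monoisotopic mass (MH+) is, with two documented exceptions, unique within
its family. `peptide_mh()` computes

MH+ = Σ residue masses + m(H₂O) + m(H⁺),

with standard monoisotopic residue masses from a versioned constants file
(`inst/extdata/residue_masses.tsv`), water 18.010565 Da and proton
1.007276 Da. Cys is treated as unmodified; the packaged Cys-containing TUB6
record reproduces its printed mass only under that convention, which is why
no carbamidomethylation is applied.

The CNBr-converted terminal Met could in principle be recorded as
homoserine lactone (−48.0034 Da), homoserine (−29.9928 Da) or unmodified.
Rather than hard-coding one convention, `resolve_met_convention()` fits all
three against the printed masses of the terminal-Met records in the
packaged table and accepts the unique candidate that reproduces all of them
within 0.01 Da. On the packaged records that is homoserine lactone, from 11
terminal-Met peptides; the choice (and the proton-mass convention it
implies) is logged on every run.

Five of the 36 distinct packaged records carry printed masses that are
inconsistent with their own printed sequences by 0.009–0.037 Da under every
candidate convention (one deviates by exactly one CH₂, suggesting a
transcription slip between Glu and Asp in the table as printed). The package
reproduces the printed sequences faithfully and reports the computed
masses; the discrepancy is surfaced by the test suite rather than patched.

`digest()` implements both proteases used around the reporter concept:
CNBr (cut after every Met, converted terminal Met flagged) and trypsin
(cut after Lys/Arg, suppressed before Pro and at modified positions).
The trypsin rule encodes the Lys-40 acetylation diagnostic: an acetylated
Lys-40 blocks cleavage and merges the flanking N-terminal fragments, so the
short/long peptide pair around residue 40 reports the acetylation state. A
synthetic N-terminal TUA fragment with the conserved Lys-40 context is
shipped for this purpose (labelled synthetic; it is a constructed stand-in,
not a sequence from any particular accession).

## PTM isoform scanning

`enumerate_isoforms()` forms the cartesian product of reporter peptides and
modifications, gated by sequence applicability: dY needs an encoded ...Y
terminus, dEY needs ...EY, glutamylation an acidic tail, acetylation a Lys.
The gating encodes a biological point: isotypes ending in Met, Glu or Gln
cannot take part in the tyrosination cycle at all. Glutamylation is scanned
at n = 1..3 added Glu by default; the classical mass search targets the
+129 Da (n = 1) satellite, so the n ≥ 2 satellites are an extension.

`scan_spectrum()` gives each isoform one of three verdicts:

* **detected** — a peak lies within tolerance of the expected MH+, its
  isotopic envelope validates, and its intensity clears the signal floor;
* **background** — a peak matches but fails the envelope or floor test;
* **absent** — no peak within tolerance.

Two thresholds make the qualitative notion of "near background" testable:

* **Matching tolerance**: ±0.3 Da by default — a documented assumption;
  0.3 Da is a realistic figure for linear-TOF spectra of
  ~3.1–4.3 kDa peptides and is configurable everywhere.
* **Signal floor**: median + 3 × MAD of the peak intensities of the
  spectrum under scrutiny. This presumes a noise-dominated peak list, which
  is true of the simulated spectra and of real MALDI peak lists, but not of
  a list containing only a handful of hand-picked peaks.

**Envelope validation** (`envelope_ok()`) accepts a candidate monoisotopic
peak only when peaks exist at +1 and +2 isotope spacings (1.00235 Da)
within tolerance and the first isotopologue holds 0.3–3.0× the candidate's
intensity — for ~4 kDa peptides the first isotopologue is comparable to the
monoisotopic peak, hence the wide band. Lone peaks at a diagnostic mass are
deemed background — the reading a spectroscopist would apply by eye.
The check also requires that the candidate be genuinely monoisotopic: a
peak one spacing below with ≥ 50% of its intensity marks the candidate as
an interior isotopologue of a larger envelope and vetoes it. Without this
veto, any reporter envelope would spuriously "detect" isoforms of other
isotypes whose masses sit one or two isotope spacings higher.

**Uninformative masses.** Some modified masses coincide with other
reporters outright: TUB17 + 2 Glu has exactly the TUB18 reporter mass
(its tail differs by two encoded Glu), and TUB13 + 2 Glu falls within
0.05 Da of TUA8. A match at such an m/z cannot be attributed to the PTM, so
`scan_spectrum()` flags these isoforms (`mass_conflict`) and `run_all()`
excludes them from detection counts while reporting them separately.

## Label-free quantification

`quantify_isotypes()` assigns each reporter the summed intensity of its
validated envelope (k = 0..2) and normalizes within family — TUA and TUB
separately, because their absolute signals differ by an order of magnitude
and only within-family fractions are comparable. Reporters whose theoretical
masses differ by less than 2 × tolerance are merged into an ambiguity group
(the TUA4/TUA5 pair, 0.037 Da apart, and the TUB3/TUB20 pair, identical in
mass). A group can be relabelled to a single member when transcript
evidence shows all other members essentially unexpressed (within-family
FPKM share below 5% by default); the reassignment is logged, mirroring the
argument by which the TUA4/5 signal is attributed to TUA5 when TUA4
transcripts are barely detected.

Reporters whose masses differ by almost exactly one or two isotope
spacings (e.g. TUB7 vs TUB16, 1.02 Da) have overlapping envelopes that
summed-intensity quantification cannot separate; the monoisotopic veto then
suppresses the lighter signal's +1 neighbour. This is an inherent
resolution limit of linear-TOF quantification, and the recovery tests
sample their mixtures from envelope-resolvable isotypes.

## Transcript quantification

`extract_region()` builds, per gene, a reference of ≤ 200 bp covering the
C-terminal coding tail plus part of the 3'-UTR. `map_reads()` aligns each
read glocally (read-global, region-local; match +1, mismatch −1, gap open
−2, gap extend −1) against every region — both strands by default, forward
only under `stranded = TRUE` (the emulated libraries are stranded) — and
applies the stated filters: read-length coverage > 0.95 and edit operations
≤ floor(0.02 × read length), gaps counting as edits. Among surviving
candidates only the unique best score is assigned; equal best scores on
different regions are discarded as `ambiguous_tie` rather than assigned at
random, because random assignment would fabricate resolution between
near-identical paralogs — the exact failure the 3'-regions are meant to
avoid. Coverage is measured against the read length (hit-length coverage
could also be read against the reference span; the read-length reading is
the implemented one). Reads with no plausible
candidate are `unmapped`. Exact full-length matches are resolved by a
dictionary scan and only inexact reads reach the dynamic-programming
aligner, restricted to regions sharing an exact 15-bp window with the read
(a read within the mismatch allowance always retains a clean window).

`compute_fpkm()` counts assigned reads per region and reports
fragments / (region kb) / (library size in millions), including zeros.
`concordance_report()` joins protein and transcript abundances per isotype,
computes a Spearman rank correlation per family, and flags isotypes whose
transcript sits in the top quartile of the family while the protein falls
at or below the median — the discordance pattern shown by TUB17/TUB18,
whose transcripts are abundant but whose peptide signals are low.

## Bait assembly

`iterate_assembly()` re-implements the iterative reference-correction loop
at desk scale: recruit reads matching the current baits, assemble them,
align contigs to the per-gene reference, keep assigned contigs as the new
baits, and repeat until the recruited read-id set repeats or 10 iterations
have run — in practice the loop stabilizes well inside that cap.
Stability is defined on the recruited read-id set rather than
on contig sequences, which may oscillate under consensus ties. The external
read mapper, assembler and aligner such a pipeline would normally shell out
to are replaced by in-package plumbing: k-mer recruitment (k = 21; k < 11 is rejected as
spurious) verified by overlap alignment at ≤ 5% edits over the aligned
overlap, and a deterministic greedy assembler merging reads by maximal
exact suffix–prefix overlap ≥ 30 bp (ties broken by longer overlap, then
lexicographic read id; containments absorbed). Because merged overlaps are
exact, errors do not propagate through a contig — an erroneous read either
fails to merge across its error or contributes only its clean extension —
at the cost that high error rates fragment contigs instead of corrupting
them. Contigs are assigned to a gene at ≥ 90% identity over ≥ 100 bp, a
declared assumption for which contigs count as relevant enough to become
baits. The longest contig per gene is returned, so
a true transcript a few percent diverged from its reference bait displaces
the bait after one or two rounds of re-recruitment.

## What the simulators emulate — and what they do not

`make_transcript_family()` builds one transcript per isotype from a shared
random core (paralogs are near-identical outside the tail), the
deterministic reverse translation of the isotype's own reporter peptide
(so paralog tails differ exactly where the peptides differ), a stop codon
and an isotype-specific random UTR. `simulate_family()` adds point
substitutions at 5× the core rate in the tail+UTR, with a truth log.
`simulate_reads()` draws multinomial origins, uniform start positions and
i.i.d. substitution errors (defaults: 75 bp reads, 0.5% per-base error,
8000 reads — enough counting statistics for ±15% recovery at the smallest
simulated proportions while staying desk-scale; real libraries are three
orders of magnitude deeper). `simulate_spectrum()` emits a 4-peak envelope
per expressed isotype (geometric decay 0.7, within the envelope ratio
band), satellite envelopes for PTM spike-ins scaled by stoichiometry, and
uniform noise peaks constrained to ≥ 1.5 Da spacing so that noise can never
satisfy the envelope check — a deliberate idealization that makes the
envelope criterion a clean discriminator in the null simulations.

Consequently a green simulation test establishes that the pipeline's
decision rules behave as designed under the stated statistical structure.
It does not establish instrument realism: no peak shapes, baseline drift,
calibration error, ionization bias, quality-score error models or
paired-end structure are modelled, and the biological headline (absence of
C-terminal PTMs in real xylem) is represented only by the null-spike
behaviour of the simulator, not re-derived from instrument data.

## Numerical and design choices

* Masses are compared at full precision; rounding (half-even, 3 decimals
  for tables, 1 decimal where the source prints one) happens only at the
  display edge.
* `peak_list()` sorts peaks and merges exact m/z ties by summing intensity;
  scanning functions insist on sorted input.
* Degenerate-mass merging threshold is 2 × matching tolerance.
* Recruitment uses overlap alignment with free end gaps so reads
  overhanging a partial bait are recruited; the k-mer gate carries the
  specificity.
* All simulator stages draw from substreams derived deterministically from
  the manifest seed, so stages can be re-run in isolation; outputs carry
  the manifest's md5 fingerprint.
* The demo mixture in `demo_manifest()` reflects the reported xylem
  profile: TUA1/TUA5 and TUB15/TUB16 predominant.
* Region placement for the simulated references is 60 bp of coding tail +
  140 bp of UTR: extending regions further into the conserved reporter
  prefix only recruits ambiguous alignments, which the 3'-anchored design
  exists to avoid.
* Only positive ion mode is modelled; negative-mode spectra are out of
  scope.

## Known limitations

* Reporters closer than the matching tolerance (TUA4/TUA5) are only
  resolvable by transcript evidence; reporters at ±1–2 isotope spacings are
  not separable by summed-envelope quantification at all.
* The greedy exact-overlap assembler fragments rather than corrupts under
  sequencing errors; it has no paired-end or splice-graph awareness.
* The FPKM model counts single-end reads as fragments.
* MS/MS fragment-ion (b/y) scoring is out of scope; acetylation support is
  limited to digestion-pattern logic and mass offsets.
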