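---
title: "tagkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tagkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagkit)
```

tagkit supports a C-terminal protein-tagging workflow built on homologous
recombination (HR) in hyper-recombinogenic cell lines such as chicken DT40.
The wet-lab strategy it models inserts, just before a gene's stop codon, a
cassette encoding a quantification peptide, a TEV protease cleavage site and
a reporter (protein A, FLAG or EGFP), followed by a loxP-flanked block
(3'UTR, selection cassette, plasmid backbone) that Cre recombinase later
removes. This vignette records the models the package implements, the
parameters that matter, and the design decisions taken where the underlying
protocol leaves the computational details open.

## The cloning simulator

Everything downstream rests on a small deterministic molecular-biology
engine (`find_sites()`, `digest()`, `self_circularize()`, `simulate_pcr()`,
`slic_assemble()`, `cre_excise()`, `simulate_hr_integration()`).

**Coordinates.** All positions are 1-based inclusive, the R/Bioconductor
convention (IRanges, Biostrings). Adopting the ecosystem's native convention
keeps every `substr()` and feature interval directly comparable with other
Bioconductor tooling and avoids a translation layer.

**Fragments and cohesive ends.** A restriction fragment is stored as its
top-strand projection spanning from the upstream site's top-strand cut to
the downstream site's bottom-strand cut. A 5' extension therefore appears
once at each end of the string, and two fragments flanking the same cut
duplicate those bases. This makes the two bookkeeping invariants exact:
concatenating fragment cores (counting each extension once) reconstructs the
input, and self-ligation of a cohesive fragment shortens it by exactly one
extension copy. Cohesive-end compatibility is exact sequence equality of the
extensions; in the top-strand projection that is the correct annealing test
for 5' extensions. Enzymes with 3' extensions are not modelled (none of the
bundled enzymes produce them).

**Circularity.** Circular molecules have a storage origin but no semantic
one: pattern searches scan a doubled string truncated to length L so that a
site laid across the origin is found exactly once, and digestion of a
circular molecule with n sites yields n fragments regardless of where the
origin falls.

**PCR.** Annealing is perfect-match only, and each primer's annealing
region must occur exactly once in the template counting both strands;
anything else raises a non-specific-priming error. This is a design-time
contract, not a mispriming predictor: thermodynamic off-target models
belong to primer-design software proper and are out of scope. Amplicons are
capped at 12 kb by default (a practical limit for high-fidelity polymerases
on the fragment sizes involved).

**SLIC.** Sequence- and ligation-independent cloning is modelled at its
design contract: the insert's terminal bases must exactly match the
linearized vector's termini, with the realised maximal terminal identities
reported and a configurable floor (default 25 bp, with 30 bp the designed
value). Chew-back extent, annealing kinetics and bacterial gap repair are
abstracted away — in practice the method succeeds or fails on terminal
identity, which is what the simulator checks.

**Cre/loxP.** Both site copies are the 34-bp wild-type loxP sequence. The
protocol distinguishes "loxP L" and "loxP R" sites but never specifies
variant sequences; since marker loss after Cre induction is the documented
behaviour, wild-type excision between two same-orientation sites is the
modelled reaction, and material is conserved exactly:
`len(remaining) + len(excised) = len(input)`, each product keeping one
site. Opposite-orientation pairs (inversion substrates) are rejected rather
than silently inverted.

**HR integration.** Targeted integration anchors a `min_arm`-long exact
seed at each construct terminus (tolerating up to 10 nt of non-homologous
tail, the restriction-site remnant that end resection removes in vivo),
requires both seeds to map uniquely and colinearly to the locus, and splices
the construct between the genomic arm copies. Random (non-homologous)
integration is deliberately not modelled.

## Construct design

`design_construct()` reproduces the two-PCR inversion strategy: one genomic
PCR amplifies both homology arms as a single fragment with NotI sites on
4-bp-spacered overhangs; NotI digestion and self-ligation yield a circle;
a second PCR across the circle's junction inverts the arms and adds 30-bp
SLIC homology to the HindIII/XhoI-linearized vector termini. The assembled
construct is checked for a unique linearization site, linearized,
integrated into the locus in silico, and Cre-excised to predict the final
tagged locus.

Key choices:

* **Arm length** defaults to 2500 bp with a 2200 bp floor — the working
  range for efficient targeting in this system.
* **Junction frame.** The fixture vector places one padding base after the
  HindIII site so that the HindIII remnant plus pad (`AGCTTG`, Ser-Leu)
  joins the gene's final sense codon to the tag CDS in frame, and the tag
  CDS carries its own stop codon. Where the fusion's stop lies is not
  dictated by the protocol; supplying it from the tag is the only choice
  that leaves the post-Cre product a complete fusion gene.
* **Primer tuning.** Design primers sit at fixed template positions (they
  define the amplicon), so only the annealing length is tuned (15–32 nt)
  toward a 60 ± 3 °C melting temperature; in-band ties prefer the shorter
  primer, then fewer A/T among the three 3'-terminal bases. If the band is
  unreachable the closest-Tm length is used, because the position is not
  negotiable. Verification primers may additionally slide their anchor
  outward (up to 60 nt) and do fail when no unique in-band primer exists.
* **Melting temperature.** Two-state nearest-neighbour model with the
  unified parameter set (Allawi & SantaLucia 1997), entropic salt
  correction `0.368·(N−1)·ln[Na+]` and concentration term `R·ln(CT/4)`,
  at 50 mM monovalent salt and 500 nM total primer. The constants live in
  the configuration; reproducibility across machines was weighted over
  absolute thermodynamic accuracy.
* **Strand handling.** Minus-strand loci are reverse-complemented at
  ingest; all designs are reported on the gene's coding strand.
* **Fusion prediction.** Predicting the fusion protein requires knowing
  where translation starts, which a bare genomic sequence plus stop
  coordinate cannot supply for intron-containing genes. The locus model
  therefore accepts an optional contiguous-ORF start (always set by the
  synthetic generator); without it the design still completes and reports
  the tagged locus only. Designs treat the locus as plain genomic
  sequence — intron/exon structure is not consulted, matching how the arms
  are designed in practice.
* **Verification primers.** One genomic primer strictly outside each arm is
  paired with a primer inside the selection cassette, so each pair amplifies
  only the targeted allele; the upstream pair's reverse primer sits at (or
  slides just past) the cassette's 3' end, so its product contains the
  entire resistance cassette. Both behaviours are verified by simulated PCR
  on both alleles at design time.

## Peptide tools

The tag architecture is an 11-residue quantification remnant
(`KLAADITSLYK`) that stays on the bait after TEV elution, the TEV site, and
the reporter. TEV cleavage is implemented as `ENLYFQ↓(G/S)` — the canonical
recognition and P1' tolerance. Trypsin cleaves after K or R except before
proline (the classical Keil rule); with zero missed cleavages the peptides
partition the protein, and the quantification peptide `LAADITSLYK`
(10 residues) is the digest product ending at the TEV-site boundary,
released in 1:1 stoichiometry with the bait. A bait that happens to contain
the same decapeptide internally breaks that stoichiometry, so extraction
warns in that case.

Monoisotopic masses are summed from residue elemental compositions and
CODATA/AME atomic masses (water added once; modifications as explicit
shifts). The heavy internal standard Lys(13C6, 15N2) shifts by
`6·(13.0033548 − 12) + 2·(15.0001089 − 14.0030740) = +8.0142 Da`, the
"+8 Da" label. The spiked standard is modelled as the 10-mer with a heavy
C-terminal lysine, as the labelling chemistry implies.

## CoIP scoring

For a protein group with intensities across bait replicates and control
runs:

* **abundance** = mean bait intensity (missing = 0) / molecular weight
  (kDa), an approximate molar scale;
* **specificity** = mean bait intensity / mean control intensity, with the
  denominator floored at 1 intensity unit when the protein is undetected in
  every control run.

Missing-as-zero is deliberate: the background-floor rule only makes sense if
zeros are meaningful, and it keeps the score deterministic. Molecular weight
is taken from the table rather than recomputed from sequence. No FDR layer
is added — the score is descriptive, thresholds are the analyst's call.
With multiple control runs the mean-of-runs enters the ratio (the
alternative, per-run ratios averaged afterwards, differs only in noise
weighting and was rejected for simplicity).

## Absolute quantification

`eluate_fmol = (light / heavy) × spike` with a 500-fmol (0.5 pmol) default
spike; `copies_per_cell = fmol × 1e−15 × N_A / (n_cells × yield)` with a
50% default CoIP yield. Replicates are summarised as mean ± sample SD of
the per-replicate amounts. Reported copy numbers are rounded to one
significant figure (configurable) — the precision such measurements honestly
support — with raw values always retained alongside. Calibration series are
checked by ordinary least squares with a default r² ≥ 0.99 linearity flag.
Peak volumes are abstract scalars: chromatogram integration and
isotope-envelope processing happen upstream. C-terminal degradation of the
bait (which silently decouples the quantification peptide from the
functional protein) is not detectable from volumes alone; inspecting peptide
maps remains the analyst's quality control.

## Transcriptome-derived search database

Six-frame ORF calling is stop-to-stop with an ATG requirement by default
(minimum 100 residues; partial ORFs at transcript ends only on request) —
the assembler-bundled ORF scorer this replaces is not described in enough
detail to clone, so the conventional definition is used and documented.
Annotation takes, per ORF and per species independently, the alignment hit
with the lowest e-value at a 1e-10 cutoff; ties break by higher bit score,
then lexicographic subject id, so results are invariant to input order.
One representative per transcript group is kept — the longest in amino
acids (it is a protein database), ties by lexicographic id. Unannotated
proteins are kept and counted, since the ambiguity of whether they belong
in the final set is best left visible. The group key comes from a
transcript-id suffix pattern (`_i<n>` stripped), emulating assembler
component ids; the species of a hit comes from a configurable subject-id
prefix map. The database FASTA appends configured extra entries; only the
quantification peptide ships as a default, and the fixture's TEV entry is
labelled synthetic because the true protease sequence is not something this
package should invent.

## Synthetic fixtures: what they emulate, and what they do not

All generators are pure functions of a `fixture_config()` (seed included).
Defaults are the study conditions: a 6.2-kb locus with a contiguous ORF
ending 2.8 kb in (room for 2.5-kb arms plus primer landing zones), a ~5-kb
vector with the canonical feature order, two bait replicates versus one
control at 10% log-normal intensity CV, planted interactors at enrichments
50/20/8, a 500-fmol spike into eluates from 4×10^7 cells at 50% yield with
5% volume noise, and planted copy numbers (≈2078/602/4035/5842) chosen to
reproduce the reference eluate amounts of 69/20/134/194 fmol. Placeholder
CDSs are random sense codons — the pipeline's contracts depend on feature
layout, not sequence identity, and real sequences can be dropped in via
configuration.

Accidental NotI/HindIII/XhoI sites are removed by seeded point repair
(codon-resampled inside CDSs to stay stop-free in frame, including across
the vector's circular origin). Intensity noise is multiplicative log-normal
with mean 1 — the simplest model consistent with label-free MS practice.

What the fixtures do **not** emulate: introns and repetitive genomic
context, real codon usage, correlated or intensity-dependent MS noise,
missing-value structure from data-dependent acquisition, chromatography,
or read-level sequencing. Passing tests therefore demonstrate the
correctness of the algorithms under clean, known-truth conditions — not
robustness to every pathology of real data.

## Problem sizes and determinism

The test suite runs the full design pipeline on 100 seeded loci at default
geometry (2.5-kb arms), brute-force-verifies the ORF finder on 200 random
transcripts, and exercises the scoring and quantification round trips on
fixture-scale tables (hundreds of protein groups, tens of replicates);
these sizes give stable statistics while keeping the whole suite around a
minute on one CPU. Transcriptome-scale behaviour (10^5 ORFs from tens of
gigabases of reads) is a linear scan of the same per-transcript code path
and is not separately exercised. Every stochastic step is seeded
explicitly, so reruns are byte-identical.

## Known limitations

* No mispriming thermodynamics, heteroduplex repair, or loxP inversion.
* HR integration models the designed outcome only; targeting frequency and
  random integration are biological quantities outside the model.
* The specificity score inherits the control run's detection limits; with a
  single control run a protein absent by chance is indistinguishable from a
  true bait-only interactor.
* Copy-number accuracy is bounded by the assumed CoIP yield — a systematic,
  not statistical, uncertainty (halving the yield doubles every copy
  number).
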