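---
title: "Methods and design of kozakscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of kozakscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kozakscan)
```

## The model

Translation initiation in eukaryotes is strongly influenced by the
nucleotide context around the initiation codon: the Kozak consensus, with
its purine three nucleotides upstream of the start and a G immediately
downstream, marks efficient starts, and weak contexts promote leaky
scanning past a codon. Noncanonical initiation — at the nine near-cognate
codons one substitution away from ATG, frequently in 5'UTRs — follows the
same logic, which is what makes a context score useful for triaging
candidate translation initiation codons (TICs).

The Kozak Similarity Score of a codon is computed from the ten nucleotides
on each side of it. Given a matrix of non-negative heights $h(p, n)$ for
positions $p = 1..20$ (1–10: upstream flank read 5'→3'; 11–20: downstream
flank) and nucleotides $n \in \{A, C, G, T\}$,

$$\mathrm{KSS} = \frac{\sum_{p=1}^{20} h(p, n_p)}{\sum_{p=1}^{20} \max_n h(p, n)}.$$

The denominator (`kss_max()`) is the maximum attainable sum, so
$\mathrm{KSS} \in [0, 1]$ and equals 1 exactly when every flank position
carries a maximal-height nucleotide. The codon itself contributes nothing:
the score measures context only, which is what lets the same matrix score
ATG and near-cognate candidates alike.

## The packaged bits matrix

The height values behind previously published Kozak-similarity scores are
not publicly available, so `default_kozak_matrix()` ships the package's own
consensus-motif model. Heights encode nucleotide preference scaled by
positional impact, in three tiers (0.60 / 0.40 / 0.25 at the modal
nucleotide): a strong A-over-G purine preference at position 8 (the classic
−3 position), a strong G at position 11 (+4 for an ATG), moderate
preferences in the C-rich core near the codon — with the position
immediately 5' of the codon modelled A-leaning — and low, nearly flat
heights at the positions far from the codon. Under this matrix a uniform
random context scores about 0.44 on average, and the consensus context
scores 1.

Two points matter for interpretation. First, heights are *not* plain
sequence-logo letter heights (frequency × information content): over
realistic start-context frequencies those are nearly flat away from −3/+4,
which would make the score almost insensitive to most of the window and
would also make the synthetic generator's concentration knob (below)
ineffective at practical values. Scaling preferences by positional impact
keeps the informative positions dominant while letting every position
contribute. Second, the packaged values are a model, not a measurement:
scores are internally consistent and reproducible, but not numerically
identical to scores computed with any external matrix. Users who need a
specific published matrix can supply it with `load_bits_matrix()` (TSV,
columns `position A C G T`, rows 1–20); every function takes the matrix as
an argument.

## Conventions and edge cases

* **Coordinates** are 0-based half-open internally (`transcript_record()`:
  the 5'UTR is the prefix of length `main_tic_start`); all report writers
  emit 1-based positions. GenBank CDS locations (1-based inclusive) are
  converted on input.
* **"Upstream"** means the candidate's first nucleotide lies strictly 5' of
  the main TIC, in any reading frame; a candidate overlapping the main TIC
  boundary still counts, since a scanning ribosome reaches it first. The
  stricter `UTR5` region requires the whole codon inside the 5'UTR.
* **Partial flanks.** Candidates within 10 nt of a transcript end cannot be
  scored on the full window; they are returned flagged and excluded from
  scoring and ranking by default. A `pad` option scores them with absent
  positions contributing zero bits, for users who prefer completeness over
  comparability.
* **Ambiguity codes** in flanks raise an error by default; a lenient mode
  scores them as zero bits. Silent zero-scoring by default could mask data
  problems.
* **Ties.** Identical flanks give identical scores (this happens in real
  paralogue pairs), so ranking is ordinal with a documented tie-break: the
  5'-most candidate wins, and at most one candidate per pool has rank 1.
  Competition ranking ("1-2-2-4") is available via `method =
  "competition"`. Rank pools contain only fully flanked candidates; the
  number excluded is recorded as an attribute.
* **Scores** are computed in double precision and rounded to 3 decimals
  only in output files.

## Peptide-evidence inference

N-terminal peptides are matched against the three forward-frame
translations (inputs are mRNA-sense transcripts, so reverse frames are
meaningless here). Matching is exact — the evidence type is short
N-terminal peptides, where overlap finding, not alignment, is the
appropriate operation — with one deliberate refinement: for peptides
beginning with methionine, the initiator residue is aligned to the codon
one step 5' of the exact match of residues 2..k. The initiator Met is
delivered by the initiator tRNA regardless of the codon, so an M-initial
peptide can legitimately map onto a near-cognate initiator; requiring the
first residue to match the genetic-code translation would force every
M-initial peptide onto an ATG and make near-cognate starts undiscoverable
from intact peptides.

Inference then applies the methionine-excision rules. An M-initial peptide
keeps its aligned codon as the TIC (still checked to be ATG or
near-cognate; an anomalous codon is excluded with a reason rather than
silently kept). A peptide without an N-terminal Met is assumed to have lost
exactly the initiator residue, so the next codon upstream and in frame is
taken as the TIC; if that codon is neither ATG nor near-cognate, more than
one residue was likely removed and the evidence is excluded rather than
searched further upstream. By default this cleavage inference is applied to
all Met-less peptides; `strict_acetyl = TRUE` restricts it to acetylated
peptides (whose acetylation certifies a true protein N-terminus) and
excludes the rest. Kept TICs are classified by reading frame and in-frame
stops into N-terminal extensions, novel upstream products, downstream
starts, or the main start itself, and deduplicated so counts refer to
unique TICs. Peptides matching several loci produce one inference per
locus; disambiguation is left to the user, since nothing in the evidence
itself can resolve it.

## Statistics

Group comparisons use the one-sided Mann–Whitney U test (first group
stochastically greater), the standard nonparametric choice for skewed
score and length distributions. For combined samples of at most 16 without
ties the exact permutation distribution is used; otherwise the normal
approximation with midrank tie correction and continuity correction (ties
arise naturally when identical flanks repeat). Both corrections are on by
default and recorded in the result's `method`. Removal of the single
lowest noncanonical score is available as an explicit, flagged option and
is never automatic, so analyses can report both variants. The random-codon
baseline draws a fixed number of positions (default 4) uniformly without
replacement from each transcript's fully flanked positions — every
position, not just candidate starts, since it is a baseline over arbitrary
codons — and is seed-parameterised.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the package is tested
under:

* **5'UTR lengths** are log-normal, parameterised directly by their median
  (205 nt for the long, "cancer-like" regime; 112 nt for the short regime)
  with log-scale spread 0.55 — strictly positive and right-skewed like real
  UTR length distributions. Lengths are re-drawn when a draw cannot host
  the requested planted TICs (floor 38 nt + 35 nt per additional TIC);
  genuinely infeasible specifications raise an error naming the
  transcript.
* **Contexts** are sampled positionwise with probability proportional to
  $\exp(c \cdot h(p, n))$: concentration $c = 0$ gives uniform background
  and large $c$ gives the consensus, so similarity to consensus is a single
  continuous knob, and expected KSS is non-decreasing in $c$. Under the
  packaged matrix, $c = 6$ yields a median KSS near 0.74 and $c = 7.5$
  near 0.79; these two values are the package's canonical/noncanonical
  regimes for shift-detection experiments (a ~+0.05 median shift). Planted
  TICs default to $c = 10$ (median ≈ 0.86), a clearly favourable context.
* **Structure.** Each transcript is background sequence (default uniform
  composition) with a main ATG in a sampled context followed by a
  stop-free CDS ending in a stop codon, and non-overlapping planted TICs
  at uniform 5'UTR positions. The five codons downstream of each planted
  TIC are kept stop-free (and the first non-ATG) so every planted TIC
  supports an N-terminal peptide; `generate_peptide_evidence()` emits
  intact or Met-excised acetylated peptides, plus optional decoys that
  violate the upstream-codon rule.
* **Reproducibility.** All sampling flows through R's RNG from the spec's
  seed; identical seeds give byte-identical FASTA/TSV output.

What the generator does *not* emulate: real codon usage and base
composition (human 5'UTRs are GC-rich and ATG-depleted; uniform background
makes spurious upstream ATGs far more common than in real transcripts, so
the generator's "first ATG is the canonical TIC" fraction is much lower
than in curated data), splice isoforms, and mRNA secondary structure.
Passing tests on synthetic cohorts demonstrate correctness of the
machinery — enumeration, scoring, ranking, inference, testing — under
controlled truth, not biological performance on real transcriptomes.

## Problem sizes and verification

The test suite checks scoring against an independent brute-force
accumulation (1000 random matrix/context pairs, 1e-12 relative tolerance),
enumeration against an exhaustive 3-mer scan (100 random transcripts,
50–5000 nt), ranking against a stable sort oracle (200 random
transcripts), the peptide filters against a hand-traced fixture covering
every rule branch, and the Mann–Whitney implementation against full
enumeration, a hand-derived normal approximation, and a 2000-replicate
null calibration of its type-I error. End-to-end: planted TICs at
concentration 10 are recovered at rank 1 in ≥ 95% of 200 transcripts; the
canonical-vs-noncanonical concentration regimes (6 vs 7.5) are separated
at α = 0.05 in ≥ 90% of 100 replicates at group sizes 94 vs 87; and the
two UTR regimes at cohort sizes 85 vs 3615 give one-sided p < 1e-6 in ≥
95% of 20 replicates. `scripts/acceptance.R` recomputes the package's
headline quantities from scratch on a fresh simulated study cohort (87
transcripts, 94 planted noncanonical TICs, 80/7 single/double split) at
those same regimes.

## Known limitations

* The packaged matrix is a model; absolute scores are not comparable to
  scores from other matrices (relative ranking within a matrix is the
  meaningful output).
* Genome-coordinate (spliced) inputs and minus-strand handling are out of
  scope: inputs are mRNA-sense transcript sequences by contract.
* The GenBank reader handles single, simple `start..end` CDS features
  only; multi-CDS or joined records should be provided via the FASTA +
  annotation route.
* Peptide matching is exact and I/L-aware only to the extent the input is;
  mass-spectrometry ambiguities (I/L, FDR) must be resolved upstream.
* Colour-bin thresholds (0.50 / 0.62 / 0.72 / 0.80) are global defaults
  chosen for cross-transcript comparability — 0.80 marks the region where
  favourable noncanonical contexts concentrate under strong matrices — and
  are user-overridable per report.
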