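---
title: "Methods: fusion validation, neoepitope windows and the fusion fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion validation, neoepitope windows and the fusion fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionneo)
```

## The model

`fusionneo` treats a fusion call as a *hypothesis* stated by a read-pair
caller — two genes, a breakpoint, and a junction sequence with the
breakpoint marked — and asks whether an independently assembled
transcriptome contains a contig that reconstructs the same junction. The
assumptions behind each stage are worth stating explicitly.

**Junction window.** The caller's junction sequence is split at its
breakpoint marker and each arm is trimmed to the `max_arm = 250` bases
nearest the breakpoint, giving a window of up to 500 nt. This is the
region over which read-pair evidence and assembly evidence can be expected
to agree even when the two tools disagree about distal transcript
structure; arms shorter than the cap are used as-is.

**Concordance.** For each contig, and for both orientations (de novo
assembly strand is arbitrary, so both are always tried), the package
computes the optimal affine-gap local alignment of the window against the
contig: match +1, mismatch −2, gap open −3, gap extend −1, a gap of length
L costing `3 + L`. The contig *covers the junction* when the optimal
alignment's span on the window contains both breakpoint-flanking bases,
and its concordance is then

\[
C = 100 \cdot \frac{\text{identically aligned window bases}}{\text{window length}},
\]

otherwise the contig contributes `C = 0`. A fusion is validated when its
best covering contig reaches `C \ge 25` (the inclusive comparator is the
default; a strict one is a flag).

A design point deserves emphasis because the two candidate definitions
disagree on real inputs. One could instead search for the best alignment
*constrained* to cross the breakpoint. That definition is degenerate: for
a contig that assembles only one partner gene, the constrained optimum
happily pays a small gap or a few mismatches to poke across the junction,
inheriting a high score from the one matching arm — a one-armed contig
could then "validate" a fusion at ~50% concordance, which is exactly the
false-positive mode the validation step exists to remove. The definition
used here — align freely, then require that the *optimal* alignment
crosses — makes a one-armed contig score 0 by construction, because its
best alignment has no reason to leave the matching arm. The cost is a
small conservatism: a contig whose best alignment is one-armed but which
also contains a genuine (lower-scoring) junction match is discarded; with
both tools run on the same reads this situation is rare, and conservatism
is the right default for a validation filter.

**Tie-breaking and determinism.** Among equally concordant covering
contigs the lexicographically smaller `contig_id` wins, then the `+`
orientation. Inside the aligner the traceback is canonical: the end cell
is the maximal match-state cell with the smallest window index, then the
smallest contig index; at each step the preference is stop (at
contribution 0), then diagonal, then gap-in-window, then gap-in-contig.
Every result is therefore a pure function of the inputs — required both
for reproducibility and for exact oracle tests (the test suite contains an
independently structured pure-R dynamic-programming implementation that
must agree exactly, plus a cross-check of optimal scores against
`Biostrings::pairwiseAlignment`).

**Classification.** TIC (transcription-induced chimera) is called when the
caller flagged adjacency/read-through, or when the annotation shows the
two genes to be neighbours: same chromosome, no annotated gene strictly
between the gene bodies, gap ≤ 1 Mb. Strand orientation deliberately does
not veto a TIC — read-through chimeras of divergently transcribed
neighbours exist. Otherwise different chromosomes give INTER, the same
chromosome INTRA. Control subtraction matches by unordered gene-name pair
rather than exact breakpoint, because a control fusion at any breakpoint
marks the pair as untrustworthy.

**ORFs and frame.** ORF discovery enumerates every ATG paired with its
first in-frame stop across all six frames; ORFs that run off the contig
are kept and flagged incomplete, because assembly truncation is common and
a truncated fusion ORF is still informative (its tail is reported as
censored). The junction ORF is the longest ORF spanning the breakpoint,
with **no minimum length** — short novel tails are exactly the neoantigen
payload and must not be filtered (the standalone ORF lister defaults to
`min_aa = 30`). Frame is classified by k-mer membership: the fusion is
in-frame when the first `k = 8` residues translated past the junction
occur verbatim in the downstream partner's reference protein. This works
on assembled contigs whose splice structure is unknown, where
annotation-phase arithmetic would not; the trade-off is that fewer than
`k` residues of downstream context weaken the test (with a very short
in-frame remainder the available residues are used as-is). Unusual
splicing (e.g. intron retention at the junction) is reported as a free-text
anomaly note when the junction alignment contains an internal gap of
≥ 20 nt; full splice-graph analysis is out of scope. The reported
`transcript_direction` is the chosen ORF's strand relative to the junction
window, a proxy that can disagree with splicing-based direction assignment
on unspliced contigs.

**Neoepitope windows and tiling.** In-frame: up to 11 residues on each
side of the junction (a 22-mer holds every junction-spanning 8–11-mer).
Frameshift: up to 11 upstream residues plus the entire novel tail.
Tiling keeps junction-*overlapping* peptides only: for in-frame fusions a
peptide wholly on either side of the junction is a self peptide and is
removed (`spanning_only = FALSE` restores naive tiling, since whether the
original procedure removed wild-type-matching peptides before prediction
is not documented); for frameshifts, peptides wholly inside the novel tail
are fully novel and are kept. With full context the number of spanning
k-mers is exactly `k − 1`, so a 22-mer yields 7+8+9+10 = 34 peptides — a
closed form the tests assert. Strong binders are `rank < 0.5` percent,
strictly. The bundled mock predictor is a stable 64-bit hash mapped to
[0, 100) — deterministic across platforms, uniform by construction,
carrying no biology; it exists so the pipeline and its tests run offline.

**Fusion fraction.** `FF = Σ span counts of validated INTER+INTRA fusions
per 10⁷ mapped paired reads`. Two readings of the underlying phrase are
defensible — summing span counts versus counting fusions — and both are
implemented (`ff_mode`); span-sum is the default because the definition
names the span count explicitly. TICs are excluded: they do not evidence
chromosomal breakage. FF is exactly invariant under common scaling of
spans and read totals, and stable in expectation under read subsampling —
the depth-stability property the tests verify exactly (scaling) and within
three binomial standard errors (subsampling). The survival split at
`FF > 2.7` and the 2× control rule are configuration defaults, not
constants: both are cohort-derived quantities (the 2.7 cut corresponds to
a top quartile in the motivating data) and should be re-derived for new
cohorts. Boundary semantics are literal: exactly 2.7 goes to the low
group; exactly 2× control is not high.

**Survival.** The Kaplan–Meier product-limit estimator and the two-sample
log-rank test are implemented from the standard formulas (per-event-time
hypergeometric expectation and variance, `χ² = (ΣO₁−E₁)²/ΣV₁`, 1 df), with
the pre-installed `survival` package used only as an independent
cross-check in tests. Variance terms with a risk set of one are skipped
(they are 0/0 and contribute nothing). At time zero both curves are 1.

**TIC read ratio.** Arithmetic means of per-base depth over the last
10 nt of the shared exon and the first 10 nt of the retained intron;
`ratio = intron mean / exon mean`. A zero exon mean makes the ratio
undefined (error); a zero intron mean gives ratio 0.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `probability_threshold` | 0.5 | caller probability | strict "more than"; the caller's own confidence cut |
| `max_arm` | 250 | nt | caps the junction window at 500 nt |
| scoring | +1/−2/−3/−1 | per base | standard local-alignment weights; fixed, configurable |
| `concordance_threshold` | 25 | % of window | separates assembly agreement from noise; inclusive `≥` |
| `inframe_kmer` (`k`) | 8 | aa | short enough to survive near-junction truncation, long enough that chance hits are negligible (20⁻⁸) |
| `flank_aa` | 11 | aa | one residue short of the longest peptide tiled, so every 8–11-mer can span |
| `peptide_lengths` | 8–11 | aa | MHC class I ligand lengths |
| `strong_rank` | 0.5 | % rank | strict `<`; standard strong-binder cut |
| `ff_threshold` | 2.7 | FF | cohort-derived split; re-derive per cohort |
| `control_multiplier` | 2 | fold | high-FF vs. matched controls, strict `>` |
| `min_recommended_reads` | 4×10⁷ | paired reads | below this, assembly misses prominent fusion transcripts; warning only |
| `max_tic_gap` | 10⁶ | nt | adjacency fallback for TIC when caller flags are absent |

## What the synthetic generator does and does not emulate

`make_toy_annotation()` builds multi-exon genes whose spliced exon chains
are complete CDSs on random strands across several chromosomes;
`plant_fusions()` joins two CDSs at codon boundaries (in-frame) or with a
one/two-base shift (frameshift), emits the fusion transcript as a contig
(exact, mutated at a controlled rate around the junction, or withheld),
writes a deFuse-dialect candidate row, and records every truth in a
manifest. Frameshift constructions are rejection-sampled until the novel
tail is at least 8 residues and the planted ORF is provably the unique
longest junction-spanning ORF, so the manifest is guaranteed consistent
with what the pipeline's stated selection rule must find; the generator
plants a stop codon for the shifted frame when the transcript would
otherwise end without one. Decoy contigs — random sequence and a
single-arm contig — are always added.

The generator emulates: breakpoint-marked junction rows, arbitrary
assembly strand, multi-fusion contigs (constructible), concordance
degradation by point mutation, TIC adjacency (including opposite-strand
neighbours), span counts and read totals, binomially sampled intron
coverage for the read-through ratio. It does **not** emulate: read-level
error or coverage fluctuation, alternative isoforms, paralogy (junctions
are unique by construction — the BLAST-uniqueness screen of a real
workflow is untested here), expression-dependent assembly failure, or
caller-specific probability calibration. A green planted-truth test
therefore establishes that the pipeline's logic is faithful to its
definitions, not that those definitions have a particular sensitivity or
specificity on real tumour data.

## Numerical and degenerate-input choices

* Windows shorter than 16 nt are unscoreable (error), as are junction
  sequences without exactly one marker or with an empty arm.
* Alignment scores are integer-valued doubles; all equality comparisons in
  the canonical traceback are exact.
* A junction that lands on an ORF's stop codon yields
  `NO_ORF_AT_JUNCTION` (nothing is encoded past it).
* Parsers never silently drop rows: records failing validation are
  reported in a `problems` attribute with one reason each, and
  `rows = records + problems` always holds.
* Coverage tracks reject contradictory overlapping depths but collapse
  agreeing duplicates; positions absent from a track read as depth 0.
* `mock_rank_predictor` hashes `peptide, allele` with FNV-1a/splitmix64 —
  uniformity is a property of the finisher, and the KS test in the suite
  checks it empirically at n = 10,000.

## Known limitations

* Concordance is defined on nucleotide identity within one optimal local
  alignment; if the historical tool used k-mer sharing instead, absolute
  percentages are not comparable even though the ≥ 25% validation
  behaviour on exact/near-exact junctions is.
* The in-frame k-mer test can misclassify when fewer than `k` residues
  follow the junction, and cannot see in-frame fusions whose immediate
  downstream sequence is mutated.
* `transcript_direction` is an ORF-strand proxy, not a splicing analysis.
* The TIC adjacency fallback depends on annotation completeness; a missing
  gene between two others turns an INTRA into an apparent TIC.
* Survival stratification implements only the two-group log-rank test; no
  Cox regression, no multi-group generalization.
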