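# fusionneo

Validation of gene-fusion transcripts from RNA-seq, fusion-derived
neoepitope prediction, and per-sample genomic-instability metrics.

## The problem

Fusion callers that work from discordant read pairs (deFuse and its kin)
produce long candidate lists with many false positives, while de novo
transcriptome assemblers (Trinity and its kin) reconstruct full-length
transcripts — including fusion transcripts — without using a reference.
The two lines of evidence are independent: a fusion supported by both a
read-pair caller *and* an assembled contig that crosses the same breakpoint
is far more credible than either alone. `fusionneo` implements that
cross-validation and everything downstream of it that turns a validated
fusion into an immunotherapy lead:

1. **Candidate filtering** — keep calls with caller probability > 0.5,
   subtract fusions also seen in normal (osteoblast) controls, exclude
   artifact-prone gene families (SRGAP2 and its segmental duplicates).
2. **Classification** — INTER (different chromosomes), INTRA (same
   chromosome, non-adjacent), or TIC (transcription-induced chimera:
   read-through of neighbouring genes, which does not require any genomic
   rearrangement and may join genes transcribed in opposite directions).
3. **Junction concordance** — align the window of up to 250 nt on each side
   of the caller's breakpoint against every contig (both orientations,
   since assembly strand is arbitrary) with an affine-gap local aligner
   (match +1, mismatch −2, gap open −3, gap extend −1). A contig validates
   a fusion only if its best alignment *spans* the breakpoint; concordance
   is the percentage of window bases identically aligned,
   `C = 100 · m / |W|`, and `C ≥ 25%` validates. A contig that assembles
   only one partner gene can never validate a fusion.
4. **ORF and fusion-protein characterization** — six-frame ORF discovery on
   the validated contig, selection of the longest ORF spanning the
   breakpoint, and frame classification: the fusion is in-frame when the
   first 8 residues translated past the junction occur verbatim in the
   downstream partner's reference protein; otherwise it is a frameshift
   whose *novel tail* (junction to first premature stop) is pure
   tumour-specific sequence.
5. **Neoepitope tiling** — peptide windows of 11 aa upstream + 11 aa
   downstream (in-frame) or 11 aa upstream + the entire novel tail
   (frameshift), tiled into all junction-overlapping 8–11-mers for MHC
   class I binding prediction; predicted binders with percent rank < 0.5
   against the patient's HLA alleles are *strong binders*.
6. **Fusion fraction (FF)** — a genomic-instability index per sample:

   ```
   FF = Σ span_count(validated INTER+INTRA fusions) / (mapped paired reads / 10⁷)
   ```

   TICs are excluded (read-through, not chromosomal breakage). FF is
   scale-invariant in sequencing depth; samples above 2× the control FF are
   flagged, and a Kaplan–Meier / two-sample log-rank stratification at
   FF > 2.7 (implemented from the product-limit and
   `(ΣO₁−E₁)²/ΣV₁` formulas) tests the survival association.
7. **TIC read ratio** — for a read-through chimera that retains an intron,
   the mean coverage over the first 10 nt of the retained intron
   (chimera-only reads) divided by the mean over the last 10 nt of the
   shared exon (chimera + native transcripts) estimates the chimera's share
   of transcription.

MHC binding prediction itself, HLA typing, and running the fusion
caller/assembler are out of scope: the package writes peptide FASTA for an
external predictor and reads its tabular output back (a deterministic mock
predictor stands in for tests and offline runs).

Everything is testable offline: `make_toy_annotation()` + `plant_fusions()`
generate a synthetic genome, annotation, deFuse-style candidate table,
contig FASTA and a truth manifest (fusion class, reading frame, novel tail,
concordance band, span counts) as a pure function of a seed.

## Worked example

```r
library(fusionneo)
library(dplyr)

toy <- make_toy_annotation(seed = 42)          # synthetic genome + genes
fx  <- plant_fusions(toy$annotation, seed = 7) # 6 fusions, all classes

val <- fx$candidates |>
  classify_fusions(toy$annotation) |>
  filter_candidates() |>
  filter(kept) |>
  validate_fusions(fx$contigs)

val |> select(cluster_id, fusion_class, concordance_percent, validated, span_count)
#>   cluster_id fusion_class concordance_percent validated span_count
#> 1 F001       INTER                        100 TRUE              12
#> 2 F002       INTER                        100 TRUE              25
#> 3 F003       INTRA                        100 TRUE               8
#> 4 F004       INTRA                        100 TRUE              30
#> 5 F005       TIC                          100 TRUE              15
#> 6 F006       TIC                          100 TRUE              20
```

Every planted fusion is validated at 100% concordance (the fixture emits
exact contigs). Characterization recovers the reading frame and, for
frameshifts, the novel C-terminal tail:

```r
reports <- characterize_fusions(val, fx$contigs, toy$annotation)
reports |> select(cluster_id, frame_class, junction_aa_index, novel_tail)
#>   cluster_id frame_class  junction_aa_index novel_tail
#> 1 F001       IN_FRAME                    45 ""
#> 2 F002       OUT_OF_FRAME                69 "SQVSFRVLHITHPMPYG"
#> 3 F003       IN_FRAME                    88 ""
#> 4 F004       OUT_OF_FRAME                63 "SRPGLGLAF"
#> 5 F005       IN_FRAME                    74 ""
#> 6 F006       OUT_OF_FRAME                55 "PTLDCDGPPTGSQVSFRVLHITHPMPYG"
```

Tile the junction windows into 8–11-mers and keep strong binders (here via
the deterministic mock predictor; substitute `read_binding_table()` on real
predictor output):

```r
extract_windows(reports) |>
  tile_peptides() |>
  predict_binding_mock(c("HLA-A*02:01", "HLA-B*07:02")) |>
  filter_strong_binders()
#>   cluster_id peptide    hla_allele  rank_percent strong
#> 1 F002       SQVSFRVLHI HLA-A*02:01        0.386 TRUE
#> 2 F006       SQVSFRVLHI HLA-A*02:01        0.386 TRUE
```

The sample's fusion fraction counts the validated INTER+INTRA span counts
(12 + 25 + 8 + 30 = 75; the two TICs are excluded) per 10 million of the
60 million mapped paired reads:

```r
fusion_fraction(val, mapped_paired_reads = 6e7, sample_id = "tumor_A")
#>   sample_id n_validated span_total mapped_paired_reads fusion_fraction
#> 1 tumor_A             4         75            6e+07               12.5
```

`km_stratify()` (with `tidy()`, `glance()`, `autoplot()` methods) splits a
cohort at FF > 2.7 and reports the log-rank chi-square;
`tic_read_ratio()` computes the exon/intron coverage ratio. A thin CLI over
the same functions ships in `inst/cli/fusionneo`
(`fusionneo {classify,validate,characterize,epitopes,fraction,survival,tic-ratio,simulate,run}`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end to end on a seeded synthetic fixture —
candidate filtering, contig validation, protein characterization, peptide
tiling, strong-binder filtering and the fusion fraction — verifies the run
against the fixture's planted truth, and writes the JSON result object.
The package's quantitative acceptance checks (alignment-oracle equivalence,
ORF enumeration equivalence, tiling closed forms, planted-truth recovery,
threshold semantics, FF depth stability, log-rank correctness, TIC-ratio
recovery) run as part of the test suite in
`tests/testthat/test-acceptance.R`.
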