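#' Pipeline configuration
#'
#' Collects every tunable constant of the fusion-to-neoepitope pipeline with
#' its default: candidate probability must exceed 0.5; junction concordance
#' of at least 25 percent validates a fusion; peptide windows take 11
#' residues of flank; 8-11-mers are tiled; percent rank below 0.5 defines a
#' strong binder; fusion fractions above 2.7 define the high-FF survival
#' group; a sample is high-FF relative to controls above 2 times the control
#' FF; the SRGAP2 family is excluded; read totals under 40 million paired
#' reads only warn. The configuration is echoed into every run summary so
#' outputs alone reconstruct the parameterization.
#'
#' @param probability_threshold,concordance_threshold,concordance_inclusive,flank_aa,peptide_lengths,strong_rank,ff_mode,ff_threshold,control_multiplier,excluded_families,min_recommended_reads,max_arm,inframe_kmer,seed
#'   See descriptions above; defaults in the function signature.
#' @return A named list of class `fusionneo_config`.
#' @export
fusion_config <- function(probability_threshold = 0.5,
                          concordance_threshold = 25,
                          concordance_inclusive = TRUE,
                          flank_aa = 11,
                          peptide_lengths = 8:11,
                          strong_rank = 0.5,
                          ff_mode = c("span_sum", "fusion_count"),
                          ff_threshold = 2.7,
                          control_multiplier = 2,
                          excluded_families = c("SRGAP2", "SRGAP2B",
                                                "SRGAP2C", "SRGAP2D"),
                          min_recommended_reads = 4e7,
                          max_arm = 250,
                          inframe_kmer = 8,
                          seed = 1) {
  stopifnot_scalar_number(probability_threshold, "probability_threshold", 0, 1)
  stopifnot_scalar_number(concordance_threshold, "concordance_threshold", 0, 100)
  stopifnot_scalar_number(strong_rank, "strong_rank", 0, 100)
  structure(list(
    probability_threshold = probability_threshold,
    concordance_threshold = concordance_threshold,
    concordance_inclusive = concordance_inclusive,
    flank_aa = flank_aa, peptide_lengths = peptide_lengths,
    strong_rank = strong_rank, ff_mode = match.arg(ff_mode),
    ff_threshold = ff_threshold, control_multiplier = control_multiplier,
    excluded_families = excluded_families,
    min_recommended_reads = min_recommended_reads,
    max_arm = max_arm, inframe_kmer = inframe_kmer, seed = seed),
    class = "fusionneo_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the fusion-to-neoepitope pipeline end to end
#'
#' Wires the modules into the full analysis: candidate filtering and
#' classification, contig validation by junction concordance, fusion-protein
#' characterization, neoepitope window extraction and peptide tiling, strong
#' binder filtering (against a supplied external binding table, or the
#' deterministic mock predictor when none is given), and the per-sample
#' fusion fraction. Every stage writes a TSV under `out_dir` and contributes
#' counts to a machine-readable `run_summary.json` (which also echoes the
#' full configuration); the funnel conserves counts at every stage.
#'
#' @param defuse Candidate table: path to a deFuse-style TSV or a tibble
#'   from [read_defuse_table()].
#' @param contigs Contig set: FASTA path or tibble.
#' @param annotation Annotation tibble with reference proteins (or a list
#'   `list(gtf = , genome = )` of paths).
#' @param mapped_paired_reads Mapped paired-read total for the sample.
#' @param out_dir Output directory, created if needed.
#' @param config A [fusion_config()] list.
#' @param sample_id Sample label.
#' @param hla_alleles Patient HLA alleles for the mock predictor (used only
#'   when `binding` is `NULL`).
#' @param binding Optional external binding predictions: path or tibble in
#'   [read_binding_table()] layout, joined to tiled peptides by peptide.
#' @param control_pairs Control fusion gene pairs for subtraction (see
#'   [filter_candidates()]).
#' @return Invisibly, a list with the stage tibbles (`candidates`,
#'   `validated`, `reports`, `windows`, `peptides`, `strong`, `profile`) and
#'   the `summary` list.
#' @export
run_pipeline <- function(defuse, contigs, annotation, mapped_paired_reads,
                         out_dir, config = fusion_config(),
                         sample_id = "sample",
                         hla_alleles = c("HLA-A*02:01", "HLA-B*07:02"),
                         binding = NULL, control_pairs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) message(sprintf("[fusionneo +%.1fs] ",
                                       as.numeric(Sys.time() - t0, "secs")),
                               sprintf(...))

  candidates <- stage("read", {
    if (is.character(defuse)) read_defuse_table(defuse) else defuse
  })
  contigs <- stage("read", {
    if (is.character(contigs)) read_fasta(contigs) else contigs
  })
  annotation <- stage("read", {
    if (is.list(annotation) && !is.data.frame(annotation)) {
      read_gene_annotation(annotation$gtf, annotation$genome)
    } else annotation
  })
  n_input <- nrow(candidates)
  say("read %d candidates, %d contigs, %d genes", n_input, nrow(contigs),
      nrow(annotation))

  candidates <- stage("classify", classify_fusions(candidates, annotation))
  candidates <- stage("filter", filter_candidates(
    candidates, probability_threshold = config$probability_threshold,
    control_pairs = control_pairs,
    excluded_family = config$excluded_families))
  readr::write_tsv(candidates |> select(-dplyr::any_of("exons")),
                   file.path(out_dir, "candidates_classified.tsv"))
  drop_counts <- table(candidates$drop_reason)
  say("filter kept %d / %d", sum(candidates$kept), n_input)

  kept <- candidates[candidates$kept, ]
  validated <- stage("validate", validate_fusions(
    kept, contigs, concordance_threshold = config$concordance_threshold,
    inclusive = config$concordance_inclusive, max_arm = config$max_arm))
  readr::write_tsv(validated |> select(-"junction_sequence"),
                   file.path(out_dir, "validated.tsv"))
  say("validated %d / %d junction-concordant fusions",
      sum(validated$validated), nrow(validated))

  reports <- stage("characterize", characterize_fusions(
    validated, contigs, annotation, k = config$inframe_kmer))
  readr::write_tsv(reports, file.path(out_dir, "fusion_proteins.tsv"))

  windows <- stage("epitopes", extract_windows(reports, flank = config$flank_aa))
  peptides <- stage("epitopes", tile_peptides(windows,
                                              lengths = config$peptide_lengths))
  if (nrow(peptides) > 0L) {
    write_peptide_fasta(
      tibble(peptide_id = sprintf("%s_%03d", peptides$cluster_id,
                                  seq_len(nrow(peptides))),
             peptide = peptides$peptide),
      file.path(out_dir, "peptides.fasta"))
  }
  records <- stage("epitopes", {
    if (is.null(binding)) {
      predict_binding_mock(peptides, hla_alleles)
    } else {
      b <- if (is.character(binding)) read_binding_table(binding) else binding
      dplyr::inner_join(peptides[c("cluster_id", "peptide")], b, by = "peptide")
    }
  })
  strong <- stage("epitopes", filter_strong_binders(records,
                                                    threshold = config$strong_rank))
  readr::write_tsv(strong, file.path(out_dir, "epitopes.tsv"))
  say("%d strong binders from %d tiled peptides", nrow(strong), nrow(peptides))

  profile <- stage("fraction", fusion_fraction(
    validated, mapped_paired_reads, sample_id = sample_id,
    mode = config$ff_mode,
    min_recommended_reads = config$min_recommended_reads))
  readr::write_tsv(profile, file.path(out_dir, "fusion_profile.tsv"))
  say("fusion fraction %.3f", profile$fusion_fraction)

  summary <- list(
    sample_id = sample_id,
    config = unclass(config),
    counts = list(
      input = n_input,
      kept = sum(candidates$kept),
      dropped = as.list(stats::setNames(as.integer(drop_counts),
                                        names(drop_counts))),
      by_class = as.list(table(candidates$fusion_class[candidates$kept])),
      validated = sum(validated$validated),
      rejected = sum(!validated$validated),
      frame_class = as.list(table(reports$frame_class)),
      windows = nrow(windows),
      peptides = nrow(peptides),
      binding_records = nrow(records),
      strong_binders = nrow(strong)),
    fusion_fraction = profile$fusion_fraction,
    mapped_paired_reads = mapped_paired_reads)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(candidates = candidates, validated = validated,
                 reports = reports, windows = windows, peptides = peptides,
                 strong = strong, profile = profile, summary = summary))
}

#' Plot junction concordance per candidate
#'
#' Bar chart of the best-contig concordance for each candidate, coloured by
#' validation status, with the validation threshold drawn.
#'
#' @param validated Output of [validate_fusions()].
#' @param threshold Threshold line, default 25.
#' @return A ggplot object.
#' @export
plot_concordance <- function(validated, threshold = 25) {
  ggplot2::ggplot(validated,
                  ggplot2::aes(x = stats::reorder(.data$cluster_id,
                                                  -.data$concordance_percent),
                               y = .data$concordance_percent,
                               fill = .data$validated)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Junction concordance (%)", fill = "Validated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
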