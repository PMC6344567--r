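#' Classify fusion candidates as INTER, INTRA or TIC
#'
#' A candidate is a transcription-induced chimera (TIC) when the caller
#' flagged it as adjacent or read-through, or when its two genes are
#' neighbours in the annotation: same chromosome, no annotated gene strictly
#' between the two gene bodies, and a gap of at most `max_tic_gap` bases.
#' A same-chromosome pair that cannot be resolved in the annotation needs
#' caller flags (`NA` flags are an error in that case). Strand orientation
#' does not veto the TIC call: read-through chimeras of genes transcribed in
#' opposite directions are real (the exemplar TIC joins two adjacent,
#' divergently transcribed genes on chromosome 4). Otherwise the candidate
#' is INTER when the partner genes sit on different chromosomes and INTRA
#' when on the same chromosome.
#'
#' @param candidates Candidate tibble (see [read_defuse_table()]).
#' @param annotation Optional annotation tibble, required for the adjacency
#'   fallback when a same-chromosome candidate carries `NA` flags.
#' @param max_tic_gap Maximum gap (bases) between neighbouring gene bodies
#'   for the annotation fallback, default 1e6.
#' @return `candidates` with a `fusion_class` factor column
#'   (`INTER`/`INTRA`/`TIC`).
#' @export
classify_fusions <- function(candidates, annotation = NULL, max_tic_gap = 1e6) {
  n <- nrow(candidates)
  cls <- character(n)
  ann_by_id <- if (!is.null(annotation)) split(annotation, annotation$gene_id)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    if (isTRUE(cand$read_through_flag) || isTRUE(cand$adjacent_flag)) {
      cls[i] <- "TIC"
      next
    }
    if (!identical(cand$chrom1, cand$chrom2)) {
      cls[i] <- "INTER"
      next
    }
    flags_present <- !is.na(cand$read_through_flag) && !is.na(cand$adjacent_flag)
    g1 <- ann_by_id[[cand$gene1_id]]
    g2 <- ann_by_id[[cand$gene2_id]]
    if (is.null(g1) || is.null(g2)) {
      # same-chromosome pair not resolvable in the annotation: the caller
      # flags are the only adjacency evidence
      if (flags_present) {
        cls[i] <- "INTRA"
        next
      }
      abort(paste0("cannot classify ", cand$cluster_id,
                   ": gene(s) absent from annotation and caller flags absent"))
    }
    lo <- min(g1$end, g2$end)
    hi <- max(g1$start, g2$start)
    gap_ok <- (hi - lo) <= max_tic_gap
    others <- annotation[annotation$chrom == cand$chrom1 &
                           !annotation$gene_id %in% c(cand$gene1_id, cand$gene2_id), ]
    between <- any(others$start >= lo & others$end <= hi)
    cls[i] <- if (gap_ok && !between) "TIC" else "INTRA"
  }
  candidates$fusion_class <- factor(cls, levels = c("INTER", "INTRA", "TIC"))
  candidates
}

#' Filter fusion candidates
#'
#' Applies the three candidate filters used ahead of contig validation:
#' * `LOW_PROBABILITY`: caller probability must be strictly greater than
#'   `probability_threshold` (default 0.5);
#' * `IN_CONTROL`: the unordered gene-name pair was also seen in a control
#'   (e.g. normal osteoblast) sample;
#' * `EXCLUDED_FAMILY`: either partner belongs to a gene family known to
#'   generate artifactual calls through incomplete annotation (default the
#'   SRGAP2 family and its segmental duplicates).
#'
#' The result is the full input with a logical `kept` column and a
#' `drop_reason` column (`NA` for kept rows), so kept plus dropped always
#' partitions the input. When several rules apply, `drop_reason` reports
#' `LOW_PROBABILITY` over `IN_CONTROL` over `EXCLUDED_FAMILY`.
#'
#' @param candidates Candidate tibble.
#' @param probability_threshold Keep only `probability >` this value
#'   (strict, so a candidate at exactly the threshold is dropped).
#' @param control_pairs Character vector of control fusions, each
#'   `"GENE1|GENE2"` (order-insensitive), or a two-column data frame of gene
#'   names. Matching is by unordered gene-name pair.
#' @param excluded_family Gene names to exclude outright.
#' @return `candidates` plus `kept` (logical) and `drop_reason` (factor with
#'   levels `LOW_PROBABILITY`, `IN_CONTROL`, `EXCLUDED_FAMILY`).
#' @export
filter_candidates <- function(candidates,
                              probability_threshold = 0.5,
                              control_pairs = NULL,
                              excluded_family = c("SRGAP2", "SRGAP2B",
                                                  "SRGAP2C", "SRGAP2D")) {
  stopifnot_scalar_number(probability_threshold, "probability_threshold", 0, 1)
  ctl <- character(0)
  if (!is.null(control_pairs)) {
    if (is.data.frame(control_pairs)) {
      ctl <- pair_key(control_pairs[[1]], control_pairs[[2]])
    } else if (length(control_pairs) > 0L) {
      parts <- stringr::str_split_fixed(control_pairs, stringr::fixed("|"), 2)
      ctl <- pair_key(parts[, 1], parts[, 2])
    }
  }
  reason <- rep(NA_character_, nrow(candidates))
  if (nrow(candidates) > 0L) {
    low <- candidates$probability <= probability_threshold
    in_ctl <- pair_key(candidates$gene1_name, candidates$gene2_name) %in% ctl
    fam <- candidates$gene1_name %in% excluded_family |
      candidates$gene2_name %in% excluded_family
    reason[fam] <- "EXCLUDED_FAMILY"
    reason[in_ctl] <- "IN_CONTROL"
    reason[low] <- "LOW_PROBABILITY"
  }
  candidates$kept <- is.na(reason)
  candidates$drop_reason <- factor(reason, levels = c("LOW_PROBABILITY",
                                                      "IN_CONTROL",
                                                      "EXCLUDED_FAMILY"))
  candidates
}
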