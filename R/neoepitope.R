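#' Extract the neoepitope peptide window around a fusion junction
#'
#' For in-frame fusions the window is up to `flank` residues on each side of
#' the junction (default 11, so at most 22 residues: every 8-11-mer spanning
#' the junction fits inside it). For frameshifted fusions the window is up
#' to `flank` upstream residues plus the entire novel tail, down to the
#' first premature stop. `junction_index` records how many upstream residues
#' were actually available (it is less than `flank` near a protein start).
#'
#' @param reports Rows from [characterize_fusions()]; rows with
#'   `frame_class == "NO_ORF_AT_JUNCTION"` (or unvalidated `NA` rows) are
#'   skipped.
#' @param flank Upstream/downstream flank length in residues, default 11.
#' @return Tibble with columns `cluster_id`, `sequence`, `junction_index`
#'   (0-based index of the first post-junction residue), `frame_class`.
#' @export
extract_windows <- function(reports, flank = 11) {
  stopifnot_scalar_number(flank, "flank", 1)
  usable <- reports[!is.na(reports$frame_class) &
                      reports$frame_class != "NO_ORF_AT_JUNCTION", ]
  rows <- purrr::map(seq_len(nrow(usable)), function(i) {
    rep <- usable[i, ]
    protein <- rep$orf_protein
    j <- rep$junction_aa_index          # upstream residues available in ORF
    u <- min(flank, j)
    upstream <- substring(protein, j - u + 1L, j)
    downstream <- if (rep$frame_class == "IN_FRAME") {
      substring(protein, j + 1L, min(j + flank, nchar(protein)))
    } else {
      rep$novel_tail
    }
    window <- paste0(upstream, downstream)
    if (nchar(window) == 0L) abort(paste0("empty peptide window for ", rep$cluster_id))
    tibble(cluster_id = rep$cluster_id, sequence = window,
           junction_index = u, frame_class = as.character(rep$frame_class))
  })
  if (length(rows) == 0L) {
    return(tibble(cluster_id = character(0), sequence = character(0),
                  junction_index = integer(0), frame_class = character(0)))
  }
  bind_rows(rows)
}

#' Tile candidate 8-11-mer peptides over a junction window
#'
#' Enumerates all substrings of each window whose length is in `lengths`.
#' By default only *junction-overlapping* peptides are kept: every peptide
#' must contain at least one residue at or past `junction_index` (novel
#' content), and for in-frame windows with upstream context also at least
#' one residue before it (a peptide wholly on either side of an in-frame
#' junction is a self peptide and cannot be a neoantigen). Frameshift
#' windows keep peptides lying wholly inside the novel tail, which is fully
#' novel sequence. `spanning_only = FALSE` restores naive tiling.
#' Duplicate peptides within a window are dropped, first occurrence kept;
#' the same peptide arising from different fusions is kept per fusion so
#' that per-fusion neoepitope loads remain countable.
#'
#' @param windows Tibble from [extract_windows()].
#' @param lengths Peptide lengths to tile, default `8:11`.
#' @param spanning_only Apply the junction-overlap rule (default `TRUE`).
#' @return Tibble with columns `cluster_id`, `peptide`, `start` (0-based
#'   offset in the window), `length`.
#' @export
tile_peptides <- function(windows, lengths = 8:11, spanning_only = TRUE) {
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    wrow <- windows[i, ]
    wseq <- wrow$sequence
    n <- nchar(wseq)
    ji <- wrow$junction_index
    per_k <- purrr::map(sort(lengths), function(k) {
      if (n < k) return(NULL)
      starts <- 0:(n - k)
      if (spanning_only) {
        has_novel <- starts + k - 1L >= ji
        keep <- has_novel
        if (identical(wrow$frame_class, "IN_FRAME") && ji > 0L) {
          keep <- keep & (starts < ji)
        }
        starts <- starts[keep]
      }
      if (length(starts) == 0L) return(NULL)
      tibble(cluster_id = wrow$cluster_id,
             peptide = substring(wseq, starts + 1L, starts + k),
             start = starts, length = k)
    })
    res <- bind_rows(per_k)
    if (!is.null(res) && nrow(res) > 0L) res <- res[!duplicated(res$peptide), ]
    res
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) {
    return(tibble(cluster_id = character(0), peptide = character(0),
                  start = integer(0), length = integer(0)))
  }
  bind_rows(rows)
}

#' Deterministic mock MHC-binding rank predictor
#'
#' A stand-in for an external class I binding predictor, for tests and
#' offline pipeline runs: the percent rank is a deterministic pseudo-uniform
#' value in `[0, 100)` derived from a stable 64-bit hash of the
#' (peptide, allele) pair, identical across runs, sessions and platforms.
#' It carries no biology; real analyses must substitute predictions from an
#' actual predictor via [read_binding_table()].
#'
#' @param peptide,hla_allele Character vectors (recycled to equal length).
#' @return Numeric vector of pseudo percent ranks in `[0, 100)`.
#' @export
mock_rank_predictor <- function(peptide, hla_allele) {
  n <- max(length(peptide), length(hla_allele))
  peptide <- rep_len(peptide, n)
  hla_allele <- rep_len(hla_allele, n)
  .rank_hash(paste0(peptide, "\r", hla_allele))
}

#' Predict mock binding ranks for tiled peptides against patient alleles
#'
#' Convenience wrapper crossing peptides with a patient's HLA alleles and
#' scoring each pair with [mock_rank_predictor()].
#'
#' @param peptides Tibble from [tile_peptides()].
#' @param hla_alleles Character vector of four-digit alleles
#'   (e.g. `"HLA-A*02:01"`).
#' @return Binding-record tibble: `cluster_id`, `peptide`, `hla_allele`,
#'   `rank_percent`.
#' @export
predict_binding_mock <- function(peptides, hla_alleles) {
  grid <- tidyr::crossing(peptides[c("cluster_id", "peptide")],
                          hla_allele = hla_alleles) |>
    arrange(factor(.data$cluster_id, levels = unique(peptides$cluster_id)))
  grid$rank_percent <- mock_rank_predictor(grid$peptide, grid$hla_allele)
  grid
}

#' Filter strong MHC binders
#'
#' Keeps records with predicted percent rank strictly below `threshold`
#' (default 0.5, so a peptide at exactly rank 0.5 is *not* a strong binder)
#' and flags them `strong = TRUE`.
#'
#' @param records Binding-record tibble with `rank_percent` (and typically
#'   `peptide`, `hla_allele`, `cluster_id`).
#' @param threshold Strict upper bound on percent rank, default 0.5.
#' @return The qualifying rows with a `strong` column appended.
#' @seealso [neoepitope_load()]
#' @export
filter_strong_binders <- function(records, threshold = 0.5) {
  stopifnot_scalar_number(threshold, "threshold", 0)
  out <- records[!is.na(records$rank_percent) & records$rank_percent < threshold, ]
  out$strong <- rep(TRUE, nrow(out))
  out
}

#' Count strong-binding neoepitopes per fusion
#'
#' The per-fusion neoepitope load: number of distinct (peptide, allele)
#' strong binders attributed to each candidate.
#'
#' @param strong Output of [filter_strong_binders()] with a `cluster_id`
#'   column.
#' @return Tibble `cluster_id`, `n_neoepitopes`.
#' @export
neoepitope_load <- function(strong) {
  strong |>
    distinct(.data$cluster_id, .data$peptide, .data$hla_allele) |>
    dplyr::count(.data$cluster_id, name = "n_neoepitopes")
}
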