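#' Build the junction window around a fusion breakpoint
#'
#' Trims each arm of a `"|"`-marked junction sequence to its innermost
#' `max_arm` bases (those nearest the breakpoint), removes the marker, and
#' records the breakpoint offset: the 0-based index, within the concatenated
#' window, of the first base downstream of the junction. With the default
#' `max_arm = 250` the window covers up to 500 nt around the breakpoint,
#' the region over which the caller and the assembler are expected to agree.
#'
#' @param junction_sequence Character vector of junction sequences, each
#'   containing exactly one `"|"` with non-empty arms.
#' @param max_arm Maximum retained length per arm (default 250).
#' @return A tibble with columns `left_arm`, `right_arm`, `window`,
#'   `breakpoint_offset`.
#' @export
make_junction_window <- function(junction_sequence, max_arm = 250) {
  stopifnot_scalar_number(max_arm, "max_arm", 1)
  parts <- stringr::str_split_fixed(junction_sequence, stringr::fixed("|"), 3)
  if (any(parts[, 3] != "") ||
      any(stringr::str_count(junction_sequence, stringr::fixed("|")) != 1L))
    abort("junction sequence must contain exactly one '|'")
  left <- parts[, 1]
  right <- parts[, 2]
  if (any(left == "" | right == "")) abort("empty junction arm")
  left <- stringr::str_sub(left, -max_arm)
  right <- stringr::str_sub(right, 1, max_arm)
  tibble(left_arm = left, right_arm = right,
         window = paste0(left, right),
         breakpoint_offset = nchar(left))
}

#' Score concordance between a junction window and assembled contigs
#'
#' For each contig, and for both its orientations (assembly strand is
#' arbitrary), the optimal local alignment of the window against the contig
#' is computed under an affine-gap scheme (defaults: match +1, mismatch -2,
#' gap open -3, gap extend -1; a gap of length L costs open + L * extend).
#' A contig *covers the junction* when that optimal alignment's span on the
#' window contains both breakpoint-flanking bases (window positions
#' `breakpoint_offset - 1` and `breakpoint_offset`). For covering contigs the
#' concordance is `100 * identically aligned window bases / window length`;
#' a contig whose best alignment stays on one side of the breakpoint
#' contributes nothing, so a contig assembling only one partner gene can
#' never validate a fusion. The best covering contig is reported, with ties
#' broken deterministically (higher concordance, then lexicographically
#' smaller `contig_id`, then the `+` orientation).
#'
#' @param window One row of [make_junction_window()] output (or a list with
#'   `window` and `breakpoint_offset`).
#' @param contigs Contig tibble (`contig_id`, `sequence`).
#' @param scoring Named list overriding `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @return A one-row tibble: `best_contig_id` (`NA` when no contig covers
#'   the junction), `concordance_percent`, `junction_covered`,
#'   `matched_strand`, `window_span_start`, `window_span_end` (0-based
#'   half-open on the window), `contig_break_pos` (0-based position, on the
#'   matched orientation of the best contig, of the first base downstream of
#'   the junction), and `alignment_score`.
#' @export
compute_concordance <- function(window, contigs,
                                scoring = list()) {
  sc <- utils::modifyList(list(match = 1, mismatch = -2,
                               gap_open = 3, gap_extend = 1), scoring)
  w <- if (is.data.frame(window)) window$window[1] else window$window
  bp <- if (is.data.frame(window)) window$breakpoint_offset[1] else window$breakpoint_offset
  if (nchar(w) < 16L) abort("junction window shorter than 16 nt is unscoreable")
  if (nrow(contigs) == 0L) abort("empty contig list")

  empty <- tibble(best_contig_id = NA_character_, concordance_percent = 0,
                  junction_covered = FALSE, matched_strand = NA_character_,
                  window_span_start = NA_integer_, window_span_end = NA_integer_,
                  contig_span_start = NA_integer_, contig_span_end = NA_integer_,
                  contig_break_pos = NA_integer_, alignment_score = 0)

  best <- NULL
  ord <- order(contigs$contig_id)
  for (k in ord) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") contigs$sequence[k] else revcomp(contigs$sequence[k])
      aln <- .gotoh_local(w, seq, sc$match, sc$mismatch, sc$gap_open, sc$gap_extend)
      if (aln$score <= 0) next
      covered <- aln$w_start <= bp - 1L && aln$w_end >= bp + 1L
      if (!covered) next
      conc <- 100 * aln$identities / nchar(w)
      if (is.null(best) || conc > best$concordance_percent + 1e-12) {
        hit <- match(bp, aln$step_window_index)
        best <- tibble(best_contig_id = contigs$contig_id[k],
                       concordance_percent = conc,
                       junction_covered = TRUE,
                       matched_strand = strand,
                       window_span_start = aln$w_start,
                       window_span_end = aln$w_end,
                       contig_span_start = aln$c_start,
                       contig_span_end = aln$c_end,
                       contig_break_pos = aln$step_contig_pos[hit],
                       alignment_score = aln$score)
      }
    }
  }
  best %||% empty
}

#' Validate fusion candidates against de novo assembled contigs
#'
#' Runs [make_junction_window()] and [compute_concordance()] for every
#' candidate and flags as validated those whose best covering contig reaches
#' the concordance threshold (default: at least 25 percent). A single contig
#' may validate several candidates (multi-fusion contigs, e.g. a triple
#' fusion assembled into one transcript, are legal).
#'
#' @param candidates Candidate tibble (typically the `kept` rows of
#'   [filter_candidates()], after [classify_fusions()]).
#' @param contigs Contig tibble from [read_fasta()].
#' @param concordance_threshold Minimum concordance percent, default 25.
#' @param inclusive Comparator for the threshold: `TRUE` (default) keeps
#'   candidates at exactly the threshold (`>=`), `FALSE` requires `>`.
#' @param max_arm Passed to [make_junction_window()].
#' @param scoring Passed to [compute_concordance()].
#' @return `candidates` with the [compute_concordance()] columns and a
#'   logical `validated` column bound on.
#' @export
validate_fusions <- function(candidates, contigs, concordance_threshold = 25,
                             inclusive = TRUE, max_arm = 250, scoring = list()) {
  stopifnot_scalar_number(concordance_threshold, "concordance_threshold", 0, 100)
  if (nrow(candidates) == 0L) {
    res <- candidates
    res$best_contig_id <- character(0)
    res$concordance_percent <- numeric(0)
    res$junction_covered <- logical(0)
    res$matched_strand <- character(0)
    res$window_span_start <- integer(0)
    res$window_span_end <- integer(0)
    res$contig_span_start <- integer(0)
    res$contig_span_end <- integer(0)
    res$contig_break_pos <- integer(0)
    res$alignment_score <- numeric(0)
    res$breakpoint_offset <- integer(0)
    res$validated <- logical(0)
    return(res)
  }
  windows <- make_junction_window(candidates$junction_sequence, max_arm = max_arm)
  conc <- purrr::map(seq_len(nrow(candidates)),
                     ~ compute_concordance(windows[.x, ], contigs, scoring = scoring)) |>
    bind_rows()
  res <- bind_cols(candidates, conc)
  res$breakpoint_offset <- windows$breakpoint_offset
  res$validated <- res$junction_covered &
    if (inclusive) res$concordance_percent >= concordance_threshold
    else res$concordance_percent > concordance_threshold
  res
}
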