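#' Translate nucleotide sequence under the standard genetic code
#'
#' Vectorized translation. Codons containing any character outside A/C/G/T
#' (e.g. N) translate to `"X"`; trailing partial codons are dropped. Stop
#' codons render as `"*"` unless `to_stop = TRUE`, in which case translation
#' halts before the first stop.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param frame Offset 0, 1 or 2: translation starts at `frame + 1`.
#' @param to_stop Stop at the first stop codon (default `FALSE`).
#' @return Character vector of amino-acid sequences.
#' @export
translate_dna <- function(sequence, frame = 0, to_stop = FALSE) {
  if (!frame %in% 0:2) abort("frame must be 0, 1 or 2")
  code <- CODON_TABLE
  vapply(sequence, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- toupper(s)
    n <- nchar(s) - frame
    if (n < 3L) return("")
    n_cod <- n %/% 3L
    starts <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    if (to_stop) {
      stop_at <- match("*", aa)
      if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# standard genetic code, keyed by codon, stops as "*"
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

#' Find open reading frames in an assembled transcript
#'
#' Enumerates ORFs in all six frames (three frames on each strand): every
#' ATG paired with its first downstream in-frame stop codon, or with the
#' transcript end when no stop follows (reported with `complete = FALSE`;
#' assembly truncation is common). Coordinates are 0-based half-open on the
#' transcript's forward strand; `frame` is the offset on the ORF's own
#' strand. The stop codon is included in `[start, end)` but not in the
#' protein.
#'
#' @param transcript One-row tibble with `contig_id` and `sequence`, or a
#'   plain nucleotide string.
#' @param min_aa Minimum protein length in residues, default 30.
#' @return Tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `protein`, `complete`, sorted by protein length (descending),
#'   then `start`, then strand.
#' @export
find_orfs <- function(transcript, min_aa = 30) {
  if (is.character(transcript)) {
    transcript <- tibble(contig_id = "contig", sequence = transcript)
  }
  seq <- toupper(transcript$sequence[1])
  id <- transcript$contig_id[1]
  L <- nchar(seq)
  out <- list()
  if (L >= 3L) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (f in 0:2) {
        n_cod <- (L - f) %/% 3L
        if (n_cod < 1L) next
        starts_nt <- f + 1L + 3L * (seq_len(n_cod) - 1L)
        codons <- substring(s, starts_nt, starts_nt + 2L)
        is_start <- codons == "ATG"
        is_stop <- codons %in% c("TAA", "TAG", "TGA")
        stop_idx <- which(is_stop)
        for (a in which(is_start)) {
          t <- stop_idx[stop_idx >= a]
          complete <- length(t) > 0L
          t <- if (complete) t[1] else n_cod + 1L  # exclusive codon bound
          prot_cod <- if (complete) (t - a) else (n_cod - a + 1L)
          if (prot_cod < min_aa || prot_cod == 0L) next
          nt_start <- f + 3L * (a - 1L)                    # 0-based on s
          nt_end <- f + 3L * (if (complete) t else n_cod)  # includes stop if any
          protein <- paste(CODON_TABLE[codons[a:(a + prot_cod - 1L)]] |>
                             (\(x) { x[is.na(x)] <- "X"; x })(),
                           collapse = "")
          if (strand == "+") {
            iv <- c(nt_start, nt_end)
          } else {
            iv <- c(L - nt_end, L - nt_start)
          }
          out[[length(out) + 1L]] <- tibble(
            contig_id = id, start = iv[1], end = iv[2], strand = strand,
            frame = f, protein = protein, complete = complete)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(contig_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0), frame = integer(0),
                  protein = character(0), complete = logical(0)))
  }
  bind_rows(out) |>
    arrange(desc(nchar(.data$protein)), .data$start, .data$strand)
}

#' Characterize fusion proteins from validated candidates
#'
#' For every validated candidate, locates the breakpoint inside the best
#' matching contig (using the alignment from [validate_fusions()]), selects
#' the longest ORF spanning that position (no minimum length: short novel
#' tails are exactly the neoantigen payload), and classifies the junction:
#'
#' * `IN_FRAME` - the first `k` residues translated past the junction occur
#'   verbatim in the downstream partner's reference protein (k-mer
#'   membership rather than annotation-phase arithmetic, since assembled
#'   contigs have unknown splice structure);
#' * `OUT_OF_FRAME` - otherwise; `novel_tail` is the translation from the
#'   junction to the first stop (stop excluded). When the ORF runs off the
#'   contig without a stop the tail is censored (`tail_censored = TRUE`);
#' * `NO_ORF_AT_JUNCTION` - no ORF spans the breakpoint.
#'
#' `novel_start_flag` is set when the ORF begins before any `k`-mer match to
#' the upstream partner's reference protein; `novel_end_flag` when the ORF's
#' C-terminus is not found in the downstream partner (always true for
#' `OUT_OF_FRAME`). An `anomaly` note flags junction alignments with
#' internal gaps of `>= 20` nt (unusual splicing, e.g. intron retention);
#' full splice-graph analysis is out of scope. `transcript_direction` is the
#' chosen ORF's strand relative to the junction window orientation (`"+"`
#' means the ORF reads left arm into right arm).
#'
#' @param validated Output rows of [validate_fusions()] (only rows with
#'   `validated == TRUE` are characterized; others pass through with `NA`s).
#' @param contigs Contig tibble.
#' @param annotation Annotation tibble carrying `protein_sequence` for both
#'   partner genes (see [add_annotation_sequences()]). A missing downstream
#'   reference protein is an error.
#' @param k In-frame test k-mer length in residues, default 8.
#' @return One row per input candidate: `cluster_id`, `frame_class`,
#'   `junction_aa_index` (0-based index in the ORF protein of the first
#'   residue encoded past the breakpoint), `novel_tail`, `novel_start_flag`,
#'   `novel_end_flag`, `tail_censored`, `transcript_direction`,
#'   `orf_protein`, `orf_start`, `orf_end`, `anomaly`.
#' @export
characterize_fusions <- function(validated, contigs, annotation, k = 8) {
  seq_by_id <- stats::setNames(contigs$sequence, contigs$contig_id)
  prot_by_gene <- stats::setNames(annotation$protein_sequence, annotation$gene_id)
  empty_row <- function(id, class = NA_character_) {
    tibble(cluster_id = id, frame_class = class,
           junction_aa_index = NA_integer_, novel_tail = NA_character_,
           novel_start_flag = NA, novel_end_flag = NA, tail_censored = NA,
           transcript_direction = NA_character_, orf_protein = NA_character_,
           orf_start = NA_integer_, orf_end = NA_integer_,
           anomaly = NA_character_)
  }
  rows <- purrr::map(seq_len(nrow(validated)), function(i) {
    cand <- validated[i, ]
    if (!isTRUE(cand$validated)) return(empty_row(cand$cluster_id))
    prot2 <- prot_by_gene[[cand$gene2_id]]
    if (is.null(prot2) || is.na(prot2)) {
      abort(paste0("no reference protein for downstream gene ", cand$gene2_id))
    }
    prot1 <- prot_by_gene[[cand$gene1_id]]
    contig_seq <- seq_by_id[[cand$best_contig_id]]
    if (is.null(contig_seq)) abort(paste0("contig missing: ", cand$best_contig_id))
    oriented <- if (cand$matched_strand == "-") revcomp(contig_seq) else contig_seq
    L <- nchar(oriented)
    jpos <- cand$contig_break_pos  # first downstream base, 0-based, oriented

    orfs <- find_orfs(tibble(contig_id = cand$best_contig_id,
                             sequence = oriented), min_aa = 1)
    spanning <- orfs[orfs$start <= jpos - 1L & orfs$end >= jpos + 1L, ]
    anomaly <- NA_character_
    gap_nt <- abs((cand$window_span_end - cand$window_span_start) -
                    (cand$contig_span_end - cand$contig_span_start))
    if (isTRUE(gap_nt >= 20)) {
      anomaly <- sprintf("internal alignment gap of %d nt at the junction (unusual splicing?)",
                         gap_nt)
    }
    if (nrow(spanning) == 0L) {
      out <- empty_row(cand$cluster_id, "NO_ORF_AT_JUNCTION")
      out$anomaly <- anomaly
      return(out)
    }
    orf <- spanning |>
      arrange(desc(nchar(.data$protein)), .data$strand, .data$start) |>
      dplyr::slice(1)
    protein <- orf$protein
    # junction offset in the ORF's reading direction
    if (orf$strand == "+") {
      aa_idx <- (jpos - orf$start) %/% 3L
    } else {
      aa_idx <- ((L - jpos) - (L - orf$end)) %/% 3L
    }
    n_aa <- nchar(protein)
    down <- substring(protein, aa_idx + 1L, min(aa_idx + k, n_aa))
    in_frame <- nchar(down) > 0L && !is.na(prot2) &&
      grepl(down, prot2, fixed = TRUE)
    # novel start: does the protein begin before any k-mer hit to gene1?
    first_hit <- NA_integer_
    if (!is.null(prot1) && !is.na(prot1) && n_aa >= k) {
      for (p in seq_len(n_aa - k + 1L)) {
        if (grepl(substring(protein, p, p + k - 1L), prot1, fixed = TRUE)) {
          first_hit <- p
          break
        }
      }
    }
    novel_start <- is.na(first_hit) || first_hit > 1L
    tail_censored <- !orf$complete
    if (in_frame) {
      cterm <- substring(protein, max(1L, n_aa - k + 1L), n_aa)
      novel_end <- !grepl(cterm, prot2, fixed = TRUE)
      tail <- ""
    } else {
      tail <- substring(protein, aa_idx + 1L)
      novel_end <- TRUE
      if (nchar(tail) == 0L) {
        # junction falls on the stop codon itself: nothing is encoded past it
        out <- empty_row(cand$cluster_id, "NO_ORF_AT_JUNCTION")
        out$anomaly <- anomaly
        return(out)
      }
    }
    tibble(cluster_id = cand$cluster_id,
           frame_class = if (in_frame) "IN_FRAME" else "OUT_OF_FRAME",
           junction_aa_index = as.integer(aa_idx),
           novel_tail = tail,
           novel_start_flag = novel_start, novel_end_flag = novel_end,
           tail_censored = tail_censored,
           transcript_direction = orf$strand,
           orf_protein = protein,
           orf_start = as.integer(orf$start), orf_end = as.integer(orf$end),
           anomaly = anomaly)
  })
  out <- bind_rows(rows)
  out$frame_class <- factor(out$frame_class,
                            levels = c("IN_FRAME", "OUT_OF_FRAME",
                                       "NO_ORF_AT_JUNCTION"))
  out
}
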