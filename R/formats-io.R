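#' Read a deFuse-style fusion candidate table
#'
#' Parses the tab-separated fusion candidate output of a deFuse-like caller
#' into a tidy candidate table. Coordinates are kept 1-based as in the file.
#' The junction sequence (`splitr_sequence`) must contain exactly one `"|"`
#' breakpoint marker separating the two arms.
#'
#' Rows violating a record-level invariant (marker count, empty arm,
#' probability outside \[0,1\], negative span count, missing required field)
#' are rejected: they are reported in the `"problems"` attribute (one row per
#' rejected record, with its `cluster_id` and reason) and a warning is
#' emitted, so that `nrow(result) + nrow(problems)` always equals the number
#' of data rows in the file.
#'
#' @param path Path to a TSV file with (at least) the columns `cluster_id`,
#'   `splitr_sequence`, `gene1`, `gene2`, `gene_name1`, `gene_name2`,
#'   `gene_chromosome1`, `gene_chromosome2`, `gene_strand1`, `gene_strand2`,
#'   `genomic_break_pos1`, `genomic_break_pos2`, `span_count`, `splitr_count`,
#'   `probability`, `adjacent`, `read_through`. Extra columns are ignored.
#' @return A tibble with one row per accepted candidate and columns
#'   `cluster_id`, `gene1_id`, `gene2_id`, `gene1_name`, `gene2_name`,
#'   `chrom1`, `chrom2`, `strand1`, `strand2`, `genomic_break_pos1`,
#'   `genomic_break_pos2`, `junction_sequence`, `span_count`, `split_count`,
#'   `probability`, `adjacent_flag`, `read_through_flag`.
#' @seealso [write_defuse_table()], [validate_fusions()]
#' @export
read_defuse_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("cluster_id", "splitr_sequence", "gene1", "gene2",
                "gene_name1", "gene_name2", "gene_chromosome1",
                "gene_chromosome2", "gene_strand1", "gene_strand2",
                "genomic_break_pos1", "genomic_break_pos2",
                "span_count", "splitr_count", "probability",
                "adjacent", "read_through")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("deFuse table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }

  parse_flag <- function(x) toupper(x) %in% c("Y", "TRUE", "1")
  out <- tibble(
    cluster_id = raw$cluster_id,
    gene1_id = raw$gene1, gene2_id = raw$gene2,
    gene1_name = raw$gene_name1, gene2_name = raw$gene_name2,
    chrom1 = raw$gene_chromosome1, chrom2 = raw$gene_chromosome2,
    strand1 = raw$gene_strand1, strand2 = raw$gene_strand2,
    genomic_break_pos1 = suppressWarnings(as.integer(raw$genomic_break_pos1)),
    genomic_break_pos2 = suppressWarnings(as.integer(raw$genomic_break_pos2)),
    junction_sequence = toupper(raw$splitr_sequence),
    span_count = suppressWarnings(as.integer(raw$span_count)),
    split_count = suppressWarnings(as.integer(raw$splitr_count)),
    probability = suppressWarnings(as.numeric(raw$probability)),
    adjacent_flag = parse_flag(raw$adjacent),
    read_through_flag = parse_flag(raw$read_through)
  )

  n_marker <- stringr::str_count(out$junction_sequence, stringr::fixed("|"))
  arms <- stringr::str_split_fixed(out$junction_sequence, stringr::fixed("|"), 2)
  reason <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(out$cluster_id) | out$cluster_id == "", "missing cluster_id")
  reason <- flag(is.na(n_marker) | n_marker != 1L,
                 "junction sequence must contain exactly one '|'")
  reason <- flag(n_marker == 1L & (arms[, 1] == "" | arms[, 2] == ""),
                 "empty junction arm")
  reason <- flag(!is_dna(gsub("\\|", "", out$junction_sequence)),
                 "junction sequence has non-ACGTN characters")
  reason <- flag(is.na(out$probability) | out$probability < 0 | out$probability > 1,
                 "probability outside [0, 1]")
  reason <- flag(is.na(out$span_count) | out$span_count < 0L, "invalid span_count")
  reason <- flag(is.na(out$split_count) | out$split_count < 0L, "invalid split_count")

  bad <- !is.na(reason)
  problems <- tibble(row = which(bad), cluster_id = out$cluster_id[bad],
                     reason = reason[bad])
  if (nrow(problems) > 0L) {
    warn(sprintf("read_defuse_table: rejected %d of %d records (see attr(x, \"problems\"))",
                 nrow(problems), nrow(out)))
  }
  out <- out[!bad, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Write a candidate table in deFuse dialect
#'
#' Inverse of [read_defuse_table()]: serializes a candidate tibble to the
#' TSV dialect the reader consumes, so `read(write(x))` round-trips.
#'
#' @param candidates Candidate tibble as returned by [read_defuse_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_defuse_table <- function(candidates, path) {
  out <- tibble(
    cluster_id = candidates$cluster_id,
    splitr_sequence = candidates$junction_sequence,
    gene1 = candidates$gene1_id, gene2 = candidates$gene2_id,
    gene_name1 = candidates$gene1_name, gene_name2 = candidates$gene2_name,
    gene_chromosome1 = candidates$chrom1, gene_chromosome2 = candidates$chrom2,
    gene_strand1 = candidates$strand1, gene_strand2 = candidates$strand2,
    genomic_break_pos1 = candidates$genomic_break_pos1,
    genomic_break_pos2 = candidates$genomic_break_pos2,
    span_count = candidates$span_count, splitr_count = candidates$split_count,
    probability = candidates$probability,
    adjacent = ifelse(candidates$adjacent_flag, "Y", "N"),
    read_through = ifelse(candidates$read_through_flag, "Y", "N")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read assembled transcripts from FASTA
#'
#' Reads a Trinity-style contig FASTA into a two-column tibble. The contig id
#' is the first whitespace-delimited token of the header; sequences are
#' uppercased. Duplicate ids and empty records are errors.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `contig_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate contig id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) abort("empty FASTA record")
  tibble(contig_id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `contig_id` and `sequence` (nucleotide).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$contig_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a per-base coverage track from a BED-like file
#'
#' Accepts rows `chrom start end depth` (0-based half-open, constant-depth
#' runs) and expands them to one row per base. Overlapping runs that disagree
#' on depth are an error; agreeing duplicates are collapsed.
#'
#' @param path BED/bedGraph-like file (no header).
#' @return A tibble with columns `chrom`, `pos` (0-based), `depth`.
#' @seealso [coverage_window()], [tic_read_ratio()]
#' @export
read_coverage_bed <- function(path) {
  runs <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                          show_col_types = FALSE,
                          col_types = readr::cols("c", "i", "i", "d"))
  if (any(is.na(runs$start) | is.na(runs$end) | is.na(runs$depth)))
    abort("malformed coverage row (non-numeric start/end/depth)")
  if (any(runs$end <= runs$start)) abort("coverage run with end <= start")
  if (any(runs$depth < 0)) abort("negative depth")
  track <- runs |>
    mutate(.run = row_number()) |>
    tidyr::uncount(.data$end - .data$start, .id = ".off") |>
    mutate(pos = .data$start + .data$.off - 1L) |>
    select("chrom", "pos", "depth") |>
    distinct()
  clash <- track |> dplyr::count(.data$chrom, .data$pos) |> filter(.data$n > 1L)
  if (nrow(clash) > 0L) {
    abort(sprintf("contradictory depths at %d position(s), first at %s:%d",
                  nrow(clash), clash$chrom[1], clash$pos[1]))
  }
  arrange(track, .data$chrom, .data$pos)
}

#' Extract a per-base depth vector over an interval
#'
#' @param track Coverage tibble from [read_coverage_bed()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Integer-ish numeric vector of length `end - start`; positions
#'   absent from the track have depth 0.
#' @export
coverage_window <- function(track, chrom, start, end) {
  if (end <= start) abort("end must be > start")
  sub <- track[track$chrom == chrom & track$pos >= start & track$pos < end, ]
  depth <- rep(0, end - start)
  depth[sub$pos - start + 1L] <- sub$depth
  depth
}

#' Read an MHC-binding prediction table
#'
#' Parses a simplified long-format binding table (`peptide`, `allele`,
#' `rank`), the dialect written by [write_binding_table()] and the format the
#' pipeline expects back from an external class I binding predictor. Column
#' name synonyms `hla_allele` (for allele) and `rank_percent` / `%rank` (for
#' rank) are accepted. Rows with a non-numeric rank or a peptide outside
#' 8-11 residues are rejected into the `"problems"` attribute with a warning.
#'
#' @param path TSV file path.
#' @return A tibble with columns `peptide`, `hla_allele`, `rank_percent`.
#' @export
read_binding_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(raw) <- tolower(names(raw))
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (length(hit) == 0L)
      abort(paste0("binding table is missing a column named one of: ",
                   paste(cands, collapse = ", ")))
    raw[[hit[1]]]
  }
  out <- tibble(
    peptide = toupper(pick("peptide")),
    hla_allele = pick(c("allele", "hla_allele", "hla")),
    rank_percent = suppressWarnings(as.numeric(pick(c("rank", "rank_percent", "%rank"))))
  )
  reason <- rep(NA_character_, nrow(out))
  reason <- ifelse(is.na(out$rank_percent) | out$rank_percent < 0,
                   "non-numeric or negative rank", reason)
  reason <- ifelse(is.na(reason) & !nchar(out$peptide) %in% 8:11,
                   "peptide length outside 8-11", reason)
  bad <- !is.na(reason)
  problems <- tibble(row = which(bad), peptide = out$peptide[bad], reason = reason[bad])
  if (nrow(problems) > 0L) {
    warn(sprintf("read_binding_table: rejected %d of %d records", nrow(problems), nrow(out)))
  }
  out <- out[!bad, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Write an MHC-binding prediction table
#'
#' @param records Tibble with columns `peptide`, `hla_allele`, `rank_percent`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binding_table <- function(records, path) {
  readr::write_tsv(
    tibble(peptide = records$peptide, allele = records$hla_allele,
           rank = records$rank_percent),
    path)
  invisible(path)
}

#' Write candidate neoepitope peptides to FASTA
#'
#' Emits one record per peptide, in input order, for submission to an
#' external MHC class I predictor. Peptides must be 8-11 residues over the
#' 20 standard amino acids.
#'
#' @param peptides Character vector of peptides, or a tibble with columns
#'   `peptide_id` and `peptide`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  if (is.data.frame(peptides)) {
    ids <- peptides$peptide_id
    pep <- peptides$peptide
  } else {
    pep <- as.character(peptides)
    ids <- if (!is.null(names(pep)) && all(nzchar(names(pep)))) names(pep)
           else sprintf("pep%04d", seq_along(pep))
  }
  if (length(pep) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (!all(nchar(pep) %in% 8:11)) abort("peptides must be 8-11 residues long")
  ok <- vapply(strsplit(pep, ""), function(a) all(a %in% AA_STANDARD), logical(1))
  if (!all(ok)) {
    abort(paste0("peptide with non-standard residue: ", pep[!ok][1]))
  }
  set <- Biostrings::AAStringSet(pep)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read peptides back from FASTA
#'
#' @param path FASTA file path.
#' @return Tibble with columns `peptide_id`, `peptide`.
#' @export
read_peptide_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(peptide_id = sub("\\s.*$", "", names(set)),
         peptide = unname(as.character(set)))
}
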