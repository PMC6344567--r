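#' Gene annotation tables
#'
#' A gene annotation is a tibble with one row per gene and columns:
#' `gene_id`, `gene_name`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end`
#' (0-based half-open gene body on the chromosome), `exons` (list column of
#' tibbles with 0-based half-open `start`, `end`, sorted, non-overlapping),
#' and optionally `cds_sequence` / `protein_sequence` (filled by
#' [add_annotation_sequences()] or by the synthetic generator).
#'
#' @param gene_id,gene_name,chrom,strand,start,end,exons,cds_sequence,protein_sequence
#'   Column values; `exons` defaults to one exon spanning the gene body.
#' @return A validated annotation tibble.
#' @export
gene_annotation <- function(gene_id, gene_name = gene_id, chrom, strand,
                            start, end, exons = NULL,
                            cds_sequence = NA_character_,
                            protein_sequence = NA_character_) {
  if (is.null(exons)) {
    exons <- purrr::map2(start, end, ~ tibble(start = .x, end = .y))
  }
  ann <- tibble(gene_id = as.character(gene_id),
                gene_name = as.character(gene_name),
                chrom = as.character(chrom), strand = as.character(strand),
                start = as.integer(start), end = as.integer(end),
                exons = exons,
                cds_sequence = cds_sequence,
                protein_sequence = protein_sequence)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (any(ann$start >= ann$end)) abort("annotation with start >= end")
  if (!all(ann$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene_id in annotation")
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exons[[i]]
    if (nrow(ex) == 0L) abort("gene with no exons")
    if (any(ex$start >= ex$end)) abort("exon with start >= end")
    if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1L)
      abort("exons must be sorted")
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      abort("overlapping exons")
    if (ex$start[1] < ann$start[i] || ex$end[nrow(ex)] > ann$end[i])
      abort("exon outside gene body")
  }
  ann
}

#' Read a GTF-like gene annotation
#'
#' Loads gene models from a GTF file (via rtracklayer) into the annotation
#' tibble layout used throughout the package. Exon features are grouped by
#' `gene_id`; the gene body is the exon span. External GTF coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention. If a genome FASTA is supplied, spliced CDS and protein
#' sequences are attached with [add_annotation_sequences()].
#'
#' @param path GTF file path.
#' @param genome_path Optional genome FASTA path.
#' @return An annotation tibble (see [gene_annotation()]).
#' @export
read_gene_annotation <- function(path, genome_path = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- as_tibble(as.data.frame(gr))
  df$gene_name <- if ("gene_name" %in% names(df)) df$gene_name else df$gene_id
  ann <- df |>
    mutate(start0 = .data$start - 1L, end0 = .data$end) |>
    group_by(.data$gene_id) |>
    summarise(gene_name = dplyr::first(.data$gene_name),
              chrom = as.character(dplyr::first(.data$seqnames)),
              strand = as.character(dplyr::first(.data$strand)),
              start = min(.data$start0), end = max(.data$end0),
              # plain names here: tibble() would re-bind the .data pronoun
              exons = list(tibble(start = sort(start0),
                                  end = end0[order(start0)])),
              .groups = "drop")
  ann$cds_sequence <- NA_character_
  ann$protein_sequence <- NA_character_
  ann <- validate_annotation(ann)
  if (!is.null(genome_path)) {
    genome <- read_fasta(genome_path)
    ann <- add_annotation_sequences(ann, genome)
  }
  ann
}

#' Write a gene annotation as GTF
#'
#' @param ann Annotation tibble.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("writing GTF requires the rtracklayer package")
  rows <- purrr::pmap(ann, function(gene_id, gene_name, chrom, strand, start,
                                    end, exons, ...) {
    tibble(seqnames = chrom, start = exons$start + 1L, end = exons$end,
           strand = strand, type = "exon", gene_id = gene_id,
           gene_name = gene_name)
  }) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  gr$type <- rows$type
  gr$gene_id <- rows$gene_id
  gr$gene_name <- rows$gene_name
  gr$source <- "fusionneo"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Attach spliced CDS and protein sequences to an annotation
#'
#' Splices each gene's exons out of the genome (reverse-complementing minus
#' strand genes) and translates the result. Assumes the exon chain is the
#' CDS, the layout produced by [make_toy_annotation()].
#'
#' @param ann Annotation tibble.
#' @param genome Tibble of chromosome sequences (`contig_id`, `sequence`),
#'   e.g. from [read_fasta()].
#' @return `ann` with `cds_sequence` and `protein_sequence` filled.
#' @export
add_annotation_sequences <- function(ann, genome) {
  chrom_seq <- stats::setNames(genome$sequence, genome$contig_id)
  ann$cds_sequence <- vapply(seq_len(nrow(ann)), function(i) {
    cs <- chrom_seq[[ann$chrom[i]]]
    if (is.null(cs)) abort(paste0("chromosome missing from genome: ", ann$chrom[i]))
    ex <- ann$exons[[i]]
    spliced <- paste(substring(cs, ex$start + 1L, ex$end), collapse = "")
    if (ann$strand[i] == "-") revcomp(spliced) else spliced
  }, character(1))
  ann$protein_sequence <- translate_dna(ann$cds_sequence, to_stop = TRUE)
  ann
}
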