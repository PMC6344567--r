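# small builders shared by tests

make_candidate <- function(cluster_id = "C1", junction = NULL,
                           gene1 = "G001", gene2 = "G002",
                           gene1_name = "GENE001", gene2_name = "GENE002",
                           chrom1 = "chr1", chrom2 = "chr2",
                           span_count = 10L, probability = 0.9,
                           adjacent = FALSE, read_through = FALSE) {
  if (is.null(junction)) {
    junction <- paste0(rand_dna(60), "|", rand_dna(60))
  }
  tibble::tibble(
    cluster_id = cluster_id, gene1_id = gene1, gene2_id = gene2,
    gene1_name = gene1_name, gene2_name = gene2_name,
    chrom1 = chrom1, chrom2 = chrom2, strand1 = "+", strand2 = "+",
    genomic_break_pos1 = 1000L, genomic_break_pos2 = 2000L,
    junction_sequence = junction, span_count = as.integer(span_count),
    split_count = 5L, probability = probability,
    adjacent_flag = adjacent, read_through_flag = read_through)
}

aa_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
}

make_report <- function(protein, j, frame = "IN_FRAME", tail = "") {
  tibble::tibble(cluster_id = "C1", frame_class = frame,
                 junction_aa_index = as.integer(j), novel_tail = tail,
                 novel_start_flag = FALSE, novel_end_flag = frame != "IN_FRAME",
                 tail_censored = FALSE, transcript_direction = "+",
                 orf_protein = protein, orf_start = 0L,
                 orf_end = 3L * (nchar(protein) + 1L), anomaly = NA_character_)
}

fake_validated <- function(spans, classes, validated = TRUE) {
  tibble::tibble(cluster_id = sprintf("F%02d", seq_along(spans)),
                 span_count = as.integer(spans),
                 fusion_class = factor(classes,
                                       levels = c("INTER", "INTRA", "TIC")),
                 validated = rep_len(validated, length(spans)))
}

# three genes on chr1 (adjacent pair G101/G102, G103 further), one on chr2
toy_annotation_small <- function() {
  gene_annotation(
    gene_id = c("G101", "G102", "G103", "G201"),
    gene_name = c("GENEA", "GENEB", "GENEC", "GENED"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "-", "+", "+"),
    start = c(100L, 1500L, 9000L, 50L),
    end = c(1000L, 2500L, 9900L, 800L))
}
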