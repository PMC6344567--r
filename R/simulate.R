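# Synthetic fixture generation with planted ground truth. Everything here is
# a pure function of (seed, arguments): fixtures are rebuilt at test time,
# never stored.

.push_seed <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", .GlobalEnv, inherits = FALSE)
  }
  set.seed(seed)
  old
}

.pop_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random coding sequence: ATG + codons free of in-frame stops + stop
random_cds <- function(n_codons) {
  pool <- names(CODON_TABLE)[CODON_TABLE != "*" & names(CODON_TABLE) != "ATG"]
  body <- sample(pool, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

#' Generate a toy genome and gene annotation
#'
#' Builds a deterministic synthetic genome: `n_genes` multi-exon
#' protein-coding genes laid out over `n_chroms` chromosomes with random
#' intergenic spacers and introns. Each gene's spliced exon chain is a
#' complete CDS (ATG start, no internal stop, terminal stop), on a random
#' strand. The layout guarantees material for fusion planting of every
#' class: chromosomes carry enough genes for adjacent pairs (TIC),
#' same-chromosome non-adjacent pairs (INTRA) and cross-chromosome pairs
#' (INTER).
#'
#' @param seed Integer seed; same seed, same bytes.
#' @param n_genes Number of genes (>= 4), default 12.
#' @param n_chroms Number of chromosomes, default 3.
#' @param cds_codons Range of CDS lengths in codons, default 60-160.
#' @param n_exons Range of exons per gene, default 2-4.
#' @return List with `genome` (tibble `contig_id`, `sequence`) and
#'   `annotation` (tibble, see [gene_annotation()], with `cds_sequence` and
#'   `protein_sequence` filled).
#' @export
make_toy_annotation <- function(seed, n_genes = 12, n_chroms = 3,
                                cds_codons = c(60, 160), n_exons = c(2, 4)) {
  if (n_genes < 4) abort("n_genes must be >= 4")
  old <- .push_seed(seed)
  on.exit(.pop_seed(old))

  chrom_of <- sort(rep_len(paste0("chr", seq_len(n_chroms)), n_genes))
  genes <- list()
  chrom_seq <- stats::setNames(rep("", n_chroms), paste0("chr", seq_len(n_chroms)))
  for (g in seq_len(n_genes)) {
    chrom <- chrom_of[g]
    n_cod <- sample(cds_codons[1]:cds_codons[2], 1L)
    cds <- random_cds(n_cod)
    m <- sample(n_exons[1]:n_exons[2], 1L)
    cuts <- sort(sample(seq_len(nchar(cds) - 1L), m - 1L))
    bounds <- c(0L, cuts, nchar(cds))
    exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
    introns <- replicate(m - 1L, random_dna(sample(60:200, 1L)))
    block <- paste0(paste0(exon_seqs[-m], introns, collapse = ""), exon_seqs[m])
    rel <- tibble(start = integer(m), end = integer(m))
    off <- 0L
    for (j in seq_len(m)) {
      rel$start[j] <- off
      rel$end[j] <- off + nchar(exon_seqs[j])
      off <- rel$end[j] + if (j < m) nchar(introns[j]) else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    block_len <- nchar(block)
    if (strand == "-") {
      block <- revcomp(block)
      rel <- tibble(start = rev(block_len - rel$end),
                    end = rev(block_len - rel$start))
    }
    gap <- random_dna(sample(200:500, 1L))
    base <- nchar(chrom_seq[[chrom]]) + nchar(gap)
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], gap, block)
    genes[[g]] <- tibble(
      gene_id = sprintf("G%03d", g), gene_name = sprintf("GENE%03d", g),
      chrom = chrom, strand = strand,
      start = base, end = base + block_len,
      exons = list(tibble(start = rel$start + base, end = rel$end + base)),
      cds_sequence = cds,
      protein_sequence = translate_dna(cds, to_stop = TRUE))
  }
  # terminal spacers so genes do not abut the chromosome end
  for (chrom in names(chrom_seq)) {
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], random_dna(sample(200:400, 1L)))
  }
  list(genome = tibble(contig_id = names(chrom_seq),
                       sequence = unname(unlist(chrom_seq))),
       annotation = validate_annotation(bind_rows(genes)))
}

# genomic coordinate (0-based) of the cds base at 0-based offset `off`
cds_offset_to_genomic <- function(ann_row, off) {
  ex <- ann_row$exons[[1]]
  widths <- ex$end - ex$start
  if (ann_row$strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), ]
    widths <- rev(widths)
  }
  cum <- cumsum(widths)
  j <- which(off < cum)[1]
  within <- off - if (j > 1) cum[j - 1] else 0L
  if (ann_row$strand == "+") ex$start[j] + within else ex$end[j] - 1L - within
}

default_fusion_spec <- function() {
  tibble(class = c("INTER", "INTER", "INTRA", "INTRA", "TIC", "TIC"),
         frame_class = c("IN_FRAME", "OUT_OF_FRAME", "IN_FRAME",
                         "OUT_OF_FRAME", "IN_FRAME", "OUT_OF_FRAME"),
         concordance_band = "high",
         span_count = c(12L, 25L, 8L, 30L, 15L, 20L))
}

band_mutation_rate <- function(band) {
  c(high = 0, medium = 0.1, low = 0.45, absent = NA_real_)[band]
}

mutate_sequence <- function(seq, rate, lo, hi) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  idx <- seq(max(1L, lo + 1L), min(length(chars), hi))
  hit <- idx[stats::runif(length(idx)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Plant fusions with known truth into a toy annotation
#'
#' Fabricates a deFuse-style candidate table, a matching contig FASTA and a
#' truth manifest. Each requested fusion joins two CDSs at codon boundaries
#' (for `IN_FRAME`) or with a one-base shift (for `OUT_OF_FRAME`, producing
#' a frameshifted novel tail guaranteed to reach a stop codon); gene pairs
#' are drawn to satisfy the requested class (INTER: different chromosomes;
#' INTRA: same chromosome with at least one gene between; TIC: adjacent
#' genes, flagged read-through). The emitted contig reproduces the fusion
#' transcript exactly (`concordance_band "high"`), with controlled point
#' mutations in the junction neighbourhood (`"medium"`, `"low"`; the
#' per-band rates 0, 0.1, 0.45 can be overridden with `mutation_rate`), or
#' not at all (`"absent"`). Decoy contigs, including a single-arm contig
#' that must never validate, are added.
#'
#' @param annotation Output of [make_toy_annotation()] (the `annotation`
#'   element).
#' @param fusion_spec Tibble with columns `class`, `frame_class`,
#'   `concordance_band`, `span_count` (and optionally `probability`);
#'   default: six fusions, two per class, both frames.
#' @param seed Integer seed.
#' @param mapped_paired_reads Sample read depth recorded in the manifest,
#'   default 6e7.
#' @param mutation_rate Optional scalar overriding every band's mutation
#'   rate (used for monotonicity sweeps).
#' @param arm_range Range of junction-arm lengths written to the candidate
#'   table, default 150-250 nt.
#' @return List with `candidates` (parsed candidate tibble, as from
#'   [read_defuse_table()]), `contigs` (tibble), `manifest` (tibble with
#'   per-fusion truths: `cluster_id`, `class`, `frame_class`, `novel_tail`,
#'   `concordance_band`, `span_count`, `expected_validated`, `contig_id`,
#'   gene ids and `probability`), and `sample` (list: `mapped_paired_reads`,
#'   `true_fusion_fraction`, `seed`).
#' @export
plant_fusions <- function(annotation, fusion_spec = default_fusion_spec(),
                          seed = 1, mapped_paired_reads = 6e7,
                          mutation_rate = NULL, arm_range = c(150, 250)) {
  old <- .push_seed(seed)
  on.exit(.pop_seed(old))

  ann <- annotation
  by_chrom <- split(seq_len(nrow(ann)), ann$chrom)
  adj_pairs <- list()
  intra_pairs <- list()
  for (idx in by_chrom) {
    ord <- idx[order(ann$start[idx])]
    if (length(ord) >= 2L) {
      for (j in seq_len(length(ord) - 1L))
        adj_pairs[[length(adj_pairs) + 1L]] <- c(ord[j], ord[j + 1L])
    }
    if (length(ord) >= 3L) {
      for (j in seq_len(length(ord) - 2L))
        for (l in (j + 2L):length(ord))
          intra_pairs[[length(intra_pairs) + 1L]] <- c(ord[j], ord[l])
    }
  }
  inter_pairs <- list()
  for (a in seq_len(nrow(ann) - 1L)) {
    for (b in (a + 1L):nrow(ann)) {
      if (ann$chrom[a] != ann$chrom[b])
        inter_pairs[[length(inter_pairs) + 1L]] <- c(a, b)
    }
  }
  pools <- list(INTER = sample(inter_pairs), INTRA = sample(intra_pairs),
                TIC = sample(adj_pairs))

  n <- nrow(fusion_spec)
  if (!"probability" %in% names(fusion_spec)) {
    fusion_spec$probability <- round(stats::runif(n, 0.55, 0.99), 3)
  }
  cand_rows <- list()
  contig_rows <- list()
  manifest_rows <- list()
  used <- character(0)
  for (i in seq_len(n)) {
    spec_i <- fusion_spec[i, ]
    pool <- pools[[spec_i$class]]
    pick <- NULL
    for (p in seq_along(pool)) {
      key <- paste(sort(pool[[p]]), collapse = "-")
      if (!key %in% used) {
        pick <- pool[[p]]
        used <- c(used, key)
        break
      }
    }
    if (is.null(pick)) {
      abort(paste0("fusion spec unsatisfiable: no unused ", spec_i$class,
                   " gene pair left in the annotation"))
    }
    g1 <- ann[pick[1], ]
    g2 <- ann[pick[2], ]
    cds1 <- g1$cds_sequence
    cds2 <- g2$cds_sequence
    k1 <- nchar(g1$protein_sequence)
    k2 <- nchar(g2$protein_sequence)
    if (k1 < 30 || k2 < 30) abort("toy proteins too short for fusion planting")
    in_frame <- spec_i$frame_class == "IN_FRAME"

    # Rejection-sample breakpoints/UTRs until the planted fusion ORF is
    # demonstrably the ORF the pipeline will select (the longest one
    # spanning the junction, unique at that length) and, for frameshifts,
    # the novel tail is at least 8 residues and does not accidentally match
    # the downstream reference protein. Deterministic given the seed.
    ok <- FALSE
    for (attempt in 1:50) {
      c1 <- sample((k1 - 25L):(k1 - 10L), 1L)  # long upstream arm
      # in frame: small c2 keeps the downstream remainder (and the ORF) long;
      # frameshift: c2 ranges widely so the tail start escapes any stop-dense
      # stretch of the shifted frame, whose stop landscape is fixed per gene
      c2 <- if (in_frame) sample(10:25, 1L) else sample(10:(k2 - 10L), 1L)
      shift <- if (in_frame) 0L else sample(1:2, 1L)
      utr5 <- gsub("ATG", "ACG", random_dna(sample(30:60, 1L)), fixed = TRUE)
      upstream <- substring(cds1, 1L, 3L * c1)
      downstream <- substring(cds2, 3L * c2 + shift + 1L, nchar(cds2))
      utr3 <- random_dna(150L)
      transcript <- paste0(utr5, upstream, downstream, utr3)
      atg <- nchar(utr5)                 # 0-based ORF start
      jt <- atg + 3L * c1                # 0-based first downstream base

      if (spec_i$frame_class == "OUT_OF_FRAME") {
        tail_aa <- translate_dna(substring(transcript, jt + 1L), to_stop = TRUE)
        trans_len <- nchar(transcript) - jt
        if (3L * (nchar(tail_aa) + 1L) > trans_len) {
          # no in-frame stop before the transcript end: plant one
          pad <- (3L - (trans_len %% 3L)) %% 3L
          transcript <- paste0(transcript, random_dna(pad), "TAA",
                               random_dna(30L))
          tail_aa <- translate_dna(substring(transcript, jt + 1L), to_stop = TRUE)
        }
        novel_tail <- tail_aa
        if (nchar(novel_tail) < 8L ||
            grepl(substring(novel_tail, 1L, 8L), g2$protein_sequence,
                  fixed = TRUE)) next
        orf_end <- jt + 3L * (nchar(novel_tail) + 1L)
      } else {
        novel_tail <- ""
        orf_end <- atg + 3L * (c1 + (k2 - c2) + 1L)
      }
      orfs <- find_orfs(tibble(contig_id = "t", sequence = transcript),
                        min_aa = 1)
      spanning <- orfs[orfs$start <= jt - 1L & orfs$end >= jt + 1L, ]
      if (nrow(spanning) == 0L) next
      top_len <- max(nchar(spanning$protein))
      top <- spanning[nchar(spanning$protein) == top_len, ]
      if (nrow(top) == 1L && top$strand == "+" && top$start == atg &&
          top$end == orf_end) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(paste0("could not construct an unambiguous fusion ORF for ",
                           "%s %s (%s-%s) in 50 attempts; change the seed"),
                    spec_i$class, spec_i$frame_class, g1$gene_id, g2$gene_id))
    }

    al <- sample(arm_range[1]:arm_range[2], 1L)
    ar <- sample(arm_range[1]:arm_range[2], 1L)
    left_arm <- substring(transcript, max(1L, jt - al + 1L), jt)
    right_arm <- substring(transcript, jt + 1L, min(nchar(transcript), jt + ar))

    band <- spec_i$concordance_band
    rate <- mutation_rate %||% unname(band_mutation_rate(band))
    contig_id <- NA_character_
    if (!identical(band, "absent")) {
      contig_id <- sprintf("contig_F%03d", i)
      cseq <- mutate_sequence(transcript, rate, jt - nchar(left_arm),
                              jt + nchar(right_arm))
      if (sample(c(TRUE, FALSE), 1L)) cseq <- revcomp(cseq)  # assembly strand arbitrary
      contig_rows[[length(contig_rows) + 1L]] <-
        tibble(contig_id = contig_id, sequence = cseq)
    }

    cand_rows[[length(cand_rows) + 1L]] <- tibble(
      cluster_id = sprintf("F%03d", i),
      gene1_id = g1$gene_id, gene2_id = g2$gene_id,
      gene1_name = g1$gene_name, gene2_name = g2$gene_name,
      chrom1 = g1$chrom, chrom2 = g2$chrom,
      strand1 = g1$strand, strand2 = g2$strand,
      genomic_break_pos1 = cds_offset_to_genomic(g1, 3L * c1 - 1L) + 1L,
      genomic_break_pos2 = cds_offset_to_genomic(g2, 3L * c2 + shift) + 1L,
      junction_sequence = paste0(left_arm, "|", right_arm),
      span_count = as.integer(spec_i$span_count),
      split_count = max(1L, as.integer(spec_i$span_count) %/% 2L),
      probability = spec_i$probability,
      adjacent_flag = spec_i$class == "TIC",
      read_through_flag = spec_i$class == "TIC")

    manifest_rows[[length(manifest_rows) + 1L]] <- tibble(
      cluster_id = sprintf("F%03d", i),
      class = spec_i$class, frame_class = spec_i$frame_class,
      novel_tail = novel_tail,
      concordance_band = band, span_count = as.integer(spec_i$span_count),
      expected_validated = if (identical(band, "absent")) FALSE
                           else if (rate == 0) TRUE else NA,
      contig_id = contig_id,
      gene1_id = g1$gene_id, gene2_id = g2$gene_id,
      junction_aa_index = c1,
      probability = spec_i$probability)
  }

  # decoys: two random contigs and one single-arm (left-arm-only) contig
  contig_rows[[length(contig_rows) + 1L]] <-
    tibble(contig_id = "decoy_random_1", sequence = random_dna(400L))
  contig_rows[[length(contig_rows) + 1L]] <-
    tibble(contig_id = "decoy_random_2", sequence = random_dna(350L))
  first_left <- sub("\\|.*$", "", cand_rows[[1]]$junction_sequence)
  contig_rows[[length(contig_rows) + 1L]] <-
    tibble(contig_id = "decoy_one_arm", sequence = first_left)

  candidates <- bind_rows(cand_rows)
  manifest <- bind_rows(manifest_rows)
  validated_truth <- manifest$expected_validated %in% TRUE &
    manifest$class %in% c("INTER", "INTRA")
  true_ff <- sum(manifest$span_count[validated_truth]) /
    (mapped_paired_reads / 1e7)
  list(candidates = candidates,
       contigs = bind_rows(contig_rows),
       manifest = manifest,
       sample = list(mapped_paired_reads = mapped_paired_reads,
                     true_fusion_fraction = true_ff, seed = seed))
}

#' Write a planted fixture to disk
#'
#' Serializes a [plant_fusions()] fixture in the external formats the
#' pipeline reads: deFuse-style TSV, contig FASTA, GTF annotation, genome
#' FASTA and a JSON truth manifest.
#'
#' @param fixture Output of [plant_fusions()].
#' @param toy Output of [make_toy_annotation()] (for genome + annotation).
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture <- function(fixture, toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    defuse = file.path(dir, "candidates.tsv"),
    contigs = file.path(dir, "contigs.fasta"),
    genome = file.path(dir, "genome.fasta"),
    gtf = file.path(dir, "annotation.gtf"),
    manifest = file.path(dir, "manifest.json"))
  write_defuse_table(fixture$candidates, paths$defuse)
  write_fasta(fixture$contigs, paths$contigs)
  write_fasta(toy$genome, paths$genome)
  write_gene_annotation(toy$annotation, paths$gtf)
  jsonlite::write_json(list(fusions = fixture$manifest, sample = fixture$sample),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Subsample paired sequencing records deterministically
#'
#' Keeps every `n`-th record pair (records 1, n+1, 2n+1, ...), preserving
#' mate pairing; the output has `ceiling(N / n)` pairs. Mate identifiers
#' (ignoring trailing `/1`, `/2`) must agree or the input is rejected as
#' unpaired.
#'
#' @param mate1,mate2 Tibbles (or data frames) of paired records with an
#'   `id` column, equal row counts.
#' @param n Keep every n-th pair, `n >= 1`.
#' @return List with subsampled `mate1` and `mate2`.
#' @export
subsample_paired_records <- function(mate1, mate2, n) {
  stopifnot_scalar_number(n, "n", 1)
  if (nrow(mate1) != nrow(mate2)) abort("unpaired input: mate files differ in length")
  strip <- function(x) sub("/[12]$", "", x)
  if (!identical(strip(mate1$id), strip(mate2$id))) {
    abort("unpaired input: mate ids do not match")
  }
  keep <- seq(1L, nrow(mate1), by = as.integer(n))
  list(mate1 = mate1[keep, , drop = FALSE], mate2 = mate2[keep, , drop = FALSE])
}

#' Generate a coverage fixture with a planted chimera proportion
#'
#' Emulates the exon/intron read-ratio measurement: the terminal 10 nt of a
#' shared exon get constant depth `depth` (total transcription), the first
#' 10 nt of the retained intron get per-base `Binomial(depth, p)` draws
#' (chimera-only reads), so the expected intron/exon ratio is `p`.
#'
#' @param seed Integer seed.
#' @param p Chimera proportion in `[0, 1]`.
#' @param depth Exon depth (> 0), default 500.
#' @param chrom Chromosome label, default `"chr4"`.
#' @param exon_end 0-based end of the shared exon; the exon window is
#'   `[exon_end - 10, exon_end)` and the intron window `[exon_end,
#'   exon_end + 10)`.
#' @param width Window width, default 10.
#' @return List: `track` (coverage tibble as from [read_coverage_bed()]),
#'   `exon_window`, `intron_window` (each `c(start, end)`), `manifest`
#'   (list with `p`, `depth`, `seed`).
#' @export
make_coverage_fixture <- function(seed, p, depth = 500, chrom = "chr4",
                                  exon_end = 1000, width = 10) {
  stopifnot_scalar_number(p, "p", 0, 1)
  stopifnot_scalar_number(depth, "depth", 1)
  old <- .push_seed(seed)
  on.exit(.pop_seed(old))
  exon_pos <- (exon_end - width):(exon_end - 1L)
  intron_pos <- exon_end:(exon_end + width - 1L)
  track <- tibble(
    chrom = chrom,
    pos = as.integer(c(exon_pos, intron_pos)),
    depth = c(rep(depth, width), stats::rbinom(width, size = depth, prob = p)))
  list(track = track,
       exon_window = c(exon_end - width, exon_end),
       intron_window = c(exon_end, exon_end + width),
       manifest = list(p = p, depth = depth, seed = seed))
}

#' Write a coverage track as BED runs
#'
#' @param track Coverage tibble (`chrom`, `pos`, `depth`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(track, path) {
  runs <- track |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, diff(.data$pos) != 1L | diff(.data$depth) != 0))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              depth = dplyr::first(.data$depth), .groups = "drop") |>
    select("chrom", "start", "end", "depth")
  readr::write_tsv(runs, path, col_names = FALSE)
  invisible(path)
}
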