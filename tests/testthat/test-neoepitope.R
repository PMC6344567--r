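test_that("peptide windows honour flanks, tails and truncation", {
  # full context both sides: 22-aa window, junction at 11
  w <- extract_windows(make_report(aa_seq(60), 30))
  expect_equal(nchar(w$sequence), 22L)
  expect_equal(w$junction_index, 11L)
  expect_equal(w$sequence, substr(aa_seq(60), 20, 41))

  # frameshift with a 30-aa tail: 11 upstream + whole tail = 41
  tail30 <- aa_seq(30, seed = 2)
  prot <- paste0(substr(aa_seq(60), 1, 30), tail30)
  w2 <- extract_windows(make_report(prot, 30, "OUT_OF_FRAME", tail30))
  expect_equal(nchar(w2$sequence), 41L)
  expect_equal(substr(w2$sequence, 12, 41), tail30)

  # only 5 upstream residues exist
  w3 <- extract_windows(make_report(aa_seq(40), 5))
  expect_equal(w3$junction_index, 5L)
  expect_equal(nchar(w3$sequence), 16L)

  # NO_ORF_AT_JUNCTION rows are skipped
  r <- make_report(aa_seq(60), 30)
  r$frame_class <- "NO_ORF_AT_JUNCTION"
  expect_equal(nrow(extract_windows(r)), 0L)
})

test_that("tiling yields junction-overlapping 8-11-mers matching enumeration", {
  # closed form: 22-aa in-frame window -> 7+8+9+10 = 34 spanning peptides
  win <- tibble::tibble(cluster_id = "C1", sequence = aa_seq(22, seed = 3),
                        junction_index = 11L, frame_class = "IN_FRAME")
  tiles <- tile_peptides(win)
  expect_equal(nrow(tiles), 34L)
  expect_equal(as.integer(table(tiles$length)), c(7L, 8L, 9L, 10L))

  # general closed form: with full context, k-mers spanning = k - 1
  for (k in 8:11) {
    t_k <- tile_peptides(win, lengths = k)
    expect_equal(nrow(t_k), k - 1L)
  }

  # windows shorter than the smallest length tile to nothing
  short <- tibble::tibble(cluster_id = "C1", sequence = aa_seq(7),
                          junction_index = 3L, frame_class = "IN_FRAME")
  expect_equal(nrow(tile_peptides(short)), 0L)

  # 13-aa frameshift window with 2 novel residues -> 8 peptides
  oof <- tibble::tibble(cluster_id = "C1", sequence = aa_seq(13, seed = 4),
                        junction_index = 11L, frame_class = "OUT_OF_FRAME")
  expect_equal(nrow(tile_peptides(oof)), 8L)

  # random windows against exhaustive substring enumeration
  set.seed(45)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    ji <- sample(0:n, 1)
    fc <- sample(c("IN_FRAME", "OUT_OF_FRAME"), 1)
    w <- tibble::tibble(cluster_id = "C1", sequence = aa_seq(n, seed = 100 + i),
                        junction_index = ji, frame_class = fc)
    for (span in c(TRUE, FALSE)) {
      got <- tile_peptides(w, spanning_only = span)$peptide
      want <- oracle_tiles(w$sequence, ji, fc, spanning_only = span)
      expect_equal(got, want)
    }
  }
})

test_that("tiled peptides are window substrings with novel content", {
  set.seed(46)
  for (i in 1:10) {
    n <- sample(12:40, 1)
    ji <- sample(1:(n - 1), 1)
    w <- tibble::tibble(cluster_id = "C1", sequence = aa_seq(n, seed = 200 + i),
                        junction_index = ji, frame_class = "IN_FRAME")
    tiles <- tile_peptides(w)
    for (j in seq_len(nrow(tiles))) {
      expect_true(grepl(tiles$peptide[j], w$sequence, fixed = TRUE))
      # spans the junction: starts before it, ends at/after it
      expect_lt(tiles$start[j], ji)
      expect_gte(tiles$start[j] + tiles$length[j] - 1L, ji)
    }
  }
})

test_that("mock rank predictor is deterministic, allele-sensitive and uniform", {
  p <- c("ACDEFGHK", "LMNPQRST")
  expect_equal(mock_rank_predictor(p, "HLA-A*02:01"),
               mock_rank_predictor(p, "HLA-A*02:01"))
  expect_false(any(mock_rank_predictor(p, "HLA-A*02:01") ==
                     mock_rank_predictor(p, "HLA-B*07:02")))
  set.seed(47)
  peps <- vapply(1:10000, function(i) aa_seq(9, seed = 1e6 + i), character(1))
  ranks <- mock_rank_predictor(peps, "HLA-A*02:01")
  expect_true(all(ranks >= 0 & ranks < 100))
  ks <- suppressWarnings(stats::ks.test(ranks / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("strong-binder filtering is strict at rank 0.5", {
  recs <- tibble::tibble(cluster_id = "C1",
                         peptide = sprintf("ACDEFGHK%d", 1:4) |>
                           substr(1, 8),
                         hla_allele = "HLA-A*02:01",
                         rank_percent = c(0.4, 0.5, 0.49999, 2))
  out <- filter_strong_binders(recs)
  expect_equal(out$rank_percent, c(0.4, 0.49999))
  expect_true(all(out$strong))

  # brute-force agreement on a planted mixed list
  set.seed(48)
  mixed <- tibble::tibble(cluster_id = sample(c("A", "B"), 100, TRUE),
                          peptide = vapply(1:100, function(i) aa_seq(9, 300 + i),
                                           character(1)),
                          hla_allele = "HLA-A*02:01",
                          rank_percent = round(runif(100, 0, 2), 3))
  got <- filter_strong_binders(mixed)
  expect_equal(got$peptide, mixed$peptide[mixed$rank_percent < 0.5])
  load <- neoepitope_load(got)
  expect_equal(sum(load$n_neoepitopes), nrow(got))
})

test_that("window -> tile -> FASTA -> binding round trip is loss-free", {
  toy <- make_toy_annotation(seed = 71)
  fx <- plant_fusions(toy$annotation, seed = 72)
  val <- validate_fusions(classify_fusions(fx$candidates, toy$annotation),
                          fx$contigs)
  reps <- characterize_fusions(val, fx$contigs, toy$annotation)
  tiles <- tile_peptides(extract_windows(reps))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_peptide_fasta(tibble::tibble(
    peptide_id = sprintf("%s_%04d", tiles$cluster_id, seq_len(nrow(tiles))),
    peptide = tiles$peptide), fa)
  back <- read_peptide_fasta(fa)
  expect_equal(back$peptide, tiles$peptide)

  recs <- predict_binding_mock(tiles, c("HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(nrow(recs), 2L * nrow(tiles))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_binding_table(recs, tsv)
  reread <- read_binding_table(tsv)
  expect_equal(reread$rank_percent, recs$rank_percent)
  # strong set identical whether filtered before or after the round trip
  expect_equal(filter_strong_binders(reread)$peptide,
               filter_strong_binders(recs)$peptide)
})
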