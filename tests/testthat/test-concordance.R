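test_that("junction windows truncate arms to their innermost bases", {
  set.seed(31)
  l300 <- rand_dna(300)
  r300 <- rand_dna(300)
  w <- make_junction_window(paste0(l300, "|", r300))
  expect_equal(nchar(w$window), 500L)
  expect_equal(w$breakpoint_offset, 250L)
  expect_equal(w$left_arm, substr(l300, 51, 300))   # innermost 250 kept
  expect_equal(w$right_arm, substr(r300, 1, 250))

  w2 <- make_junction_window(paste0(rand_dna(80), "|", rand_dna(90)))
  expect_equal(nchar(w2$window), 170L)
  expect_equal(w2$breakpoint_offset, 80L)

  w3 <- make_junction_window(paste0(rand_dna(600), "|", rand_dna(100)))
  expect_equal(c(nchar(w3$left_arm), nchar(w3$right_arm)), c(250L, 100L))

  expect_error(make_junction_window("ACGT|ACG|T"), "exactly one")
  expect_error(make_junction_window("|ACGT"), "empty")
})

test_that("exact containment scores 100 and one-armed contigs never cover", {
  set.seed(32)
  left <- rand_dna(120)
  right <- rand_dna(120)
  win <- make_junction_window(paste0(left, "|", right))
  fusion_contig <- paste0(rand_dna(50), win$window, rand_dna(70))
  contigs <- tibble::tibble(
    contig_id = c("armonly", "fusion"),
    sequence = c(left, fusion_contig))
  res <- compute_concordance(win, contigs)
  expect_equal(res$best_contig_id, "fusion")
  expect_equal(res$concordance_percent, 100)
  expect_true(res$junction_covered)
  # breakpoint mapped to the correct contig base
  expect_equal(res$contig_break_pos, 50L + win$breakpoint_offset)

  # the one-armed contig alone: best alignment stays left of the junction
  res_arm <- compute_concordance(win, contigs[1, ])
  expect_false(res_arm$junction_covered)
  expect_equal(res_arm$concordance_percent, 0)
  expect_true(is.na(res_arm$best_contig_id))

  expect_error(compute_concordance(
    list(window = "ACGTACGTACGT", breakpoint_offset = 6), contigs), "16 nt")
})

test_that("concordance is strand-symmetric with deterministic tie-breaks", {
  set.seed(33)
  for (i in 1:10) {
    win <- make_junction_window(paste0(rand_dna(80), "|", rand_dna(80)))
    contig <- paste0(rand_dna(30), win$window, rand_dna(30))
    # plant some mismatches
    contig <- oracle_mutate(contig, 0.05)
    fwd <- compute_concordance(win, tibble::tibble(contig_id = "c",
                                                   sequence = contig))
    rev <- compute_concordance(win, tibble::tibble(contig_id = "c",
                                                   sequence = oracle_revcomp(contig)))
    expect_equal(rev$concordance_percent, fwd$concordance_percent)
    expect_equal(rev$junction_covered, fwd$junction_covered)
    if (fwd$junction_covered) {
      expect_false(identical(fwd$matched_strand, rev$matched_strand))
    }
  }
  # two identical contigs: lexicographically smaller id wins
  set.seed(34)
  win <- make_junction_window(paste0(rand_dna(60), "|", rand_dna(60)))
  contig <- win$window
  res <- compute_concordance(win, tibble::tibble(contig_id = c("b", "a"),
                                                 sequence = contig))
  expect_equal(res$best_contig_id, "a")
})

test_that("concordance matches the full-DP oracle on random instances", {
  set.seed(35)
  for (i in 1:40) {
    m <- sample(20:120, 1)
    bp <- sample(8:(m - 8), 1)
    win <- list(window = rand_dna(m), breakpoint_offset = bp)
    contigs <- tibble::tibble(
      contig_id = sprintf("c%02d", 1:3),
      sequence = vapply(1:3, function(k) {
        if (k == 1) {
          # related contig: embedded, mutated junction neighbourhood
          oracle_mutate(paste0(rand_dna(sample(0:40, 1)), win$window,
                               rand_dna(sample(0:40, 1))),
                        runif(1, 0, 0.3))
        } else {
          rand_dna(sample(60:300, 1))
        }
      }, character(1)))
    got <- compute_concordance(win, contigs)
    want <- oracle_concordance(win$window, bp, contigs)
    expect_equal(got$concordance_percent, want$concordance_percent)
    expect_equal(got$junction_covered, want$junction_covered)
    expect_equal(got$best_contig_id, want$best_contig_id)
    if (got$junction_covered) {
      expect_equal(got$matched_strand, want$matched_strand)
    }
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(36)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    w <- rand_dna(sample(20:100, 1))
    s <- oracle_mutate(paste0(rand_dna(10), w, rand_dna(10)), runif(1, 0, 0.4))
    ours <- fusionneo:::.gotoh_local(w, s)
    ref <- Biostrings::pairwiseAlignment(w, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 3, gapExtension = 1)
    expect_equal(ours$score, max(0, Biostrings::score(ref)))
  }
})

test_that("validation applies the 25% threshold and multi-fusion contigs work", {
  set.seed(37)
  toy <- make_toy_annotation(seed = 91)
  fx <- plant_fusions(toy$annotation, seed = 92)
  cands <- classify_fusions(fx$candidates, toy$annotation)
  res <- validate_fusions(cands, fx$contigs)
  expect_true(all(res$validated))
  expect_true(all(res$concordance_percent == 100))

  # exact-threshold semantics: >= by default, > when inclusive = FALSE
  res26 <- validate_fusions(cands[1, ], fx$contigs, concordance_threshold = 100)
  expect_true(res26$validated)
  res_strict <- validate_fusions(cands[1, ], fx$contigs,
                                 concordance_threshold = 100,
                                 inclusive = FALSE)
  expect_false(res_strict$validated)

  # one contig carrying two junctions validates both candidates
  j1 <- make_junction_window(cands$junction_sequence[1])
  j2 <- make_junction_window(cands$junction_sequence[2])
  triple <- tibble::tibble(contig_id = "triple",
                           sequence = paste0(j1$window, rand_dna(20), j2$window))
  both <- validate_fusions(cands[1:2, ], triple)
  expect_true(all(both$validated))
  expect_equal(both$best_contig_id, c("triple", "triple"))
})

test_that("extra mismatches never increase concordance (monotonicity)", {
  set.seed(38)
  win <- make_junction_window(paste0(rand_dna(100), "|", rand_dna(100)))
  base <- paste0(rand_dna(25), win$window, rand_dna(25))
  prev <- 101
  for (rate in c(0, 0.05, 0.1, 0.2, 0.3)) {
    set.seed(39)  # same mutation positions, nested by rate
    contig <- oracle_mutate(base, rate)
    res <- compute_concordance(win, tibble::tibble(contig_id = "c",
                                                   sequence = contig))
    expect_lte(res$concordance_percent, prev)
    prev <- res$concordance_percent
  }
})
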