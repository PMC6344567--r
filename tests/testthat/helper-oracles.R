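# Independent oracles used to verify the implementation. The aligner oracle
# is a pure-R Gotoh DP with a different fill structure (vectorized rows, a
# running-max formulation for the horizontal gap state) but the same scoring
# scheme and the same documented canonical traceback rules as the package
# aligner; score, identities and alignment span must agree exactly.

oracle_align <- function(w, c, match = 1, mismatch = -2, open = 3, ext = 1) {
  m <- nchar(w)
  n <- nchar(c)
  wv <- strsplit(w, "")[[1]]
  cv <- strsplit(c, "")[[1]]
  open1 <- open + ext
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)  # gap in window (consumes contig)
  Iy <- matrix(NEG, m + 1, n + 1)  # gap in contig (consumes window)
  for (i in seq_len(m)) {
    s <- ifelse(cv == wv[i], match, mismatch)
    prev <- pmax(0, M[i, 1:n], Ix[i, 1:n], Iy[i, 1:n])
    M[i + 1, 2:(n + 1)] <- s + prev
    Iy[i + 1, 2:(n + 1)] <- pmax(M[i, 2:(n + 1)] - open1,
                                 Ix[i, 2:(n + 1)] - open1,
                                 Iy[i, 2:(n + 1)] - ext)
    # Ix[i+1, j] = max_{k < j} (max(M[i+1,k], Iy[i+1,k]) - open - (j-k) ext)
    a <- pmax(M[i + 1, 1:n], Iy[i + 1, 1:n]) - open + (1:n) * ext
    Ix[i + 1, 2:(n + 1)] <- cummax(a) - (2:(n + 1)) * ext
  }
  best <- 0
  bi <- bj <- -1L
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      if (M[i, j] > best) {
        best <- M[i, j]
        bi <- i
        bj <- j
      }
    }
  }
  if (bi < 0) return(list(score = 0))
  i <- bi; j <- bj; state <- "M"
  identities <- 0L
  w_min <- m; w_max <- -1L; c_min <- n; c_max <- -1L
  step_wi <- integer(0); step_cj <- integer(0)
  repeat {
    if (state == "M") {
      if (wv[i - 1] == cv[j - 1]) identities <- identities + 1L
      w_min <- min(w_min, i - 2L); w_max <- max(w_max, i - 2L)
      c_min <- min(c_min, j - 2L); c_max <- max(c_max, j - 2L)
      step_wi <- c(step_wi, i - 2L); step_cj <- c(step_cj, j - 2L)
      s <- if (wv[i - 1] == cv[j - 1]) match else mismatch
      v <- M[i, j] - s
      i <- i - 1L; j <- j - 1L
      if (v <= 0) break
      state <- if (M[i, j] == v) "M" else if (Ix[i, j] == v) "Ix" else "Iy"
    } else if (state == "Ix") {
      c_min <- min(c_min, j - 2L); c_max <- max(c_max, j - 2L)
      v <- Ix[i, j]
      j <- j - 1L
      state <- if (M[i, j] - open1 == v) "M"
               else if (Ix[i, j] - ext == v) "Ix" else "Iy"
    } else {
      w_min <- min(w_min, i - 2L); w_max <- max(w_max, i - 2L)
      step_wi <- c(step_wi, i - 2L); step_cj <- c(step_cj, j - 1L)
      v <- Iy[i, j]
      i <- i - 1L
      state <- if (M[i, j] - open1 == v) "M"
               else if (Ix[i, j] - open1 == v) "Ix" else "Iy"
    }
  }
  list(score = best, identities = identities,
       w_start = w_min, w_end = w_max + 1L,
       c_start = c_min, c_end = c_max + 1L,
       step_window_index = step_wi, step_contig_pos = step_cj)
}

# independent reverse complement (no Biostrings, no package internals)
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# full contig-selection logic on top of oracle_align
oracle_concordance <- function(window, bp, contigs) {
  best <- NULL
  for (k in order(contigs$contig_id)) {
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") contigs$sequence[k] else oracle_revcomp(contigs$sequence[k])
      aln <- oracle_align(window, seq)
      if (aln$score <= 0) next
      if (!(aln$w_start <= bp - 1L && aln$w_end >= bp + 1L)) next
      conc <- 100 * aln$identities / nchar(window)
      if (is.null(best) || conc > best$concordance_percent + 1e-12) {
        best <- list(best_contig_id = contigs$contig_id[k],
                     concordance_percent = conc, junction_covered = TRUE,
                     matched_strand = strand)
      }
    }
  }
  best %||% list(best_contig_id = NA_character_, concordance_percent = 0,
                 junction_covered = FALSE, matched_strand = NA_character_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force six-frame ORF enumeration, independent of find_orfs internals;
# translation via Biostrings::GENETIC_CODE
oracle_orfs <- function(seq, min_aa = 1) {
  gc <- Biostrings::GENETIC_CODE
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    chars <- strsplit(s, "")[[1]]
    for (p in 0:(L - 3)) {
      if (paste(chars[(p + 1):(p + 3)], collapse = "") != "ATG") next
      aa <- character(0)
      q <- p
      complete <- FALSE
      while (q + 3 <= L) {
        codon <- paste(chars[(q + 1):(q + 3)], collapse = "")
        r <- unname(gc[codon])
        if (is.na(r)) r <- "X"
        if (r == "*") {
          complete <- TRUE
          q <- q + 3
          break
        }
        aa <- c(aa, r)
        q <- q + 3
      }
      if (length(aa) < min_aa) next
      nt_start <- p
      nt_end <- q
      iv <- if (strand == "+") c(nt_start, nt_end) else c(L - nt_end, L - nt_start)
      rows[[length(rows) + 1L]] <- data.frame(
        start = iv[1], end = iv[2], strand = strand, frame = p %% 3,
        protein = paste(aa, collapse = ""), complete = complete,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), complete = logical(0)))
  }
  do.call(rbind, rows)
}

# exhaustive substring enumeration for peptide tiling
oracle_tiles <- function(window, junction_index, frame_class,
                         lengths = 8:11, spanning_only = TRUE) {
  n <- nchar(window)
  out <- character(0)
  for (k in sort(lengths)) {
    if (n < k) next
    for (s in 0:(n - k)) {
      if (spanning_only) {
        has_novel <- (s + k - 1) >= junction_index
        has_up <- s < junction_index
        ok <- if (frame_class == "IN_FRAME" && junction_index > 0) {
          has_novel && has_up
        } else {
          has_novel
        }
        if (!ok) next
      }
      out <- c(out, substr(window, s + 1, s + k))
    }
  }
  out[!duplicated(out)]
}

# random DNA helper for property tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# point-mutate each base with probability `rate`; drawing the uniform and the
# replacement for every base up front makes mutation sets nested across rates
# under a fixed seed (needed for monotonicity sweeps)
oracle_mutate <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  u <- stats::runif(length(chars))
  repl <- vapply(chars, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1), USE.NAMES = FALSE)
  hit <- u < rate
  chars[hit] <- repl[hit]
  paste(chars, collapse = "")
}
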