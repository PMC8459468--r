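## a convenient hand-built reference: 140-base window, junction at offset 69
make_ref <- function(seed = 10, clen = 300, W = 70) {
  circ <- random_dna(clen, seed = seed)
  w <- build_circular_window(circ, W = W)
  tibble::tibble(circ_id = "c1", window = w$window,
                 window_offset = w$junction_offset,
                 linear_left = NA_character_, linear_left_offset = NA_integer_,
                 linear_right = NA_character_, linear_right_offset = NA_integer_)
}

## read covering `left` bases left of the junction, length L
junction_read <- function(ref, left, L = 70) {
  p <- ref$window_offset + 2L - left
  substr(ref$window, p, p + L - 1)
}

test_that("an exact junction-spanning read yields a zero-mismatch hit", {
  ref <- make_ref()
  rd <- junction_read(ref, left = 30)
  hit <- match_read_to_junction(rd, ref)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$align_offset, ref$window_offset + 2L - 30L - 1L)
  # a read that IS the 2j seed exactly spans with j per side
  seed10 <- junction_read(ref, left = 5, L = 10)
  hit10 <- match_read_to_junction(seed10, ref, j = 5)
  expect_equal(hit10$mismatches, 0L)
})

test_that("reads with fewer than j bases on one side of the junction are rejected", {
  ref <- make_ref()
  for (left in 1:4) {
    expect_equal(nrow(match_read_to_junction(junction_read(ref, left), ref)), 0)
    expect_equal(nrow(match_read_to_junction(junction_read(ref, 70 - left), ref)), 0)
  }
  expect_equal(nrow(match_read_to_junction(junction_read(ref, 5), ref)), 1)
  expect_equal(nrow(match_read_to_junction(junction_read(ref, 65), ref)), 1)
  # reads shorter than 2j cannot span
  expect_equal(nrow(match_read_to_junction(substr(junction_read(ref, 5), 1, 9),
                                           ref)), 0)
})

test_that("mismatches in the seed kill the hit; outside the seed m are tolerated", {
  ref <- make_ref()
  rd <- junction_read(ref, left = 35)
  flip <- function(s, i) {
    ch <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), ch)[1]
    s
  }
  # seed occupies read positions 31..40 here
  expect_equal(nrow(match_read_to_junction(flip(rd, 33), ref)), 0)
  expect_equal(nrow(match_read_to_junction(flip(rd, 40), ref)), 0)
  r1 <- flip(rd, 1); r2 <- flip(r1, 2); r3 <- flip(r2, 70)
  expect_equal(match_read_to_junction(r1, ref)$mismatches, 1L)
  expect_equal(match_read_to_junction(r2, ref)$mismatches, 2L)
  expect_equal(nrow(match_read_to_junction(r3, ref)), 0)          # m = 2 default
  expect_equal(match_read_to_junction(r3, ref, m = 3)$mismatches, 3L)
  # N counts as a mismatch wherever it falls
  rn <- rd; substr(rn, 35, 35) <- "N"
  expect_equal(nrow(match_read_to_junction(rn, ref)), 0)
  rn2 <- rd; substr(rn2, 1, 1) <- "N"
  expect_equal(match_read_to_junction(rn2, ref)$mismatches, 1L)
})

test_that("stranded mode ignores antisense reads; unstranded recovers them", {
  ref <- make_ref(seed = 11)
  rd <- junction_read(ref, left = 30)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  expect_equal(nrow(match_read_to_junction(rc, ref, strandedness = "forward")), 0)
  expect_equal(nrow(match_read_to_junction(rc, ref, strandedness = "unstranded")), 1)
})

test_that("random reads match the exhaustive sliding-window oracle", {
  set.seed(20)
  ref <- make_ref(seed = 20, clen = 120, W = 60)
  for (i in 1:150) {
    L <- sample(c(12, 30, 70), 1)
    rd <- if (runif(1) < 0.5) {
      random_dna(L)
    } else {
      r <- junction_read(ref, left = sample(1:(L - 1), 1), L = L)
      # sprinkle mutations
      for (k in seq_len(sample(0:3, 1))) {
        i0 <- sample(nchar(r), 1)
        substr(r, i0, i0) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      r
    }
    got <- match_read_to_junction(rd, ref)
    want <- oracle_match_read(rd, ref$window, ref$window_offset)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$mismatches, want$mm)
      expect_equal(got$align_offset, want$offset)
    }
  }
})

test_that("end-to-end placement search agrees with exhaustive search", {
  set.seed(21)
  subjects <- Biostrings::DNAStringSet(c(s1 = random_dna(400), s2 = random_dna(300)))
  reads <- character(60)
  for (i in seq_len(60)) {
    reads[i] <- if (runif(1) < 0.3) {
      random_dna(30)
    } else {
      S <- as.character(subjects[[sample(2, 1)]])
      p <- sample(nchar(S) - 29, 1)
      r <- substr(S, p, p + 29)
      if (runif(1) < 0.5) {
        r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      }
      for (k in seq_len(sample(0:4, 1))) {
        i0 <- sample(30, 1)
        substr(r, i0, i0) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    }
  }
  names(reads) <- paste0("r", seq_len(60))
  got <- find_end_to_end_placements(reads, subjects, m = 2)
  want <- vapply(reads, oracle_placed, logical(1), subjects = subjects, m = 2)
  expect_equal(got, unname(want))
})

test_that("the exclusion filter removes linear-explainable circular hits", {
  study <- small_study()
  ann <- study$annotation; g <- study$genome; refs <- study$refs
  tx <- extract_transcriptome(ann, g)
  # a read wholly within one exon matches the transcriptome -> discarded
  ex <- dplyr::filter(ann, gene_id == study$truth$host_gene[1])
  exonic <- substr(get_tx_seq <- as.character(tx[[ex$transcript_id[1]]]), 10, 79)
  # a true junction-spanning read survives
  circ_ref <- refs[refs$circ_id == study$truth$circ_id[1], ]
  spanning <- substr(circ_ref$window, circ_ref$window_offset - 33, circ_ref$window_offset + 36)
  reads <- tibble::tibble(read_id = c("lin", "circ"), mate = 0L,
                          seq = c(exonic, spanning))
  hits <- dplyr::bind_rows(
    tibble::tibble(read_id = "lin", mate = 0L, circ_id = "x",
                   junction = "circular", orientation = "forward",
                   align_offset = 0L, mismatches = 0L),
    match_junction_reads(reads, refs, "circular")
  )
  kept <- exclusion_filter(hits, reads, g, tx)
  expect_true("circ" %in% kept$read_id)
  expect_false("lin" %in% kept$read_id)
  expect_equal(attr(kept, "n_excluded_transcriptome") +
                 attr(kept, "n_excluded_genome"), 1L)
})

test_that("a read from a tandem duplication planted in the genome is excluded", {
  set.seed(22)
  circ <- random_dna(200)
  w <- build_circular_window(circ, W = 70)
  ref <- tibble::tibble(circ_id = "dup", window = w$window,
                        window_offset = w$junction_offset)
  # genome carries the circle twice in tandem: the backsplice-like junction
  # sequence exists linearly, so its reads are not circular evidence
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste0(random_dna(150), circ, circ, random_dna(150))))
  rd <- substr(w$window, w$junction_offset - 33, w$junction_offset + 36)
  reads <- tibble::tibble(read_id = "r", mate = 0L, seq = rd)
  hits <- match_junction_reads(reads, ref, "circular")
  expect_equal(nrow(hits), 1)  # it does match the junction window
  kept <- exclusion_filter(hits, reads, genome,
                           Biostrings::DNAStringSet(c(t1 = random_dna(100))))
  expect_equal(nrow(kept), 0)  # exhaustive-substring check: present linearly
  expect_true(oracle_placed(rd, genome, m = 2))
})

test_that("fragment counting never counts a fragment twice and flags ambiguity", {
  # PE fragment with both mates spanning the same junction counts once
  hits <- tibble::tibble(
    read_id = c("f1", "f1"), mate = 1:2, circ_id = "c1",
    junction = "circular", orientation = "forward",
    align_offset = 0L, mismatches = 0L
  )
  cc <- count_junctions(hits, circ_ids = "c1")
  expect_equal(cc$circ_count, 1L)
  # 10 SE reads on one junction add up
  hits10 <- tibble::tibble(read_id = paste0("r", 1:10), mate = 0L,
                           circ_id = "c1", junction = "circular",
                           orientation = "forward", align_offset = 0L,
                           mismatches = 0L)
  expect_equal(count_junctions(hits10, circ_ids = "c1")$circ_count, 10L)
  # a read hitting two distinct circular junctions is discarded as ambiguous
  amb <- tibble::tibble(read_id = "r", mate = 0L, circ_id = c("c1", "c2"),
                        junction = "circular", orientation = "forward",
                        align_offset = 0L, mismatches = 0L)
  cc2 <- count_junctions(amb, circ_ids = c("c1", "c2"))
  expect_equal(cc2$circ_count, c(0L, 0L))
  expect_equal(attr(cc2, "stats")$n_ambiguous, 1L)
})

test_that("two circles sharing a boundary region make their reads ambiguous", {
  set.seed(23)
  # two circle isoforms with identical junction-proximal sequence (same
  # boundary exons): their windows coincide, so junction reads cannot be
  # attributed to either one
  circA <- random_dna(220)
  wA <- build_circular_window(circA, W = 30)
  refs <- tibble::tibble(circ_id = c("A", "B"),
                         window = c(wA$window, wA$window),
                         window_offset = wA$junction_offset)
  rd <- substr(wA$window, wA$junction_offset - 13, wA$junction_offset + 16)
  hits <- match_junction_reads(c(r = rd), refs, "circular")
  expect_equal(sort(hits$circ_id), c("A", "B"))
  cc <- count_junctions(hits, circ_ids = c("A", "B"))
  expect_equal(sum(cc$circ_count), 0L)
  expect_equal(attr(cc, "stats")$n_ambiguous, 1L)
})

test_that("duplicated read id + mate index in a library is fatal", {
  reads <- tibble::tibble(read_id = c("r1", "r1"), mate = 1L,
                          seq = c("ACGTACGTACGT", "ACGTACGTACGT"))
  expect_error(match_junction_reads(reads, make_ref(), "circular"),
               "twice with the same mate")
})

test_that("counts are monotone: non-increasing in j, non-decreasing in m", {
  study <- small_study()
  reads <- study$sim$libraries[[1]]$mock
  refs <- study$refs
  n_hits <- function(j, m) {
    nrow(match_junction_reads(reads, refs, "circular", j = j, m = m))
  }
  h <- c(n_hits(4, 2), n_hits(5, 2), n_hits(8, 2), n_hits(12, 2))
  expect_true(all(diff(h) <= 0))
  h2 <- c(n_hits(5, 0), n_hits(5, 1), n_hits(5, 2), n_hits(5, 4))
  expect_true(all(diff(h2) >= 0))
})

test_that("quantification is invariant to reverse-complementing reads in unstranded mode", {
  study <- small_study()
  reads <- study$sim$libraries[[1]]$mock
  rc_reads <- reads
  rc_reads$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$seq)))
  tx <- extract_transcriptome(study$annotation, study$genome)
  q1 <- suppressMessages(quantify_library(reads, study$refs, study$genome,
                                          transcriptome = tx,
                                          strandedness = "unstranded"))
  q2 <- suppressMessages(quantify_library(rc_reads, study$refs, study$genome,
                                          transcriptome = tx,
                                          strandedness = "unstranded"))
  expect_equal(plain(q1), plain(q2))
  # and in stranded mode antisense reads yield zero circular counts
  q3 <- suppressMessages(quantify_library(rc_reads, study$refs, study$genome,
                                          transcriptome = tx,
                                          strandedness = "forward"))
  expect_equal(sum(q3$circ_count), 0L)
})

test_that("an empty library yields an all-zero count table with a warning", {
  study <- small_study()
  empty <- tibble::tibble(read_id = character(), mate = integer(),
                          seq = character())
  expect_warning(
    q <- quantify_library(empty, study$refs, study$genome,
                          transcriptome = extract_transcriptome(
                            study$annotation, study$genome)),
    "no reads"
  )
  expect_equal(sum(q$circ_count), 0L)
  expect_equal(attr(q, "library_size"), 0)
  expect_equal(nrow(q), nrow(study$refs))
})
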