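## shared toy fixtures and independent oracles, built in code

# the canonical two-exon transcript used in worked examples:
# exons [100,200) and [300,500) on chr1, plus strand
toy_transcript <- function(strand = "+", chrom = "chr1",
                           gene = "g1", tx = "t1") {
  rank <- if (identical(strand, "+")) 1:2 else 2:1
  tibble::tibble(
    chrom = chrom, start = c(100L, 300L), end = c(200L, 500L),
    strand = strand, gene_id = gene, transcript_id = tx,
    exon_rank = rank
  )
}

## data frame stripped of all non-structural attributes, for comparisons
plain <- function(x) {
  a <- as.data.frame(x)
  attributes(a) <- attributes(a)[c("names", "class", "row.names")]
  a
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

toy_genome <- function(len = 2000, seed = 1, name = "chr1") {
  g <- Biostrings::DNAStringSet(random_dna(len, seed))
  names(g) <- name
  g
}

## brute-force boundary scoring over all transcripts of an annotation
oracle_best_score <- function(cand, annotation) {
  scores <- vapply(split(annotation, annotation$transcript_id), function(ex) {
    score_candidate_against_transcript(cand, ex)
  }, integer(1))
  ov <- vapply(split(annotation, annotation$transcript_id), function(ex) {
    ex$chrom[1] == cand$chrom && ex$strand[1] == cand$strand &&
      min(ex$start) < cand$end && max(ex$end) > cand$start
  }, logical(1))
  if (!any(ov)) return(list(score = 0L, tx = NA_character_))
  s <- scores[ov]
  best <- max(s)
  list(score = best, tx = sort(names(s)[s == best])[1])
}

## exhaustive sliding-window junction matcher (independent of the
## package's seed-anchored search)
oracle_match_read <- function(read, window, off0, j = 5, m = 2) {
  L <- nchar(read)
  W <- nchar(window)
  if (L > W || L < 2 * j) return(NULL)
  rs <- strsplit(read, "")[[1]]
  best <- NULL
  for (p in seq_len(W - L + 1)) {
    left <- off0 + 2L - p           # read bases at or left of the junction
    right <- L - left
    if (left < j || right < j) next
    ws <- strsplit(substr(window, p, p + L - 1), "")[[1]]
    mm <- (rs != ws) | rs == "N" | ws == "N"
    seed_idx <- (left - j + 1):(left + j)
    if (any(mm[seed_idx])) next
    tot <- sum(mm)
    if (tot > m) next
    if (is.null(best) || tot < best$mm) best <- list(offset = p - 1L, mm = tot)
  }
  best
}

## exhaustive ungapped end-to-end placement search over a character
## sequence set (both strands)
oracle_placed <- function(read, subjects, m = 2) {
  L <- nchar(read)
  rs <- strsplit(read, "")[[1]]
  subj <- as.character(subjects)
  subj <- c(subj, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(subj))))
  for (S in subj) {
    if (nchar(S) < L) next
    for (p in seq_len(nchar(S) - L + 1)) {
      ws <- strsplit(substr(S, p, p + L - 1), "")[[1]]
      mm <- sum((rs != ws) | rs == "N" | ws == "N")
      if (mm <= m) return(TRUE)
    }
  }
  FALSE
}

## nearest-rank quantile by explicit sort-and-index
oracle_quantile <- function(x, c) sort(x)[ceiling(c * length(x))]

## a small simulated study shared by several test files (cached)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7, n_genes = 30, n_true_circles = 8,
                        n_decoys = 8, reads_per_circle_set1 = 30,
                        linear_reads_per_gene = 40)
      cache <<- suppressMessages(run_pipeline(cfg))
    }
    cache
  }
})
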