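#' Merge circRNA candidates reported by multiple detection pipelines
#'
#' Deduplicates backsplice-junction candidates across upstream pipelines.
#' Candidates sharing the exact normalized key (chrom, start, end,
#' strand) are merged, with the `pipelines` field recording the union of
#' sources. With `tolerance > 0`, candidates on the same chrom/strand
#' whose start coordinates differ by at most `tolerance` bases *and*
#' whose end coordinates differ by at most `tolerance` bases are
#' clustered (single linkage); the cluster is represented by the
#' coordinates of the member supported by most pipelines (ties broken by
#' smallest start, then smallest end).
#'
#' @param candidates A tibble with columns `chrom`, `start`, `end`,
#'   `strand`, `pipeline` (and optionally `count`), already in internal
#'   0-based half-open coordinates — typically `dplyr::bind_rows()` over
#'   [read_candidates_bed()] outputs; alternatively a named list of such
#'   per-pipeline tibbles (names supply the `pipeline` column).
#' @param tolerance Maximum per-boundary disagreement, in bases, for two
#'   candidates to be considered the same junction. Default 0 (exact).
#' @param genome Optional `DNAStringSet`; candidates on sequences absent
#'   from it are dropped with a warning.
#' @return Tibble with one row per merged candidate: `chrom`, `start`,
#'   `end`, `strand`, `n_pipelines`, `pipelines` (comma-joined, sorted),
#'   sorted by coordinates.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100L, end = 500L,
#'                     strand = "+", pipeline = "p1")
#' b <- tibble::tibble(chrom = "chr1", start = 100L, end = 500L,
#'                     strand = "+", pipeline = "p2")
#' merge_candidates(dplyr::bind_rows(a, b))
#' @export
merge_candidates <- function(candidates, tolerance = 0L, genome = NULL) {
  if (is.list(candidates) && !is.data.frame(candidates)) {
    stopifnot(!is.null(names(candidates)))
    candidates <- purrr::imap(candidates, function(x, nm) {
      if (!"pipeline" %in% names(x)) x$pipeline <- nm
      x
    }) |> bind_rows()
  }
  req <- c("chrom", "start", "end", "strand", "pipeline")
  stopifnot(all(req %in% names(candidates)))
  if (nrow(candidates) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_pipelines = integer(),
                  pipelines = character()))
  }
  if (!is.null(genome)) {
    known <- candidates$chrom %in% names(genome)
    if (any(!known)) {
      warn(sprintf("dropping %d candidate(s) on sequences absent from the genome: %s",
                   sum(!known),
                   paste(unique(candidates$chrom[!known]), collapse = ", ")))
      candidates <- candidates[known, ]
    }
  }
  exact <- candidates |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(pipes = list(sort(unique(.data$pipeline))), .groups = "drop") |>
    mutate(n_pipelines = lengths(.data$pipes))

  if (tolerance > 0 && nrow(exact) > 1) {
    exact <- exact |>
      group_by(.data$chrom, .data$strand) |>
      group_modify(~ cluster_candidates(.x, tolerance)) |>
      ungroup()
  }
  exact |>
    mutate(pipelines = purrr::map_chr(.data$pipes, paste, collapse = ",")) |>
    select("chrom", "start", "end", "strand", "n_pipelines", "pipelines") |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

## single-linkage clustering of exact-key candidates within one
## chrom/strand group: edges where both boundary offsets are <= tol
cluster_candidates <- function(x, tol) {
  x <- arrange(x, .data$start, .data$end)
  n <- nrow(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      if (x$start[k] - x$start[i] > tol) break
      if (abs(x$end[k] - x$end[i]) <= tol) {
        parent[find(k)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  x |>
    mutate(.cluster = root) |>
    group_by(.data$.cluster) |>
    group_modify(function(g, key) {
      rep_row <- g |>
        arrange(desc(.data$n_pipelines), .data$start, .data$end) |>
        slice(1)
      all_pipes <- sort(unique(unlist(g$pipes)))
      tibble(start = rep_row$start, end = rep_row$end,
             pipes = list(all_pipes), n_pipelines = length(all_pipes))
    }) |>
    ungroup() |>
    select(-".cluster")
}

#' Score a candidate's boundary consistency against one transcript
#'
#' Most circRNAs are flanked by annotated splice sites, so boundary
#' agreement with an exon model is evidence that the candidate's
#' coordinates are right. The score is 2 when the candidate's start
#' coincides with some exon start *and* its end with some exon end of
#' the transcript; 1 when exactly one boundary matches; 0 otherwise.
#' A chrom or strand mismatch means the transcript cannot host the
#' candidate and scores 0.
#'
#' @param candidate One-row tibble (or list) with `chrom`, `start`,
#'   `end`, `strand` in internal coordinates.
#' @param transcript_exons Exon tibble of a single transcript (columns
#'   `chrom`, `start`, `end`, `strand`).
#' @return Integer score in {0, 1, 2}.
#' @examples
#' tx <- tibble::tibble(chrom = "chr1", start = c(100L, 300L),
#'                      end = c(200L, 500L), strand = "+")
#' cand <- list(chrom = "chr1", start = 100L, end = 500L, strand = "+")
#' score_candidate_against_transcript(cand, tx)  # 2
#' @export
score_candidate_against_transcript <- function(candidate, transcript_exons) {
  if (candidate$chrom[1] != transcript_exons$chrom[1] ||
      candidate$strand[1] != transcript_exons$strand[1]) {
    return(0L)
  }
  as.integer(candidate$start[1] %in% transcript_exons$start) +
    as.integer(candidate$end[1] %in% transcript_exons$end)
}

#' Assign each candidate to its best-fitting transcript
#'
#' For every candidate, transcripts overlapping the candidate span on
#' the same chrom and strand are scored with
#' [score_candidate_against_transcript()], and the transcript with the
#' maximal score is chosen. Equal-score ties are broken by the
#' lexicographically smallest `transcript_id` by default, or uniformly
#' at random (reproducibly) when `random_tiebreak` is set. A candidate
#' overlapped by no transcript keeps `transcript_id = NA`, score 0, and
#' an exon chain equal to its own genomic span.
#'
#' The exon chain of the chosen transcript is clipped to the candidate:
#' exons intersecting `[start, end)` are kept with the first and last
#' clipped to the candidate boundaries.
#'
#' @param candidates Tibble of merged candidates (from
#'   [merge_candidates()] or compatible, requiring `chrom`, `start`,
#'   `end`, `strand`).
#' @param annotation Exon tibble from [read_gtf()] or [make_toy_genome()].
#' @param random_tiebreak Logical; break score ties randomly instead of
#'   lexicographically.
#' @param seed RNG seed used when `random_tiebreak = TRUE`.
#' @return The input tibble with added columns `circ_id`
#'   (`chrom:start-end:strand`), `transcript_id`, `score`, and
#'   `exon_chain` (list-column of clipped exon tibbles with `start`,
#'   `end`).
#' @export
assign_transcripts <- function(candidates, annotation,
                               random_tiebreak = FALSE, seed = 1L) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(candidates)))
  n <- nrow(candidates)
  circ_id <- sprintf("%s:%d-%d:%s", candidates$chrom, candidates$start,
                     candidates$end, candidates$strand)
  if (anyDuplicated(circ_id)) {
    abort("duplicate candidate keys after merging")
  }
  tx_span <- annotation |>
    group_by(.data$transcript_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  hits <- overlap_pairs(candidates, tx_span)

  exons_by_tx <- split(annotation, annotation$transcript_id)

  tx_id <- rep(NA_character_, n)
  score <- integer(n)
  chain <- vector("list", n)
  if (random_tiebreak) {
    rng <- local({ set.seed(seed); function(k) sample.int(k, 1L) })
  }
  hit_list <- split(hits$tx_idx, hits$cand_idx)
  for (key in names(hit_list)) {
    i <- as.integer(key)
    cand <- candidates[i, ]
    ids <- tx_span$transcript_id[hit_list[[key]]]
    sc <- vapply(ids, function(id) {
      score_candidate_against_transcript(cand, exons_by_tx[[id]])
    }, integer(1))
    best <- max(sc)
    tied <- sort(ids[sc == best])
    chosen <- if (random_tiebreak && length(tied) > 1) {
      tied[rng(length(tied))]
    } else {
      tied[1]
    }
    tx_id[i] <- chosen
    score[i] <- best
    chain[[i]] <- clip_exon_chain(exons_by_tx[[chosen]], cand$start, cand$end)
  }
  no_hit <- is.na(tx_id)
  chain[no_hit] <- purrr::map(which(no_hit), function(i) {
    tibble(start = candidates$start[i], end = candidates$end[i])
  })
  candidates |>
    mutate(circ_id = circ_id, transcript_id = tx_id, score = score,
           exon_chain = chain)
}

## candidate x transcript-span overlap on same chrom and strand;
## returns tibble(cand_idx, tx_idx)
overlap_pairs <- function(candidates, tx_span) {
  if (nrow(tx_span) == 0 || nrow(candidates) == 0) {
    return(tibble(cand_idx = integer(), tx_idx = integer()))
  }
  gr_c <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$start + 1L, candidates$end),
    strand = candidates$strand
  )
  gr_t <- GenomicRanges::GRanges(
    tx_span$chrom,
    IRanges::IRanges(tx_span$start + 1L, tx_span$end),
    strand = tx_span$strand
  )
  ov <- GenomicRanges::findOverlaps(gr_c, gr_t, ignore.strand = FALSE)
  tibble(cand_idx = S4Vectors::queryHits(ov), tx_idx = S4Vectors::subjectHits(ov))
}

## exons intersecting [start, end), first/last clipped to the boundaries
clip_exon_chain <- function(exons, start, end) {
  keep <- exons$end > start & exons$start < end
  ch <- exons[keep, c("start", "end")]
  if (nrow(ch) == 0) return(tibble(start = start, end = end))
  ch$start <- pmax(ch$start, start)
  ch$end <- pmin(ch$end, end)
  arrange(ch, .data$start)
}
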