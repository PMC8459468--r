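## genomic substring in internal 0-based half-open coordinates,
## on the plus strand
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("sequence '%s' not present in the genome FASTA", chrom))
  }
  len <- Biostrings::width(genome[names(genome) == chrom][1])
  if (start < 0 || end > len) {
    abort(sprintf("interval %s:%d-%d extends past the sequence end (%d bases)",
                  chrom, start, end, len))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract circle sequences for assigned candidates
#'
#' For candidates with boundary score >= 1 the circle sequence is the
#' spliced concatenation of the clipped exon chain of the best-fit
#' transcript; for score-0 candidates it is the unspliced genomic span.
#' Minus-strand circles are reverse-complemented so every returned
#' sequence reads 5' to 3' on the transcript strand.
#'
#' @param assignments Tibble from [assign_transcripts()].
#' @param genome A named `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet()`).
#' @return `assignments` with added columns `circle_seq` and
#'   `circle_length`.
#' @export
circle_sequence <- function(assignments, genome) {
  seqs <- purrr::pmap_chr(
    list(assignments$chrom, assignments$strand, assignments$score,
         assignments$exon_chain, assignments$start, assignments$end),
    function(chrom, strand, score, chain, start, end) {
      s <- if (score >= 1) {
        paste(purrr::map2_chr(chain$start, chain$end,
                              ~ get_seq(genome, chrom, .x, .y)),
              collapse = "")
      } else {
        get_seq(genome, chrom, start, end)
      }
      if (strand == "-") revcomp(s) else s
    }
  )
  mutate(assignments, circle_seq = seqs, circle_length = nchar(seqs))
}

#' Build a junction-centred circular reference window
#'
#' Only junction-spanning reads are informative for a backsplice, so the
#' reference indexes a window of half-width `W` centred on the junction
#' rather than the full circle: the last `k` bases of the circle
#' followed by its first `k` bases, with `k = min(W, circle length)`.
#' For circles shorter than `W` this "rolling" window is a rotated copy
#' of the circle containing exactly one junction copy, so any read lying
#' on the (conceptually infinite) rolled circle and crossing the
#' junction is still representable.
#'
#' @param circle_seq Character vector of circle sequences (5'->3' on the
#'   transcript strand).
#' @param W Window half-width in bases; default 70 (one read length).
#' @return Tibble with columns `window` and `junction_offset`, where the
#'   offset is the 0-based index of the base immediately left (5') of
#'   the backsplice junction.
#' @examples
#' build_circular_window("ABCDEFGH", W = 3)  # window "FGHABC", offset 2
#' @export
build_circular_window <- function(circle_seq, W = 70L) {
  stopifnot(W >= 1)
  if (any(!nzchar(circle_seq))) abort("empty circle sequence")
  len <- nchar(circle_seq)
  k <- pmin(W, len)
  window <- paste0(substr(circle_seq, len - k + 1L, len),
                   substr(circle_seq, 1L, k))
  tibble(window = window, junction_offset = k - 1L)
}

#' Build circular and linear junction references
#'
#' Combines [circle_sequence()] and [build_circular_window()] with the
#' linear-junction references used as the RNase R-sensitive comparison
#' set: `linear_left` joins the closest upstream annotated exon (within
#' the chosen transcript) to the 5' end of the circle, and
#' `linear_right` joins the 3' end of the circle to the closest
#' downstream exon. Each carries the canonical splice junction of the
#' host gene at the recorded offset. A side lacking a neighbouring exon
#' (circle at a transcript terminus), and every score-0 candidate, gets
#' a declared-absent (`NA`) linear reference.
#'
#' @inheritParams circle_sequence
#' @param annotation Exon tibble (the same one used for assignment).
#' @param W Window half-width in bases (default 70); the circle
#'   contribution to each linear reference is capped at `W` bases.
#' @return Tibble with one row per candidate: `circ_id`, `chrom`,
#'   `start`, `end`, `strand`, `transcript_id`, `score`,
#'   `circle_length`, `window`, `window_offset`, `linear_left`,
#'   `linear_left_offset`, `linear_right`, `linear_right_offset`.
#' @export
build_junction_references <- function(assignments, annotation, genome, W = 70L) {
  asg <- circle_sequence(assignments, genome)
  win <- build_circular_window(asg$circle_seq, W)
  exons_by_tx <- split(annotation, annotation$transcript_id)

  lin <- purrr::pmap(
    list(asg$chrom, asg$strand, asg$score, asg$transcript_id,
         asg$start, asg$end, asg$circle_seq),
    function(chrom, strand, score, tx, start, end, cseq) {
      absent <- list(left = NA_character_, left_off = NA_integer_,
                     right = NA_character_, right_off = NA_integer_)
      if (score < 1 || is.na(tx)) {
        inform(sprintf("no linear reference for score-%d candidate %s:%d-%d",
                       score, chrom, start, end))
        return(absent)
      }
      ex <- arrange(exons_by_tx[[tx]], .data$start)
      first_ov <- which(ex$end > start)[1]
      last_ov <- max(which(ex$start < end))
      ## neighbours in genomic order; transcript 5' neighbour depends on strand
      before <- if (first_ov > 1) ex[first_ov - 1L, ] else NULL
      after <- if (last_ov < nrow(ex)) ex[last_ov + 1L, ] else NULL
      if (strand == "+") { up <- before; down <- after } else { up <- after; down <- before }
      k <- min(W, nchar(cseq))
      out <- absent
      if (!is.null(up)) {
        up_seq <- get_seq(genome, chrom, up$start, up$end)
        if (strand == "-") up_seq <- revcomp(up_seq)
        out$left <- paste0(up_seq, substr(cseq, 1L, k))
        out$left_off <- nchar(up_seq) - 1L
      }
      if (!is.null(down)) {
        down_seq <- get_seq(genome, chrom, down$start, down$end)
        if (strand == "-") down_seq <- revcomp(down_seq)
        out$right <- paste0(substr(cseq, nchar(cseq) - k + 1L, nchar(cseq)),
                            down_seq)
        out$right_off <- k - 1L
      }
      out
    }
  )
  tibble(
    circ_id = asg$circ_id,
    chrom = asg$chrom, start = asg$start, end = asg$end,
    strand = asg$strand, transcript_id = asg$transcript_id,
    score = asg$score, circle_length = asg$circle_length,
    window = win$window, window_offset = win$junction_offset,
    linear_left = purrr::map_chr(lin, "left"),
    linear_left_offset = purrr::map_int(lin, "left_off"),
    linear_right = purrr::map_chr(lin, "right"),
    linear_right_offset = purrr::map_int(lin, "right_off")
  )
}

#' Write junction references to FASTA plus an offsets table
#'
#' Emits `circular.fa`, `linear_left.fa`, `linear_right.fa` (60-column
#' wrapped, headers = `circ_id`; absent linear references are simply
#' omitted from their file) and `offsets.tsv` holding the junction
#' offsets and window metadata. The output round-trips losslessly
#' through [read_reference_fasta()].
#'
#' @param refs Reference tibble from [build_junction_references()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference_fasta <- function(refs, dir) {
  if (anyDuplicated(refs$circ_id)) abort("duplicate circ_id in references")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(seqs, ids, file) {
    keep <- !is.na(seqs)
    ss <- Biostrings::DNAStringSet(setNames(seqs[keep], ids[keep]))
    Biostrings::writeXStringSet(ss, file.path(dir, file), width = 60L)
  }
  write_one(refs$window, refs$circ_id, "circular.fa")
  write_one(refs$linear_left, refs$circ_id, "linear_left.fa")
  write_one(refs$linear_right, refs$circ_id, "linear_right.fa")
  meta <- refs |>
    select("circ_id", "chrom", "start", "end", "strand", "transcript_id",
           "score", "circle_length", "window_offset", "linear_left_offset",
           "linear_right_offset") |>
    mutate(window_len = nchar(refs$window))
  write_tsv_meta(meta, file.path(dir, "offsets.tsv"))
  invisible(dir)
}

#' Read junction references written by [write_reference_fasta()]
#'
#' @param dir Directory holding `circular.fa`, `linear_left.fa`,
#'   `linear_right.fa` and `offsets.tsv`.
#' @return A reference tibble in the layout of
#'   [build_junction_references()].
#' @export
read_reference_fasta <- function(dir) {
  meta <- read_tsv_meta(file.path(dir, "offsets.tsv"))
  grab <- function(file) {
    ss <- Biostrings::readDNAStringSet(file.path(dir, file))
    setNames(as.character(ss), names(ss))
  }
  circ <- grab("circular.fa")
  ll <- grab("linear_left.fa")
  lr <- grab("linear_right.fa")
  if (nrow(meta) == 0) {
    return(mutate(meta, window = character(0), linear_left = character(0),
                  linear_right = character(0)))
  }
  meta |>
    mutate(
      transcript_id = as.character(.data$transcript_id),
      window = unname(circ[.data$circ_id]),
      linear_left = unname(ll[.data$circ_id]),
      linear_right = unname(lr[.data$circ_id])
    ) |>
    select("circ_id", "chrom", "start", "end", "strand", "transcript_id",
           "score", "circle_length", "window", window_offset = "window_offset",
           "linear_left", "linear_left_offset",
           "linear_right", "linear_right_offset")
}

#' Spliced transcript sequences for the whole annotation
#'
#' Builds the linear transcriptome used by the exclusion filter: the
#' spliced (exon-concatenated) sequence of every annotated transcript,
#' reverse-complemented for minus-strand transcripts so each reads
#' 5'->3'.
#'
#' @param annotation Exon tibble.
#' @param genome Named `DNAStringSet`.
#' @return A named `DNAStringSet`, one sequence per transcript.
#' @export
extract_transcriptome <- function(annotation, genome) {
  txs <- split(annotation, annotation$transcript_id)
  seqs <- vapply(txs, function(ex) {
    ex <- arrange(ex, .data$start)
    s <- paste(purrr::map2_chr(ex$start, ex$end,
                               ~ get_seq(genome, ex$chrom[1], .x, .y)),
               collapse = "")
    if (ex$strand[1] == "-") revcomp(s) else s
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}
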