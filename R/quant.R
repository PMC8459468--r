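## mismatch count between equal-width string pairs; any N (either side)
## counts as a mismatch, so N never matches anything
count_mismatches <- function(x, y) {
  n <- length(x)
  if (n == 0) return(integer(0))
  w <- nchar(x)
  stopifnot(all(w == nchar(y)))
  out <- integer(n)
  for (width in unique(w)) {
    idx <- which(w == width)
    for (chunk in split(idx, ceiling(seq_along(idx) / 20000))) {
      A <- matrix(unlist(strsplit(x[chunk], "", fixed = TRUE),
                         use.names = FALSE), ncol = width, byrow = TRUE)
      B <- matrix(unlist(strsplit(y[chunk], "", fixed = TRUE),
                         use.names = FALSE), ncol = width, byrow = TRUE)
      out[chunk] <- as.integer(rowSums(A != B | A == "N" | B == "N"))
    }
  }
  out
}

## canonical in-memory read table: read_id, mate (0 = unpaired), seq
as_read_table <- function(reads, mate = 0L) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    if (!"mate" %in% names(reads)) reads$mate <- mate
    tb <- as_tibble(reads)
  } else if (inherits(reads, "XStringSet")) {
    tb <- tibble(read_id = sub("\\s.*$", "", names(reads)),
                 mate = mate, seq = unname(as.character(reads)))
  } else if (is.character(reads) && !is.null(names(reads))) {
    tb <- tibble(read_id = names(reads), mate = mate, seq = unname(reads))
  } else {
    abort("reads must be a tibble, a named character vector, or a DNAStringSet")
  }
  if (anyDuplicated(tb[c("read_id", "mate")])) {
    dup <- tb$read_id[duplicated(tb[c("read_id", "mate")])][1]
    abort(sprintf("read id '%s' occurs twice with the same mate index", dup))
  }
  tb
}

#' Read a FASTQ library into a read table
#'
#' @param paths One path (single-end) or two paths `c(R1, R2)`
#'   (paired-end); plain or gzip FASTQ.
#' @return Tibble with `read_id`, `mate` (0 for SE, 1/2 for PE; the
#'   trailing `/1`/`/2` is stripped from ids so mates share a fragment
#'   id) and `seq`.
#' @export
read_fastq <- function(paths) {
  stopifnot(length(paths) %in% c(1, 2))
  one <- function(p, mate) {
    ss <- Biostrings::readDNAStringSet(p, format = "fastq")
    tb <- as_read_table(ss, mate = mate)
    tb$read_id <- sub("/[12]$", "", tb$read_id)
    tb
  }
  if (length(paths) == 1) one(paths, 0L)
  else bind_rows(one(paths[1], 1L), one(paths[2], 2L))
}

## empty hit tibble
empty_hits <- function() {
  tibble(read_id = character(), mate = integer(), circ_id = character(),
         junction = character(), orientation = character(),
         align_offset = integer(), mismatches = integer())
}

#' Match reads to junction references with the seed rule
#'
#' A read supports a junction only if the junction is included in the
#' read: the read must have an ungapped placement on the reference
#' window covering at least `j` bases on each side of the junction, the
#' `2j` seed bases centred on the junction must match exactly, and at
#' most `m` mismatches are allowed over the rest of the read. `N` in
#' either read or reference counts as a mismatch everywhere. Among
#' multiple valid placements of a read on one reference, the placement
#' with fewest mismatches (ties: smallest offset) is kept.
#'
#' In `"forward"` strandedness only the read as given is matched (reads
#' are expected sense to the junction reference); `"unstranded"` also
#' tries the reverse complement.
#'
#' @param reads Read table (see [read_fastq()]), named character vector
#'   or `DNAStringSet`.
#' @param refs Reference tibble from [build_junction_references()].
#' @param kind Which junction to match: `"circular"`, `"linear_left"`
#'   or `"linear_right"`.
#' @param j Seed half-width in bases (default 5: a 10-base exact seed).
#' @param m Maximum mismatches outside the seed (default 2).
#' @param strandedness `"forward"` or `"unstranded"`.
#' @return A hit tibble: `read_id`, `mate`, `circ_id`, `junction`,
#'   `orientation`, `align_offset` (0-based placement of the read on
#'   the reference), `mismatches`.
#' @export
match_junction_reads <- function(reads, refs,
                                 kind = c("circular", "linear_left", "linear_right"),
                                 j = 5L, m = 2L,
                                 strandedness = c("forward", "unstranded")) {
  kind <- match.arg(kind)
  strandedness <- match.arg(strandedness)
  stopifnot(j >= 1, m >= 0)
  reads <- as_read_table(reads)
  if (nrow(reads) == 0 || nrow(refs) == 0) return(empty_hits())

  seq_col <- switch(kind, circular = "window", linear_left = "linear_left",
                    linear_right = "linear_right")
  off_col <- switch(kind, circular = "window_offset",
                    linear_left = "linear_left_offset",
                    linear_right = "linear_right_offset")

  L <- nchar(reads$seq)
  too_short <- L < 2L * j
  sets <- list(forward = Biostrings::DNAStringSet(reads$seq))
  if (strandedness == "unstranded") {
    sets$reverse <- Biostrings::reverseComplement(sets$forward)
  }
  read_chars <- purrr::map(sets, as.character)

  rows <- list()
  for (r in seq_len(nrow(refs))) {
    rseq <- refs[[seq_col]][r]
    off0 <- refs[[off_col]][r]
    if (is.na(rseq) || is.na(off0)) next
    ss <- off0 - j + 2L          # 1-based seed start on the reference
    se <- off0 + j + 1L
    if (ss < 1L || se > nchar(rseq)) next
    seed <- substr(rseq, ss, se)
    if (grepl("N", seed, fixed = TRUE)) next
    for (ori in names(sets)) {
      mi <- Biostrings::vmatchPattern(seed, sets[[ori]], fixed = TRUE)
      nhit <- S4Vectors::elementNROWS(mi)
      if (sum(nhit) == 0) next
      ridx <- rep(seq_along(nhit), nhit)
      q <- BiocGenerics::start(unlist(mi, use.names = FALSE))
      keep <- !too_short[ridx]
      ridx <- ridx[keep]; q <- q[keep]
      if (length(ridx) == 0) next
      p <- ss - q + 1L                         # read start on the reference
      Lr <- L[ridx]
      ok <- p >= 1L & p + Lr - 1L <= nchar(rseq)
      ridx <- ridx[ok]; p <- p[ok]; Lr <- Lr[ok]
      if (length(ridx) == 0) next
      refsub <- substr(rep(rseq, length(p)), p, p + Lr - 1L)
      mm <- count_mismatches(read_chars[[ori]][ridx], refsub)
      ok <- mm <= m
      if (!any(ok)) next
      rows[[length(rows) + 1]] <- tibble(
        read_id = reads$read_id[ridx[ok]], mate = reads$mate[ridx[ok]],
        circ_id = refs$circ_id[r], junction = kind, orientation = ori,
        align_offset = p[ok] - 1L, mismatches = mm[ok]
      )
    }
  }
  if (length(rows) == 0) return(empty_hits())
  bind_rows(rows) |>
    group_by(.data$read_id, .data$mate, .data$circ_id) |>
    arrange(.data$mismatches, .data$align_offset,
            .data$orientation, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Match one read against one junction reference
#'
#' Scalar convenience wrapper around [match_junction_reads()].
#'
#' @param read A single read sequence (character scalar).
#' @param ref One-row reference tibble.
#' @inheritParams match_junction_reads
#' @return A one-row hit tibble, or a zero-row tibble when the read does
#'   not support the junction.
#' @export
match_read_to_junction <- function(read, ref, kind = "circular",
                                   j = 5L, m = 2L, strandedness = "forward") {
  match_junction_reads(c(read_1 = read), ref[1, , drop = FALSE], kind = kind,
                       j = j, m = m, strandedness = strandedness)
}

#' Find ungapped end-to-end placements of reads in a sequence set
#'
#' Tests, for each read, whether it has at least one ungapped full-length
#' placement with at most `m` mismatches anywhere in `subjects` (both
#' strands by default). Placements are found by pigeonhole k-mer
#' seeding: the read is split into `m + 1` disjoint blocks of width
#' `k = floor(L / (m + 1))`; any placement with <= `m` mismatches must
#' contain at least one exact block, so exact block matches enumerate
#' every candidate placement, which is then verified base by base
#' (N counting as mismatch).
#'
#' @param reads Read table, named character vector or `DNAStringSet`.
#' @param subjects Named `DNAStringSet` (genome chromosomes or spliced
#'   transcripts).
#' @param m Maximum mismatches for a placement.
#' @param both_strands Also search the reverse complement of each
#'   subject.
#' @return Logical vector, one element per read (in input order).
#' @export
find_end_to_end_placements <- function(reads, subjects, m = 2L,
                                       both_strands = TRUE) {
  reads <- as_read_table(reads)
  n <- nrow(reads)
  placed <- rep(FALSE, n)
  if (n == 0 || length(subjects) == 0) return(placed)
  widths <- nchar(reads$seq)

  subj_chr <- as.character(subjects)
  strands <- if (both_strands) c("+", "-") else "+"
  subj_by_strand <- list("+" = subj_chr)
  if (both_strands) {
    subj_by_strand[["-"]] <- as.character(Biostrings::reverseComplement(subjects))
  }

  for (L in unique(widths)) {
    stopifnot(L >= m + 1L)
    idx <- which(widths == L)
    k <- L %/% (m + 1L)
    seg_off <- (0:m) * k                       # 0-based block offsets in read
    segs <- character(0)
    seg_read <- integer(0)
    seg_o <- integer(0)
    for (s in seg_off) {
      piece <- substr(reads$seq[idx], s + 1L, s + k)
      usable <- !grepl("N", piece, fixed = TRUE)
      segs <- c(segs, piece[usable])
      seg_read <- c(seg_read, idx[usable])
      seg_o <- c(seg_o, rep(s, sum(usable)))
    }
    if (length(segs) == 0) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(segs))
    for (si in seq_along(subjects)) {
      for (st in strands) {
        S <- subj_by_strand[[st]][si]
        mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(S))
        nhit <- S4Vectors::elementNROWS(mi)
        if (sum(nhit) == 0) next
        pat <- rep(seq_along(nhit), nhit)
        hs <- BiocGenerics::start(unlist(mi, use.names = FALSE))
        cand_read <- seg_read[pat]
        cand_start <- hs - seg_o[pat]           # 1-based read start on subject
        ok <- cand_start >= 1L & cand_start + L - 1L <= nchar(S) &
          !placed[cand_read]
        cand_read <- cand_read[ok]; cand_start <- cand_start[ok]
        if (length(cand_read) == 0) next
        key <- paste(cand_read, cand_start)
        first <- !duplicated(key)
        cand_read <- cand_read[first]; cand_start <- cand_start[first]
        refsub <- substr(rep(S, length(cand_start)),
                         cand_start, cand_start + L - 1L)
        mm <- count_mismatches(reads$seq[cand_read], refsub)
        placed[cand_read[mm <= m]] <- TRUE
      }
    }
  }
  placed
}

#' Exclude circular hits whose reads align linearly
#'
#' A read supporting a backsplice junction must not be explainable by
#' the linear world: any read with an ungapped end-to-end placement
#' (<= `m` mismatches, either strand) in the genome or in the spliced
#' linear transcriptome is discarded. The survivors are the confirmed
#' circular junction reads.
#'
#' @param hits Hit tibble from [match_junction_reads()] (circular kind).
#' @param reads The read table the hits refer to.
#' @param genome Named `DNAStringSet` of genome sequences.
#' @param transcriptome Named `DNAStringSet` of spliced transcripts
#'   (see [extract_transcriptome()]).
#' @param m Maximum mismatches for an excluding placement.
#' @return The retained hits, with attributes `n_excluded_genome` and
#'   `n_excluded_transcriptome` (distinct reads removed by each filter).
#' @export
exclusion_filter <- function(hits, reads, genome, transcriptome, m = 2L) {
  reads <- as_read_table(reads)
  if (nrow(hits) == 0) {
    attr(hits, "n_excluded_genome") <- 0L
    attr(hits, "n_excluded_transcriptome") <- 0L
    return(hits)
  }
  sub <- reads |>
    semi_join(hits, by = c("read_id", "mate"))
  placed_g <- find_end_to_end_placements(sub, genome, m = m)
  placed_t <- find_end_to_end_placements(sub, transcriptome, m = m)
  bad_g <- sub[placed_g, c("read_id", "mate")]
  bad_t <- sub[placed_t & !placed_g, c("read_id", "mate")]
  out <- hits |>
    anti_join(bind_rows(bad_g, bad_t), by = c("read_id", "mate"))
  attr(out, "n_excluded_genome") <- nrow(bad_g)
  attr(out, "n_excluded_transcriptome") <- nrow(bad_t)
  out
}

new_circ_counts <- function(x, library_id = NA_character_,
                            library_size = NA_real_, stats = list()) {
  x <- as_tibble(x)
  class(x) <- c("circ_counts", class(x))
  attr(x, "library_id") <- library_id
  attr(x, "library_size") <- library_size
  attr(x, "stats") <- stats
  x
}

#' Count junction-supporting fragments per circRNA
#'
#' Fragment-level counting of retained hits: for paired-end data the two
#' mates of a fragment hitting the same junction contribute a single
#' count, never two. A fragment hitting more than one distinct circRNA
#' for the same junction kind is discarded as ambiguous. After counting,
#' the multiset of counted (fragment, junction) pairs is asserted to be
#' duplicate-free.
#'
#' @param hits Hit tibble (any mix of junction kinds) surviving
#'   [exclusion_filter()].
#' @param circ_ids Character vector giving the full circRNA universe for
#'   zero-filling (defaults to the ids present in `hits`).
#' @return A `circ_counts` tibble: `circ_id`, `circ_count`,
#'   `linear_left_count`, `linear_right_count`; the number of discarded
#'   ambiguous fragments is in `attr(, "stats")$n_ambiguous` and the
#'   audited (fragment, junction) pairs in `attr(, "counted")`.
#' @export
count_junctions <- function(hits, circ_ids = NULL) {
  if (is.null(circ_ids)) circ_ids <- sort(unique(hits$circ_id))
  frag <- hits |>
    distinct(.data$read_id, .data$circ_id, .data$junction)
  amb <- frag |>
    group_by(.data$read_id, .data$junction) |>
    filter(n_distinct(.data$circ_id) > 1) |>
    ungroup()
  n_ambiguous <- amb |>
    filter(.data$junction == "circular") |>
    distinct(.data$read_id) |>
    nrow()
  counted <- frag |> anti_join(amb, by = c("read_id", "junction"))
  if (anyDuplicated(counted[c("read_id", "circ_id", "junction")]) > 0) {
    abort("internal audit failed: a fragment was counted twice for one junction")
  }
  wide <- counted |>
    count(.data$circ_id, .data$junction) |>
    tidyr::pivot_wider(names_from = "junction", values_from = "n",
                       values_fill = 0L)
  for (col in c("circular", "linear_left", "linear_right")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  out <- tibble(circ_id = circ_ids) |>
    left_join(wide, by = "circ_id") |>
    transmute(circ_id = .data$circ_id,
              circ_count = dplyr::coalesce(.data$circular, 0L),
              linear_left_count = dplyr::coalesce(.data$linear_left, 0L),
              linear_right_count = dplyr::coalesce(.data$linear_right, 0L))
  out <- new_circ_counts(out, stats = list(n_ambiguous = n_ambiguous))
  attr(out, "counted") <- counted
  out
}

#' Quantify a sequencing library against junction references
#'
#' Full quantification of one library: reads are matched to the
#' circular, `linear_left` and `linear_right` junction references with
#' the seed rule ([match_junction_reads()]); circular hits are passed
#' through the genome/transcriptome exclusion filter; surviving hits
#' are counted at fragment level ([count_junctions()]). The library
#' size recorded for normalization is the number of reads that found
#' any ungapped placement — genome, transcriptome, or a junction
#' reference.
#'
#' @param reads FASTQ path(s) (`c(R1, R2)` for paired-end), a read
#'   table, a named character vector or a `DNAStringSet`.
#' @param refs Reference tibble from [build_junction_references()].
#' @param genome Named `DNAStringSet`.
#' @param annotation Exon tibble; used to build the spliced linear
#'   transcriptome unless `transcriptome` is given directly.
#' @param transcriptome Optional pre-built `DNAStringSet` of spliced
#'   transcripts.
#' @param library_id Label stored with the counts.
#' @inheritParams match_junction_reads
#' @return A `circ_counts` tibble (see [count_junctions()]) with
#'   attributes `library_id`, `library_size`, `stats` (reads in,
#'   exclusion and ambiguity tallies) and `evidence` (the per-read hit
#'   report: read id, circRNA, junction kind, offset, mismatches).
#' @export
quantify_library <- function(reads, refs, genome, annotation = NULL,
                             transcriptome = NULL, library_id = "library",
                             j = 5L, m = 2L,
                             strandedness = c("forward", "unstranded")) {
  strandedness <- match.arg(strandedness)
  if (is.character(reads) && is.null(names(reads)) &&
      all(file.exists(reads))) {
    reads <- read_fastq(reads)
  }
  reads <- as_read_table(reads)
  if (is.null(transcriptome)) {
    if (is.null(annotation)) abort("supply either annotation or transcriptome")
    transcriptome <- extract_transcriptome(annotation, genome)
  }
  if (nrow(reads) == 0) {
    warn(sprintf("library '%s': no reads; emitting all-zero counts", library_id))
    out <- count_junctions(empty_hits(), circ_ids = refs$circ_id)
    attr(out, "library_id") <- library_id
    attr(out, "library_size") <- 0
    return(out)
  }

  hits_c <- match_junction_reads(reads, refs, "circular", j = j, m = m,
                                 strandedness = strandedness)
  hits_l <- match_junction_reads(reads, refs, "linear_left", j = j, m = m,
                                 strandedness = strandedness)
  hits_r <- match_junction_reads(reads, refs, "linear_right", j = j, m = m,
                                 strandedness = strandedness)

  placed_g <- find_end_to_end_placements(reads, genome, m = m)
  placed_t <- find_end_to_end_placements(reads, transcriptome, m = m)

  key <- paste(reads$read_id, reads$mate)
  hit_key <- paste(c(hits_c$read_id, hits_l$read_id, hits_r$read_id),
                   c(hits_c$mate, hits_l$mate, hits_r$mate))
  library_size <- sum(placed_g | placed_t | key %in% hit_key)

  excl_key <- key[placed_g | placed_t]
  retained_c <- hits_c |>
    filter(!paste(.data$read_id, .data$mate) %in% excl_key)
  n_exg <- length(unique(paste(hits_c$read_id, hits_c$mate)[
    paste(hits_c$read_id, hits_c$mate) %in% key[placed_g]]))
  n_ext <- length(unique(paste(hits_c$read_id, hits_c$mate)[
    paste(hits_c$read_id, hits_c$mate) %in% key[placed_t & !placed_g]]))

  all_hits <- bind_rows(retained_c, hits_l, hits_r)
  out <- count_junctions(all_hits, circ_ids = refs$circ_id)
  attr(out, "library_id") <- library_id
  attr(out, "library_size") <- library_size
  attr(out, "stats") <- c(attr(out, "stats"),
                          list(n_reads = nrow(reads),
                               n_excluded_genome = n_exg,
                               n_excluded_transcriptome = n_ext))
  attr(out, "evidence") <- all_hits
  inform(sprintf(
    "library '%s': %d reads in, %d aligned, %d circular hit-reads (%d excluded genome, %d excluded transcriptome, %d ambiguous)",
    library_id, nrow(reads), library_size,
    nrow(distinct(retained_c, .data$read_id, .data$mate)),
    n_exg, n_ext, attr(out, "stats")$n_ambiguous))
  out
}

#' @export
glance.circ_counts <- function(x, ...) {
  st <- attr(x, "stats") %||% list()
  tibble(
    library_id = attr(x, "library_id") %||% NA_character_,
    library_size = attr(x, "library_size") %||% NA_real_,
    n_junctions = nrow(x),
    total_circ = sum(x$circ_count),
    total_linear = sum(x$linear_left_count + x$linear_right_count),
    n_ambiguous = st$n_ambiguous %||% NA_integer_,
    n_excluded_genome = st$n_excluded_genome %||% NA_integer_,
    n_excluded_transcriptome = st$n_excluded_transcriptome %||% NA_integer_
  )
}
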