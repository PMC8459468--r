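#' Read an exon annotation from a GTF file
#'
#' Parses exon features from a GTF file (UCSC dialect, 1-based closed
#' coordinates) into the tidy exon table used throughout the package:
#' one row per exon, 0-based half-open coordinates, with `exon_rank`
#' numbering exons 5' to 3' along the transcript strand.
#'
#' Non-exon features are skipped. Exons missing a `gene_id` or
#' `transcript_id` attribute, and transcripts whose exons overlap one
#' another, are fatal errors.
#'
#' @param path Path to a GTF file (plain or gzip).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, `exon_rank`, sorted by transcript and
#'   genomic start.
#' @seealso [write_gtf()], [assign_transcripts()]
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(),
      transcript_id = character(), exon_rank = integer()
    ))
  }
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id)) {
    bad <- which(is.na(md$gene_id) | is.na(md$transcript_id))[1]
    abort(sprintf(
      "GTF exon record %d lacks a gene_id/transcript_id attribute", bad %||% 1
    ))
  }
  ex <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id)
  )
  if (any(!ex$strand %in% c("+", "-"))) {
    abort("GTF exon records must carry strand '+' or '-'")
  }
  ex <- ex |> arrange(.data$transcript_id, .data$start)
  bad_tx <- ex |>
    group_by(.data$transcript_id) |>
    summarise(overlap = any(.data$start[-1] < head(.data$end, -1)),
              .groups = "drop") |>
    filter(.data$overlap)
  if (nrow(bad_tx) > 0) {
    abort(sprintf("overlapping exons within transcript(s): %s",
                  paste(bad_tx$transcript_id, collapse = ", ")))
  }
  rank_exons(ex)
}

## assign exon_rank 1..n along the transcript strand (5' -> 3')
rank_exons <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "+") seq_len(n()) else rev(seq_len(n()))) |>
    ungroup() |>
    arrange(.data$transcript_id, .data$start)
}

#' Write an exon table to GTF
#'
#' Inverse of [read_gtf()]: converts internal 0-based half-open exon
#' intervals back to 1-based closed GTF exon lines.
#'
#' @param exons Exon tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  lines <- sprintf(
    '%s\tbacksplicer\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Coordinate dialects for candidate lists
#'
#' Upstream circRNA-detection pipelines disagree on coordinate
#' conventions. A dialect name declares how a pipeline's (start, end)
#' pair maps onto the internal 0-based half-open convention:
#' * `"bed"` — 0-based half-open (BED); identity.
#' * `"one_based_closed"` — 1-based fully closed; start is shifted down
#'   by one.
#'
#' @param x Tibble with integer `start` and `end` columns.
#' @param dialect Dialect name.
#' @return `x` with coordinates normalized to 0-based half-open.
#' @export
normalize_coordinates <- function(x, dialect) {
  shift <- switch(dialect,
    bed = 0L,
    one_based_closed = 1L,
    abort(sprintf("unknown coordinate dialect '%s'", dialect))
  )
  mutate(x, start = .data$start - shift)
}

#' Read a BED6 candidate list from one detection pipeline
#'
#' Reads a six-column BED-like file of backsplice-junction candidates
#' (chrom, start, end, name, score, strand). The `score` column is taken
#' as the pipeline's read count when numeric ("." otherwise). Records
#' with strand "." are rejected with a warning — the backsplice strand is
#' semantically required. Malformed records (non-numeric coordinates,
#' start >= end after normalization) are skipped with a warning; the
#' number rejected is recorded in the `rejected` attribute.
#'
#' @param path Path to a BED6 TSV (plain or gzip), `#` comments allowed.
#' @param pipeline Name of the pipeline that produced the list.
#' @param dialect Coordinate dialect; see [normalize_coordinates()].
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `pipeline`, `count`, in internal coordinates.
#' @export
read_candidates_bed <- function(path, pipeline, dialect = "bed") {
  ## validate dialect before touching the file: unknown dialect is fatal
  normalize_coordinates(tibble(start = integer(), end = integer()), dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), pipeline = character(),
                  count = integer())
    attr(out, "rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_rejected <- 0L
  rows <- purrr::map(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 6) {
      n_rejected <<- n_rejected + 1L
      warn(sprintf("%s line %d: fewer than 6 columns, skipped", path, i))
      return(NULL)
    }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      n_rejected <<- n_rejected + 1L
      warn(sprintf("%s line %d: non-numeric coordinates, skipped", path, i))
      return(NULL)
    }
    if (!f[6] %in% c("+", "-")) {
      n_rejected <<- n_rejected + 1L
      warn(sprintf("%s line %d: strand '%s' rejected (strand required)",
                   path, i, f[6]))
      return(NULL)
    }
    tibble(chrom = f[1], start = s, end = e, strand = f[6],
           count = suppressWarnings(as.integer(f[5])))
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- normalize_coordinates(out, dialect)
    keep <- out$start < out$end
    if (any(!keep)) {
      n_rejected <- n_rejected + sum(!keep)
      warn(sprintf("%s: %d record(s) with start >= end skipped",
                   path, sum(!keep)))
      out <- out[keep, ]
    }
    out <- mutate(out, pipeline = pipeline, .before = "count")
  }
  attr(out, "rejected") <- n_rejected
  out
}

#' Write a tibble as TSV with a commented metadata header
#'
#' All tabular outputs of the package use plain TSV with `#`-prefixed
#' header lines carrying run metadata, so files are self-describing and
#' round-trip through [read_tsv_meta()].
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param meta Named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path Path to the TSV.
#' @return A tibble; metadata lines are parsed into the `meta` attribute
#'   (a named character vector).
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^# ", lines)
  meta <- character()
  if (any(is_meta)) {
    kv <- sub("^# ", "", lines[is_meta])
    keys <- sub("=.*$", "", kv)
    meta <- setNames(sub("^[^=]*=", "", kv), keys)
  }
  body <- lines[!is_meta]
  x <- if (length(body) <= 1 && (length(body) == 0 || !nzchar(body))) {
    tibble()
  } else {
    as_tibble(utils::read.table(text = body, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                check.names = FALSE))
  }
  attr(x, "meta") <- meta
  x
}

#' Write a junction count table to TSV
#'
#' @param counts A `circ_counts` tibble from [quantify_library()] or
#'   [count_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  write_tsv_meta(
    as_tibble(counts), path,
    meta = list(library_id = attr(counts, "library_id") %||% NA,
                library_size = attr(counts, "library_size"))
  )
}

#' Read a junction count table written by [write_count_table()]
#'
#' @param path Path to the TSV.
#' @return A `circ_counts` tibble with `library_id` and `library_size`
#'   attributes restored.
#' @export
read_count_table <- function(path) {
  x <- read_tsv_meta(path)
  meta <- attr(x, "meta")
  new_circ_counts(x,
                  library_id = meta[["library_id"]],
                  library_size = as.numeric(meta[["library_size"]]))
}

#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline with its default. The defaults
#' are: seed half-width `j = 5` bases each side of the junction (10-base
#' exact seed total), `m = 2` mismatches allowed outside the seed,
#' junction window half-width `W = 70` bases (one read length),
#' classification cutoff `c = 0.9`, `min_mock = 1` read, DE matrix filter
#' `min_reads = 2`, forward-stranded matching, exact-coordinate merging
#' (`tolerance = 0`).
#'
#' @param ... Overrides for any default field. Unknown keys are rejected.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    j = 5L, m = 2L, W = 70L, cutoff = 0.9, min_mock = 1L, min_reads = 2L,
    strandedness = "forward", tolerance = 0L, pairing = "SE",
    seed = 1L, dialects = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown run_config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}
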