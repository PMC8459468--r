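#' Configuration for the synthetic circRNA study generator
#'
#' Bundles every knob of the toy-data generator with its default. The
#' defaults describe the validation study the package is tested under:
#' a random two-chromosome genome of 120 single-transcript genes (2-8
#' exons of 150-300 bases, introns of 60-150 bases), 50 planted true
#' circles (exon-boundary aligned) and 50 decoy junctions
#' (boundary-shifted or intergenic), 70-base single-end reads with 64
#' junction-spanning reads planted per junction and 100 linear reads
#' per host gene, and an RNase R treatment that keeps each circular
#' read with probability 0.9 and each linear or decoy read with
#' probability 0.05. Setting `set_halving = TRUE` with `n_sets = 7` and
#' `reads_per_circle_set1 = 640` reproduces the serial-dilution design
#' in which each read set carries half the circular reads of the one
#' before (640, 320, ..., 10).
#'
#' @param seed Integer RNG seed; every random choice of the generator
#'   derives from it.
#' @param n_chroms,n_genes Genome layout.
#' @param exons_per_gene,exon_length,intron_length,intergenic Integer
#'   ranges `c(min, max)` in exons / bases.
#' @param n_true_circles,n_decoys Number of planted true and decoy
#'   junctions.
#' @param frac_intergenic_decoys Fraction of decoys placed in
#'   intergenic space (the rest are boundary-shifted within genes).
#' @param read_length Read length in bases (default 70).
#' @param n_sets Number of read sets; `set_halving` halves the planted
#'   junction reads per set.
#' @param reads_per_circle_set1 Junction-spanning reads planted per
#'   junction in set 1.
#' @param linear_reads_per_gene Reads drawn uniformly from each host
#'   gene's spliced transcript, per set.
#' @param survival_circ,survival_linear Per-read survival probabilities
#'   under RNase R for circular junction reads and for linear/decoy
#'   reads.
#' @param pairing `"SE"` or `"PE"`.
#' @param fragment_length PE fragment length in bases.
#' @param min_junction_overlap Minimum bases a planted junction read
#'   keeps on each side of the junction (default 5, one seed
#'   half-width, so every planted read is countable).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, n_genes = 120L,
                       exons_per_gene = c(2L, 8L),
                       exon_length = c(150L, 300L),
                       intron_length = c(60L, 150L),
                       intergenic = c(200L, 400L),
                       n_true_circles = 50L, n_decoys = 50L,
                       frac_intergenic_decoys = 0.2,
                       read_length = 70L,
                       n_sets = 1L, set_halving = FALSE,
                       reads_per_circle_set1 = 64L,
                       linear_reads_per_gene = 100L,
                       survival_circ = 0.9, survival_linear = 0.05,
                       pairing = c("SE", "PE"), fragment_length = 150L,
                       min_junction_overlap = 5L) {
  pairing <- match.arg(pairing)
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              n_genes = n_genes, exons_per_gene = exons_per_gene,
              exon_length = exon_length, intron_length = intron_length,
              intergenic = intergenic, n_true_circles = n_true_circles,
              n_decoys = n_decoys,
              frac_intergenic_decoys = frac_intergenic_decoys,
              read_length = read_length, n_sets = n_sets,
              set_halving = set_halving,
              reads_per_circle_set1 = reads_per_circle_set1,
              linear_reads_per_gene = linear_reads_per_gene,
              survival_circ = survival_circ,
              survival_linear = survival_linear, pairing = pairing,
              fragment_length = fragment_length,
              min_junction_overlap = min_junction_overlap)
  stopifnot(
    survival_circ >= 0, survival_circ <= 1,
    survival_linear >= 0, survival_linear <= 1,
    read_length >= 2L * min_junction_overlap,
    exon_length[1] <= exon_length[2], exon_length[1] > 0,
    intron_length[1] <= intron_length[2], intron_length[1] > 0,
    exons_per_gene[1] >= 1, exons_per_gene[1] <= exons_per_gene[2]
  )
  structure(cfg, class = "sim_config")
}

rand_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a toy genome and exon annotation
#'
#' Builds a random genome with non-overlapping single-transcript genes
#' laid out left to right on each chromosome, separated by intergenic
#' gaps, with random strands. The output is deterministic for a given
#' config seed (two calls produce byte-identical FASTA and GTF files).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; writes `genome.fa` and
#'   `annotation.gtf` there.
#' @return List with `genome` (named `DNAStringSet`), `annotation`
#'   (exon tibble as from [read_gtf()]), and `files` (paths, when `dir`
#'   is given).
#' @export
make_toy_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes_per_chrom <- diff(c(0, round(seq_len(config$n_chroms) *
                                       config$n_genes / config$n_chroms)))
  exon_rows <- list()
  chrom_len <- integer(config$n_chroms)
  g <- 0L
  for (ci in seq_len(config$n_chroms)) {
    pos <- 0L
    for (gi in seq_len(genes_per_chrom[ci])) {
      g <- g + 1L
      pos <- pos + rand_int(1, config$intergenic)
      n_ex <- rand_int(1, config$exons_per_gene)
      ex_len <- rand_int(n_ex, config$exon_length)
      in_len <- if (n_ex > 1) rand_int(n_ex - 1, config$intron_length) else integer(0)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      strand <- sample(c("+", "-"), 1)
      gene_id <- sprintf("g%03d", g)
      exon_rows[[g]] <- tibble(
        chrom = sprintf("chr%d", ci), start = as.integer(starts),
        end = as.integer(ends), strand = strand, gene_id = gene_id,
        transcript_id = paste0(gene_id, ".t1")
      )
      pos <- ends[n_ex]
    }
    chrom_len[ci] <- pos + rand_int(1, config$intergenic)
  }
  annotation <- rank_exons(bind_rows(exon_rows))
  genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- sprintf("chr%d", seq_len(config$n_chroms))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(genome, fa, width = 60L)
    write_gtf(annotation, gtf)
    files <- c(genome = fa, annotation = gtf)
  }
  list(genome = genome, annotation = annotation, files = files)
}

#' Plant true circles and decoy junctions in a toy annotation
#'
#' True circles are exon-boundary-aligned spans over interior exons of
#' a host gene, so they score 2 by construction. Decoys emulate
#' pipeline false positives: junctions whose boundaries are shifted
#' 1-10 bases off the exon boundaries (score 1 when one side is
#' shifted, 0 when both are) or placed in intergenic space (score 0).
#' Each eligible gene hosts at most one junction, and decoy reads are
#' later depleted like linear reads by the simulated RNase R treatment.
#' Pipeline provenance is fabricated for diagnostics: true circles are
#' "reported" by 3-5 of 5 pipelines, decoys by 1-2.
#'
#' @param annotation Exon tibble from [make_toy_genome()].
#' @param config A [sim_config()].
#' @return Truth tibble: `chrom`, `start`, `end`, `strand`, `circ_id`,
#'   `type` (`circle`/`decoy`), `host_gene` (`NA` for intergenic
#'   decoys), `n_pipelines`, `pipelines`.
#' @export
plant_circles <- function(annotation, config) {
  set.seed(config$seed + 1L)
  ## interior spans need an exon on each side: genes with >= 3 exons
  genes <- annotation |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              n_ex = n(), .groups = "drop") |>
    filter(.data$n_ex >= 3)
  n_intg <- round(config$n_decoys * config$frac_intergenic_decoys)
  n_genic_decoys <- config$n_decoys - n_intg
  need <- config$n_true_circles + n_genic_decoys
  if (nrow(genes) < need) {
    abort(sprintf("only %d genes with >= 3 exons; %d hosts needed",
                  nrow(genes), need))
  }
  hosts <- genes[sample.int(nrow(genes)), ][seq_len(need), ]
  ex_by_gene <- split(annotation, annotation$gene_id)

  span_over <- function(gene_id) {
    ex <- arrange(ex_by_gene[[gene_id]], .data$start)
    i <- sample(2:(nrow(ex) - 1), 1)
    jj <- if (i < nrow(ex) - 1) sample(i:(nrow(ex) - 1), 1) else i
    c(ex$start[i], ex$end[jj])
  }

  rows <- list()
  for (t in seq_len(config$n_true_circles)) {
    h <- hosts[t, ]
    sp <- span_over(h$gene_id)
    rows[[length(rows) + 1]] <- tibble(
      chrom = h$chrom, start = sp[1], end = sp[2], strand = h$strand,
      type = "circle", host_gene = h$gene_id
    )
  }
  for (d in seq_len(n_genic_decoys)) {
    h <- hosts[config$n_true_circles + d, ]
    sp <- span_over(h$gene_id)
    mode <- sample(c("start", "end", "both"), 1)
    shift <- sample(1:10, 2, replace = TRUE)
    if (mode %in% c("start", "both")) sp[1] <- sp[1] + shift[1]
    if (mode %in% c("end", "both")) sp[2] <- sp[2] - shift[2]
    rows[[length(rows) + 1]] <- tibble(
      chrom = h$chrom, start = sp[1], end = sp[2], strand = h$strand,
      type = "decoy", host_gene = h$gene_id
    )
  }
  if (n_intg > 0) {
    ## gaps between consecutive genes, large enough for a short span
    gaps <- annotation |>
      group_by(.data$chrom, .data$gene_id) |>
      summarise(gs = min(.data$start), ge = max(.data$end), .groups = "drop") |>
      group_by(.data$chrom) |>
      arrange(.data$gs, .by_group = TRUE) |>
      mutate(gap_start = .data$ge + 10L,
             gap_end = lead(.data$gs) - 10L) |>
      ungroup() |>
      filter(!is.na(.data$gap_end), .data$gap_end - .data$gap_start >= 120L)
    if (nrow(gaps) < n_intg) abort("not enough intergenic space for decoys")
    pick <- gaps[sample.int(nrow(gaps)), ][seq_len(n_intg), ]
    for (d in seq_len(n_intg)) {
      gp <- pick[d, ]
      len <- sample(100:min(300, gp$gap_end - gp$gap_start), 1)
      s <- gp$gap_start + sample.int(gp$gap_end - gp$gap_start - len + 1, 1) - 1L
      rows[[length(rows) + 1]] <- tibble(
        chrom = gp$chrom, start = s, end = s + len,
        strand = sample(c("+", "-"), 1),
        type = "decoy", host_gene = NA_character_
      )
    }
  }
  truth <- bind_rows(rows)
  n_pipes <- ifelse(truth$type == "circle",
                    sample(3:5, nrow(truth), replace = TRUE),
                    sample(1:2, nrow(truth), replace = TRUE))
  truth |>
    mutate(
      circ_id = sprintf("%s:%d-%d:%s", .data$chrom, .data$start, .data$end,
                        .data$strand),
      n_pipelines = n_pipes,
      pipelines = purrr::map_chr(n_pipes, ~ paste0("p", seq_len(.x),
                                                   collapse = ","))
    ) |>
    select("chrom", "start", "end", "strand", "circ_id", "type",
           "host_gene", "n_pipelines", "pipelines")
}

## one batch of junction-spanning reads from a circle sequence; start
## positions uniform over placements keeping >= ov bases on each side
## of the junction and at most one junction copy in the read
junction_reads <- function(cseq, n, L, ov) {
  clen <- nchar(cseq)
  lo <- max(ov, L - clen)
  hi <- min(L - ov, clen)
  if (lo > hi) {
    abort(sprintf("read length %d incompatible with circle of %d bases", L, clen))
  }
  a <- sample(lo:hi, n, replace = TRUE)   # bases kept left of the junction
  big <- strrep(cseq, 2L)
  substr(rep(big, n), clen - a + 1L, clen - a + L)
}

#' Simulate mock and RNase R read libraries with a truth ledger
#'
#' For every planted junction (circle or decoy) and every read set,
#' plants junction-spanning reads with uniform random start positions
#' constrained to keep at least `min_junction_overlap` bases on each
#' side of the junction; linear reads are drawn uniformly from the
#' spliced transcript of each host gene. The mock library holds every
#' planted read; the RNase R library keeps each circular read with
#' probability `survival_circ` and each decoy/linear read with
#' probability `survival_linear` (decoys behave like linear RNA — that
#' is what makes them decoys). With `set_halving`, set `s` plants
#' `round(reads_per_circle_set1 / 2^(s-1))` junction reads per
#' junction. Read ids encode origin, class and set for audit, and every
#' decision is recorded in the ledger.
#'
#' @param truth Truth tibble from [plant_circles()].
#' @param annotation,genome Toy annotation and genome from
#'   [make_toy_genome()].
#' @param config A [sim_config()].
#' @param dir Optional directory: writes
#'   `set{s}_{mock|rnaser}[_R1|_R2].fastq.gz` plus `truth.json`.
#' @return List with `truth`, `ledger` (one row per planted read:
#'   `read_id`, `origin`, `class`, `set`, `in_mock`, `in_rnaser`),
#'   `planted` (per junction x set planted/surviving junction-read
#'   counts), `libraries` (nested list `[[set]][[mock|rnaser]]` of read
#'   tables), and `files` (tibble of written paths, when `dir` given).
#' @export
generate_reads <- function(truth, annotation, genome, config, dir = NULL) {
  set.seed(config$seed + 2L)
  L <- config$read_length
  ov <- config$min_junction_overlap
  pe <- config$pairing == "PE"

  asg <- assign_transcripts(truth, annotation)
  asg <- circle_sequence(asg, genome)
  cseq_of <- setNames(asg$circle_seq, asg$circ_id)
  full_tx <- extract_transcriptome(annotation, genome)
  hosts <- unique(stats::na.omit(truth$host_gene))
  tx_seq <- NULL
  if (length(hosts) > 0) {
    host_ann <- filter(annotation, .data$gene_id %in% hosts)
    tx <- extract_transcriptome(host_ann, genome)
    gene_of <- host_ann |> distinct(.data$gene_id, .data$transcript_id)
    tx_seq <- setNames(as.character(tx)[gene_of$transcript_id], gene_of$gene_id)
  }

  ledger <- list()
  libraries <- list()
  files <- list()
  planted <- list()
  for (s in seq_len(config$n_sets)) {
    n_j <- if (config$set_halving) {
      as.integer(round(config$reads_per_circle_set1 / 2^(s - 1)))
    } else {
      config$reads_per_circle_set1
    }
    set_rows <- list()
    for (e in seq_len(nrow(asg))) {
      if (n_j == 0) break
      frag_len <- if (pe) config$fragment_length else L
      frs <- junction_reads(asg$circle_seq[e], n_j, frag_len, ov)
      set_rows[[length(set_rows) + 1]] <- tibble(
        origin = asg$circ_id[e],
        class = ifelse(asg$type[e] == "circle", "circular", "decoy"),
        frag = frs
      )
    }
    for (gid in names(tx_seq)) {
      ts <- tx_seq[[gid]]
      frag_len <- if (pe) config$fragment_length else L
      if (nchar(ts) < frag_len) next
      n_l <- config$linear_reads_per_gene
      st <- sample.int(nchar(ts) - frag_len + 1L, n_l, replace = TRUE)
      set_rows[[length(set_rows) + 1]] <- tibble(
        origin = gid, class = "linear",
        frag = substr(rep(ts, n_l), st, st + frag_len - 1L)
      )
    }
    reads <- bind_rows(set_rows)
    ## a junction read whose short junction overhang can be explained as a
    ## linear read (an end-to-end placement in the genome or spliced
    ## transcriptome within the default mismatch allowance) is not valid
    ## circular evidence; redraw its start position so every planted read
    ## is recoverable by the counter
    if (!pe && nrow(reads) > 0) {
      junc <- which(reads$class != "linear")
      for (iter in seq_len(30)) {
        if (length(junc) == 0) break
        rt <- tibble(read_id = as.character(junc), mate = 0L,
                     seq = reads$frag[junc])
        placed <- find_end_to_end_placements(rt, genome, m = 2L) |
          find_end_to_end_placements(rt, full_tx, m = 2L)
        bad <- junc[placed]
        if (length(bad) == 0) break
        if (iter == 30) abort("could not draw linear-inexplicable junction reads")
        for (o in unique(reads$origin[bad])) {
          bi <- bad[reads$origin[bad] == o]
          reads$frag[bi] <- junction_reads(cseq_of[[o]], length(bi), L, ov)
        }
        junc <- bad
      }
    }
    if (nrow(reads) > 0) {
      reads <- reads |>
        group_by(.data$origin) |>
        mutate(read_id = sprintf("%s;%s;set%d;%05d", .data$origin,
                                 .data$class, s, seq_len(n()))) |>
        ungroup()
      p_survive <- ifelse(reads$class == "circular",
                          config$survival_circ, config$survival_linear)
      reads$in_rnaser <- runif(nrow(reads)) < p_survive
    } else {
      reads <- tibble(origin = character(), class = character(),
                      frag = character(), read_id = character(),
                      in_rnaser = logical())
    }
    ledger[[s]] <- reads |>
      transmute(read_id = .data$read_id, origin = .data$origin,
                class = .data$class, set = s, in_mock = TRUE,
                in_rnaser = .data$in_rnaser)
    planted[[s]] <- reads |>
      filter(.data$class != "linear") |>
      group_by(circ_id = .data$origin) |>
      summarise(set = s, n_planted = n(), n_surviving = sum(.data$in_rnaser),
                .groups = "drop")

    to_read_table <- function(x) {
      if (pe) {
        bind_rows(
          tibble(read_id = x$read_id, mate = 1L,
                 seq = substr(x$frag, 1L, L)),
          tibble(read_id = x$read_id, mate = 2L,
                 seq = as.character(Biostrings::reverseComplement(
                   Biostrings::DNAStringSet(
                     substr(x$frag, nchar(x$frag) - L + 1L, nchar(x$frag))))))
        )
      } else {
        tibble(read_id = x$read_id, mate = 0L, seq = x$frag)
      }
    }
    libraries[[s]] <- list(
      mock = to_read_table(reads),
      rnaser = to_read_table(reads[reads$in_rnaser, ])
    )
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (lib in c("mock", "rnaser")) {
        tb <- libraries[[s]][[lib]]
        if (pe) {
          for (mt in 1:2) {
            path <- file.path(dir, sprintf("set%d_%s_R%d.fastq.gz", s, lib, mt))
            write_fastq(tb[tb$mate == mt, ], path, mate_suffix = mt)
            files[[length(files) + 1]] <- tibble(set = s, library = lib,
                                                 mate = mt, path = path)
          }
        } else {
          path <- file.path(dir, sprintf("set%d_%s.fastq.gz", s, lib))
          write_fastq(tb, path)
          files[[length(files) + 1]] <- tibble(set = s, library = lib,
                                               mate = 0L, path = path)
        }
      }
    }
  }
  out <- list(truth = truth, ledger = bind_rows(ledger),
              planted = bind_rows(planted), libraries = libraries,
              files = if (length(files)) bind_rows(files) else NULL,
              config = config)
  if (!is.null(dir)) {
    jsonlite::write_json(
      list(truth = truth, ledger = out$ledger, planted = out$planted),
      file.path(dir, "truth.json")
    )
  }
  out
}

#' Write a read table as FASTQ
#'
#' Qualities are constant `I`: the junction-counting method never uses
#' base qualities.
#'
#' @param reads Read table (`read_id`, `seq`).
#' @param path Output path (`.gz` for gzip).
#' @param mate_suffix Optional mate number appended to ids as `/1`/`/2`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate_suffix = NULL) {
  ids <- reads$read_id
  if (!is.null(mate_suffix)) ids <- paste0(ids, "/", mate_suffix)
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, ids))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Truncate reads to their first L bases
#'
#' Emulates computational read trimming: every read is clipped to its
#' first `L` bases; reads already at most `L` bases long are unchanged.
#'
#' @param reads Read table, named character vector, `DNAStringSet`, or
#'   a FASTQ path (then `out` must name the output FASTQ).
#' @param L Target length in bases.
#' @param out Output FASTQ path when `reads` is a path.
#' @return Same shape as the input (read table for in-memory input;
#'   `out` for file input).
#' @export
truncate_reads <- function(reads, L, out = NULL) {
  stopifnot(L >= 1)
  if (is.character(reads) && is.null(names(reads)) && length(reads) == 1 &&
      file.exists(reads)) {
    tb <- read_fastq(reads)
    tb$seq <- substr(tb$seq, 1L, L)
    stopifnot(!is.null(out))
    return(write_fastq(tb, out))
  }
  tb <- as_read_table(reads)
  tb$seq <- substr(tb$seq, 1L, L)
  tb
}

#' Select random exon-chain transcripts as a background set
#'
#' Builds, for each gene with enough exons, a random pseudo-transcript:
#' the gene's starting (5'-most) exon plus `n - 1` further exons drawn
#' without replacement, kept in transcript order. These serve as a
#' length/composition-matched background for comparisons against circle
#' exon chains.
#'
#' @param annotation Exon tibble.
#' @param n Exons per random transcript.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param genome Optional `DNAStringSet`; when given, spliced sequences
#'   are attached.
#' @return Exon tibble of the random transcripts (`transcript_id` =
#'   `<gene>.rand`), with a `seq` attribute (named character) when
#'   `genome` is supplied.
#' @export
select_random_exon_transcripts <- function(annotation, n, seed = 1L,
                                           genome = NULL) {
  set.seed(seed)
  eligible <- annotation |>
    group_by(.data$gene_id) |>
    filter(n() >= n) |>
    ungroup()
  if (nrow(eligible) == 0) {
    abort(sprintf("no gene has %d exons to sample from", n))
  }
  picked <- eligible |>
    group_by(.data$gene_id) |>
    group_modify(function(ex, key) {
      ex <- arrange(ex, .data$exon_rank)
      rest <- if (n > 1) sort(1L + sample(nrow(ex) - 1L, n - 1L)) else integer(0)
      ex[c(1L, rest), ]
    }) |>
    ungroup() |>
    mutate(transcript_id = paste0(.data$gene_id, ".rand"))
  if (!is.null(genome)) {
    attr(picked, "seq") <- as.character(extract_transcriptome(picked, genome))
  }
  picked
}
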