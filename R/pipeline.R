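#' Run the full annotate-quantify-classify flow on simulated data
#'
#' End-to-end driver used for validation and worked examples: generates
#' a toy study with [make_toy_genome()], [plant_circles()] and
#' [generate_reads()], annotates the planted candidates against the toy
#' exon model, builds junction references, quantifies the mock and
#' RNase R libraries of one read set, computes ratios and classifies.
#' Because the truth is known, sensitivity (planted circles called
#' true) and decoy false-positive rate (decoys called true) are
#' reported alongside.
#'
#' @param config A [sim_config()] describing the study.
#' @param set Which read set to quantify (default 1).
#' @param cutoff Classification cutoff; default 0.9.
#' @param j,m Seed half-width and mismatch allowance for matching.
#' @param dir Optional directory for the simulator's FASTQ/GTF output.
#' @return List with `truth`, `annotation`, `assignments`, `refs`,
#'   `mock`, `rnaser` (count tables), `ratios`, `classification`, `sim`
#'   (the generator output) and `performance` (one-row tibble:
#'   `sensitivity`, `decoy_fpr`, `tau`, counts).
#' @export
run_pipeline <- function(config = sim_config(), set = 1L, cutoff = 0.9,
                         j = 5L, m = 2L, dir = NULL) {
  toy <- make_toy_genome(config, dir = dir)
  truth <- plant_circles(toy$annotation, config)
  sim <- generate_reads(truth, toy$annotation, toy$genome, config, dir = dir)

  asg <- assign_transcripts(truth, toy$annotation)
  refs <- build_junction_references(asg, toy$annotation, toy$genome,
                                    W = config$read_length)
  strandedness <- if (config$pairing == "PE") "unstranded" else "forward"
  tx <- extract_transcriptome(toy$annotation, toy$genome)
  mock <- quantify_library(sim$libraries[[set]]$mock, refs, toy$genome,
                           transcriptome = tx, library_id = "mock",
                           j = j, m = m, strandedness = strandedness)
  rnaser <- quantify_library(sim$libraries[[set]]$rnaser, refs, toy$genome,
                             transcriptome = tx, library_id = "rnaser",
                             j = j, m = m, strandedness = strandedness)
  ratios <- compute_ratios(mock, rnaser)
  classification <- classify_circles(ratios, cutoff = cutoff,
                                     candidates = truth)
  called_true <- classification$circ_id[classification$classification == "true"]
  circles <- truth$circ_id[truth$type == "circle"]
  decoys <- truth$circ_id[truth$type == "decoy"]
  performance <- tibble(
    sensitivity = mean(circles %in% called_true),
    decoy_fpr = mean(decoys %in% called_true),
    tau = attr(classification, "tau"),
    n_true_called = length(called_true),
    n_circles = length(circles), n_decoys = length(decoys)
  )
  list(truth = truth, annotation = toy$annotation, genome = toy$genome,
       assignments = asg, refs = refs, mock = mock, rnaser = rnaser,
       ratios = ratios, classification = classification, sim = sim,
       performance = performance)
}

#' Plot a cutoff sweep
#'
#' Companion diagnostic to [cutoff_sweep()]: the number of candidates
#' called true (and, when available, the retained fraction of fully
#' supported candidates) as the cutoff varies.
#'
#' @param sweep Tibble from [cutoff_sweep()].
#' @return A ggplot object.
#' @export
plot_cutoff_sweep <- function(sweep) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$cutoff, y = .data$n_true)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cutoff (fraction of linear junctions excluded)",
                  y = "candidates classified true")
  if ("frac_true_full_support" %in% names(sweep)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$frac_true_full_support * max(sweep$n_true)),
      linetype = "dotted")
  }
  p
}
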