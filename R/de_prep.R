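#' Assemble a multi-library count matrix for external DE testing
#'
#' Combines per-library circular junction counts into one wide matrix
#' of raw fragment counts (rows = circRNAs, columns = libraries) for an
#' external differential-expression tool. Rows can be restricted to a
#' true list from classification; rows with too few reads are dropped —
#' by default fewer than 2 in total across the matrix (`filter =
#' "per_sample"` instead requires the maximum per-library count to
#' reach `min_reads`). Raw counts are preserved: normalization is the
#' DE tool's job, and library sizes travel in the `library_sizes`
#' attribute sidecar.
#'
#' @param count_tables Named list of `circ_counts` tibbles, one per
#'   library; names (or `library_id` attributes) must be unique.
#' @param true_list Optional character vector of `circ_id` keys (e.g.
#'   true-classified circRNAs) restricting the rows.
#' @param min_reads Minimum read support for a row (default 2).
#' @param filter `"total"` (default) or `"per_sample"`; see above.
#' @return Tibble with `circ_id` plus one raw-count column per library,
#'   with attributes `library_sizes` (named numeric) and `filter`
#'   metadata.
#' @export
build_de_matrix <- function(count_tables, true_list = NULL, min_reads = 2L,
                            filter = c("total", "per_sample")) {
  filter <- match.arg(filter)
  ids <- names(count_tables) %||%
    purrr::map_chr(count_tables, ~ attr(.x, "library_id"))
  if (anyDuplicated(ids)) abort("duplicated library_id in count tables")
  sizes <- setNames(purrr::map_dbl(count_tables, ~ attr(.x, "library_size")),
                    ids)
  wide <- purrr::map2(count_tables, ids, function(x, id) {
    as_tibble(x) |> select("circ_id", !!id := "circ_count")
  }) |>
    purrr::reduce(full_join, by = "circ_id") |>
    mutate(across(-"circ_id", ~ dplyr::coalesce(.x, 0L)))
  if (!is.null(true_list)) {
    wide <- filter(wide, .data$circ_id %in% true_list)
  }
  counts <- as.matrix(wide[-1])
  keep <- if (filter == "total") {
    rowSums(counts) >= min_reads
  } else {
    apply(counts, 1, max) >= min_reads
  }
  out <- wide[keep, ]
  attr(out, "library_sizes") <- sizes
  attr(out, "filter") <- list(min_reads = min_reads, mode = filter)
  out
}

#' Counts per million aligned reads
#'
#' @param counts A `circ_counts` tibble with a positive `library_size`
#'   attribute.
#' @return Tibble `circ_id`, `count`, `cpm` where
#'   `cpm = count / library_size * 1e6`.
#' @export
normalize_cpm <- function(counts) {
  ls <- attr(counts, "library_size")
  if (is.null(ls) || is.na(ls) || ls <= 0) {
    abort("library_size attribute must be positive")
  }
  as_tibble(counts) |>
    transmute(circ_id = .data$circ_id, count = .data$circ_count,
              cpm = .data$circ_count / ls * 1e6)
}

#' Total circRNA load per sample and between-condition test
#'
#' Sums normalized (CPM) circular reads over the true circRNAs for each
#' library, rescales so the reference-condition mean equals 1, and
#' compares the two conditions with a Welch two-sample t-test.
#'
#' @param count_tables Named list of `circ_counts` tibbles.
#' @param conditions Named character vector mapping library name to
#'   condition label (exactly two conditions, each with >= 2
#'   libraries).
#' @param true_list Optional `circ_id` filter (the true list).
#' @param reference Condition whose mean is scaled to 1; default the
#'   first condition encountered.
#' @return An object of class `circ_load`. [tidy()] gives per-sample
#'   totals (`library_id`, `condition`, `total_cpm`, `relative`);
#'   [glance()] the group means, SEMs, ratio of means, and the Welch
#'   `t`, `df` and p-value.
#' @export
total_circ_load <- function(count_tables, conditions, true_list = NULL,
                            reference = NULL) {
  ids <- names(count_tables)
  stopifnot(!is.null(ids), all(ids %in% names(conditions)))
  cond <- conditions[ids]
  if (length(unique(cond)) != 2) abort("exactly two conditions required")
  if (any(table(cond) < 2)) {
    abort("each condition needs >= 2 libraries for a variance estimate")
  }
  reference <- reference %||% cond[[1]]
  totals <- purrr::map2_dfr(count_tables, ids, function(x, id) {
    cpm <- normalize_cpm(x)
    if (!is.null(true_list)) cpm <- filter(cpm, .data$circ_id %in% true_list)
    tibble(library_id = id, condition = conditions[[id]],
           total_cpm = sum(cpm$cpm))
  })
  ref_mean <- mean(totals$total_cpm[totals$condition == reference])
  totals$relative <- totals$total_cpm / ref_mean
  other <- setdiff(unique(cond), reference)
  tt <- tryCatch(
    t.test(totals$total_cpm[totals$condition == other],
           totals$total_cpm[totals$condition == reference],
           var.equal = FALSE),
    error = function(e) {
      warn(sprintf("Welch test unavailable (%s); reporting NA statistics",
                   conditionMessage(e)))
      list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    }
  )
  structure(list(samples = totals, test = tt,
                 reference = reference, other = other),
            class = "circ_load")
}

#' @export
tidy.circ_load <- function(x, ...) x$samples

#' @export
glance.circ_load <- function(x, ...) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  ref <- x$samples$total_cpm[x$samples$condition == x$reference]
  oth <- x$samples$total_cpm[x$samples$condition == x$other]
  tibble(
    reference = x$reference, comparison = x$other,
    mean_reference = mean(ref), mean_comparison = mean(oth),
    sem_reference = sem(ref), sem_comparison = sem(oth),
    ratio_of_means = mean(oth) / mean(ref),
    t = unname(x$test$statistic), df = unname(x$test$parameter),
    p_value = x$test$p.value
  )
}

#' @export
autoplot.circ_load <- function(object, ...) {
  df <- object$samples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$relative)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = sprintf("total circRNA load (%s = 1)",
                                        object$reference))
}
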