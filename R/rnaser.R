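#' Compute RNase R / mock junction ratios
#'
#' RNase R degrades linear RNA but spares covalently closed circles, so
#' the ratio of normalized junction signal between a treated and a mock
#' library separates real circRNAs from linear artifacts. Counts are
#' normalized to counts per million aligned reads (CPM) using each
#' library's recorded size, and the ratio `rnaser_cpm / mock_cpm` is
#' computed per junction. Only junctions expressed in the mock sample
#' (`mock count >= min_mock`) are retained: the circular rows are the
#' classification candidates, and the pooled `linear_left` /
#' `linear_right` rows — the canonical splice junctions of the host
#' genes — form the RNase R-sensitive comparison sample from which the
#' threshold is drawn.
#'
#' @param mock,rnaser `circ_counts` tibbles for the mock and
#'   RNase R-treated libraries of one sample (shared `circ_id`
#'   universe), with `library_size` attributes set.
#' @param min_mock Minimum raw mock count for a junction to enter the
#'   analysis (default 1).
#' @param normalized Use CPM normalization (default). `FALSE` computes
#'   ratios on raw counts.
#' @return A long tibble with one row per retained junction: `circ_id`,
#'   `junction` (`circular`, `linear_left`, `linear_right`),
#'   `mock_count`, `rnaser_count`, `mock_cpm`, `rnaser_cpm`, `ratio`.
#'   Library sizes are kept in the `library_sizes` attribute.
#' @export
compute_ratios <- function(mock, rnaser, min_mock = 1L, normalized = TRUE) {
  ms <- attr(mock, "library_size")
  rs <- attr(rnaser, "library_size")
  if (is.null(ms) || is.null(rs) || is.na(ms) || is.na(rs) ||
      ms <= 0 || rs <= 0) {
    abort("both libraries must carry a positive library_size attribute")
  }
  long <- function(x, prefix) {
    as_tibble(x) |>
      select("circ_id", circular = "circ_count",
             linear_left = "linear_left_count",
             linear_right = "linear_right_count") |>
      tidyr::pivot_longer(-"circ_id", names_to = "junction",
                          values_to = prefix)
  }
  out <- long(mock, "mock_count") |>
    inner_join(long(rnaser, "rnaser_count"), by = c("circ_id", "junction")) |>
    filter(.data$mock_count >= min_mock) |>
    mutate(
      mock_cpm = .data$mock_count / ms * 1e6,
      rnaser_cpm = .data$rnaser_count / rs * 1e6,
      ratio = if (normalized) .data$rnaser_cpm / .data$mock_cpm
              else .data$rnaser_count / .data$mock_count
    )
  attr(out, "library_sizes") <- c(mock = ms, rnaser = rs)
  out
}

#' Select the classification threshold from the linear-junction ratios
#'
#' The cutoff `c` is expressed as the fraction of linear junctions to be
#' declared RNase R-sensitive: a 0.90 cutoff excludes 90% of the linear
#' junctions. The threshold is the nearest-rank (upper) empirical
#' quantile: the `ceiling(c * n)`-th smallest of the `n` linear ratios,
#' so that exactly `ceiling(c * n)` linear ratios fall at or below it.
#' Candidates are subsequently called true when their ratio is strictly
#' above the threshold.
#'
#' @param linear_ratios Numeric vector of linear-junction
#'   RNase R / mock ratios.
#' @param cutoff Fraction in (0, 1) of linear junctions to exclude.
#' @return The threshold `tau` (a ratio-scale value).
#' @export
select_threshold <- function(linear_ratios, cutoff = 0.9) {
  linear_ratios <- linear_ratios[!is.na(linear_ratios)]
  n <- length(linear_ratios)
  if (n < 10) {
    abort(sprintf(
      "only %d linear-junction ratios available (need >= 10); consider pooling tissues to enlarge the linear sample",
      n))
  }
  stopifnot(cutoff > 0, cutoff < 1)
  sort(linear_ratios)[ceiling(cutoff * n)]
}

#' Classify candidates as bona fide circRNAs by RNase R resistance
#'
#' Applies the empirical-quantile threshold from [select_threshold()]
#' to the circular-junction ratios: a candidate is classified `"true"`
#' iff its ratio is strictly greater than the threshold; ties and lower
#' values are `"false"` (conservative — a false call can later be
#' rescued across tissues, see [collapse_rescue()]). Alternatively a
#' fixed fold-change threshold can be requested with `fold_cutoff`
#' (classification `ratio >= fold_cutoff`), mirroring the common fixed
#' 5-fold-enrichment practice for comparison.
#'
#' @param ratios Long ratio tibble from [compute_ratios()].
#' @param cutoff Quantile cutoff in (0, 1); default 0.9.
#' @param fold_cutoff If non-`NULL`, bypass the quantile rule and use
#'   this fixed ratio threshold instead.
#' @param candidates Optional merged-candidate tibble; when given (and
#'   carrying `circ_id`-derivable coordinates plus `n_pipelines`),
#'   pipeline support is joined onto the result.
#' @return A `circ_classification` tibble of the circular-junction
#'   records with `classification` set, carrying `cutoff`, `tau` and the
#'   linear ratio sample as attributes. [tidy()] returns the records,
#'   [glance()] the one-row summary, [autoplot()] the ratio-distribution
#'   diagnostic.
#' @export
classify_circles <- function(ratios, cutoff = 0.9, fold_cutoff = NULL,
                             candidates = NULL) {
  circ <- filter(ratios, .data$junction == "circular")
  linear <- filter(ratios, .data$junction != "circular")
  if (is.null(fold_cutoff)) {
    tau <- select_threshold(linear$ratio, cutoff)
    cls <- ifelse(circ$ratio > tau, "true", "false")
  } else {
    tau <- fold_cutoff
    cls <- ifelse(circ$ratio >= tau, "true", "false")
  }
  out <- circ |>
    select(-"junction") |>
    mutate(classification = cls)
  if (!is.null(candidates) && "n_pipelines" %in% names(candidates)) {
    cand <- candidates
    if (!"circ_id" %in% names(cand)) {
      cand <- mutate(cand, circ_id = sprintf("%s:%d-%d:%s", .data$chrom,
                                             .data$start, .data$end,
                                             .data$strand))
    }
    out <- left_join(out, select(cand, "circ_id", "n_pipelines"),
                     by = "circ_id")
  }
  class(out) <- c("circ_classification", class(out))
  attr(out, "cutoff") <- if (is.null(fold_cutoff)) cutoff else NA_real_
  attr(out, "tau") <- tau
  attr(out, "mode") <- if (is.null(fold_cutoff)) "quantile" else "fold"
  attr(out, "linear_ratios") <- linear$ratio
  out
}

#' @export
tidy.circ_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "circ_classification")
  as_tibble(out)
}

#' @export
glance.circ_classification <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    cutoff = attr(x, "cutoff"),
    tau = attr(x, "tau"),
    n_linear = length(attr(x, "linear_ratios")),
    n_candidates = nrow(x),
    n_true = sum(x$classification %in% c("true", "rescued")),
    n_false = sum(x$classification == "false")
  )
}

#' @export
autoplot.circ_classification <- function(object, ...) {
  df <- bind_rows(
    tibble(ratio = object$ratio, set = "circRNA candidates"),
    tibble(ratio = attr(object, "linear_ratios"), set = "linear junctions")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$ratio + 1e-3),
                                   fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = log10(attr(object, "tau") + 1e-3),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "log10(RNaseR/mock ratio)", y = "density",
      title = "RNase R resistance of circular vs linear junctions",
      subtitle = sprintf("threshold tau = %.3g (cutoff %.2f)",
                         attr(object, "tau"), attr(object, "cutoff"))
    )
}

#' Sweep the classification cutoff over a grid
#'
#' Recomputes the threshold and classification at each cutoff of a
#' grid, reporting how many candidates are called true overall and —
#' when pipeline support is available — the fraction of maximally
#' supported candidates (those reported by every pipeline) that survive.
#' This is the diagnostic used to choose the cutoff: the true count is
#' monotone non-increasing in the cutoff, and the value is typically
#' picked where well-supported, well-expressed candidates are still
#' retained.
#'
#' @param ratios Long ratio tibble from [compute_ratios()].
#' @param grid Numeric vector of cutoffs in (0, 1).
#' @param candidates Optional candidate tibble with `n_pipelines`.
#' @return Tibble with one row per cutoff: `cutoff`, `tau`, `n_true`,
#'   `n_false`, and `frac_true_full_support` when support is known.
#' @export
cutoff_sweep <- function(ratios, grid = seq(0.8, 0.99, by = 0.01),
                         candidates = NULL) {
  purrr::map_dfr(grid, function(cc) {
    cl <- classify_circles(ratios, cutoff = cc, candidates = candidates)
    row <- tibble(cutoff = cc, tau = attr(cl, "tau"),
                  n_true = sum(cl$classification == "true"),
                  n_false = sum(cl$classification == "false"))
    if ("n_pipelines" %in% names(cl)) {
      full <- filter(cl, .data$n_pipelines == max(.data$n_pipelines))
      row$frac_true_full_support <- mean(full$classification == "true")
    }
    row
  })
}

#' Rescue false calls across tissues of one species
#'
#' A circRNA can fail the cutoff in one tissue (shallow mock coverage,
#' condition-specific expression) while passing in another. Collapsing
#' rescues such calls: the union of all per-tissue true keys — plus any
#' externally validated lists — is built, and every false record whose
#' key is in the union is re-annotated `"rescued"`. The final per-tissue
#' true list is the true calls plus the rescued ones; rescue provenance
#' records which tissue(s) or external list caused each rescue.
#'
#' @param per_tissue Named list of `circ_classification` tibbles (or
#'   plain tibbles with `circ_id` and `classification`), one per tissue.
#' @param external_true Optional character vector (or named list of
#'   vectors) of externally validated `circ_id` keys.
#' @return One tibble over all tissues with columns `tissue`, `circ_id`,
#'   `classification` (`true`/`false`/`rescued`) and
#'   `rescue_provenance` (comma-joined sources, `NA` if not rescued).
#' @export
collapse_rescue <- function(per_tissue, external_true = NULL) {
  stopifnot(is.list(per_tissue), !is.null(names(per_tissue)))
  true_by_tissue <- purrr::map(per_tissue, function(x) {
    unique(x$circ_id[x$classification == "true"])
  })
  ext <- list()
  if (!is.null(external_true)) {
    if (!is.list(external_true)) external_true <- list(external = external_true)
    bad <- purrr::map(external_true, ~ .x[!grepl("^.+:\\d+-\\d+:[+-]$", .x)])
    purrr::iwalk(bad, function(b, nm) {
      for (k in b) warn(sprintf("external list '%s': malformed key '%s'", nm, k))
    })
    ext <- purrr::map2(external_true, bad, setdiff)
  }
  sources <- c(true_by_tissue, ext)
  purrr::imap_dfr(per_tissue, function(x, tissue) {
    x <- as_tibble(x)
    class(x) <- setdiff(class(x), "circ_classification")
    prov <- purrr::map_chr(x$circ_id, function(id) {
      from <- names(sources)[purrr::map_lgl(sources, ~ id %in% .x)]
      from <- setdiff(from, tissue)
      if (length(from) == 0) NA_character_ else paste(from, collapse = ",")
    })
    rescued <- x$classification == "false" & !is.na(prov)
    x |>
      mutate(tissue = tissue, .before = 1) |>
      mutate(
        classification = ifelse(rescued, "rescued", .data$classification),
        rescue_provenance = ifelse(rescued, prov, NA_character_)
      )
  })
}

#' Annotate candidates with expression strata
#'
#' Splits records into low / mid / high expression terciles of mock CPM
#' (within-sample nearest-rank terciles). Purely diagnostic — the strata
#' support the "well-expressed, well-supported candidates should pass"
#' check when choosing a cutoff — and never alter classification. When
#' all values tie (degenerate spread) every record is `mid`.
#'
#' @param records Tibble with a `mock_cpm` column (e.g. a
#'   classification or ratio tibble).
#' @return `records` with an added `expression_stratum` column.
#' @export
expression_strata <- function(records) {
  x <- records$mock_cpm
  q <- quantile(x, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  stratum <- if (q[1] == q[2]) {
    ifelse(x < q[1], "low", ifelse(x > q[2], "high", "mid"))
  } else {
    ifelse(x <= q[1], "low", ifelse(x > q[2], "high", "mid"))
  }
  mutate(records, expression_stratum = stratum)
}
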