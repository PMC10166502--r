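# Genome coverage ratios per repeat group and fold enrichment of
# peak-bound repeats relative to their genomic distribution.

#' Genomic coverage ratio per repeat class or family
#'
#' For each repeat group, sums the merged-union genomic length of its
#' copies and divides by the genome length: overlapping copies within a
#' group are counted once.
#'
#' @param repeats Repeat tibble ([read_rmsk()] layout).
#' @param genome_length Total genome length in bp (e.g. the sum of a
#'   chrom-sizes table).
#' @param level `"class"` or `"family"`.
#' @return A tibble `group`, `covered_bp`, `genome_length`, `ratio`.
#' @export
genome_coverage_ratio <- function(repeats, genome_length,
                                  level = c("class", "family")) {
  level <- match.arg(level)
  stopifnot(genome_length > 0)
  repeats$group <- if (level == "class") repeats$rep_class else
    repeats$rep_family
  out <- repeats |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      covered_bp = coverage_bp(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::mutate(genome_length = genome_length,
                  ratio = .data$covered_bp / genome_length) |>
    dplyr::arrange(dplyr::desc(.data$covered_bp), .data$group)
  if (any(out$covered_bp > genome_length)) {
    stop("covered bp exceeds genome length for group ",
         out$group[out$covered_bp > genome_length][1], call. = FALSE)
  }
  out
}

#' Frequency of repeat groups among annotated peaks
#'
#' Three definitions of the "frequency" of a repeat group in a peak set:
#' \describe{
#'   \item{incidence}{distinct (peak, group) incidences over all
#'     incidences (default).}
#'   \item{bp_fraction}{bp of peak sequence overlapped by the group over
#'     total peak bp.}
#'   \item{peak_fraction}{fraction of peaks containing at least one copy of
#'     the group (column need not sum to 1).}
#' }
#'
#' @param annotation Output of [annotate_peaks_with_tes()].
#' @param level `"class"` or `"family"`.
#' @param mode Frequency definition, see Details.
#' @return A tibble `group`, `frequency`.
#' @export
peak_frequency <- function(annotation, level = c("class", "family"),
                           mode = c("incidence", "bp_fraction",
                                    "peak_fraction")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (nrow(annotation) == 0L) stop("empty annotation table", call. = FALSE)
  n_peaks <- dplyr::n_distinct(annotation$peak_id)
  peak_bp <- annotation |>
    dplyr::distinct(.data$peak_id, .keep_all = TRUE) |>
    dplyr::summarise(bp = sum(.data$end - .data$start)) |>
    dplyr::pull(.data$bp)
  te_rows <- annotation[!is.na(annotation$rep_class), ]
  te_rows$group <- if (level == "class") te_rows$rep_class else
    te_rows$rep_family
  out <- switch(
    mode,
    incidence = te_rows |>
      dplyr::distinct(.data$peak_id, .data$group) |>
      dplyr::count(.data$group, name = "n") |>
      dplyr::mutate(frequency = .data$n / sum(.data$n)),
    bp_fraction = te_rows |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = sum(.data$overlap_bp), .groups = "drop") |>
      dplyr::mutate(frequency = .data$n / peak_bp),
    peak_fraction = te_rows |>
      dplyr::distinct(.data$peak_id, .data$group) |>
      dplyr::count(.data$group, name = "n") |>
      dplyr::mutate(frequency = .data$n / n_peaks)
  )
  out |>
    dplyr::select("group", "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$group)
}

#' Fold enrichment of repeat groups in peaks
#'
#' Divides each group's peak frequency by its genomic coverage ratio:
#' `E = f / c`. Values above 1 mean the peaks sit over that repeat group
#' more often than its genomic abundance alone would produce.
#'
#' @param freqs Output of [peak_frequency()].
#' @param ratios Output of [genome_coverage_ratio()]; every group present
#'   in `freqs` must be present here.
#' @return A tibble `group`, `frequency`, `ratio`, `enrichment`; groups
#'   with zero genomic coverage get `NA` enrichment and `zero_coverage =
#'   TRUE` rather than a division.
#' @export
enrichment_fold <- function(freqs, ratios) {
  missing_groups <- setdiff(freqs$group, ratios$group)
  if (length(missing_groups) > 0) {
    stop("groups absent from coverage table: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  out <- freqs |>
    dplyr::left_join(ratios[, c("group", "ratio")], by = "group") |>
    dplyr::mutate(
      zero_coverage = .data$ratio == 0,
      enrichment = dplyr::if_else(.data$zero_coverage, NA_real_,
                                  .data$frequency / .data$ratio)
    ) |>
    dplyr::arrange(dplyr::desc(.data$enrichment), .data$group)
  out
}

#' One-call TE enrichment analysis
#'
#' Convenience wrapper: annotates peaks with repeats, computes frequencies
#' and coverage ratios at the requested level, and returns the enrichment
#' table.
#'
#' @inheritParams annotate_peaks_with_tes
#' @inheritParams genome_coverage_ratio
#' @inheritParams peak_frequency
#' @return The [enrichment_fold()] table.
#' @export
te_enrichment <- function(peaks, repeats, genome_length,
                          level = c("class", "family"),
                          mode = c("incidence", "bp_fraction",
                                   "peak_fraction")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  annotation <- annotate_peaks_with_tes(peaks, repeats)
  enrichment_fold(
    peak_frequency(annotation, level = level, mode = mode),
    genome_coverage_ratio(repeats, genome_length, level = level)
  )
}
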