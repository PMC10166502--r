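# Peak x repeat matching, genomic-feature classification, cCRE labelling,
# and the composition summaries built from them.

new_composition_summary <- function(tbl, level, denominator,
                                    denominator_def, n_peaks = NA_integer_,
                                    pct_peaks_with_te = NA_real_) {
  structure(
    tbl,
    class = c("composition_summary", class(tbl)),
    level = level,
    denominator = denominator,
    denominator_def = denominator_def,
    n_peaks = n_peaks,
    pct_peaks_with_te = pct_peaks_with_te
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Composition summary (level: ", attr(x, "level"),
      "; denominator: ", attr(x, "denominator"), " = ",
      attr(x, "denominator_def"), ")\n", sep = "")
  if (!is.na(attr(x, "pct_peaks_with_te"))) {
    cat(sprintf("peaks with >=1 TE: %.1f%%\n", attr(x, "pct_peaks_with_te")))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.composition_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a composition summary
#'
#' @param object A `composition_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composition_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- stats::reorder(df$group, -df$percentage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = attr(object, "level"), y = "percentage",
                  caption = attr(object, "denominator_def")) +
    ggplot2::theme_minimal()
}

#' Annotate peaks with overlapping repeat elements
#'
#' Matches repeat elements to peak coordinates (any overlap of at least
#' `min_bp`, strand-agnostic). A peak overlapped by k repeats yields k rows
#' (replicated lines); a repeat-free peak yields a single row with the
#' repeat fields `NA`, so every input peak appears at least once.
#'
#' @param peaks Peak tibble ([read_peaks()] layout).
#' @param repeats Repeat tibble ([read_rmsk()] layout).
#' @param min_bp Minimum overlap in bp.
#' @return A tibble with one row per (peak, repeat) match plus one NA row
#'   per unmatched peak: peak columns, `rep_name`, `rep_family`,
#'   `rep_class`, `te_start`, `te_end`, `overlap_bp`. Row order follows the
#'   input peak order, then repeat input order.
#' @export
annotate_peaks_with_tes <- function(peaks, repeats, min_bp = 1L) {
  peaks <- validate_intervals(peaks, "peaks")
  if (!"peak_id" %in% names(peaks)) {
    stop("peaks must carry a peak_id column", call. = FALSE)
  }
  keep <- intersect(
    c("peak_id", "chrom", "start", "end", "summit_offset", "q_value"),
    names(peaks)
  )
  base <- peaks[, keep]
  if (nrow(repeats) > 0) {
    hits <- find_overlaps(peaks, repeats, min_bp = min_bp)
  } else {
    hits <- tibble::tibble(query_index = integer(), subject_index = integer(),
                           overlap_bp = integer())
  }
  matched <- dplyr::bind_cols(
    base[hits$query_index, ],
    tibble::tibble(
      rep_name = repeats$rep_name[hits$subject_index],
      rep_family = repeats$rep_family[hits$subject_index],
      rep_class = repeats$rep_class[hits$subject_index],
      te_start = repeats$start[hits$subject_index],
      te_end = repeats$end[hits$subject_index],
      overlap_bp = as.numeric(hits$overlap_bp)
    )
  )
  orphan_idx <- setdiff(seq_len(nrow(peaks)), unique(hits$query_index))
  orphans <- dplyr::bind_cols(
    base[orphan_idx, ],
    tibble::tibble(
      rep_name = rep(NA_character_, length(orphan_idx)),
      rep_family = NA_character_,
      rep_class = NA_character_,
      te_start = NA_real_,
      te_end = NA_real_,
      overlap_bp = NA_real_
    )
  )
  out <- dplyr::bind_rows(matched, orphans)
  ord <- order(match(out$peak_id, peaks$peak_id), out$te_start)
  out[ord, ]
}

#' TE class/family composition of annotated peaks
#'
#' Summarises which repeat classes (or families) the peaks sit over.
#' Counting rules (`mode`):
#' \describe{
#'   \item{incidence}{each distinct (peak, group) pair counts once -- a peak
#'     over 3 SINEs and 1 LINE contributes SINE once and LINE once
#'     (default).}
#'   \item{rows}{every replicated peak-repeat row counts.}
#'   \item{primary_by_max_overlap}{each peak contributes only the group of
#'     its largest-overlap repeat.}
#' }
#' The summary also reports the fraction of peaks containing at least one
#' repeat.
#'
#' @param annotation Output of [annotate_peaks_with_tes()].
#' @param level `"class"` or `"family"`.
#' @param within_class Optional repeat class; restricts to peaks rows of
#'   that class and summarises its families (e.g. family make-up of
#'   SINE-bound peaks).
#' @param mode Counting rule, see Details.
#' @return A `composition_summary`: tibble of `group`, `count`,
#'   `percentage` with attributes `pct_peaks_with_te`, `denominator`.
#' @export
te_composition <- function(annotation, level = c("class", "family"),
                           within_class = NULL,
                           mode = c("incidence", "rows",
                                    "primary_by_max_overlap")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (nrow(annotation) == 0L) stop("empty annotation table", call. = FALSE)
  n_peaks <- dplyr::n_distinct(annotation$peak_id)
  te_rows <- annotation[!is.na(annotation$rep_class), ]
  pct_with_te <- 100 * dplyr::n_distinct(te_rows$peak_id) / n_peaks
  if (!is.null(within_class)) {
    te_rows <- te_rows[te_rows$rep_class == within_class, ]
    level <- "family"
  }
  te_rows$group <- if (level == "class") te_rows$rep_class else
    te_rows$rep_family
  if (nrow(te_rows) == 0L) {
    return(new_composition_summary(
      tibble::tibble(group = character(), count = integer(),
                     percentage = numeric()),
      level = level, denominator = 0L,
      denominator_def = paste0("(peak, ", level, ") incidences"),
      n_peaks = n_peaks, pct_peaks_with_te = pct_with_te
    ))
  }
  units <- switch(
    mode,
    incidence = dplyr::distinct(te_rows, .data$peak_id, .data$group),
    rows = te_rows,
    primary_by_max_overlap = te_rows |>
      dplyr::group_by(.data$peak_id) |>
      dplyr::slice_max(.data$overlap_bp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  )
  denom_def <- switch(
    mode,
    incidence = paste0("distinct (peak, ", level, ") incidences"),
    rows = "replicated peak-repeat rows",
    primary_by_max_overlap = "peaks with >=1 repeat (primary repeat only)"
  )
  tbl <- units |>
    dplyr::count(.data$group, name = "count") |>
    dplyr::mutate(percentage = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$group)
  new_composition_summary(
    tbl, level = level, denominator = sum(tbl$count),
    denominator_def = denom_def, n_peaks = n_peaks,
    pct_peaks_with_te = pct_with_te
  )
}

# Internal: long per-gene feature intervals with precedence ranks.
# Rank order: promoter < 5'UTR < CDS < 3'UTR < exon < intron.
gene_feature_intervals <- function(genes, promoter_up = 2000,
                                   promoter_down = 500) {
  one_gene <- function(i) {
    g <- genes[i, ]
    exons <- g$exons[[1]]
    cds <- g$cds[[1]]
    minus <- identical(g$strand, "-")
    prom <- if (minus) {
      tibble::tibble(start = max(0, g$end - promoter_down),
                     end = g$end + promoter_up, feature = "promoter")
    } else {
      tibble::tibble(start = max(0, g$start - promoter_up),
                     end = g$start + promoter_down, feature = "promoter")
    }
    if (nrow(cds) > 0) {
      cds_min <- min(cds$start)
      cds_max <- max(cds$end)
      left <- exons |>
        dplyr::mutate(end = pmin(.data$end, cds_min)) |>
        dplyr::filter(.data$end > .data$start)
      right <- exons |>
        dplyr::mutate(start = pmax(.data$start, cds_max)) |>
        dplyr::filter(.data$end > .data$start)
      left$feature <- if (minus) "3'UTR" else "5'UTR"
      right$feature <- if (minus) "5'UTR" else "3'UTR"
      exonic <- dplyr::bind_rows(
        left, right, dplyr::mutate(cds, feature = "CDS")
      )
    } else {
      exonic <- dplyr::mutate(exons, feature = "exon")
    }
    introns <- tibble::tibble(start = utils::head(sort(exons$end), -1),
                              end = sort(exons$start)[-1]) |>
      dplyr::filter(.data$end > .data$start) |>
      dplyr::mutate(feature = "intron")
    dplyr::bind_rows(prom, exonic, introns) |>
      dplyr::mutate(chrom = g$chrom, gene_id = g$gene_id)
  }
  feats <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), one_gene))
  rank_map <- c("promoter" = 1, "5'UTR" = 2, "CDS" = 3, "3'UTR" = 4,
                "exon" = 5, "intron" = 6)
  feats$rank <- rank_map[feats$feature]
  feats
}

#' Classify peaks into genomic features
#'
#' Assigns exactly one feature label per peak based on its summit position
#' (midpoint when no summit is recorded): `promoter` (a strand-aware
#' `[TSS - promoter_up, TSS + promoter_down)` window), `5'UTR`, `CDS`,
#' `3'UTR` (or undifferentiated `exon` for genes without CDS), `intron`, or
#' `intergenic`. Precedence follows that order; among equal-precedence
#' candidates from overlapping genes the smallest containing feature wins.
#'
#' @param peaks Peak tibble.
#' @param genes Gene models from [read_gene_model()].
#' @param promoter_up,promoter_down Extended-promoter window around the
#'   TSS, in bp upstream/downstream.
#' @return `peaks` with an added `feature` column.
#' @export
classify_peak_features <- function(peaks, genes, promoter_up = 2000,
                                   promoter_down = 500) {
  peaks <- validate_intervals(peaks, "peaks")
  so <- if ("summit_offset" %in% names(peaks)) peaks$summit_offset else
    rep(NA_real_, nrow(peaks))
  pos <- ifelse(!is.na(so), peaks$start + so,
                floor((peaks$start + peaks$end) / 2))
  points <- tibble::tibble(chrom = peaks$chrom, start = pos, end = pos + 1)
  feats <- gene_feature_intervals(genes, promoter_up, promoter_down)
  hits <- find_overlaps(points, feats[, c("chrom", "start", "end")])
  label <- rep("intergenic", nrow(peaks))
  if (nrow(hits) > 0) {
    hits$rank <- feats$rank[hits$subject_index]
    hits$width <- (feats$end - feats$start)[hits$subject_index]
    best <- hits |>
      dplyr::arrange(.data$query_index, .data$rank, .data$width,
                     .data$subject_index) |>
      dplyr::distinct(.data$query_index, .keep_all = TRUE)
    label[best$query_index] <- feats$feature[best$subject_index]
  }
  dplyr::mutate(peaks, feature = label)
}

#' Composition summary of peak feature labels
#'
#' @param classified Output of [classify_peak_features()].
#' @return A `composition_summary` over peaks.
#' @export
feature_composition <- function(classified) {
  if (nrow(classified) == 0L) stop("empty table", call. = FALSE)
  tbl <- classified |>
    dplyr::count(group = .data$feature, name = "count") |>
    dplyr::mutate(percentage = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$group)
  new_composition_summary(
    tbl, level = "feature", denominator = nrow(classified),
    denominator_def = "all peaks (one label each)",
    n_peaks = nrow(classified)
  )
}

#' Label peaks with overlapping cCREs
#'
#' A peak may carry several candidate cis-regulatory element labels (any
#' overlap). Percentages are reported over peaks, so a label's percentage
#' is the share of peaks carrying it and the column need not sum to 100.
#'
#' @param peaks Peak tibble.
#' @param ccres cCRE tibble from [read_ccre()].
#' @return A list: `labels`, a tibble of (peak_id, label) pairs, and
#'   `summary`, a `composition_summary` with percentages over peaks.
#' @export
classify_peak_ccres <- function(peaks, ccres) {
  peaks <- validate_intervals(peaks, "peaks")
  hits <- find_overlaps(peaks, ccres)
  labels <- tibble::tibble(
    peak_id = peaks$peak_id[hits$query_index],
    label = ccres$label[hits$subject_index]
  ) |> dplyr::distinct()
  tbl <- labels |>
    dplyr::count(group = .data$label, name = "count") |>
    dplyr::mutate(percentage = 100 * .data$count / nrow(peaks)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$group)
  summary <- new_composition_summary(
    tbl, level = "ccre", denominator = nrow(peaks),
    denominator_def = "all peaks (multi-label; percentages per peak)",
    n_peaks = nrow(peaks)
  )
  list(labels = labels, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
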