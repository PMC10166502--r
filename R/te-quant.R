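# TE-transcripts-style counting with random multi-mapper assignment,
# median-of-ratios normalisation, a simplified negative-binomial Wald test,
# BH correction, and global / per-chromosome differential expression.

# Deterministic per-read hash: polynomial rolling hash of the read id mixed
# with the seed, Lehmer-mixed; order-invariant across input shuffles.
hash_reads <- function(read_ids, seed) {
  p <- 2147483647
  vapply(strsplit(read_ids, ""), function(chars) {
    h <- (seed %% p)
    for (code in utf8ToInt(paste(chars, collapse = ""))) {
      h <- (h * 31 + code) %% p
    }
    for (k in 1:3) h <- (h * 48271) %% p
    h
  }, numeric(1))
}

#' Resolve multi-mapped reads by deterministic random assignment
#'
#' Each read with several candidate placements (NH > 1) keeps exactly one,
#' chosen uniformly by a counter-based hash of (read id, seed): the same
#' read always resolves the same way for a given seed, independent of
#' input order.
#'
#' @param records Alignment tibble with one row per candidate placement:
#'   `read_id`, `sample`, `chrom`, `start`, `end`, `nh` (the declared
#'   number of placements).
#' @param seed Integer seed driving the assignment.
#' @return One row per read: the chosen placement.
#' @export
assign_multimappers <- function(records, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!"sample" %in% names(records)) records$sample <- "sample_1"
  records <- records |>
    dplyr::group_by(.data$sample, .data$read_id) |>
    dplyr::mutate(.n_placements = dplyr::n()) |>
    dplyr::ungroup()
  bad <- records$.n_placements != records$nh
  if (any(bad)) {
    stop("NH mismatch for read ", records$read_id[bad][1], ": declared ",
         records$nh[bad][1], ", listed ", records$.n_placements[bad][1],
         call. = FALSE)
  }
  # rank placements deterministically within read, then pick hash %% NH
  records <- records |>
    dplyr::arrange(.data$sample, .data$read_id, .data$chrom, .data$start,
                   .data$end)
  keys <- paste(records$sample, records$read_id, sep = "\r")
  first <- !duplicated(keys)
  h <- hash_reads(paste(records$sample[first], records$read_id[first],
                        sep = "\r"), seed)
  chosen_rank <- (h %% records$nh[first]) + 1
  rank_within <- stats::ave(seq_along(keys), keys, FUN = seq_along)
  keep <- rank_within == chosen_rank[match(keys, keys[first])]
  out <- records[keep, setdiff(names(records), c(".n_placements", "nh"))]
  out
}

#' Count assigned reads into TE (and gene) features
#'
#' Each placement is counted to the repeat subfamily containing its
#' midpoint. When gene models are supplied, exonic placements are counted
#' to the gene instead (gene > TE precedence); placements hitting neither
#' are dropped (their number is recorded in attribute `n_unassigned`).
#' TE feature keys are `name:family:class`, aggregated genome-wide in
#' `global` mode and suffixed `:chrom` in `per_chromosome` mode.
#'
#' @param assigned Output of [assign_multimappers()].
#' @param repeats Repeat tibble.
#' @param genes Optional gene models ([read_gene_model()]); `NULL` for
#'   TE-only counting.
#' @param mode `"global"` or `"per_chromosome"`.
#' @return A count tibble: `feature` column plus one column per sample.
#' @export
count_te_features <- function(assigned, repeats, genes = NULL,
                              mode = c("global", "per_chromosome")) {
  mode <- match.arg(mode)
  samples <- unique(assigned$sample)
  mid <- floor((assigned$start + assigned$end) / 2)
  points <- tibble::tibble(chrom = assigned$chrom, start = mid,
                           end = mid + 1)
  feature <- rep(NA_character_, nrow(assigned))
  if (!is.null(genes) && nrow(genes) > 0) {
    exons <- genes |>
      dplyr::select("gene_id", "chrom", "exons") |>
      tidyr::unnest("exons")
    gh <- find_overlaps(points, exons[, c("chrom", "start", "end")])
    gh <- gh[!duplicated(gh$query_index), ]
    feature[gh$query_index] <- exons$gene_id[gh$subject_index]
  }
  th <- find_overlaps(points, repeats[, c("chrom", "start", "end")])
  th$w <- (repeats$end - repeats$start)[th$subject_index]
  th <- th[order(th$query_index, th$w, th$subject_index), ]
  th <- th[!duplicated(th$query_index), ]
  te_key <- paste(repeats$rep_name[th$subject_index],
                  repeats$rep_family[th$subject_index],
                  repeats$rep_class[th$subject_index], sep = ":")
  if (mode == "per_chromosome") {
    te_key <- paste(te_key, repeats$chrom[th$subject_index], sep = ":")
  }
  open <- is.na(feature[th$query_index])
  feature[th$query_index[open]] <- te_key[open]
  n_unassigned <- sum(is.na(feature))
  tab <- tibble::tibble(feature = feature, sample = assigned$sample) |>
    dplyr::filter(!is.na(.data$feature)) |>
    dplyr::count(.data$feature, .data$sample) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$feature)
  for (s in setdiff(samples, names(tab))) tab[[s]] <- 0L
  tab <- tab[, c("feature", samples)]
  attr(tab, "n_unassigned") <- n_unassigned
  tab
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors in the DESeq2 convention: for every
#' feature with all-positive counts, take the ratio of the sample's count
#' to the feature's geometric mean across samples; the sample's factor is
#' the median of those ratios. Factors are rescaled so their geometric
#' mean is 1. If no feature has all-positive counts, features positive in
#' the sample are used instead, with a warning.
#'
#' @param counts Count tibble (`feature` + sample columns) or matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (is.data.frame(counts)) counts_to_matrix(counts) else counts
  log_geo <- rowMeans(log(m))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    warning("no feature has all-positive counts; ",
            "falling back to positive-subset medians", call. = FALSE)
    sf <- apply(m, 2, function(col) {
      lg <- rowMeans(log(m), na.rm = TRUE)
      ok <- col > 0 & is.finite(lg)
      exp(stats::median(log(col[ok]) - lg[ok]))
    })
  } else {
    sf <- apply(m, 2, function(col) {
      exp(stats::median(log(col[usable]) - log_geo[usable]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Simplified negative-binomial Wald test
#'
#' A deliberately compact two-group differential test in the DESeq2 mould:
#' median-of-ratios normalisation, per-feature method-of-moments NB
#' dispersion (floored at 1e-8) shrunk 50/50 toward the mean dispersion
#' across features, a log2 fold change of pseudo-counted (+0.5) group
#' means, a delta-method standard error, and a two-sided normal Wald
#' p-value with Benjamini-Hochberg adjustment. It omits DESeq2's
#' Cox-Reid dispersion shrinkage, LFC shrinkage, Cook's filtering and
#' independent filtering.
#'
#' @param counts Count tibble (`feature` + samples) or matrix.
#' @param condition Two-level factor/character over samples; the first
#'   level is the reference, the fold change is second vs first.
#' @param size_factors Optional precomputed factors; estimated by
#'   [size_factors_median_of_ratios()] when `NULL`.
#' @return A `te_de` tibble: `feature`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`. All-zero features get `NA` test
#'   columns.
#' @export
nb_wald_test <- function(counts, condition, size_factors = NULL) {
  m <- if (is.data.frame(counts)) counts_to_matrix(counts) else counts
  if (!is.factor(condition)) {
    condition <- factor(condition, levels = unique(condition))
  }
  if (nlevels(condition) != 2) {
    stop("condition must have exactly 2 levels", call. = FALSE)
  }
  if (any(table(condition) < 2)) {
    stop("each condition needs >= 2 replicates", call. = FALSE)
  }
  if (length(condition) != ncol(m)) {
    stop("condition length must match sample count", call. = FALSE)
  }
  if (is.null(size_factors)) {
    size_factors <- size_factors_median_of_ratios(m)
  }
  y <- sweep(m, 2, size_factors, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  base_mean <- rowMeans(y)
  # method-of-moments dispersion from pooled within-group residuals
  rss <- rowSums((y[, g1, drop = FALSE] - m1)^2) +
    rowSums((y[, g2, drop = FALSE] - m2)^2)
  var_pooled <- rss / (n1 + n2 - 2)
  alpha_raw <- pmax((var_pooled - base_mean) / base_mean^2, 1e-8)
  alpha_raw[!is.finite(alpha_raw)] <- 1e-8
  alpha <- 0.5 * alpha_raw + 0.5 * mean(alpha_raw[base_mean > 0])
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  # delta method: Var(group mean of K_ij / s_j), K ~ NB(s_j mu, alpha)
  v1 <- (m1 * sum(1 / size_factors[g1]) / n1^2) + alpha * m1^2 / n1
  v2 <- (m2 * sum(1 / size_factors[g2]) / n2^2) + alpha * m2^2 / n2
  lfc_se <- sqrt(v1 / (m1 + 0.5)^2 + v2 / (m2 + 0.5)^2) / log(2)
  stat <- lfc / lfc_se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  zero <- base_mean == 0
  lfc[zero] <- 0
  lfc_se[zero] <- NA_real_
  stat[zero] <- NA_real_
  pvalue[zero] <- NA_real_
  out <- tibble::tibble(
    feature = rownames(m) %||% paste0("feature_", seq_len(nrow(m))),
    baseMean = unname(base_mean),
    log2FoldChange = unname(lfc),
    lfcSE = unname(lfc_se),
    stat = unname(stat),
    pvalue = unname(pvalue),
    padj = unname(bh_adjust(pvalue))
  )
  structure(out, class = c("te_de", class(out)),
            condition_levels = levels(condition),
            n_per_group = c(n1, n2), size_factors = size_factors)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `padj_(k) = min_(k' >= k) m p_(k') / k'`,
#' capped at 1, in the original order. `NA` p-values stay `NA` and do not
#' count toward m.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance threshold summary of a DE table
#'
#' @param de A `te_de` table (or anything with `padj` and
#'   `log2FoldChange`).
#' @param padj_cut Adjusted-p cutoff (exclusive).
#' @param lfc_cut Require `|log2FoldChange| > lfc_cut` (default 0).
#' @return A one-row tibble: `total`, `up`, `down`. `NA` padj rows are
#'   excluded.
#' @export
threshold_summary <- function(de, padj_cut = 0.05, lfc_cut = 0) {
  sig <- !is.na(de$padj) & de$padj < padj_cut &
    abs(de$log2FoldChange) > lfc_cut
  tibble::tibble(
    total = sum(sig),
    up = sum(sig & de$log2FoldChange > 0),
    down = sum(sig & de$log2FoldChange < 0)
  )
}

#' Per-chromosome differential expression
#'
#' Runs the full pipeline (size factors, NB Wald test, BH adjustment)
#' independently within each chromosome's feature set, for count tables
#' whose keys carry a `:chrom` suffix (per-chromosome counting mode). The
#' BH family is the chromosome: locus-specific signal diluted in a
#' genome-wide aggregation can reach significance here.
#'
#' @param counts Per-chromosome-mode count tibble.
#' @param condition Two-level condition over samples.
#' @return Concatenated `te_de` tables with a `chromosome` column.
#'   Chromosomes with fewer than 2 features are skipped with a warning.
#' @export
per_chromosome_de <- function(counts, condition) {
  chrom <- sub(".*:", "", counts$feature)
  pieces <- split(seq_len(nrow(counts)), chrom)
  out <- purrr::map_dfr(names(pieces), function(ch) {
    idx <- pieces[[ch]]
    if (length(idx) < 2) {
      warning("skipping chromosome ", ch, ": fewer than 2 features",
              call. = FALSE)
      return(NULL)
    }
    res <- nb_wald_test(counts[idx, ], condition)
    dplyr::mutate(tibble::as_tibble(res), chromosome = ch, .before = 1)
  })
  out
}

#' @export
tidy.te_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.te_de <- function(x, padj_cut = 0.05, ...) {
  ts <- threshold_summary(x, padj_cut = padj_cut)
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    sig_total = ts$total, sig_up = ts$up, sig_down = ts$down,
    padj_cut = padj_cut
  )
}

#' Volcano plot of a DE result
#'
#' @param object A `te_de` table.
#' @param padj_cut Highlight features below this adjusted p.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_de <- function(object, padj_cut = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$pvalue)) |>
    dplyr::mutate(sig = !is.na(.data$padj) & .data$padj < padj_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2FoldChange,
                                   y = -log10(.data$pvalue),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "firebrick"),
                                 name = paste0("padj < ", padj_cut)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_minimal()
}
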