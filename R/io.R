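# Readers and writers for the external formats the pipeline touches.
# All genomic output tibbles use 0-based half-open coordinates.

ccre_vocabulary <- c("enhD", "enhP", "prom", "CTCF", "K4m3")

# UCSC rmsk table dump column names (17-column dialect).
rmsk_ucsc_cols <- c(
  "bin", "swScore", "milliDiv", "milliDel", "milliIns", "genoName",
  "genoStart", "genoEnd", "genoLeft", "strand", "repName", "repClass",
  "repFamily", "repStart", "repEnd", "repLeft", "id"
)

#' Read a RepeatMasker annotation table
#'
#' Parses either the UCSC rmsk table dump (17 columns, header optional) or a
#' compact 7-column dialect (`genoName genoStart genoEnd strand repName
#' repClass repFamily`). Coordinates are kept 0-based half-open as in the
#' source. Each record carries the strict name/family/class hierarchy
#' (e.g. B1_Mus1 / Alu / SINE).
#'
#' @param path Path to a tab-separated rmsk-style file.
#' @param drop_classes Character vector of repClass values to discard
#'   (default none).
#' @param quiet Suppress the parsed/dropped row count message.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_family`, `rep_class`.
#' @export
read_rmsk <- function(path, drop_classes = character(), quiet = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty rmsk file: ", path, call. = FALSE)
  has_header <- grepl("genoName", lines[1], fixed = TRUE)
  first_data <- strsplit(lines[if (has_header) 2L else 1L], "\t")[[1]]
  ncol_data <- length(first_data)
  if (has_header) {
    header <- strsplit(lines[1], "\t")[[1]]
  } else if (ncol_data == 17L) {
    header <- rmsk_ucsc_cols
  } else if (ncol_data == 7L) {
    header <- c("genoName", "genoStart", "genoEnd", "strand",
                "repName", "repClass", "repFamily")
  } else {
    stop("unknown rmsk dialect: ", ncol_data,
         " columns and no recognisable header", call. = FALSE)
  }
  needed <- c("genoName", "genoStart", "genoEnd", "strand",
              "repName", "repClass", "repFamily")
  if (!all(needed %in% header)) {
    stop("rmsk header lacks required column(s): ",
         paste(setdiff(needed, header), collapse = ", "), call. = FALSE)
  }
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop("malformed rmsk row at line ", bad + offset, ": expected ",
         length(header), " fields, found ", nf[bad], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  start <- suppressWarnings(as.numeric(mat[, "genoStart"]))
  end <- suppressWarnings(as.numeric(mat[, "genoEnd"]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed rmsk row at line ", bad + offset,
         ": non-numeric coordinates", call. = FALSE)
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    stop("malformed rmsk row at line ", bad[1] + offset,
         ": genoEnd <= genoStart", call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = mat[, "genoName"],
    start = start,
    end = end,
    strand = mat[, "strand"],
    rep_name = mat[, "repName"],
    rep_family = mat[, "repFamily"],
    rep_class = mat[, "repClass"]
  )
  if (any(!nzchar(out$rep_name) | !nzchar(out$rep_family) |
          !nzchar(out$rep_class))) {
    bad <- which(!nzchar(out$rep_name) | !nzchar(out$rep_family) |
                   !nzchar(out$rep_class))[1]
    stop("malformed rmsk row at line ", bad + offset,
         ": empty repeat name/family/class", call. = FALSE)
  }
  dropped <- out$rep_class %in% drop_classes
  if (!quiet) {
    message("read_rmsk: parsed ", nrow(out), " rows, dropped ",
            sum(dropped), " by class filter")
  }
  out[!dropped, ]
}

#' Read peak calls
#'
#' Supported dialects: ENCODE `narrowPeak` (BED6+4; column 10 is the summit
#' offset, -1 meaning absent), plain `bed` (3-6 columns, no summit), and
#' MACS2 `.xls` output (1-based starts, converted; significance kept on the
#' -log10 scale). The q-value significance filter is deliberately not
#' applied here.
#'
#' @param path Input file.
#' @param dialect One of `"narrowPeak"`, `"bed"`, `"macs2_xls"`.
#' @return A tibble of peaks: `peak_id`, `chrom`, `start`, `end`, `strand`,
#'   `score`, `q_value`, `summit_offset`; attribute `q_scale` records
#'   whether `q_value` is `"neglog10"` or absent (`NA`). Missing names are
#'   synthesised as `peak_<n>`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed", "macs2_xls")) {
  dialect <- match.arg(dialect)
  if (dialect == "macs2_xls") {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    out <- tibble::tibble(
      peak_id = as.character(tab$name),
      chrom = as.character(tab$chr),
      start = as.numeric(tab$start) - 1,    # MACS2 xls is 1-based
      end = as.numeric(tab$end),
      strand = ".",
      score = as.numeric(tab$fold_enrichment),
      q_value = as.numeric(tab[["-log10(qvalue)"]]),
      summit_offset = as.numeric(tab$abs_summit) - as.numeric(tab$start)
    )
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(X1 = readr::col_character()))
    nc <- ncol(tab)
    if (dialect == "narrowPeak" && nc < 10L) {
      stop("narrowPeak requires 10 columns, found ", nc, call. = FALSE)
    }
    out <- tibble::tibble(
      peak_id = if (nc >= 4L) as.character(tab[[4]]) else NA_character_,
      chrom = tab[[1]],
      start = as.numeric(tab[[2]]),
      end = as.numeric(tab[[3]]),
      strand = if (nc >= 6L) as.character(tab[[6]]) else ".",
      score = if (dialect == "narrowPeak") as.numeric(tab[[7]])
              else if (nc >= 5L) as.numeric(tab[[5]]) else NA_real_,
      q_value = if (dialect == "narrowPeak") as.numeric(tab[[9]]) else NA_real_,
      summit_offset = if (dialect == "narrowPeak") as.numeric(tab[[10]])
                      else NA_real_
    )
    out$summit_offset[!is.na(out$summit_offset) & out$summit_offset < 0 &
                        out$summit_offset != -1] <- NaN
    if (any(is.nan(out$summit_offset))) {
      stop("negative summit offset at row ", which(is.nan(out$summit_offset))[1],
           call. = FALSE)
    }
    out$summit_offset[out$summit_offset == -1] <- NA_real_
  }
  missing_id <- is.na(out$peak_id) | out$peak_id == "." | out$peak_id == ""
  out$peak_id[missing_id] <- paste0("peak_", which(missing_id))
  if (anyDuplicated(out$peak_id)) {
    stop("duplicate peak id: ", out$peak_id[duplicated(out$peak_id)][1],
         call. = FALSE)
  }
  validate_intervals(out, "peaks")
  bad_summit <- !is.na(out$summit_offset) &
    (out$summit_offset < 0 | out$summit_offset >= out$end - out$start)
  if (any(bad_summit)) {
    stop("summit offset outside peak at row ", which(bad_summit)[1],
         call. = FALSE)
  }
  attr(out, "q_scale") <- if (dialect == "bed") NA_character_ else "neglog10"
  out
}

#' Write peaks as narrowPeak
#'
#' Deterministic 10-column ENCODE narrowPeak output; inverse of
#' [read_peaks()] for the fields that format carries.
#'
#' @param peaks A peak tibble as produced by [read_peaks()] or
#'   [simulate_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = peaks$peak_id,
    score = 0L,
    strand = ifelse(is.na(peaks$strand) | peaks$strand == "", ".",
                    peaks$strand),
    signalValue = peaks$score,
    pValue = -1,
    qValue = ifelse(is.na(peaks$q_value), -1, peaks$q_value),
    peak = ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' Builds one model per gene: the per-gene union of exons over all its
#' transcripts, the gene span, and the CDS union where annotated. GTF input
#' (1-based closed) is converted to 0-based half-open. Transcripts without
#' exon records are skipped with a warning.
#'
#' @param path Input annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, plus list-columns `exons` and `cds`, each a
#'   tibble of `start`/`end` intervals (sorted, non-overlapping).
#' @export
read_gene_model <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% names(md)) {
      stop("GTF lacks gene_id attributes", call. = FALSE)
    }
    ex <- gr[md$type == "exon"]
    if ("transcript_id" %in% names(md)) {
      tx_all <- unique(stats::na.omit(md$transcript_id[md$type %in%
                                        c("transcript", "exon")]))
      tx_with_exons <- unique(S4Vectors::mcols(ex)$transcript_id)
      orphans <- setdiff(tx_all, tx_with_exons)
      if (length(orphans) > 0) {
        warning("skipping ", length(orphans),
                " transcript(s) without exon records: ",
                paste(utils::head(orphans, 3), collapse = ", "),
                call. = FALSE)
      }
    }
    cds <- gr[md$type == "CDS"]
    genes <- unique(S4Vectors::mcols(ex)$gene_id)
    build_one <- function(g) {
      e <- GenomicRanges::reduce(ex[S4Vectors::mcols(ex)$gene_id == g])
      cd <- GenomicRanges::reduce(cds[S4Vectors::mcols(cds)$gene_id == g])
      name <- S4Vectors::mcols(ex)$gene_name[
        S4Vectors::mcols(ex)$gene_id == g][1]
      tibble::tibble(
        gene_id = g,
        gene_name = if (is.null(name) || is.na(name)) g else name,
        chrom = as.character(GenomicRanges::seqnames(e))[1],
        start = min(GenomicRanges::start(e)) - 1,
        end = max(GenomicRanges::end(e)),
        strand = as.character(GenomicRanges::strand(e))[1],
        exons = list(tibble::tibble(
          start = GenomicRanges::start(e) - 1,
          end = as.numeric(GenomicRanges::end(e)))),
        cds = list(tibble::tibble(
          start = GenomicRanges::start(cd) - 1,
          end = as.numeric(GenomicRanges::end(cd))))
      )
    }
    out <- dplyr::bind_rows(lapply(genes, build_one))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(S4Vectors::mcols(gr)$blocks)) {
      stop("BED12 input required: no block definitions found", call. = FALSE)
    }
    build_one <- function(i) {
      blocks <- S4Vectors::mcols(gr)$blocks[[i]]
      gstart <- GenomicRanges::start(gr)[i] - 1   # back to 0-based
      exons <- tibble::tibble(
        start = gstart + IRanges::start(blocks) - 1,
        end = gstart + as.numeric(IRanges::end(blocks))
      )
      thick <- S4Vectors::mcols(gr)$thick[i]
      cds <- tibble::tibble(start = numeric(), end = numeric())
      if (!is.null(thick) && IRanges::width(thick) > 1) {
        ts <- IRanges::start(thick) - 1
        te <- as.numeric(IRanges::end(thick))
        cds <- exons |>
          dplyr::mutate(start = pmax(.data$start, ts),
                        end = pmin(.data$end, te)) |>
          dplyr::filter(.data$end > .data$start)
      }
      nm <- S4Vectors::mcols(gr)$name[i]
      tibble::tibble(
        gene_id = if (is.null(nm) || is.na(nm)) paste0("gene_", i) else nm,
        gene_name = .data$gene_id,
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = gstart,
        end = as.numeric(GenomicRanges::end(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        exons = list(exons),
        cds = list(cds)
      )
    }
    out <- dplyr::bind_rows(lapply(seq_along(gr), build_one))
  }
  out$strand[!out$strand %in% c("+", "-")] <- "."
  out
}

#' Read ENCODE candidate cis-regulatory elements
#'
#' BED input with the cCRE label (`enhD`, `enhP`, `prom`, `CTCF`, `K4m3`)
#' in a configurable column (default the BED name column).
#'
#' @param path Input BED file.
#' @param label_col Column index holding the label.
#' @param on_bad_label `"warn"` (keep rows, warn once) or `"error"`.
#' @return A tibble `chrom`, `start`, `end`, `label`.
#' @export
read_ccre <- function(path, label_col = 4L,
                      on_bad_label = c("warn", "error")) {
  on_bad_label <- match.arg(on_bad_label)
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(X1 = readr::col_character()))
  if (ncol(tab) < label_col) {
    stop("cCRE file has no column ", label_col, call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = tab[[1]],
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    label = as.character(tab[[label_col]])
  )
  bad <- !out$label %in% ccre_vocabulary
  if (any(bad)) {
    msg <- paste0(sum(bad), " cCRE label(s) outside vocabulary {",
                  paste(ccre_vocabulary, collapse = ", "), "}: ",
                  paste(unique(out$label[bad])[1:min(3, sum(bad))],
                        collapse = ", "))
    if (on_bad_label == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  validate_intervals(out, "cCREs")
  out
}

#' Read a feature-by-sample count table
#'
#' Tab-separated with a header; the first column is the feature key, all
#' remaining columns are sample counts (non-negative).
#'
#' @param path Input TSV.
#' @return A tibble whose first column is `feature`.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) stop("count table needs >= 2 columns", call. = FALSE)
  names(tab)[1] <- "feature"
  tab$feature <- as.character(tab$feature)
  vals <- as.matrix(tab[, -1])
  if (!is.numeric(vals)) stop("non-numeric counts", call. = FALSE)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative count at feature ",
         tab$feature[which(rowSums(vals < 0) > 0)[1]], call. = FALSE)
  }
  tab
}

#' Write a result table as TSV
#'
#' Deterministic column and row order (rows written as given); `NA` written
#' literally.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Internal: count tibble (feature + samples) -> integer matrix.
counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "feature"), drop = FALSE])
  rownames(m) <- counts$feature
  storage.mode(m) <- "double"
  m
}
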