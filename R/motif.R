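# Position-weight matrices, exact p-values under an i.i.d. background,
# FIMO-style scanning, motif-in-TE accounting, and frameshift ORF
# prediction. The motif scanner is scoring-only: motif discovery is out of
# scope and the motif matrix is user input.

dna_bases <- c("A", "C", "G", "T")

new_pwm <- function(probs, background, pseudocount) {
  stopifnot(nrow(probs) == 4)
  rownames(probs) <- dna_bases
  background <- background / sum(background)
  names(background) <- dna_bases
  structure(
    list(
      width = ncol(probs),
      probs = probs,
      background = background,
      pseudocount = pseudocount,
      log_odds = log2(probs / background)   # bits
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM: width", x$width, "bp; background",
      paste(sprintf("%s=%.3f", dna_bases, x$background), collapse = " "),
      "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a position-weight matrix
#'
#' From aligned binding-site sequences (all the same length) or a 4 x W
#' count/probability matrix (rows A, C, G, T). Columns are normalised to
#' probabilities after adding the pseudocount; the log-odds matrix (bits)
#' is taken against the background.
#'
#' @param sites Character vector of equal-length DNA sites, or a 4 x W
#'   numeric matrix of per-position counts.
#' @param pseudocount Added to every count before normalisation.
#' @param background Base frequencies (A, C, G, T); uniform by default.
#' @return A `pwm` object.
#' @export
build_pwm <- function(sites, pseudocount = 0.25,
                      background = rep(0.25, 4)) {
  if (is.character(sites)) {
    widths <- nchar(sites)
    if (length(unique(widths)) != 1L) {
      stop("ragged site set: all sites must have equal length",
           call. = FALSE)
    }
    chars <- do.call(rbind, strsplit(toupper(sites), ""))
    counts <- vapply(seq_len(ncol(chars)), function(j) {
      tabulate(match(chars[, j], dna_bases), nbins = 4)
    }, numeric(4))
  } else {
    counts <- as.matrix(sites)
    if (nrow(counts) != 4) stop("count matrix must be 4 x W", call. = FALSE)
    if (any(counts < 0)) stop("negative counts", call. = FALSE)
  }
  counts <- counts + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  new_pwm(probs, background, pseudocount)
}

#' Exact PWM score to p-value map
#'
#' Computes P(score >= s) for a window drawn i.i.d. from the background,
#' by position-wise convolution of the per-position score distributions
#' discretised at `resolution` bits (the standard exact-null dynamic
#' programme used by motif scanners).
#'
#' @param pwm A `pwm` object (finite log-odds; guaranteed by a positive
#'   pseudocount or background floor).
#' @param resolution Score discretisation step, in bits.
#' @param max_bins Safety cap on the discretised support size.
#' @return A `pwm_pvalues` object usable with [pwm_pvalue()] and
#'   [scan_sequences()].
#' @export
exact_pvalues <- function(pwm, resolution = 1e-3, max_bins = 5e7) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(!is.finite(pwm$log_odds))) {
    stop("PWM has infinite log-odds; rebuild with a positive pseudocount",
         call. = FALSE)
  }
  ints <- round(pwm$log_odds / resolution)
  lo_min <- sum(apply(ints, 2, min))
  lo_max <- sum(apply(ints, 2, max))
  n_bins <- lo_max - lo_min + 1
  if (n_bins > max_bins) {
    stop("discretised score support has ", n_bins,
         " bins; increase `resolution`", call. = FALSE)
  }
  # dist[k] = P(partial score == lo_min_partial + k - 1)
  dist <- 1
  dmin <- 0
  for (j in seq_len(pwm$width)) {
    col <- ints[, j]
    cmin <- min(col)
    span <- max(col) - cmin
    new <- numeric(length(dist) + span)
    for (b in 1:4) {
      off <- col[b] - cmin
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * pwm$background[b]
    }
    dist <- new
    dmin <- dmin + cmin
  }
  tail_p <- rev(cumsum(rev(dist)))
  tail_p <- pmin(tail_p, 1)
  structure(
    list(resolution = resolution, int_min = dmin, tail = tail_p,
         int_scores = ints, width = pwm$width),
    class = "pwm_pvalues"
  )
}

#' Look up the exact p-value of a PWM score
#'
#' The null distribution lives on a discretised score grid whose bins are
#' sums of per-position rounded log-odds, so a real score can land up to
#' `W/2` bins away from its own bin. With `snap = TRUE` (default) the
#' lookup moves to the nearest achievable (positive-probability) bin
#' within that tolerance, which makes the lookup exact whenever distinct
#' achievable scores are separated by more than `W * resolution` bits.
#'
#' @param pvmap A `pwm_pvalues` object.
#' @param score Numeric score(s) in bits.
#' @param snap Snap to the nearest achievable score bin (see Details).
#' @return P(score >= s) under the background, in (0, 1].
#' @export
pwm_pvalue <- function(pvmap, score, snap = TRUE) {
  n_bins <- length(pvmap$tail)
  idx <- round(score / pvmap$resolution) - pvmap$int_min + 1
  if (snap) {
    dist0 <- c(-diff(c(pvmap$tail, 0)))   # per-bin probability mass
    occupied <- which(dist0 > 0)
    slack <- ceiling(pvmap$width / 2)
    idx <- vapply(idx, function(i) {
      near <- occupied[abs(occupied - i) <= slack]
      if (length(near) == 0) i else near[which.min(abs(near - i))]
    }, numeric(1))
  }
  idx <- pmax(1, idx)
  p <- rep(0, length(score))
  inside <- idx <= n_bins
  p[inside] <- pvmap$tail[idx[inside]]
  p
}

# Internal: integer window scores for one integer-coded sequence.
window_scores_int <- function(idx, ints) {
  W <- ncol(ints)
  n_win <- length(idx) - W + 1
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(W)) {
    b <- idx[seq_len(n_win) + j - 1]
    miss <- is.na(b)
    ok <- ok & !miss
    b[miss] <- 1L
    sc <- sc + ints[cbind(b, j)]
  }
  sc[!ok] <- NA
  sc
}

#' Scan sequences for PWM matches
#'
#' Scores every window of width W on one or both strands and reports those
#' whose exact p-value is at or below the threshold. Windows containing N
#' are skipped; sequences shorter than W yield no hits. Unless a
#' background is supplied, the 0-order background is estimated from the
#' scanned sequences themselves and the PWM log-odds are re-derived
#' against it.
#'
#' @param pwm A `pwm` object.
#' @param sequences Named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param p_threshold Report windows with p-value <= this.
#' @param both_strands Also scan the reverse strand.
#' @param background Optional base frequencies (A, C, G, T) overriding the
#'   estimate from the sequences.
#' @return A tibble of hits: `seq_id`, `offset` (0-based, forward-strand
#'   coordinates of the window start), `strand`, `score` (bits),
#'   `p_value`; ordered by input sequence, offset, strand. The motif width
#'   is attached as attribute `motif_width`.
#' @export
scan_sequences <- function(pwm, sequences, p_threshold = 1e-4,
                           both_strands = TRUE, background = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(sequences, ""), use.names = FALSE),
                        levels = dna_bases))
    background <- as.numeric(tab)
    if (sum(background) == 0) background <- rep(1, 4)
    background <- pmax(background, 1)   # floor: no zero-frequency base
  }
  pwm <- new_pwm(pwm$probs, background, pwm$pseudocount)
  pvmap <- exact_pvalues(pwm)
  W <- pwm$width
  ints <- pvmap$int_scores
  lo <- pwm$log_odds
  scan_one <- function(seq, strand) {
    if (strand == "-") {
      seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    idx <- match(strsplit(seq, "")[[1]], dna_bases)
    sci <- window_scores_int(idx, ints)
    if (length(sci) == 0) return(NULL)
    p <- rep(NA_real_, length(sci))
    p[!is.na(sci)] <- pvmap$tail[
      pmax(1, pmin(length(pvmap$tail),
                   sci[!is.na(sci)] - pvmap$int_min + 1))]
    keep <- which(!is.na(p) & p <= p_threshold)
    if (length(keep) == 0) return(NULL)
    off <- keep - 1L
    if (strand == "-") off <- nchar(seq) - W - off
    real <- vapply(keep, function(k) {
      sum(lo[cbind(idx[k:(k + W - 1)], seq_len(W))])
    }, numeric(1))
    tibble::tibble(offset = off, strand = strand, score = real,
                   p_value = p[keep])
  }
  strands <- if (both_strands) c("+", "-") else "+"
  out <- purrr::map_dfr(names(sequences), function(id) {
    hits <- dplyr::bind_rows(
      lapply(strands, function(s) scan_one(sequences[[id]], s)))
    if (nrow(hits) == 0) return(hits)
    hits$seq_id <- id
    hits
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(seq_id = character(), offset = integer(),
                          strand = character(), score = numeric(),
                          p_value = numeric())
  } else {
    out <- out[, c("seq_id", "offset", "strand", "score", "p_value")]
    out <- out[order(match(out$seq_id, names(sequences)), out$offset,
                     out$strand), ]
  }
  attr(out, "motif_width") <- W
  out
}

#' Assign motif hits to the repeats under their peaks
#'
#' Maps each hit back to genomic coordinates through its peak, assigns it
#' to the repeat whose interval contains the hit midpoint (half-open;
#' nested repeats resolve to the smallest), or to `"none"`, and summarises
#' the distribution of hits across repeat classes (or families within a
#' class).
#'
#' @param hits Output of [scan_sequences()] where `seq_id` is a peak id.
#' @param annotation Output of [annotate_peaks_with_tes()] for the same
#'   peaks.
#' @param level `"class"` or `"family"`.
#' @param within_class Optional class; restrict to hits in that class and
#'   summarise families.
#' @param motif_width Motif width in bp; defaults to the attribute left by
#'   [scan_sequences()].
#' @return A `composition_summary` with percentages over hits, plus the
#'   per-hit assignment in attribute `assignments`.
#' @export
motif_te_occurrence <- function(hits, annotation,
                                level = c("class", "family"),
                                within_class = NULL,
                                motif_width = attr(hits, "motif_width")) {
  level <- match.arg(level)
  if (is.null(motif_width)) stop("motif_width is required", call. = FALSE)
  peak_rows <- annotation |>
    dplyr::distinct(.data$peak_id, .keep_all = TRUE)
  unknown <- setdiff(hits$seq_id, peak_rows$peak_id)
  if (length(unknown) > 0) {
    stop("hit(s) outside every peak: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  hits$mid <- peak_rows$start[match(hits$seq_id, peak_rows$peak_id)] +
    hits$offset + floor(motif_width / 2)
  te_rows <- annotation[!is.na(annotation$rep_class), ]
  assigned <- hits |>
    dplyr::left_join(
      te_rows[, c("peak_id", "rep_name", "rep_family", "rep_class",
                  "te_start", "te_end")],
      by = c("seq_id" = "peak_id"), relationship = "many-to-many") |>
    dplyr::mutate(
      contains = !is.na(.data$te_start) & .data$te_start <= .data$mid &
        .data$mid < .data$te_end,
      te_width = .data$te_end - .data$te_start
    ) |>
    dplyr::group_by(.data$seq_id, .data$offset, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$contains), .data$te_width,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      rep_class = dplyr::if_else(.data$contains, .data$rep_class, "none"),
      rep_family = dplyr::if_else(.data$contains, .data$rep_family, "none"),
      rep_name = dplyr::if_else(.data$contains, .data$rep_name, "none")
    )
  pool <- assigned
  if (!is.null(within_class)) {
    pool <- pool[pool$rep_class == within_class, ]
    level <- "family"
  }
  pool$group <- if (level == "class") pool$rep_class else pool$rep_family
  tbl <- pool |>
    dplyr::count(.data$group, name = "count") |>
    dplyr::mutate(percentage = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$group)
  out <- new_composition_summary(
    tbl, level = paste0("motif_", level), denominator = sum(tbl$count),
    denominator_def = "motif hits (midpoint assignment)"
  )
  attr(out, "assignments") <- assigned
  out
}

#' Predict the ORF produced by a deletion in a CDS
#'
#' Applies a deletion to a coding sequence, translates from the original
#' ATG to the first in-frame stop (standard genetic code), and counts the
#' missense residues, i.e. positions of the truncated peptide that differ
#' from the reference protein. An out-of-frame deletion typically yields a
#' short peptide: the intact prefix followed by a missense tail ending at
#' a novel stop.
#'
#' @param cds Coding DNA string beginning with ATG.
#' @param del_start 0-based offset of the first deleted base.
#' @param del_len Number of deleted bases.
#' @param reference_protein Reference amino-acid string; defaults to the
#'   translation of the intact `cds`.
#' @return A list: `peptide`, `length`, `missense_count`, `stop_found`
#'   (FALSE flags a runaway translation that never met a stop).
#' @export
frameshift_orf <- function(cds, del_start, del_len,
                           reference_protein = NULL) {
  cds <- toupper(cds)
  if (!startsWith(cds, "ATG")) stop("CDS must begin with ATG", call. = FALSE)
  if (del_start < 0 || del_start + del_len > nchar(cds)) {
    stop("deletion outside CDS", call. = FALSE)
  }
  translate_to_stop <- function(seq) {
    n_codon <- nchar(seq) %/% 3
    if (n_codon == 0) return(list(pep = "", stop_found = FALSE))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, 1, 3 * n_codon)),
      if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0) {
      list(pep = substr(aa, 1, stop_at - 1), stop_found = TRUE)
    } else {
      list(pep = aa, stop_found = FALSE)
    }
  }
  if (is.null(reference_protein)) {
    reference_protein <- translate_to_stop(cds)$pep
  }
  mutated <- paste0(substr(cds, 1, del_start),
                    substr(cds, del_start + del_len + 1, nchar(cds)))
  tr <- translate_to_stop(mutated)
  mut_aa <- strsplit(tr$pep, "")[[1]]
  ref_aa <- strsplit(reference_protein, "")[[1]]
  n <- length(mut_aa)
  missense <- if (n == 0) 0L else if (del_len %% 3 == 0) {
    # in-frame: residues after the junction align to the reference
    # shifted by the deleted codons, so a clean codon-aligned deletion
    # yields no missense
    shift <- del_len %/% 3
    intact <- del_start %/% 3
    ref_idx <- ifelse(seq_len(n) <= intact, seq_len(n),
                      seq_len(n) + shift)
    ref_pad <- c(ref_aa, rep("", max(0, max(ref_idx) -
                                       length(ref_aa))))[ref_idx]
    sum(mut_aa != ref_pad)
  } else {
    # frameshift: positional comparison against the reference prefix
    ref_pad <- c(ref_aa, rep("", max(0, n - length(ref_aa))))[seq_len(n)]
    sum(mut_aa != ref_pad)
  }
  list(peptide = tr$pep, length = n, missense_count = as.integer(missense),
       stop_found = tr$stop_found)
}

#' Read a MEME-minimal motif file
#'
#' Parses the first motif of a MEME minimal-format text file into a
#' [build_pwm()]-style object, using the file's background letter
#' frequencies when present (uniform otherwise).
#'
#' @param path Input file.
#' @return A `pwm` object.
#' @export
read_meme <- function(path) {
  lines <- readr::read_lines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)]
    if (length(bg) != 4) stop("malformed background line", call. = FALSE)
  }
  hdr_at <- grep("^letter-probability matrix", lines)
  if (length(hdr_at) == 0) {
    stop("no letter-probability matrix found", call. = FALSE)
  }
  hdr <- lines[hdr_at[1]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  rows <- lines[(hdr_at[1] + 1):(hdr_at[1] + w)]
  probs <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4), USE.NAMES = FALSE))
  new_pwm(t(probs), bg, pseudocount = 0)
}

#' Write a PWM as MEME-minimal text
#'
#' @param pwm A `pwm` object.
#' @param path Output path.
#' @param name Motif name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif_1") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", dna_bases, pwm$background), collapse = " "),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            pwm$width),
    apply(pwm$probs, 2, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    })
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 70)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Input FASTA.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
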