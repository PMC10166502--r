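# Ground-truth generators for every input class the pipeline consumes:
# repeat annotations, biased peak sets, NB count matrices, multi-mapped
# alignments and motif-planted sequences. Each generator is seeded and
# restores the caller's RNG state.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a repeat annotation with controllable coverage ratios
#'
#' Places non-overlapping repeat copies uniformly over a genome so that
#' each subfamily's realised coverage ratio approximates its target. Copy
#' lengths are drawn around `mean_len` (sd 10%, floored at 20 bp).
#'
#' @param genome Tibble of `chrom`, `length` (bp).
#' @param te_spec Tibble with one row per subfamily: `rep_name`,
#'   `rep_family`, `rep_class`, `mean_len`, `target_ratio`. Target ratios
#'   must sum to < 0.95 (non-overlapping packing needs headroom).
#' @param seed Integer seed.
#' @return A repeat tibble ([read_rmsk()] layout) with attributes
#'   `chrom_sizes` (the input genome) and `truth` (target vs realised
#'   coverage ratio per subfamily).
#' @export
simulate_repeat_annotation <- function(genome, te_spec, seed) {
  stopifnot(all(c("chrom", "length") %in% names(genome)),
            all(c("rep_name", "rep_family", "rep_class", "mean_len",
                  "target_ratio") %in% names(te_spec)))
  if (sum(te_spec$target_ratio) >= 0.95) {
    stop("infeasible packing: total target coverage must stay below 0.95",
         call. = FALSE)
  }
  total_bp <- sum(genome$length)
  local_seed(seed, {
    occupied <- stats::setNames(
      replicate(nrow(genome), list(start = numeric(), end = numeric()),
                simplify = FALSE),
      genome$chrom)
    rows <- list()
    for (i in seq_len(nrow(te_spec))) {
      spec <- te_spec[i, ]
      n_copies <- round(spec$target_ratio * total_bp / spec$mean_len)
      if (n_copies == 0) next
      lens <- pmax(20, round(stats::rnorm(n_copies, spec$mean_len,
                                          0.1 * spec$mean_len)))
      chrom_idx <- sample.int(nrow(genome), n_copies, replace = TRUE,
                              prob = genome$length)
      for (k in seq_len(n_copies)) {
        ch <- genome$chrom[chrom_idx[k]]
        L <- genome$length[chrom_idx[k]]
        len <- min(lens[k], L)
        placed <- FALSE
        for (attempt in 1:200) {
          s <- floor(stats::runif(1, 0, L - len))
          occ <- occupied[[ch]]
          if (!any(s < occ$end & s + len > occ$start)) {
            occupied[[ch]]$start <- c(occ$start, s)
            occupied[[ch]]$end <- c(occ$end, s + len)
            rows[[length(rows) + 1]] <- tibble::tibble(
              chrom = ch, start = s, end = s + len,
              strand = sample(c("+", "-"), 1),
              rep_name = spec$rep_name, rep_family = spec$rep_family,
              rep_class = spec$rep_class)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("infeasible packing: could not place a ", spec$rep_name,
               " copy after 200 attempts", call. = FALSE)
        }
      }
    }
    out <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$chrom, .data$start)
    truth <- te_spec |>
      dplyr::rowwise() |>
      dplyr::mutate(realized_ratio = sum(
        out$end[out$rep_name == .data$rep_name] -
          out$start[out$rep_name == .data$rep_name]) / total_bp) |>
      dplyr::ungroup()
    attr(out, "chrom_sizes") <- genome
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate peaks with a planted repeat-family placement bias
#'
#' Draws each peak center from a mixture: with probability `b_f * c_f`
#' (planted fold times genomic coverage ratio of family f) the center
#' falls uniformly inside a copy of family f; with the remaining
#' probability it falls uniformly over repeat-free sequence. The planted
#' fold `b_f` is therefore exactly the expected enrichment of family f
#' measured as the fraction of peaks overlapping it over its coverage
#' ratio, which is what makes the generator a ground-truth oracle for the
#' enrichment estimator. Requires `sum(b_f * c_f) <= 1`.
#'
#' @param repeats Repeat tibble (typically from
#'   [simulate_repeat_annotation()]).
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param n_peaks Number of peaks.
#' @param bias Named numeric vector of placement folds per `rep_family`
#'   (families not named get fold 1... i.e. no preference beyond their
#'   genomic share via the background component).
#' @param peak_len Mean peak length (sd 10%, floored at 20 bp).
#' @param seed Integer seed.
#' @return A peak tibble with attribute `truth` recording each peak's
#'   generating component (`background` or a family name).
#' @export
simulate_peaks <- function(repeats, chrom_sizes, n_peaks, bias = c(),
                           peak_len = 50, seed = 1) {
  if (n_peaks == 0) {
    out <- tibble::tibble(peak_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character(), score = numeric(),
                          q_value = numeric(), summit_offset = numeric())
    attr(out, "truth") <- tibble::tibble(peak_id = character(),
                                         source = character())
    return(out)
  }
  total_bp <- sum(chrom_sizes$length)
  fams <- unique(repeats$rep_family)
  cov <- vapply(fams, function(f) {
    coverage_bp(repeats[repeats$rep_family == f, ]) / total_bp
  }, numeric(1))
  b <- stats::setNames(rep(1, length(fams)), fams)
  if (length(bias) > 0) {
    extra <- setdiff(names(bias), fams)
    if (length(extra) > 0) {
      stop("bias names a family with zero copies: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    b[names(bias)] <- bias
  }
  w <- b * cov
  if (sum(w) > 1) {
    stop("sum(bias * coverage) exceeds 1; lower the bias or coverage",
         call. = FALSE)
  }
  local_seed(seed, {
    comp <- sample(c(fams, "background"), n_peaks, replace = TRUE,
                   prob = c(w, 1 - sum(w)))
    lens <- pmax(20, round(stats::rnorm(n_peaks, peak_len,
                                        0.1 * peak_len)))
    centers <- matrix(NA_real_, n_peaks, 1)
    chroms <- character(n_peaks)
    pos <- numeric(n_peaks)
    for (k in seq_len(n_peaks)) {
      if (comp[k] == "background") {
        repeat {
          ci <- sample.int(nrow(chrom_sizes), 1,
                           prob = chrom_sizes$length)
          p <- floor(stats::runif(1, 0, chrom_sizes$length[ci]))
          ch <- chrom_sizes$chrom[ci]
          inside_te <- any(repeats$chrom == ch & repeats$start <= p &
                             p < repeats$end)
          if (!inside_te) break
        }
      } else {
        copies <- which(repeats$rep_family == comp[k])
        ci <- copies[sample.int(length(copies), 1,
                                prob = repeats$end[copies] -
                                  repeats$start[copies])]
        ch <- repeats$chrom[ci]
        p <- floor(stats::runif(1, repeats$start[ci], repeats$end[ci]))
      }
      chroms[k] <- ch
      pos[k] <- p
    }
    half <- floor(lens / 2)
    chrom_len <- chrom_sizes$length[match(chroms, chrom_sizes$chrom)]
    start <- pmax(0, pos - half)
    end <- pmin(chrom_len, start + lens)
    start <- pmax(0, end - lens)
    out <- tibble::tibble(
      peak_id = sprintf("peak_%05d", seq_len(n_peaks)),
      chrom = chroms, start = start, end = end, strand = ".",
      score = round(stats::runif(n_peaks, 5, 50), 3),
      q_value = round(stats::runif(n_peaks, 2, 20), 3),
      summit_offset = pos - start
    )
    attr(out, "truth") <- tibble::tibble(peak_id = out$peak_id,
                                         source = comp)
    attr(out, "bias") <- b
    out
  })
}

#' Simulate an NB count matrix with known fold changes
#'
#' Feature means are log-normal; a fraction of features carry a true
#' log2 fold change of +/- `lfc` (split symmetrically across groups);
#' counts are negative-binomial with the given dispersion and per-sample
#' depth multipliers.
#'
#' @param n_features Number of features.
#' @param n_per_group Replicates per group, length 2.
#' @param depth Per-sample depth multipliers (recycled; geometric mean
#'   need not be 1 -- size-factor estimation is tested against it).
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param frac_de Fraction of features with a true effect.
#' @param lfc Absolute true log2 fold change of affected features.
#' @param mean_log_mu,sd_log_mu Log-normal parameters of feature means.
#' @param seed Integer seed.
#' @return A count tibble with attribute `truth` (feature, `true_lfc`,
#'   `base_mean`) and attribute `depths`.
#' @export
simulate_counts <- function(n_features = 2000, n_per_group = c(4, 4),
                            depth = 1, dispersion = 0.05, frac_de = 0.05,
                            lfc = 2, mean_log_mu = log(100),
                            sd_log_mu = 1, seed = 1) {
  n_samples <- sum(n_per_group)
  depth <- rep_len(depth, n_samples)
  local_seed(seed, {
    q <- exp(stats::rnorm(n_features, mean_log_mu, sd_log_mu))
    true_lfc <- numeric(n_features)
    n_de <- round(frac_de * n_features)
    if (n_de > 0) {
      idx <- sample.int(n_features, n_de)
      true_lfc[idx] <- sample(c(-lfc, lfc), n_de, replace = TRUE)
    }
    group <- rep(c(1, 2), n_per_group)
    mu <- outer(q, rep(1, n_samples)) *
      2^(outer(true_lfc, ifelse(group == 2, 0.5, -0.5))) *
      outer(rep(1, n_features), depth)
    k <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = n_features)
    samples <- paste0(rep(c("ctrl_", "trt_"), n_per_group),
                      c(seq_len(n_per_group[1]), seq_len(n_per_group[2])))
    out <- tibble::as_tibble(as.data.frame(k))
    names(out) <- samples
    out <- dplyr::bind_cols(
      tibble::tibble(feature = sprintf("feat_%05d", seq_len(n_features))),
      out)
    attr(out, "truth") <- tibble::tibble(
      feature = out$feature, true_lfc = true_lfc, base_mean = q)
    attr(out, "depths") <- stats::setNames(depth, samples)
    attr(out, "condition") <- rep(c("ctrl", "trt"), n_per_group)
    out
  })
}

#' Simulate multi-mapped read alignments with known origins
#'
#' Each read originates in one repeat copy; with probability
#' `multimap_rate` (and if the subfamily has more than one copy) the read
#' also lists 1-4 decoy placements in other copies of the same subfamily,
#' emulating the ambiguity of repeat-derived reads.
#'
#' @param repeats Repeat tibble.
#' @param n_reads Reads per sample.
#' @param multimap_rate Probability that a read is multi-mapped.
#' @param read_len Read length in bp (clipped to short copies).
#' @param samples Character vector of sample ids.
#' @param seed Integer seed.
#' @return An alignment tibble (`read_id`, `sample`, `chrom`, `start`,
#'   `end`, `nh`; one row per placement) with attribute `truth` recording
#'   each read's generating copy.
#' @export
simulate_multimap_reads <- function(repeats, n_reads, multimap_rate = 0.3,
                                    read_len = 100,
                                    samples = "sample_1", seed = 1) {
  local_seed(seed, {
    all_records <- list()
    all_truth <- list()
    for (smp in samples) {
      origin <- sample.int(nrow(repeats), n_reads, replace = TRUE,
                           prob = repeats$end - repeats$start)
      mm <- stats::runif(n_reads) < multimap_rate
      for (r in seq_len(n_reads)) {
        ci <- origin[r]
        sibs <- which(repeats$rep_name == repeats$rep_name[ci])
        nh <- 1L
        placements <- ci
        if (mm[r] && length(sibs) > 1) {
          extra <- sample(setdiff(sibs, ci),
                          min(sample(1:4, 1), length(sibs) - 1))
          placements <- c(ci, extra)
          nh <- length(placements)
        }
        rel <- stats::runif(1)
        read_id <- sprintf("%s_read_%06d", smp, r)
        ps <- vapply(placements, function(p) {
          w <- repeats$end[p] - repeats$start[p]
          len <- min(read_len, w)
          floor(repeats$start[p] + rel * (w - len))
        }, numeric(1))
        pl <- vapply(placements, function(p) {
          min(read_len, repeats$end[p] - repeats$start[p])
        }, numeric(1))
        all_records[[length(all_records) + 1]] <- tibble::tibble(
          read_id = read_id, sample = smp,
          chrom = repeats$chrom[placements],
          start = ps, end = ps + pl, nh = nh)
        all_truth[[length(all_truth) + 1]] <- tibble::tibble(
          read_id = read_id, sample = smp, true_copy = ci,
          rep_name = repeats$rep_name[ci])
      }
    }
    out <- dplyr::bind_rows(all_records)
    attr(out, "truth") <- dplyr::bind_rows(all_truth)
    out
  })
}

#' Simulate peak sequences with planted motif instances
#'
#' One i.i.d.-background sequence per peak; a fraction of peaks receive a
#' single motif instance sampled column-wise from the PWM. When a target
#' family and the repeat annotation are given, instances are planted so
#' the motif lies inside the peak's overlap with a copy of that family
#' whenever the overlap can hold it.
#'
#' @param pwm A `pwm` object.
#' @param peaks Peak tibble.
#' @param planting_rate Fraction of peaks given a planted instance.
#' @param repeats Optional repeat tibble (needed for targeted planting).
#' @param target_family Optional `rep_family` to plant into.
#' @param background Base composition of the background sequence.
#' @param seed Integer seed.
#' @return Named character vector of sequences (names = peak ids) with
#'   attribute `truth`: peak_id, planted offset (NA if none), and whether
#'   the instance lies in the target family.
#' @export
simulate_sequences <- function(pwm, peaks, planting_rate = 0,
                               repeats = NULL, target_family = NULL,
                               background = rep(0.25, 4), seed = 1) {
  if (nrow(peaks) == 0) {
    out <- character(0)
    attr(out, "truth") <- tibble::tibble(peak_id = character(),
                                        offset = numeric(),
                                        in_target = logical())
    return(out)
  }
  W <- pwm$width
  seg <- NULL
  if (!is.null(target_family) && !is.null(repeats)) {
    fam <- repeats[repeats$rep_family == target_family, ]
    ov <- find_overlaps(peaks, fam)
    seg <- tibble::tibble(
      peak = ov$query_index,
      rel_start = pmax(fam$start[ov$subject_index],
                       peaks$start[ov$query_index]) -
        peaks$start[ov$query_index],
      rel_end = pmin(fam$end[ov$subject_index],
                     peaks$end[ov$query_index]) -
        peaks$start[ov$query_index])
  }
  local_seed(seed, {
    lens <- peaks$end - peaks$start
    planted <- stats::runif(nrow(peaks)) < planting_rate & lens >= W
    seqs <- vapply(seq_len(nrow(peaks)), function(i) {
      paste(sample(dna_bases, lens[i], replace = TRUE, prob = background),
            collapse = "")
    }, character(1))
    offsets <- rep(NA_real_, nrow(peaks))
    in_target <- rep(NA, nrow(peaks))
    for (i in which(planted)) {
      slot <- NULL
      if (!is.null(seg)) {
        cand <- seg[seg$peak == i & seg$rel_end - seg$rel_start >= W, ]
        if (nrow(cand) > 0) {
          s <- cand[sample.int(nrow(cand), 1), ]
          slot <- floor(stats::runif(1, s$rel_start,
                                     s$rel_end - W + 1))
          in_target[i] <- TRUE
        }
      }
      if (is.null(slot)) {
        slot <- floor(stats::runif(1, 0, lens[i] - W + 1))
        in_target[i] <- FALSE
      }
      instance <- paste(vapply(seq_len(W), function(j) {
        sample(dna_bases, 1, prob = pwm$probs[, j])
      }, character(1)), collapse = "")
      substr(seqs[i], slot + 1, slot + W) <- instance
      offsets[i] <- slot
    }
    names(seqs) <- peaks$peak_id
    attr(seqs, "truth") <- tibble::tibble(
      peak_id = peaks$peak_id, offset = offsets, in_target = in_target)
    seqs
  })
}
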