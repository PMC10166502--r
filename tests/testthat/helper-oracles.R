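# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately avoid the package's own machinery.

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 5000, max_len = 200) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample(0:max_pos, n, replace = TRUE),
    len = sample(10:max_len, n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + len) |>
    dplyr::select(-len)
}

# all-pairs O(n*m) overlap oracle
naive_overlaps <- function(query, subject, min_bp = 1) {
  rows <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j])
      if (ov >= min_bp) {
        rows[[length(rows) + 1]] <- c(i, j, ov)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(query_index = integer(),
                          subject_index = integer(),
                          overlap_bp = integer()))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(query_index = m[, 1], subject_index = m[, 2],
                        overlap_bp = m[, 3])
  out[order(out$query_index, out$subject_index), ]
}

# per-base boolean-mask coverage oracle
mask_coverage <- function(intervals) {
  total <- 0
  for (ch in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == ch, ]
    mask <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# exhaustive PWM null: enumerate every W-mer
enumerate_pwm_null <- function(pwm) {
  W <- pwm$width
  combos <- as.matrix(expand.grid(rep(list(1:4), W)))
  scores <- apply(combos, 1, function(r) {
    sum(pwm$log_odds[cbind(r, seq_len(W))])
  })
  probs <- apply(combos, 1, function(r) prod(pwm$background[r]))
  list(scores = scores, probs = probs,
       pval = function(s) sum(probs[scores >= s - 1e-12]))
}

# codon-by-codon translation oracle (independent of Biostrings)
codon_translate <- function(seq) {
  code <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L",
            CTC = "L", CTA = "L", CTG = "L", ATT = "I", ATC = "I",
            ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V",
            GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
            CCT = "P", CCC = "P", CCA = "P", CCG = "P", ACT = "T",
            ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
            GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
            TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
            AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D",
            GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
            TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R",
            CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
            GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa <- character(0)
  for (i in seq(1, nchar(seq) - 2, by = 3)) {
    a <- code[[substr(seq, i, i + 2)]]
    if (a == "*") return(list(pep = paste(aa, collapse = ""),
                              stop_found = TRUE))
    aa <- c(aa, a)
  }
  list(pep = paste(aa, collapse = ""), stop_found = FALSE)
}

toy_repeats <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100, 180, 1000, 500),
    end = c(250, 400, 1150, 700),
    strand = c("+", "-", "+", "+"),
    rep_name = c("B1_Mus1", "L1Md_F", "B1_Mus2", "IAPLTR1_Mm"),
    rep_family = c("Alu", "L1", "Alu", "ERVK"),
    rep_class = c("SINE", "LINE", "SINE", "LTR")
  )
}

small_genome <- function() {
  tibble::tibble(chrom = c("chr1", "chr2"), length = c(5e5, 5e5))
}

# moderately covered, long-copy spec: keeps any-overlap edge inflation of
# enrichment small relative to short test peaks
null_te_spec <- function() {
  tibble::tibble(
    rep_name = c("B1_Mus1", "L1Md_F", "IAPLTR1_Mm", "MER1_type"),
    rep_family = c("Alu", "L1", "ERVK", "hAT-Charlie"),
    rep_class = c("SINE", "LINE", "LTR", "DNA"),
    mean_len = c(1200, 2500, 1500, 1000),
    target_ratio = c(0.10, 0.08, 0.05, 0.03)
  )
}
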