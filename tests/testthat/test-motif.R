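test_that("build_pwm normalises counts and sites", {
  # identical sites with zero pseudocount: probability 1 on the site base
  pwm <- build_pwm(rep("ACGT", 4), pseudocount = 0)
  expect_equal(diag(pwm$probs[c("A", "C", "G", "T"), ]), rep(1, 4))
  # uniform counts under uniform background: log-odds all zero
  pwm2 <- build_pwm(matrix(5, 4, 6), pseudocount = 0)
  expect_equal(max(abs(pwm2$log_odds)), 0)
  expect_error(build_pwm(c("ACGT", "ACG")), "ragged")
  # per-position probabilities always sum to 1
  pwm3 <- build_pwm(c("ACGTA", "AAGTC", "ACGTT"))
  expect_equal(colSums(pwm3$probs), rep(1, 5))
})

test_that("MEME-minimal text round-trips probabilities", {
  set.seed(14)
  pwm <- build_pwm(matrix(rgamma(4 * 9, 2), 4),
                   background = c(0.3, 0.2, 0.2, 0.3))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwm, f)
  back <- read_meme(f)
  expect_equal(back$width, 9)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5)
  expect_equal(back$background, pwm$background, tolerance = 1e-5)
})

test_that("exact p-values match enumeration for small widths", {
  # W = 1 uniform background: best base has p = 0.25
  pwm1 <- build_pwm(matrix(c(10, 1, 1, 1), 4, 1))
  pv1 <- exact_pvalues(pwm1)
  expect_equal(pwm_pvalue(pv1, max(pwm1$log_odds)), 0.25)

  # random PWMs up to W = 6 against the exhaustive null, on the
  # discretised score scale the DP is defined on
  set.seed(6)
  for (W in c(3, 4, 6)) {
    pwm <- build_pwm(matrix(rgamma(4 * W, 1), 4),
                     background = c(0.3, 0.2, 0.25, 0.25))
    pv <- exact_pvalues(pwm)
    oracle <- enumerate_pwm_null(pwm)
    int_scores <- apply(
      as.matrix(expand.grid(rep(list(1:4), W))), 1, function(r) {
        sum(round(pwm$log_odds[cbind(r, seq_len(W))] / pv$resolution))
      })
    for (q in sample(length(oracle$scores), 40)) {
      want <- sum(oracle$probs[int_scores >= int_scores[q]])
      got <- pv$tail[int_scores[q] - pv$int_min + 1]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("p-value lookup agrees with true-score enumeration when scores
           are separated", {
  set.seed(19)
  repeat {
    pwm <- build_pwm(matrix(rgamma(12, 1), 4))
    oracle <- enumerate_pwm_null(pwm)
    gaps <- diff(sort(unique(round(oracle$scores, 9))))
    if (min(gaps) > 3 * 1e-3 * pwm$width) break
  }
  pv <- exact_pvalues(pwm)
  got <- pwm_pvalue(pv, oracle$scores)
  want <- vapply(oracle$scores, oracle$pval, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("the score-to-p map is monotone non-increasing", {
  set.seed(20)
  pwm <- build_pwm(matrix(rgamma(4 * 8, 1), 4))
  pv <- exact_pvalues(pwm)
  expect_true(all(diff(pv$tail) <= 1e-15))
  expect_true(all(pv$tail > 0 & pv$tail <= 1))
})

test_that("scanning finds a planted consensus on both strands", {
  set.seed(4)
  pwm <- build_pwm(vapply(1:20, function(i) "GGATCCGTAC",
                          character(1)))
  bg <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 40), "GGATCCGTAC", substr(bg, 41, 80))
  hits <- scan_sequences(pwm, c(s1 = seq), p_threshold = 1e-4)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))

  # reverse-complemented input: same hit on the opposite strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  hits_rc <- scan_sequences(pwm, c(s1 = rc), p_threshold = 1e-4)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_true(any(hits_rc$offset == nchar(seq) - 10 - 40 &
                    hits_rc$strand == "-"))
})

test_that("scan hits equal a naive per-window rescoring oracle", {
  set.seed(12)
  pwm <- build_pwm(vapply(1:15, function(i) {
    s <- strsplit("TTGACGGCA", "")[[1]]
    flip <- runif(9) < 0.1
    s[flip] <- sample(c("A", "C", "G", "T"), sum(flip), TRUE)
    paste(s, collapse = "")
  }, character(1)))
  seqs <- setNames(vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  }, character(1)), paste0("s", 1:20))
  thr <- 1e-3
  hits <- scan_sequences(pwm, seqs, p_threshold = thr)

  # oracle: rebuild the background exactly as the scanner documents,
  # rescore every window on both strands, keep p <= threshold
  tab <- table(factor(unlist(strsplit(seqs, "")), levels = c("A", "C",
                                                             "G", "T")))
  pwm_bg <- build_pwm(pwm$probs * 1000, pseudocount = 0,
                      background = pmax(as.numeric(tab), 1))
  pv <- exact_pvalues(pwm_bg)
  naive <- list()
  for (id in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- seqs[[id]]
      if (strand == "-") {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      chars <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
      for (o in 0:(nchar(s) - 9)) {
        int_sc <- sum(round(pwm_bg$log_odds[cbind(chars[(o + 1):(o + 9)],
                                                  1:9)] / pv$resolution))
        p <- pv$tail[max(1, min(length(pv$tail), int_sc - pv$int_min + 1))]
        if (p <= thr) {
          off <- if (strand == "-") nchar(s) - 9 - o else o
          naive[[length(naive) + 1]] <- paste(id, off, strand)
        }
      }
    }
  }
  expect_setequal(paste(hits$seq_id, hits$offset, hits$strand),
                  unlist(naive))
})

test_that("hit count is non-increasing in the p threshold", {
  set.seed(9)
  pwm <- build_pwm(matrix(rgamma(4 * 7, 1), 4))
  seqs <- c(x = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                      collapse = ""))
  ns <- vapply(c(1e-4, 1e-3, 1e-2), function(t) {
    nrow(scan_sequences(pwm, seqs, p_threshold = t))
  }, numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("windows containing N are skipped, short sequences yield none", {
  pwm <- build_pwm(rep("ACGTAC", 10))
  hits <- scan_sequences(pwm, c(a = "ACGNACGTAC", b = "ACG"),
                         p_threshold = 1)
  expect_true(all(hits$offset >= 4 | hits$strand == "-"))
  expect_false("b" %in% hits$seq_id)
})

test_that("motif occurrence assigns hits to TEs by midpoint", {
  ann <- tibble::tibble(
    peak_id = c("p1", "p1", "p2"),
    chrom = "chr1", start = c(1000, 1000, 5000),
    end = c(1300, 1300, 5300),
    rep_name = c("B1_Mus1", "L1Md_F", NA),
    rep_family = c("Alu", "L1", NA),
    rep_class = c("SINE", "LINE", NA),
    te_start = c(1100, 1250, NA), te_end = c(1200, 1500, NA),
    overlap_bp = c(100, 50, NA))
  hits <- tibble::tibble(
    seq_id = c("p1", "p1", "p2"),
    offset = c(110, 120, 10), strand = "+",
    score = 5, p_value = 1e-5)
  # width 20: midpoints at 1220, 1230 (hits 1 and 2) and 5020 (hit 3)
  occ <- motif_te_occurrence(hits, ann, motif_width = 20)
  df <- tibble::as_tibble(occ)
  expect_equal(df$percentage[df$group == "none"], 100 / 3,
               tolerance = 1e-10)
  # midpoint exactly on te_start is inside (half-open), on te_end is not
  edge_in <- tibble::tibble(seq_id = "p1", offset = 90, strand = "+",
                            score = 5, p_value = 1e-5)   # mid 1100
  occ_in <- motif_te_occurrence(edge_in, ann, motif_width = 20)
  expect_equal(tibble::as_tibble(occ_in)$group, "SINE")
  edge_out <- tibble::tibble(seq_id = "p1", offset = 190, strand = "+",
                             score = 5, p_value = 1e-5)  # mid 1200
  occ_out <- motif_te_occurrence(edge_out, ann, motif_width = 20)
  expect_false("SINE" %in% tibble::as_tibble(occ_out)$group)
  # a hit whose peak is unknown flags a coordinate-mapping bug
  stray <- dplyr::mutate(edge_in, seq_id = "ghost")
  expect_error(motif_te_occurrence(stray, ann, motif_width = 20),
               "outside every peak")
})

test_that("motifs planted only in one family come back 100% that family", {
  genome <- small_genome()
  reps <- simulate_repeat_annotation(genome, null_te_spec(), seed = 8)
  peaks <- simulate_peaks(reps, genome, n_peaks = 150,
                          bias = c(Alu = 6), peak_len = 120, seed = 8)
  pwm <- build_pwm(rep("TTGACGGCATCG", 25))
  seqs <- simulate_sequences(pwm, peaks, planting_rate = 1,
                             repeats = reps, target_family = "Alu",
                             seed = 8)
  truth <- attr(seqs, "truth")
  planted_in <- truth$peak_id[!is.na(truth$offset) & truth$in_target]
  hits <- scan_sequences(pwm, seqs[planted_in], p_threshold = 1e-5)
  ann <- annotate_peaks_with_tes(peaks, reps)
  occ <- motif_te_occurrence(hits, ann)
  df <- tibble::as_tibble(occ)
  expect_equal(df$percentage[df$group == "SINE"], 100)
})

test_that("frameshift ORF prediction matches codon-wise translation", {
  # in-frame deletion of a whole codon: one residue shorter, no missense
  orf <- frameshift_orf("ATGAAATTTTAA", 6, 3)
  expect_equal(orf$peptide, "MK")
  expect_equal(orf$missense_count, 0L)
  expect_true(orf$stop_found)
  # 1 bp deletion that immediately exposes a stop in the new frame
  orf2 <- frameshift_orf("ATGCTAAAAA", 3, 1)
  expect_equal(orf2$peptide, "M")
  expect_true(orf2$stop_found)
  expect_error(frameshift_orf("CCCATG", 1, 1), "ATG")
  expect_error(frameshift_orf("ATGAAA", 4, 5), "outside")

  # random CDS, random 7 bp deletion, against the codon oracle
  set.seed(9)
  for (rep_i in 1:10) {
    body <- paste(sample(c("A", "C", "G", "T"), 297, TRUE), collapse = "")
    cds <- paste0("ATG", body)
    del_start <- sample(3:250, 1)
    ref <- codon_translate(cds)$pep
    mutated <- paste0(substr(cds, 1, del_start),
                      substr(cds, del_start + 8, nchar(cds)))
    want <- codon_translate(mutated)
    got <- frameshift_orf(cds, del_start, 7)
    expect_equal(got$peptide, want$pep)
    expect_equal(got$stop_found, want$stop_found)
    ref_aa <- strsplit(ref, "")[[1]]
    mut_aa <- strsplit(want$pep, "")[[1]]
    n <- length(mut_aa)
    ref_pad <- c(ref_aa, rep("", max(0, n - length(ref_aa))))[seq_len(n)]
    expect_equal(got$missense_count, sum(mut_aa != ref_pad))
  }
})

test_that("codon-aligned in-frame deletions never create missense", {
  set.seed(25)
  for (i in 1:5) {
    cds <- paste0("ATG", paste(sample(c("A", "C", "G"), 60, TRUE),
                               collapse = ""), "TAA")
    k <- sample(1:5, 1)
    orf <- frameshift_orf(cds, 3 * sample(1:10, 1), 3 * k)
    expect_equal(orf$missense_count, 0L)
  }
})
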