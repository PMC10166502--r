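test_that("multi-mapper assignment is deterministic and validates NH", {
  recs <- tibble::tibble(
    read_id = "r1", sample = "s1", chrom = "chr1",
    start = 100, end = 200, nh = 1)
  got <- assign_multimappers(recs, seed = 5)
  expect_equal(got$start, 100)
  bad <- tibble::tibble(read_id = "r2", sample = "s1", chrom = "chr1",
                        start = c(0, 500), end = c(100, 600), nh = 3)
  expect_error(assign_multimappers(bad, seed = 5), "NH mismatch")
})

test_that("NH = 2 assignment is uniform within binomial 3 sigma", {
  n <- 10000
  recs <- tibble::tibble(
    read_id = rep(sprintf("read_%05d", 1:n), each = 2),
    sample = "s1", chrom = "chr1",
    start = rep(c(1000, 9000), n), end = start + 100, nh = 2)
  got <- assign_multimappers(recs, seed = 17)
  n1 <- sum(got$start == 1000)
  expect_true(abs(n1 - 5000) <= 150)   # 3 * sqrt(n * 1/4)
})

test_that("assignment is invariant to input order", {
  set.seed(33)
  n <- 500
  recs <- tibble::tibble(
    read_id = rep(sprintf("r%04d", 1:n), each = 3),
    sample = "s1", chrom = "chr1",
    start = as.numeric(sapply(1:n, function(i) sample(1:9, 3) * 1000)),
    end = start + 50, nh = 3)
  a <- assign_multimappers(recs, seed = 2)
  b <- assign_multimappers(recs[sample(nrow(recs)), ], seed = 2)
  expect_equal(dplyr::arrange(a, read_id)$start,
               dplyr::arrange(b, read_id)$start)
  # a different seed resolves reads differently
  c <- assign_multimappers(recs, seed = 3)
  expect_false(identical(dplyr::arrange(a, read_id)$start,
                         dplyr::arrange(c, read_id)$start))
})

test_that("counting keys features by subfamily hierarchy and chromosome", {
  reps <- toy_repeats()
  asg <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10), sample = "s1",
    chrom = "chr1", start = 110, end = 160)
  cnt <- count_te_features(asg, reps, mode = "global")
  expect_equal(cnt$feature, "B1_Mus1:Alu:SINE")
  expect_equal(cnt$s1, 10L)
  cntc <- count_te_features(asg, reps, mode = "per_chromosome")
  expect_equal(cntc$feature, "B1_Mus1:Alu:SINE:chr1")
})

test_that("gene exons take precedence over TEs for exonic placements", {
  reps <- toy_repeats()
  genes <- tibble::tibble(
    gene_id = "gX", gene_name = "gX", chrom = "chr1",
    start = 100, end = 300, strand = "+",
    exons = list(tibble::tibble(start = 100, end = 300)),
    cds = list(tibble::tibble(start = numeric(), end = numeric())))
  asg <- tibble::tibble(read_id = c("r1", "r2"), sample = "s1",
                        chrom = "chr1", start = c(110, 1010),
                        end = c(160, 1060))
  cnt <- count_te_features(asg, reps, genes = genes)
  expect_setequal(cnt$feature, c("gX", "B1_Mus2:Alu:SINE"))
})

test_that("global counts equal per-chromosome counts summed, and reads
           are conserved", {
  genome <- small_genome()
  reps <- simulate_repeat_annotation(genome, null_te_spec(), seed = 3)
  rd <- simulate_multimap_reads(reps, 1500, multimap_rate = 0.4,
                                samples = c("s1", "s2"), seed = 3)
  asg <- assign_multimappers(rd, seed = 9)
  g <- count_te_features(asg, reps, mode = "global")
  pc <- count_te_features(asg, reps, mode = "per_chromosome")
  # conservation: every assigned read lands in some repeat by design
  expect_equal(sum(g$s1) + sum(g$s2), nrow(asg))
  rolled <- pc |>
    dplyr::mutate(feature = sub(":[^:]+$", "", feature)) |>
    dplyr::group_by(feature) |>
    dplyr::summarise(s1 = sum(s1), s2 = sum(s2)) |>
    dplyr::arrange(feature)
  expect_equal(as.data.frame(rolled),
               as.data.frame(dplyr::arrange(g, feature))[
                 , c("feature", "s1", "s2")],
               ignore_attr = TRUE)
})

test_that("size factors recover forced and simulated depth ratios", {
  m <- matrix(c(10, 40, 100, 10, 40, 100), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))
  m2 <- cbind(a = c(10, 40, 100), b = c(20, 80, 200))
  sf <- size_factors_median_of_ratios(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  cm <- simulate_counts(n_features = 800,
                        depth = c(1, 1.5, 0.8, 1, 2, 1, 0.6, 1),
                        seed = 23)
  sf3 <- size_factors_median_of_ratios(cm)
  d <- attr(cm, "depths")
  d <- d / exp(mean(log(d)))
  expect_true(max(abs(sf3 - d) / d) < 0.05)
})

test_that("size factors match the reference median-of-ratios
           implementation", {
  skip_if_not_installed("DESeq2")
  cm <- simulate_counts(n_features = 400, depth = c(1, 2, 1, 1, 0.5, 1,
                                                    1, 1), seed = 29)
  m <- as.matrix(cm[, -1])
  ours <- size_factors_median_of_ratios(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("the NB Wald test is inert on identical groups and recovers a
           forced fold change", {
  m <- matrix(rep(c(5, 50, 500), 8), ncol = 8,
              dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:8)))
  de <- nb_wald_test(m, rep(c("wt", "ko"), each = 4))
  expect_equal(de$log2FoldChange, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3), tolerance = 1e-8)

  m2 <- cbind(matrix(8, 2, 4), matrix(128, 2, 4))
  rownames(m2) <- c("a", "b")
  colnames(m2) <- paste0("s", 1:8)
  de2 <- nb_wald_test(m2, rep(c("wt", "ko"), each = 4),
                      size_factors = rep(1, 8))
  expect_equal(de2$log2FoldChange, rep(log2(128.5 / 8.5), 2),
               tolerance = 1e-10)
  expect_error(nb_wald_test(m2, rep("wt", 8)), "2 levels")
  expect_error(nb_wald_test(m2, c("wt", rep("ko", 7))), "replicates")
})

test_that("permuted labels give near-uniform p-values", {
  cm <- simulate_counts(n_features = 2000, frac_de = 0, lfc = 0,
                        dispersion = 0.05, seed = 51)
  # contrast orthogonal to the sampling layout: no signal aligns with it
  perm <- c("ctrl", "trt", "ctrl", "trt", "trt", "ctrl", "trt", "ctrl")
  de <- nb_wald_test(cm, perm)
  p <- de$pvalue[!is.na(de$pvalue)]
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.1)
})

test_that("true fold changes are recovered with high correlation", {
  cm <- simulate_counts(n_features = 1500, frac_de = 0.3, lfc = 2,
                        dispersion = 0.05, seed = 61)
  de <- nb_wald_test(cm, attr(cm, "condition"))
  truth <- attr(cm, "truth")
  expect_gt(cor(truth$true_lfc, de$log2FoldChange), 0.9)
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_adjust(rep(0.01, 10)), rep(0.01, 10))
  # hand computation: sorted p (0.01 0.02 0.03 0.04), m = 4
  # padj_(k) = min over k' >= k of 4 p_(k') / k' = 0.04 for all
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order restored
  p <- c(0.04, 0.001, 0.2, 0.03)
  expect_equal(bh_adjust(p)[2], min(bh_adjust(p)))
  # monotone in rank order
  set.seed(77)
  p2 <- runif(100)
  adj <- bh_adjust(p2)
  expect_true(all(diff(adj[order(p2)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 1.7)), "0, 1")
})

test_that("threshold summary splits significant features by sign", {
  empty <- tibble::tibble(padj = numeric(), log2FoldChange = numeric())
  expect_equal(unlist(threshold_summary(empty)), c(total = 0, up = 0,
                                                   down = 0))
  de <- tibble::tibble(
    padj = c(0.01, 0.2, 0.001, NA, 0.04),
    log2FoldChange = c(2, 3, -1.5, 4, 0.2))
  got <- threshold_summary(de, padj_cut = 0.05)
  expect_equal(got$total, 3L)
  expect_equal(got$up, 2L)
  expect_equal(got$down, 1L)
  # an effect-size floor removes the small fold change
  expect_equal(threshold_summary(de, 0.05, lfc_cut = 1)$total, 2L)
})

test_that("per-chromosome analysis is independent per chromosome", {
  cm <- simulate_counts(n_features = 60, frac_de = 0.2, seed = 13)
  counts2 <- dplyr::bind_rows(
    dplyr::mutate(cm, feature = paste0(feature, ":X:Y:chr1")),
    dplyr::mutate(cm, feature = paste0(feature, ":X:Y:chr2")))
  suppressWarnings(res <- per_chromosome_de(counts2,
                                            attr(cm, "condition")))
  c1 <- res[res$chromosome == "chr1", ]
  c2 <- res[res$chromosome == "chr2", ]
  expect_equal(c1$pvalue, c2$pvalue)
  expect_equal(c1$padj, c2$padj)
  # BH is applied within the chromosome family
  expect_equal(c1$padj, bh_adjust(c1$pvalue))
  # a lone feature on a chromosome is skipped with a warning
  lonely <- dplyr::bind_rows(
    counts2, dplyr::mutate(cm[1, ], feature = "solo:X:Y:chrZ"))
  expect_warning(per_chromosome_de(lonely, attr(cm, "condition")),
                 "chrZ")
})

test_that("locus-specific signal diluted globally is recovered
           per chromosome", {
  set.seed(41)
  # one subfamily: strong KO induction of the chr9 copies, a large
  # unchanged population of copies on chr2 that swamps the global key
  n <- c(4, 4)
  chr9 <- rnbinom(8, mu = rep(c(20, 200), n), size = 20)
  chr2 <- rnbinom(8, mu = 4000, size = 20)
  other <- matrix(rnbinom(8 * 40, mu = 500, size = 20), ncol = 8)
  per_chrom <- rbind(chr9, chr2, other[1:20, ], other[21:40, ])
  rownames(per_chrom) <- c("RLTR44:ERVK:LTR:chr9", "RLTR44:ERVK:LTR:chr2",
                           paste0("te", 1:20, ":f:c:chr9"),
                           paste0("te", 21:40, ":f:c:chr2"))
  colnames(per_chrom) <- paste0("s", 1:8)
  cond <- rep(c("wt", "ko"), n)
  counts_pc <- tibble::as_tibble(per_chrom, rownames = "feature")
  res_pc <- per_chromosome_de(counts_pc, cond)
  # global aggregation of the same data
  global <- rowsum(per_chrom,
                   sub(":[^:]+$", "", rownames(per_chrom)))
  res_g <- nb_wald_test(global, cond)
  p_chr9 <- res_pc$padj[res_pc$feature == "RLTR44:ERVK:LTR:chr9"]
  p_glob <- res_g$padj[res_g$feature == "RLTR44:ERVK:LTR"]
  expect_lt(p_chr9, 0.1)
  expect_gt(p_glob, p_chr9)
})

test_that("tidy, glance and autoplot work on DE results", {
  cm <- simulate_counts(n_features = 100, frac_de = 0.2, seed = 19)
  de <- nb_wald_test(cm, attr(cm, "condition"))
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "baseMean", "log2FoldChange", "lfcSE",
                     "stat", "pvalue", "padj"))
  gl <- glance(de)
  expect_equal(gl$n_features, 100L)
  expect_s3_class(autoplot(de), "ggplot")
})
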