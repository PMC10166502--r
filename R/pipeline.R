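# End-to-end orchestration: read (or simulate) every input, run the
# annotation / enrichment / motif / expression stages that the supplied
# config enables, and emit deterministic TSV tables plus a summary.json
# whose every number is re-derivable from those tables.

#' Read a pipeline configuration file
#'
#' YAML with the same nesting [run_pipeline()] accepts as a list.
#'
#' @param path YAML config path.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

check_input <- function(path, what) {
  if (!file.exists(path)) {
    stop("missing input file (", what, "): ", path, call. = FALSE)
  }
  path
}

#' Run the full peak/TE analysis pipeline
#'
#' Stages run according to what the config provides: peak-repeat
#' annotation and composition always; gene-feature and cCRE
#' classification, class/family enrichment, motif scanning with
#' repeat-occurrence accounting, and count-based differential expression
#' when their inputs are present. All outputs land in `out_dir`:
#' stage tables as TSV, a `summary.json` gathering the headline numbers,
#' and a `log.txt` with stage record counts.
#'
#' @param config A list (or path handled by [read_run_config()]) with
#'   elements:
#'   \describe{
#'     \item{inputs}{paths: `peaks` (+ `peaks_dialect`), `rmsk`, optional
#'       `genes` (+ `genes_dialect`), `ccre`, `motif` (MEME minimal),
#'       `fasta`, `counts`, `counts_per_chromosome`.}
#'     \item{genome_length}{total genome length in bp (required for
#'       enrichment).}
#'     \item{condition}{two-level sample condition for the DE stage.}
#'     \item{params}{optional: `promoter_up` (2000), `promoter_down`
#'       (500), `frequency_mode` ("incidence"), `composition_mode`
#'       ("incidence"), `within_class`, `p_threshold` (1e-4), `padj_cut`
#'       (0.05), `min_bp` (1).}
#'     \item{seed}{integer; required by any stochastic stage.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  p <- config$params %||% list()
  min_bp <- p$min_bp %||% 1L
  padj_cut <- p$padj_cut %||% 0.05
  inputs <- config$inputs
  summary <- list()

  peaks <- read_peaks(check_input(inputs$peaks, "peaks"),
                      dialect = inputs$peaks_dialect %||% "narrowPeak")
  repeats <- read_rmsk(check_input(inputs$rmsk, "rmsk"), quiet = TRUE)
  note("loaded ", nrow(peaks), " peaks and ", nrow(repeats),
       " repeat records")
  summary$peaks_total <- nrow(peaks)

  annotation <- annotate_peaks_with_tes(peaks, repeats, min_bp = min_bp)
  write_table(annotation, file.path(out_dir, "peak_annotation.tsv"))
  comp_mode <- p$composition_mode %||% "incidence"
  class_comp <- te_composition(annotation, level = "class",
                               mode = comp_mode)
  family_comp <- te_composition(annotation, level = "family",
                                mode = comp_mode)
  write_table(tidy(class_comp),
              file.path(out_dir, "composition_class.tsv"))
  write_table(tidy(family_comp),
              file.path(out_dir, "composition_family.tsv"))
  summary$pct_peaks_with_te <- attr(class_comp, "pct_peaks_with_te")
  summary$class_composition <- as.data.frame(tidy(class_comp))
  summary$family_composition <- as.data.frame(tidy(family_comp))
  if (!is.null(p$within_class)) {
    inset <- te_composition(annotation, within_class = p$within_class,
                            mode = comp_mode)
    write_table(tidy(inset),
                file.path(out_dir, "composition_within_class.tsv"))
    summary$within_class_composition <- as.data.frame(tidy(inset))
  }
  note("annotation: ", nrow(annotation), " rows; peaks with TE: ",
       sprintf("%.1f%%", summary$pct_peaks_with_te))

  if (!is.null(inputs$genes)) {
    genes <- read_gene_model(check_input(inputs$genes, "genes"),
                             dialect = inputs$genes_dialect %||% "gtf")
    classified <- classify_peak_features(
      peaks, genes,
      promoter_up = p$promoter_up %||% 2000,
      promoter_down = p$promoter_down %||% 500)
    feat_comp <- feature_composition(classified)
    write_table(classified[, c("peak_id", "feature")],
                file.path(out_dir, "peak_features.tsv"))
    write_table(tidy(feat_comp),
                file.path(out_dir, "composition_features.tsv"))
    summary$feature_composition <- as.data.frame(tidy(feat_comp))
    note("feature classification over ", nrow(genes), " genes")
  }

  if (!is.null(inputs$ccre)) {
    ccres <- read_ccre(check_input(inputs$ccre, "ccre"))
    cc <- classify_peak_ccres(peaks, ccres)
    write_table(cc$labels, file.path(out_dir, "peak_ccres.tsv"))
    write_table(tidy(cc$summary),
                file.path(out_dir, "composition_ccre.tsv"))
    summary$ccre_composition <- as.data.frame(tidy(cc$summary))
    note("cCRE labelling against ", nrow(ccres), " elements")
  }

  if (!is.null(config$genome_length)) {
    freq_mode <- p$frequency_mode %||% "incidence"
    for (lev in c("class", "family")) {
      enr <- enrichment_fold(
        peak_frequency(annotation, level = lev, mode = freq_mode),
        genome_coverage_ratio(repeats, config$genome_length, level = lev))
      write_table(enr, file.path(out_dir,
                                 paste0("enrichment_", lev, ".tsv")))
      summary[[paste0("enrichment_", lev)]] <- as.data.frame(enr)
    }
    note("enrichment at mode ", freq_mode)
  }

  if (!is.null(inputs$motif) && !is.null(inputs$fasta)) {
    pwm <- read_meme(check_input(inputs$motif, "motif"))
    seqs <- read_fasta(check_input(inputs$fasta, "fasta"))
    hits <- scan_sequences(pwm, seqs,
                           p_threshold = p$p_threshold %||% 1e-4)
    write_table(hits, file.path(out_dir, "motif_hits.tsv"))
    if (nrow(hits) > 0) {
      occ <- motif_te_occurrence(hits, annotation)
      write_table(tidy(occ), file.path(out_dir, "motif_occurrence.tsv"))
      summary$motif_occurrence <- as.data.frame(tidy(occ))
    }
    summary$motif_hits_total <- nrow(hits)
    note("motif scan: ", nrow(hits), " hits in ", length(seqs),
         " sequences")
  }

  if (!is.null(inputs$counts) && !is.null(config$condition)) {
    counts <- read_counts(check_input(inputs$counts, "counts"))
    de <- nb_wald_test(counts, config$condition)
    write_table(tidy(de), file.path(out_dir, "de_global.tsv"))
    ts <- threshold_summary(de, padj_cut = padj_cut)
    summary$de_global <- list(total = ts$total, up = ts$up,
                              down = ts$down, padj_cut = padj_cut)
    note("global DE: ", ts$total, " significant at padj < ", padj_cut)
  }
  if (!is.null(inputs$counts_per_chromosome) &&
      !is.null(config$condition)) {
    counts_pc <- read_counts(check_input(inputs$counts_per_chromosome,
                                         "counts_per_chromosome"))
    de_pc <- per_chromosome_de(counts_pc, config$condition)
    write_table(de_pc, file.path(out_dir, "de_per_chromosome.tsv"))
    ts <- threshold_summary(de_pc, padj_cut = padj_cut)
    summary$de_per_chromosome <- list(total = ts$total, up = ts$up,
                                      down = ts$down,
                                      padj_cut = padj_cut)
    note("per-chromosome DE: ", ts$total, " significant at padj < ",
         padj_cut)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  readr::write_lines(log_lines, file.path(out_dir, "log.txt"))
  invisible(summary)
}

#' Write a synthetic demonstration data set
#'
#' Generates a small, fully self-contained input bundle (repeat
#' annotation, biased peaks, cCREs, gene models, motif, peak sequences,
#' count matrices) under `dir` using the package's generators, and
#' returns a ready [run_pipeline()] config pointing at it. The planted
#' structure mirrors the biology the pipeline targets: peaks placed
#' preferentially over the SINE family, a motif planted inside
#' SINE-overlapping peak sequence, and a handful of truly
#' differentially-expressed TE subfamilies.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_peaks Number of peaks.
#' @return The config list (invisibly writes files).
#' @export
write_demo_dataset <- function(dir, seed = 7, n_peaks = 400) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- tibble::tibble(chrom = c("chr1", "chr2"),
                           length = c(6e5, 4e5))
  te_spec <- tibble::tibble(
    rep_name = c("B1_Mus1", "B2_Mm1", "L1Md_F", "IAPLTR1_Mm", "MER1_type"),
    rep_family = c("Alu", "B2", "L1", "ERVK", "hAT-Charlie"),
    rep_class = c("SINE", "SINE", "LINE", "LTR", "DNA"),
    mean_len = c(600, 500, 2000, 1500, 400),
    target_ratio = c(0.10, 0.03, 0.08, 0.05, 0.02))
  repeats <- simulate_repeat_annotation(genome, te_spec, seed = seed)
  peaks <- simulate_peaks(repeats, genome, n_peaks = n_peaks,
                          bias = c(Alu = 6), peak_len = 60,
                          seed = seed + 1)
  rmsk_path <- file.path(dir, "repeats.tsv")
  readr::write_lines(c(
    "genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
    paste(repeats$chrom,
          format(repeats$start, scientific = FALSE, trim = TRUE),
          format(repeats$end, scientific = FALSE, trim = TRUE),
          repeats$strand, repeats$rep_name, repeats$rep_class,
          repeats$rep_family, sep = "\t")), rmsk_path)
  peaks_path <- file.path(dir, "peaks.narrowPeak")
  write_narrowpeak(peaks, peaks_path)

  # cCREs: uniform small elements
  ccre <- local_seed(seed + 2, tibble::tibble(
    chrom = sample(genome$chrom, 300, replace = TRUE,
                   prob = genome$length),
    start = floor(stats::runif(300, 0, 3.8e5)),
    label = sample(ccre_vocabulary, 300, replace = TRUE,
                   prob = c(0.5, 0.2, 0.15, 0.1, 0.05))) |>
      dplyr::mutate(end = .data$start + 200) |>
      dplyr::select("chrom", "start", "end", "label") |>
      dplyr::arrange(.data$chrom, .data$start))
  ccre_path <- file.path(dir, "ccre.bed")
  readr::write_tsv(ccre, ccre_path, col_names = FALSE, progress = FALSE)

  # a few gene models as BED12
  genes_bed <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(50000, 200000, 100000),
    end = c(80000, 230000, 140000),
    name = c("geneA", "geneB", "geneC"),
    score = 0, strand = c("+", "-", "+"),
    thickStart = c(52000, 202000, 103000),
    thickEnd = c(78000, 228000, 137000),
    rgb = "0",
    blockCount = 3,
    blockSizes = "3000,4000,5000,",
    blockStarts = c("0,10000,25000,", "0,12000,25000,", "0,15000,35000,"))
  genes_path <- file.path(dir, "genes.bed12")
  readr::write_tsv(genes_bed, genes_path, col_names = FALSE,
                   progress = FALSE)

  # motif + peak sequences with instances planted into SINE overlap
  pwm <- local_seed(seed + 3, {
    consensus <- sample(dna_bases, 12, replace = TRUE)
    sites <- vapply(1:30, function(i) {
      s <- consensus
      mutate_at <- stats::runif(12) < 0.08
      s[mutate_at] <- sample(dna_bases, sum(mutate_at), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    build_pwm(sites)
  })
  motif_path <- file.path(dir, "motif.meme")
  write_meme(pwm, motif_path, name = "demo_motif")
  seqs <- simulate_sequences(pwm, peaks, planting_rate = 0.4,
                             repeats = repeats, target_family = "Alu",
                             seed = seed + 4)
  fasta_path <- file.path(dir, "peaks.fasta")
  write_fasta(seqs, fasta_path)

  counts <- simulate_counts(n_features = 300, n_per_group = c(4, 4),
                            dispersion = 0.05, frac_de = 0.1, lfc = 2,
                            seed = seed + 5)
  counts_path <- file.path(dir, "te_counts.tsv")
  write_table(counts, counts_path)

  config <- list(
    inputs = list(
      peaks = peaks_path, peaks_dialect = "narrowPeak",
      rmsk = rmsk_path,
      genes = genes_path, genes_dialect = "bed12",
      ccre = ccre_path,
      motif = motif_path, fasta = fasta_path,
      counts = counts_path),
    genome_length = sum(genome$length),
    condition = attr(counts, "condition"),
    params = list(within_class = "SINE", frequency_mode = "incidence",
                  p_threshold = 1e-4, padj_cut = 0.05),
    seed = seed)
  config
}
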