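#' Pipeline configuration
#'
#' Validated bundle of input paths and thresholds for [run_pipeline()]. When
#' `simulate = TRUE` the synthetic generator provides every input under
#' `outdir/input` and `paths` may be empty; otherwise `paths` must name the
#' required files.
#'
#' @param outdir Output directory.
#' @param seed Seed for simulation, clustering and scoring stages.
#' @param simulate Generate inputs with [simulate_regulome()]?
#' @param sim A [sim_config()] used when `simulate = TRUE` (its seed is
#'   overridden by `seed`).
#' @param paths Named list of input paths (`genome`, `gtf`, `loops`,
#'   `tf_peaks`, `k27_peaks`, `de`, `motif`, `subtype_expr`,
#'   `subtype_labels`, `cell_expr`, `gene_sets`, `tf_list`, plus one path per
#'   signal track in `tracks`).
#' @param loop_q,loop_d_min,loop_d_max Loop significance and distance range.
#' @param de_alpha Adjusted-p cutoff for DE direction calls.
#' @param promoter_halfwidth Anchor-promoter window half-width, bp.
#' @param stitch_gap,tss_exclusion ROSE stitching parameters, bp.
#' @param top_fraction Fraction of most factor-enriched motif regions kept
#'   before clustering.
#' @param k_clusters Number of chromatin clusters.
#' @param fold Subtype-specificity fold threshold.
#' @param motif_threshold PWM relative-score threshold.
#' @param target_subtype Subtype of interest in the expression matrix.
#' @param signal_span,signal_bin Signal-matrix window geometry, bp.
#' @param n_perm GSEA permutations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 0, simulate = TRUE,
                            sim = sim_config(seed = seed), paths = list(),
                            loop_q = 0.01, loop_d_min = 50000,
                            loop_d_max = 3000000, de_alpha = 0.05,
                            promoter_halfwidth = 10000, stitch_gap = 12500,
                            tss_exclusion = 0, top_fraction = 0.75,
                            k_clusters = 3, fold = 3.0,
                            motif_threshold = 0.8,
                            target_subtype = "TCF3HLF",
                            signal_span = 2000, signal_bin = 50,
                            n_perm = 500) {
  stopifnot(loop_q > 0, loop_q <= 1, de_alpha > 0, de_alpha < 1,
            promoter_halfwidth > 0, stitch_gap >= 0, top_fraction > 0,
            top_fraction <= 1, k_clusters >= 1, fold > 0,
            motif_threshold > 0, motif_threshold <= 1)
  cfg <- as.list(environment())
  cfg$sim$seed <- seed
  structure(cfg, class = "pipeline_config")
}

required_inputs <- c("genome", "gtf", "loops", "tf_peaks", "k27_peaks", "de",
                     "motif", "subtype_expr", "subtype_labels", "cell_expr",
                     "gene_sets", "tf_list")

log_stage <- function(...) message("[epregulome] ", ...)

#' Run the full regulome pipeline
#'
#' Stage order: simulate (optional) -> motif scan of loop anchors -> anchor
#' classification -> enhancer calling -> chromatin clustering -> E-P gene
#' table -> subtype specificity -> signature scoring -> summary. Each stage
#' logs input/output counts to the console (messages, never stdout results);
#' outputs are written under `config$outdir` and listed in a content-hashed
#' manifest, which makes determinism checkable by hash equality.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary` (named list of headline
#'   statistics, also written as `summary.json`), `manifest` (tibble of file,
#'   md5), and the main intermediate objects (`ep_table`, `pairs`, `rose`,
#'   `clusters`, `density`, `gsea`, `scores`, `specific`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)

  if (config$simulate) {
    log_stage("simulating inputs (seed ", config$seed, ")")
    truth <- simulate_regulome(config$sim, out("input"))
    paths <- truth$files
    paths$tracks <- truth$track_files
  } else {
    paths <- config$paths
    miss <- setdiff(required_inputs, names(paths))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files)) stop("input file not found: ",
                                    missing_files[1], call. = FALSE)
  }

  log_stage("loading inputs")
  genome <- read_fasta(paths$genome)
  genes <- read_gtf(paths$gtf, genome = genome)
  loops <- read_bedpe(paths$loops, bin_size = config$sim$bin_size %||% 5000)
  tf_peaks <- read_narrowpeak(paths$tf_peaks)
  k27_peaks <- read_narrowpeak(paths$k27_peaks)
  de <- readr::read_tsv(paths$de, show_col_types = FALSE, progress = FALSE)
  motif <- read_jaspar(paths$motif)
  tracks <- lapply(paths$tracks, read_bedgraph)
  tf_list <- readLines(paths$tf_list)
  gene_sets <- read_gmt(paths$gene_sets)
  chrom_sizes <- vapply(genome, nchar, numeric(1))

  log_stage(nrow(loops), " loops read")
  sig_loops <- filter_loops(loops, q_max = config$loop_q,
                            d_min = config$loop_d_min,
                            d_max = config$loop_d_max)
  log_stage(nrow(sig_loops), " significant loops (q <= ", config$loop_q, ")")
  anchors <- anchors_union(sig_loops)
  log_stage(nrow(anchors), " anchor bins")

  flags <- flag_motif_regions(anchors, genome, motif,
                              threshold = config$motif_threshold)
  log_stage(sum(flags$has_motif), " motif-bearing anchors")

  classes <- classify_anchors(anchors, genes, flags, tf_peaks = tf_peaks,
                              promoter_halfwidth = config$promoter_halfwidth)
  log_stage("anchor classes: ",
            paste(names(table(classes$klass)), table(classes$klass),
                  sep = "=", collapse = ", "))

  log_stage("calling enhancers (stitch gap ", config$stitch_gap, " bp)")
  stitched <- stitch_peaks(k27_peaks, stitch_gap = config$stitch_gap,
                           tss_exclusion = config$tss_exclusion, genes = genes)
  ranked <- score_and_rank(stitched, tracks$H3K27ac)
  rose <- call_super_enhancers(ranked)
  log_stage(nrow(rose), " stitched enhancers, ", sum(rose$is_super),
            " super-enhancers")

  # motif-centered chromatin states over the motif-bearing anchors
  hit_centers <- flags |>
    dplyr::filter(.data$has_motif) |>
    dplyr::mutate(hit = purrr::map(.data$hits, ~ .x[1, ])) |>
    tidyr::unnest("hit", names_sep = "_")
  centers <- tibble(chrom = hit_centers$chrom,
                    start = hit_centers$hit_start,
                    end = hit_centers$hit_end,
                    strand = hit_centers$hit_strand,
                    anchor_start = hit_centers$start,
                    anchor_end = hit_centers$end)
  sm <- build_signal_matrix(centers, tracks, span = config$signal_span,
                            bin_width = config$signal_bin,
                            chrom_sizes = chrom_sizes)
  sm_top <- select_top_enriched(sm, track = "TCF3HLF",
                                top_fraction = config$top_fraction)
  clusters <- cluster_regions(sm_top, k = config$k_clusters,
                              seed = stage_seed(config$seed, "cluster"))
  log_stage("chromatin clusters: ", paste(clusters$sizes, collapse = "/"))
  density <- density_stats(sm_top, clusters)
  corr <- cluster_signal_correlation(sm_top, clusters,
                                     track_a = "ATAC", track_b = "TCF3HLF")

  pairs <- build_ep_pairs(sig_loops, classes)
  log_stage(nrow(pairs), " I-P pairs")
  anchor_cluster <- tibble(chrom = sm_top$regions$chrom,
                           start = sm_top$regions$anchor_start,
                           end = sm_top$regions$anchor_end,
                           cluster = clusters$cluster) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE)
  anchor_class_map <- annotate_enhancer_class(
    classes[, c("chrom", "start", "end")], rose)
  table <- ep_gene_table(pairs, de,
                         anchor_enhancer_class = anchor_class_map,
                         anchor_cluster = anchor_cluster,
                         tf_list = tf_list, alpha = config$de_alpha)
  sig_genes <- ep_genes(table)
  log_stage(nrow(table), " genes with I-P pairs, ", nrow(sig_genes),
            " significant E-P genes")
  breakdown <- cluster_direction_breakdown(table)
  tfs <- tf_subset(table)

  log_stage("subtype specificity (", config$fold, "x rule)")
  expr_df <- readr::read_tsv(paths$subtype_expr, show_col_types = FALSE,
                             progress = FALSE)
  labels <- readr::read_tsv(paths$subtype_labels, show_col_types = FALSE,
                            progress = FALSE)
  specific <- subtype_specific_genes(expr_df, labels,
                                     target_subtype = config$target_subtype,
                                     fold = config$fold)

  log_stage("signature scoring")
  cell_df <- readr::read_tsv(paths$cell_expr, show_col_types = FALSE,
                             progress = FALSE)
  cell_mat <- as.matrix(cell_df[, -1])
  rownames(cell_mat) <- cell_df[[1]]
  module <- gene_sets[[1]]
  scores <- module_score(cell_mat, module,
                         seed = stage_seed(config$seed, "score"))
  ranking <- de_ranking_metric(de)
  gsea <- suppressMessages(
    preranked_gsea(ranking, gene_sets, n_perm = config$n_perm,
                   seed = stage_seed(config$seed, "gsea"))
  )

  ## outputs -----------------------------------------------------------------
  write_ep_gene_table(table, out("ep_gene_table.tsv"))
  write_ep_pairs(pairs, out("ep_pairs.bedpe"))
  write_rose_table(rose, out("rose_enhancers.tsv"))
  write_bed(dplyr::mutate(tidy(clusters), name = paste0("cluster", cluster),
                          score = cluster, strand = "."),
            out("chromatin_clusters.bed"))
  readr::write_tsv(density, out("density_stats.tsv"), progress = FALSE)
  readr::write_tsv(corr, out("cluster_correlation.tsv"), progress = FALSE)
  readr::write_tsv(breakdown, out("cluster_direction_breakdown.tsv"),
                   progress = FALSE)
  readr::write_tsv(specific, out("subtype_specificity.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(scores), out("module_scores.tsv"),
                   progress = FALSE)
  gsea_out <- dplyr::mutate(as_tibble(gsea), leading_edge = vapply(
    .data$leading_edge, paste, character(1), collapse = ","))
  readr::write_tsv(gsea_out, out("gsea_results.tsv"), progress = FALSE)

  summary <- list(
    n_loops = nrow(loops),
    n_significant_loops = nrow(sig_loops),
    n_anchor_bins = nrow(anchors),
    n_motif_anchors = sum(flags$has_motif),
    motif_anchor_fraction = mean(flags$has_motif),
    anchor_class_counts = as.list(table(classes$klass)),
    n_ip_pairs = nrow(pairs),
    both_anchor_motif_fraction = if (nrow(pairs)) {
      both_anchor_motif_fraction(pairs)
    } else NA,
    n_genes_with_pairs = nrow(table),
    n_ep_genes = nrow(sig_genes),
    n_ep_up = sum(sig_genes$de_direction == "up"),
    n_ep_down = sum(sig_genes$de_direction == "down"),
    ep_enhancer_fraction = if (nrow(sig_genes)) {
      mean(sig_genes$enhancer_class %in% c("SE", "TE"))
    } else NA,
    n_stitched_enhancers = nrow(rose),
    n_super_enhancers = sum(rose$is_super),
    cluster_sizes = as.list(stats::setNames(as.integer(clusters$sizes),
                                            seq_along(clusters$sizes))),
    n_tf_down = length(tfs$down_tfs),
    n_tf_up = length(tfs$up_tfs),
    n_subtype_specific = sum(specific$specific),
    top_gene = table$gene_id[1],
    mean_module_score = mean(scores$score),
    n_gsea_significant = sum(gsea$adj_p < 0.05, na.rm = TRUE)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- sort(list.files(config$outdir, recursive = TRUE,
                           full.names = TRUE))
  manifest <- tibble(file = sub(paste0("^", config$outdir, "/?"), "", files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)

  invisible(list(summary = summary, manifest = manifest, ep_table = table,
                 pairs = pairs, rose = rose, clusters = clusters,
                 signal_matrix = sm_top, density = density, corr = corr,
                 breakdown = breakdown, tfs = tfs, specific = specific,
                 scores = scores, gsea = gsea, anchors = classes,
                 loops = sig_loops))
}
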