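#' Classify loop anchors as promoter / motif-bearing intergenic
#'
#' Every anchor bin gets exactly one class:
#' * `P` - the anchor overlaps any TSS +/- `promoter_halfwidth` window
#'   (promoter precedence: a promoter-overlapping anchor is `P` even when it
#'   carries a motif; its motif flag is retained for the both-anchor-motif
#'   statistic);
#' * `I_HLF` - non-promoter, carries a motif hit and a 1D factor peak;
#' * `I_plain` - non-promoter with a factor peak but no motif;
#' * `other` - everything else.
#'
#' @param anchors Anchor tibble from [anchors_union()].
#' @param genes Gene models from [read_gtf()].
#' @param motif_flags Output of [flag_motif_regions()] on the same anchors
#'   (matched by coordinates).
#' @param tf_peaks Optional 1D peak tibble (e.g. narrowPeak of the factor);
#'   `NULL` treats every anchor as peak-supported (the anchors themselves are
#'   the interaction-derived peak universe).
#' @param promoter_halfwidth Promoter window half-width around the TSS, bp.
#' @return `anchors` with `is_promoter`, `has_motif`, `has_tf_peak`, `klass`
#'   and a `promoter_genes` list-column of gene ids whose TSS window overlaps
#'   the anchor.
#' @export
classify_anchors <- function(anchors, genes, motif_flags, tf_peaks = NULL,
                             promoter_halfwidth = 10000) {
  assert_intervals(anchors)
  out <- as_tibble(anchors)
  n <- nrow(out)

  windows <- tibble(chrom = genes$chrom,
                    start = pmax(0, genes$tss - promoter_halfwidth),
                    end = genes$tss + promoter_halfwidth + 1,
                    gene_id = genes$gene_id)
  ov <- overlap_pairs(out, windows)
  pg <- rep(list(character(0)), n)
  for (q in unique(ov$query)) {
    pg[[q]] <- sort(windows$gene_id[ov$subject[ov$query == q]])
  }
  out$promoter_genes <- pg
  out$is_promoter <- lengths(pg) > 0

  key <- function(d) paste(d$chrom, d$start, d$end)
  m <- match(key(out), key(motif_flags))
  if (anyNA(m)) stop("motif_flags must cover every anchor", call. = FALSE)
  out$has_motif <- motif_flags$has_motif[m]

  out$has_tf_peak <- if (is.null(tf_peaks)) {
    rep(TRUE, n)
  } else {
    seq_len(n) %in% overlap_pairs(out, tf_peaks)$query
  }

  out$klass <- dplyr::case_when(
    out$is_promoter ~ "P",
    out$has_motif & out$has_tf_peak ~ "I_HLF",
    out$has_tf_peak ~ "I_plain",
    TRUE ~ "other"
  )
  out
}

#' Build enhancer-promoter (I-P) pairs from loops
#'
#' One pair per loop whose two anchors are classed `I_HLF` and `P`
#' (heterotypic motif-anchored interactions). Promoter windows holding
#' several genes expand into the pair's gene list. Loops should already be
#' filtered by [filter_loops()].
#'
#' @param loops Filtered loop tibble.
#' @param anchor_classes Output of [classify_anchors()] covering all loop
#'   anchors.
#' @return Tibble of pairs: loop coordinates split into `i_*` (motif anchor)
#'   and `p_*` (promoter anchor) columns, `contact_count`, `q_value`,
#'   `genes` list-column, `both_anchors_motif`.
#' @export
build_ep_pairs <- function(loops, anchor_classes) {
  key <- function(ch, s, e) paste(ch, s, e)
  ak <- key(anchor_classes$chrom, anchor_classes$start, anchor_classes$end)
  i1 <- match(key(loops$chrom1, loops$start1, loops$end1), ak)
  i2 <- match(key(loops$chrom2, loops$start2, loops$end2), ak)
  if (anyNA(i1) || anyNA(i2)) {
    stop("anchor_classes must cover every loop anchor", call. = FALSE)
  }
  k1 <- anchor_classes$klass[i1]
  k2 <- anchor_classes$klass[i2]
  sel <- (k1 == "I_HLF" & k2 == "P") | (k1 == "P" & k2 == "I_HLF")
  idx <- which(sel)
  if (!length(idx)) {
    return(tibble(loop_id = integer(), chrom = character(),
                  i_start = numeric(), i_end = numeric(),
                  p_start = numeric(), p_end = numeric(),
                  contact_count = numeric(), q_value = numeric(),
                  genes = list(), both_anchors_motif = logical()))
  }
  p_is_1 <- k1[idx] == "P"
  p_row <- ifelse(p_is_1, i1[idx], i2[idx])
  i_row <- ifelse(p_is_1, i2[idx], i1[idx])
  tibble(
    loop_id = idx,
    chrom = loops$chrom1[idx],
    i_start = anchor_classes$start[i_row],
    i_end = anchor_classes$end[i_row],
    p_start = anchor_classes$start[p_row],
    p_end = anchor_classes$end[p_row],
    contact_count = loops$contact_count[idx],
    q_value = loops$q_value[idx],
    genes = anchor_classes$promoter_genes[p_row],
    both_anchors_motif = anchor_classes$has_motif[i_row] &
      anchor_classes$has_motif[p_row]
  )
}

#' Fraction of pairs with a motif at both anchors
#'
#' Heterotypic interactions dominate motif-anchored regulomes; this reports
#' how rare the homotypic (motif at both anchors) configuration is.
#'
#' @param pairs Output of [build_ep_pairs()].
#' @return A single number in `[0, 1]`.
#' @export
both_anchor_motif_fraction <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs", call. = FALSE)
  mean(pairs$both_anchors_motif)
}

enhancer_class_levels <- c("SE", "TE", "external_only", "none")

#' Aggregate I-P pairs into the per-gene E-P table
#'
#' The package's central output: one row per gene with promoter-side
#' involvement in at least one motif-anchored pair, carrying
#' * `n_pairs` and `sumCC` (the summed contact counts over all its pairs,
#'   a cumulative interaction-frequency statistic),
#' * `best_q` (the most significant pair q-value),
#' * differential-expression integration (`de_log2fc`, `de_adj_p`,
#'   `de_direction` at `adj_p < alpha`; genes absent from the DE table are
#'   retained as `absent`),
#' * the highest-precedence `enhancer_class` among the gene's motif anchors,
#' * the modal `chromatin_cluster` of its motif anchors (ties to the lowest
#'   cluster number),
#' * `is_tf` membership of the supplied transcription-factor list.
#'
#' Rows are sorted by ascending `best_q`, then descending `sumCC`, then
#' `gene_id`, making the output byte-stable under permutation of the inputs.
#' The subset with a significant direction (`up`/`down`) constitutes the
#' E-P genes; see [ep_genes()].
#'
#' @param pairs Output of [build_ep_pairs()].
#' @param de DE tibble with `gene_id`, `log2fc`, `adj_p` (knockout versus
#'   control).
#' @param anchor_enhancer_class Optional tibble mapping anchors
#'   (`chrom,start,end`) to `enhancer_class` (from
#'   [annotate_enhancer_class()]).
#' @param anchor_cluster Optional tibble mapping anchors (`chrom,start,end`)
#'   to `cluster`.
#' @param tf_list Character vector of TF gene ids.
#' @param alpha Adjusted-p threshold for calling a DE direction.
#' @return An `ep_gene_table` tibble.
#' @export
ep_gene_table <- function(pairs, de, anchor_enhancer_class = NULL,
                          anchor_cluster = NULL, tf_list = character(),
                          alpha = 0.05) {
  key <- function(ch, s, e) paste(ch, s, e)
  long <- pairs |>
    dplyr::mutate(i_key = key(.data$chrom, .data$i_start, .data$i_end)) |>
    tidyr::unnest_longer(col = "genes", values_to = "gene_id")

  ecls <- function(keys) {
    if (is.null(anchor_enhancer_class)) return(factor(rep(NA_character_, 1),
                                                      enhancer_class_levels))
    m <- match(keys, key(anchor_enhancer_class$chrom,
                         anchor_enhancer_class$start,
                         anchor_enhancer_class$end))
    v <- as.character(anchor_enhancer_class$enhancer_class[m])
    v <- v[!is.na(v)]
    if (!length(v)) return(factor("none", enhancer_class_levels))
    factor(enhancer_class_levels[min(match(v, enhancer_class_levels))],
           enhancer_class_levels)
  }
  ccl <- function(keys) {
    if (is.null(anchor_cluster)) return(NA_integer_)
    m <- match(keys, key(anchor_cluster$chrom, anchor_cluster$start,
                         anchor_cluster$end))
    v <- anchor_cluster$cluster[m]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    as.integer(names(tab)[tab == max(tab)][1])  # modal; tie -> lowest number
  }

  agg <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n_distinct(.data$loop_id),
      sumCC = sum(.data$contact_count),
      best_q = min(.data$q_value),
      enhancer_class = ecls(.data$i_key)[1],
      chromatin_cluster = ccl(.data$i_key)[1],
      .groups = "drop"
    )

  m <- match(agg$gene_id, de$gene_id)
  agg$de_log2fc <- de$log2fc[m]
  agg$de_adj_p <- de$adj_p[m]
  agg$de_direction <- dplyr::case_when(
    is.na(m) ~ "absent",
    agg$de_adj_p < alpha & agg$de_log2fc > 0 ~ "up",
    agg$de_adj_p < alpha & agg$de_log2fc < 0 ~ "down",
    TRUE ~ "ns"
  )
  agg$is_tf <- agg$gene_id %in% tf_list
  out <- dplyr::arrange(agg, .data$best_q, dplyr::desc(.data$sumCC),
                        .data$gene_id)
  class(out) <- c("ep_gene_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Significantly regulated E-P genes
#'
#' The subset of the E-P table with a significant knockout response
#' (`de_direction` `up` or `down`).
#'
#' @param table An `ep_gene_table`.
#' @return The filtered table.
#' @export
ep_genes <- function(table) {
  dplyr::filter(table, .data$de_direction %in% c("up", "down"))
}

#' @method glance ep_gene_table
#' @export
glance.ep_gene_table <- function(x, ...) {
  sig <- ep_genes(x)
  tibble(n_genes = nrow(x), n_ep_genes = nrow(sig),
         n_up = sum(sig$de_direction == "up"),
         n_down = sum(sig$de_direction == "down"),
         n_tf = sum(sig$is_tf),
         total_sumCC = sum(x$sumCC), alpha = attr(x, "alpha") %||% 0.05)
}

#' Up/down breakdown of E-P genes per chromatin cluster
#'
#' Restricted to genes with a significant direction and an assigned cluster.
#'
#' @param table An `ep_gene_table`.
#' @return Tibble with `cluster`, `n_up`, `n_down`, `fraction_down`.
#' @export
cluster_direction_breakdown <- function(table) {
  table |>
    dplyr::filter(.data$de_direction %in% c("up", "down"),
                  !is.na(.data$chromatin_cluster)) |>
    dplyr::group_by(cluster = .data$chromatin_cluster) |>
    dplyr::summarise(
      n_up = sum(.data$de_direction == "up"),
      n_down = sum(.data$de_direction == "down"),
      fraction_down = .data$n_down / (.data$n_up + .data$n_down),
      .groups = "drop"
    )
}

#' Transcription factors among the E-P genes
#'
#' @param table An `ep_gene_table`.
#' @return List with `down_tfs` and `up_tfs`: character vectors of TF gene
#'   ids with significant down-/up-regulation, sorted by ascending `best_q`.
#' @export
tf_subset <- function(table) {
  sig <- dplyr::filter(table, .data$is_tf,
                       .data$de_direction %in% c("up", "down")) |>
    dplyr::arrange(.data$best_q)
  list(down_tfs = sig$gene_id[sig$de_direction == "down"],
       up_tfs = sig$gene_id[sig$de_direction == "up"])
}

#' Subtype-specific gene filter
#'
#' A gene is specific to the target subtype when its median expression in the
#' target samples is at least `fold` times the median of **every** other
#' subtype (strict per-subtype rule, the default) or of the pooled other
#' samples (`comparison = "pooled"`). Subtypes with no samples are excluded
#' with a warning.
#'
#' @param expr Numeric gene x sample matrix with dimnames, or a data frame
#'   whose first column is `gene_id`.
#' @param labels Named character vector (`sample -> subtype`) or a tibble
#'   with `sample` and `subtype` columns.
#' @param target_subtype The subtype of interest.
#' @param fold Fold threshold.
#' @param comparison `"per_subtype"` (strict) or `"pooled"`.
#' @return Tibble with `gene_id`, `median_target`, `max_other_median`,
#'   `specific` (logical); use `dplyr::filter(specific)` for the gene list.
#' @export
subtype_specific_genes <- function(expr, labels, target_subtype, fold = 3.0,
                                   comparison = c("per_subtype", "pooled")) {
  comparison <- match.arg(comparison)
  if (is.data.frame(expr)) {
    gene_id <- expr[[1]]
    expr <- as.matrix(expr[, -1, drop = FALSE])
    rownames(expr) <- gene_id
  }
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$subtype, labels$sample)
  }
  declared <- unique(labels)
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  subtypes <- unique(labels)
  if (!target_subtype %in% subtypes) stop("target subtype absent", call. = FALSE)
  empties <- setdiff(declared, subtypes)
  if (length(empties)) warning("subtype(s) with 0 samples excluded: ",
                               paste(empties, collapse = ", "), call. = FALSE)
  tgt <- apply(expr[, labels == target_subtype, drop = FALSE], 1, stats::median)
  others <- setdiff(subtypes, target_subtype)
  if (!length(others)) stop("need >= 2 subtypes", call. = FALSE)
  if (comparison == "pooled") {
    other_med <- apply(expr[, labels != target_subtype, drop = FALSE], 1,
                       stats::median)
    max_other <- other_med
  } else {
    med_mat <- sapply(others, function(s) {
      apply(expr[, labels == s, drop = FALSE], 1, stats::median)
    })
    med_mat <- matrix(med_mat, nrow = nrow(expr))
    max_other <- apply(med_mat, 1, max)
  }
  tibble(gene_id = rownames(expr), median_target = tgt,
         max_other_median = max_other,
         specific = tgt >= fold * max_other)
}

#' Write the E-P gene table as TSV
#' @param table An `ep_gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ep_gene_table <- function(table, path) {
  out <- as_tibble(table)
  out$enhancer_class <- as.character(out$enhancer_class)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write annotated I-P pairs as BEDPE with classes
#' @param pairs Output of [build_ep_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ep_pairs <- function(pairs, path) {
  out <- tibble(
    chrom1 = pairs$chrom, start1 = pairs$i_start, end1 = pairs$i_end,
    chrom2 = pairs$chrom, start2 = pairs$p_start, end2 = pairs$p_end,
    contact_count = pairs$contact_count, q_value = pairs$q_value,
    klass = "I_HLF-P",
    genes = vapply(pairs$genes, paste, character(1), collapse = ","),
    both_anchors_motif = as.integer(pairs$both_anchors_motif)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
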