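#' Bin-matched module score
#'
#' Per-cell score of a gene module against expression-matched controls, the
#' scheme popularised by Seurat's `AddModuleScore` (defaults mirrored: 24
#' equal-frequency bins of mean expression, 100 control genes per module
#' gene, sampled with replacement from the module gene's bin). The score is
#' the mean expression of the module genes minus the mean expression of the
#' pooled control genes, per cell; it is invariant under adding a constant to
#' every matrix entry and reproducible under a fixed seed.
#'
#' @param expr Numeric gene x cell matrix (log scale) with dimnames.
#' @param module Character vector of module gene names; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Number of equal-frequency bins of mean expression.
#' @param n_ctrl Control genes sampled per module gene.
#' @param seed RNG seed for control sampling.
#' @return A `module_score_result` tibble with `cell` and `score` columns;
#'   the module used, bin count, control count and seed are attached as
#'   attributes.
#' @export
module_score <- function(expr, module, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing <- setdiff(module, rownames(expr))
  if (length(missing)) {
    warning(length(missing), " module gene(s) absent from the matrix dropped",
            call. = FALSE)
  }
  module <- intersect(module, rownames(expr))
  if (!length(module)) stop("empty module after filtering", call. = FALSE)
  avg <- rowMeans(expr)
  bin <- dplyr::ntile(avg, n_bins)
  names(bin) <- rownames(expr)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(module, function(g) {
      pool <- rownames(expr)[bin == bin[[g]]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  sc <- colMeans(expr[module, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
  out <- tibble(cell = colnames(expr) %||% as.character(seq_len(ncol(expr))),
                score = unname(sc))
  class(out) <- c("module_score_result", class(out))
  attr(out, "module") <- module
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  out
}

#' @method glance module_score_result
#' @export
glance.module_score_result <- function(x, ...) {
  tibble(n_cells = nrow(x), n_module_genes = length(attr(x, "module")),
         n_bins = attr(x, "n_bins"), n_ctrl = attr(x, "n_ctrl"),
         mean_score = mean(x$score), sd_score = stats::sd(x$score))
}

# Weighted Kolmogorov-Smirnov-style enrichment score for a preranked list.
# Evaluates the running sum only at hit positions (it is linear between
# them), which is exact and fast.
enrichment_score <- function(metric_sorted, hit_pos, weight_p = 1) {
  N <- length(metric_sorted)
  m <- length(hit_pos)
  if (m == 0 || m >= N) stop("set size must be in [1, N-1]", call. = FALSE)
  s <- sort(hit_pos)
  w <- unname(abs(metric_sorted[s]))^weight_p
  if (sum(w) == 0) w <- rep(1, m)
  cum <- cumsum(w) / sum(w)
  d <- 1 / (N - m)
  after <- cum - (s - seq_len(m)) * d        # running sum just after each hit
  before <- c(0, cum[-m]) - (s - seq_len(m)) * d  # just before each hit
  cand <- c(after, before)
  es <- cand[which.max(abs(cand))]
  k <- if (es >= 0) which.max(after) else which.min(before)
  list(es = es,
       leading = if (es >= 0) s[seq_len(k)] else s[seq(k, m)])
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted KS-style enrichment of gene sets in a ranked list, with a
#' gene-set permutation null: hit steps are `|metric|^p / sum |metric|^p`,
#' miss steps `1/(N - m)`; the enrichment score (ES) is the signed maximum
#' deviation of the running sum. The null distribution per set size draws
#' `n_perm` random same-size sets; NES divides ES by the mean magnitude of
#' same-sign null scores and the permutation p-value is
#' `(1 + #{same-sign null as-or-more extreme}) / (1 + #same-sign null)`,
#' Benjamini-Hochberg adjusted across sets.
#'
#' @param ranking Named numeric vector (gene -> metric) or a data frame with
#'   `gene_id` and `metric` columns; no duplicate genes.
#' @param gene_sets Named list of character vectors.
#' @param weight_p Hit-weight exponent (1 = classic weighted statistic).
#' @param n_perm Number of null permutations per set size.
#' @param seed RNG seed.
#' @param min_size Sets smaller than this after intersection with the
#'   ranking are skipped with a note.
#' @return A `gsea_result` tibble: `set`, `size`, `es`, `nes`, `p_perm`,
#'   `adj_p` and a `leading_edge` list-column of gene names.
#' @export
preranked_gsea <- function(ranking, gene_sets, weight_p = 1, n_perm = 1000,
                           seed = 0, min_size = 3) {
  if (is.data.frame(ranking)) {
    ranking <- stats::setNames(ranking$metric, ranking$gene_id)
  }
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking",
                                          call. = FALSE)
  ord <- order(ranking, decreasing = TRUE)
  metric <- ranking[ord]
  genes <- names(metric)
  N <- length(metric)

  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)),
                  integer(1))
  skip <- sizes < min_size
  if (any(skip)) {
    message(sum(skip), " set(s) below min_size skipped: ",
            paste(names(gene_sets)[skip], collapse = ", "))
  }
  use <- names(gene_sets)[!skip]
  if (!length(use)) {
    return(structure(tibble(set = character(), size = integer(),
                            es = numeric(), nes = numeric(),
                            p_perm = numeric(), adj_p = numeric(),
                            leading_edge = list()),
                     class = c("gsea_result", class(tibble()))))
  }

  # one shared null per distinct set size
  null_for_size <- withr::with_seed(seed, {
    out <- list()
    for (m in sort(unique(sizes[use]))) {
      out[[as.character(m)]] <- vapply(seq_len(n_perm), function(i) {
        enrichment_score(metric, sample.int(N, m), weight_p)$es
      }, numeric(1))
    }
    out
  })

  rows <- purrr::map_dfr(use, function(nm) {
    hit <- which(genes %in% gene_sets[[nm]])
    r <- enrichment_score(metric, hit, weight_p)
    null <- null_for_size[[as.character(length(hit))]]
    same <- null[sign(null) == sign(r$es)]
    if (length(same)) {
      nes <- r$es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(r$es))) / (1 + length(same))
    } else {
      nes <- NA_real_
      p <- 1 / (1 + 0)
    }
    tibble(set = nm, size = length(hit), es = r$es, nes = nes, p_perm = p,
           leading_edge = list(genes[r$leading]))
  })
  rows$adj_p <- stats::p.adjust(rows$p_perm, method = "BH")
  rows <- rows[, c("set", "size", "es", "nes", "p_perm", "adj_p",
                   "leading_edge")]
  class(rows) <- c("gsea_result", class(rows))
  rows
}

#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$adj_p < 0.05, na.rm = TRUE),
         max_abs_nes = if (nrow(x)) max(abs(x$nes), na.rm = TRUE) else NA_real_)
}

#' Read gene sets in GMT format
#' @param path Path to a GMT file (set name, description, genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Signed significance ranking metric from a DE table
#'
#' `-log10(adj_p) * sign(log2fc)`, the pipeline's default preranked-GSEA
#' input; p-values of 0 are clamped to the smallest positive double.
#'
#' @param de DE tibble with `gene_id`, `log2fc`, `adj_p`.
#' @return Named numeric vector.
#' @export
de_ranking_metric <- function(de) {
  p <- pmax(de$adj_p, .Machine$double.xmin)
  stats::setNames(-log10(p) * sign(de$log2fc), de$gene_id)
}
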