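#' Read significant interaction pairs from BEDPE
#'
#' Parses the 7-8 column tab-separated dialect emitted by FitHiChIP-style
#' loop callers: `chr1 s1 e1 chr2 s2 e2 contact_count [q_value]`. Anchors are
#' canonicalised so that anchor 1 precedes anchor 2 (by chromosome, then
#' start); a missing q column is treated as 0 (pre-filtered input). Anchor
#' widths are validated against the bin grid.
#'
#' @param path Path to the BEDPE file.
#' @param bin_size Expected anchor width in bp (the loop caller's bin size).
#' @return A tibble of loops: `chrom1,start1,end1,chrom2,start2,end2`,
#'   `contact_count`, `q_value`, `intra` (same chromosome) and `distance`
#'   (anchor start difference; NA for inter-chromosomal pairs).
#' @export
read_bedpe <- function(path, bin_size = 5000) {
  d <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 7) stop("BEDPE needs >= 7 columns", call. = FALSE)
  names(d)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "contact_count")
  d$q_value <- if (ncol(d) >= 8) as.numeric(d[[8]]) else 0
  d <- d[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
             "contact_count", "q_value")]
  bad <- which(d$end1 - d$start1 != bin_size | d$end2 - d$start2 != bin_size)
  if (length(bad)) {
    stop("anchor width != bin_size (", bin_size, ") at row ", bad[1],
         call. = FALSE)
  }
  canonicalize_loops(as_tibble(d))
}

canonicalize_loops <- function(d) {
  swap <- d$chrom1 > d$chrom2 |
    (d$chrom1 == d$chrom2 & d$start1 > d$start2)
  if (any(swap)) {
    tmp <- d[swap, c("chrom1", "start1", "end1")]
    d[swap, c("chrom1", "start1", "end1")] <-
      d[swap, c("chrom2", "start2", "end2")]
    d[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  d$intra <- d$chrom1 == d$chrom2
  d$distance <- ifelse(d$intra, d$start2 - d$start1, NA_real_)
  dplyr::arrange(d, .data$chrom1, .data$start1, .data$chrom2, .data$start2)
}

#' Write loops as BEDPE
#'
#' 8-column dialect matching [read_bedpe()]; bit-stable for identical input.
#'
#' @param loops Loop tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  out <- loops[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "contact_count", "q_value")]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Filter loops to the significant intra-chromosomal set
#'
#' Keeps intra-chromosomal loops with q-value at most `q_max` and anchor
#' distance within `[d_min, d_max]`; inter-chromosomal loops are dropped.
#' Defaults follow standard HiChIP loop-calling practice (FDR < 0.01,
#' 50 kb - 3 Mb at 5-kb bins).
#'
#' @param loops Loop tibble from [read_bedpe()].
#' @param q_max Maximum q-value.
#' @param d_min,d_max Distance range in bp, inclusive.
#' @return Filtered loop tibble (a subset of the input rows).
#' @export
filter_loops <- function(loops, q_max = 0.01, d_min = 50000, d_max = 3000000) {
  dplyr::filter(loops, .data$intra, .data$q_value <= q_max,
                .data$distance >= d_min, .data$distance <= d_max)
}

#' Union of loop anchors
#'
#' The unique anchor bins of a loop set (the 1D peak universe of the
#' interaction map), each tagged with the indices of the loops touching it.
#'
#' @param loops Loop tibble.
#' @return Tibble of unique anchors: `chrom`, `start`, `end`, `n_loops` and a
#'   `loop_ids` list-column of integer loop indices; sorted.
#' @export
anchors_union <- function(loops) {
  if (nrow(loops) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_loops = integer(), loop_ids = list()))
  }
  long <- dplyr::bind_rows(
    tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1,
           loop_id = seq_len(nrow(loops))),
    tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2,
           loop_id = seq_len(nrow(loops)))
  )
  long |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(loop_ids = list(sort(unique(.data$loop_id))),
                     .groups = "drop") |>
    dplyr::mutate(n_loops = lengths(.data$loop_ids)) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "n_loops", "loop_ids")
}

#' Read a contact matrix from triplet text
#'
#' `bin_i bin_j count` rows (0-based bins); the matrix is symmetrised.
#'
#' @param path Path to the triplet file.
#' @param n_bins Matrix dimension; inferred from the largest bin if `NULL`.
#' @param resolution Bin size in bp, stored as an attribute.
#' @return A symmetric numeric matrix with a `resolution` attribute.
#' @export
read_contact_matrix <- function(path, n_bins = NULL, resolution = 100000) {
  d <- readr::read_tsv(path, col_names = c("i", "j", "count"),
                       show_col_types = FALSE, progress = FALSE)
  n <- n_bins %||% (max(d$i, d$j) + 1L)
  m <- matrix(0, n, n)
  m[cbind(d$i + 1L, d$j + 1L)] <- d$count
  m[cbind(d$j + 1L, d$i + 1L)] <- d$count
  attr(m, "resolution") <- resolution
  m
}

#' Write a contact matrix as triplet text
#'
#' Upper triangle (including diagonal) of non-zero entries as
#' `bin_i bin_j count`.
#'
#' @param m Square symmetric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L, count = m[idx])
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# 2D box mean filter with edge truncation (window shrinks at matrix borders),
# computed from an integral image.
box_mean_filter <- function(m, h) {
  if (h == 0) return(m)
  n <- nrow(m); p <- ncol(m)
  S <- matrix(0, n + 1, p + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(n) - h, 1L); r2 <- pmin(seq_len(n) + h, n)
  c1 <- pmax(seq_len(p) - h, 1L); c2 <- pmin(seq_len(p) + h, p)
  tot <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot / cnt
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Reproducibility of two contact matrices of the same chromosome: both are
#' mean-filtered with a (2h+1) x (2h+1) window (edge-truncated, no padding),
#' then for each diagonal stratum k whose genomic offset lies within
#' `[lb, ub]` the Pearson correlation of paired entries is computed, and the
#' strata are combined with weights N_k * sd1_k * sd2_k. Strata with zero
#' variance in either matrix are skipped.
#'
#' @param m1,m2 Square symmetric matrices of equal dimension (optionally with
#'   a `resolution` attribute).
#' @param h Half-width of the smoothing window; `h = 0` disables smoothing.
#' @param lb,ub Genomic distance bounds in bp for included strata.
#' @param resolution Bin size in bp; defaults to the matrices' attribute.
#' @return SCC in `[-1, 1]`.
#' @export
scc <- function(m1, m2, h = 3, lb = 0, ub = 3000000, resolution = NULL) {
  stopifnot(is.matrix(m1), is.matrix(m2), all(dim(m1) == dim(m2)),
            nrow(m1) == ncol(m1))
  resolution <- resolution %||% attr(m1, "resolution") %||% 100000
  f1 <- box_mean_filter(m1, h)
  f2 <- box_mean_filter(m2, h)
  n <- nrow(m1)
  num <- 0; den <- 0
  for (k in 0:(n - 1)) {
    gd <- k * resolution
    if (gd < lb || gd > ub) next
    i <- seq_len(n - k)
    x <- f1[cbind(i, i + k)]
    y <- f2[cbind(i, i + k)]
    if (length(x) < 2) next
    s1 <- stats::sd(x); s2 <- stats::sd(y)
    if (s1 == 0 || s2 == 0) next
    w <- length(x) * s1 * s2
    num <- num + w * stats::cor(x, y)
    den <- den + w
  }
  if (den == 0) stop("degenerate matrices: no stratum with variance",
                     call. = FALSE)
  num / den
}
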