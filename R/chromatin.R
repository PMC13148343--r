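#' Build a motif-centered signal matrix
#'
#' For each region the midpoint is taken as the motif center and per-bin mean
#' signal is computed for every track over `center - span` to `center + span`.
#' Bins are ordered 5' to 3' on the + strand convention; rows for - strand
#' centers are flipped. Windows running past a chromosome boundary are padded
#' with zeros and flagged.
#'
#' @param centers Interval tibble (`chrom`, `start`, `end`, optional
#'   `strand`); midpoints define the centers.
#' @param tracks Named list of bedGraph tibbles (`chrom,start,end,value`).
#' @param span Half-width of the window in bp.
#' @param bin_width Bin width in bp; `2 * span / bin_width` bins result.
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   edge detection.
#' @return A `signal_matrix` object: list with `regions` (tibble, including
#'   an `edge` flag), `tracks` (named list of region x bin matrices),
#'   `span`, `bin_width`.
#' @export
build_signal_matrix <- function(centers, tracks, span = 2000, bin_width = 50,
                                chrom_sizes = NULL) {
  assert_intervals(centers)
  stopifnot(length(tracks) > 0, !is.null(names(tracks)),
            span %% bin_width == 0)
  centers <- as_tibble(centers)
  if (is.null(centers[["strand"]])) centers$strand <- "+"
  n <- nrow(centers)
  nb <- as.integer(2 * span / bin_width)
  mid <- floor((centers$start + centers$end) / 2)
  left <- mid - span
  edge <- left < 0
  if (!is.null(chrom_sizes)) {
    edge <- edge | (mid + span > unname(chrom_sizes[centers$chrom]))
  }
  # bin boundaries per region, clipped at 0; clipped area contributes 0 signal
  mats <- lapply(tracks, function(tr) {
    idx <- track_index(tr)
    m <- matrix(0, n, nb)
    for (b in seq_len(nb)) {
      a0 <- left + (b - 1) * bin_width
      b0 <- a0 + bin_width
      area <- track_area(idx, centers$chrom, pmax(0, a0), pmax(0, b0))
      m[, b] <- area / bin_width
    }
    flip <- centers$strand == "-"
    if (any(flip)) m[flip, ] <- m[flip, nb:1, drop = FALSE]
    m
  })
  regions <- centers
  regions$center <- mid
  regions$edge <- edge
  structure(list(regions = regions, tracks = mats, span = span,
                 bin_width = bin_width),
            class = "signal_matrix")
}

#' @method print signal_matrix
#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$regions), " regions x ",
      ncol(x$tracks[[1]]), " bins (", x$bin_width, " bp), tracks: ",
      paste(names(x$tracks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  nb <- ncol(x$tracks[[1]])
  pos <- seq(-x$span + x$bin_width / 2, x$span - x$bin_width / 2,
             by = x$bin_width)
  purrr::imap_dfr(x$tracks, function(m, tk) {
    tibble(track = tk,
           region = rep(seq_len(nrow(m)), times = nb),
           bin = rep(seq_len(nb), each = nrow(m)),
           position = rep(pos, each = nrow(m)),
           value = as.vector(m))
  })
}

#' @method glance signal_matrix
#' @export
glance.signal_matrix <- function(x, ...) {
  tibble(n_regions = nrow(x$regions), n_bins = ncol(x$tracks[[1]]),
         n_tracks = length(x$tracks), span = x$span, bin_width = x$bin_width)
}

subset_signal_matrix <- function(x, idx) {
  x$regions <- x$regions[idx, , drop = FALSE]
  x$tracks <- lapply(x$tracks, function(m) m[idx, , drop = FALSE])
  x
}

#' Keep the most enriched regions of a signal matrix
#'
#' Ranks regions by the row sum of the named track (typically the
#' immunoprecipitated factor's own occupancy) and keeps the top fraction;
#' ties resolve by coordinate.
#'
#' @param x A `signal_matrix`.
#' @param track Track name to rank by.
#' @param top_fraction Fraction of regions kept.
#' @return A `signal_matrix` with the selected regions.
#' @export
select_top_enriched <- function(x, track = "TCF3HLF", top_fraction = 0.75) {
  stopifnot(inherits(x, "signal_matrix"))
  if (!track %in% names(x$tracks)) {
    stop("track '", track, "' not present", call. = FALSE)
  }
  n <- nrow(x$regions)
  rs <- rowSums(x$tracks[[track]])
  ord <- order(-rs, x$regions$chrom, x$regions$start)
  keep <- sort(ord[seq_len(floor(n * top_fraction + 1e-9))])
  subset_signal_matrix(x, keep)
}

#' Cluster regions by chromatin state
#'
#' k-means on the concatenated per-track bin profiles, with each track's bins
#' standardised to zero mean / unit variance across regions so no deep track
#' dominates. Clusters are relabelled so cluster 1 has the highest mean
#' signal of the active mark (descending), making cluster identity stable
#' across seeds for well-separated states.
#'
#' @param x A `signal_matrix`.
#' @param k Number of clusters.
#' @param seed RNG seed (10 k-means restarts, best inertia kept).
#' @param active_track Track whose mean orders the cluster labels; defaults
#'   to `"H3K27ac"` when present, else the first track.
#' @return A `chromatin_clusters` object: list with `cluster` (integer vector
#'   over regions), `sizes`, `k`, `active_track`, `track_means` (cluster x
#'   track mean row-sums).
#' @export
cluster_regions <- function(x, k = 3, seed = 1, active_track = NULL) {
  stopifnot(inherits(x, "signal_matrix"))
  n <- nrow(x$regions)
  if (k > n) stop("k > number of regions", call. = FALSE)
  active_track <- active_track %||%
    (if ("H3K27ac" %in% names(x$tracks)) "H3K27ac" else names(x$tracks)[1])
  feat <- do.call(cbind, lapply(x$tracks, function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sdv, "/")
  }))
  if (k == 1) {
    cl <- rep(1L, n)
  } else {
    km <- withr::with_seed(seed,
      stats::kmeans(feat, centers = k, nstart = 10, iter.max = 100))
    cl <- km$cluster
  }
  act <- rowSums(x$tracks[[active_track]])
  means <- tapply(act, cl, mean)
  relabel <- integer(k)
  relabel[order(-means)] <- seq_len(k)
  cl <- relabel[cl]
  tm <- sapply(x$tracks, function(m) tapply(rowSums(m), cl, mean))
  tm <- matrix(tm, nrow = k, dimnames = list(seq_len(k), names(x$tracks)))
  structure(list(cluster = cl, sizes = as.integer(table(cl)), k = k,
                 active_track = active_track, track_means = tm,
                 regions = x$regions),
            class = "chromatin_clusters")
}

#' @method print chromatin_clusters
#' @export
print.chromatin_clusters <- function(x, ...) {
  cat("<chromatin_clusters> k =", x$k, ", sizes:",
      paste(x$sizes, collapse = "/"),
      ", ordered by", x$active_track, "\n")
  invisible(x)
}

#' @method tidy chromatin_clusters
#' @export
tidy.chromatin_clusters <- function(x, ...) {
  dplyr::mutate(x$regions[, c("chrom", "start", "end")],
                region = dplyr::row_number(), cluster = x$cluster)
}

#' @method glance chromatin_clusters
#' @export
glance.chromatin_clusters <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster),
         largest = max(x$sizes), smallest = min(x$sizes))
}

#' Per-cluster signal density statistics
#'
#' RPKM-style per-region density (row sum over the window, per kb, per
#' million units of total track signal) compared between every cluster pair
#' for every track with Welch two-tailed t-tests, Benjamini-Hochberg adjusted
#' across all tests of the family. The density is invariant under rescaling a
#' track by a constant.
#'
#' @param x A `signal_matrix`.
#' @param clusters A `chromatin_clusters` from [cluster_regions()].
#' @return Tibble with `track`, `cluster_a`, `cluster_b`, `mean_a`, `mean_b`,
#'   `statistic`, `p_value`, `q_value`; clusters with fewer than 2 regions
#'   are skipped with a note. Per-cluster mean densities are attached as the
#'   `cluster_means` attribute.
#' @export
density_stats <- function(x, clusters) {
  stopifnot(inherits(x, "signal_matrix"), inherits(clusters, "chromatin_clusters"))
  cl <- clusters$cluster
  span_kb <- 2 * x$span / 1000
  dens <- lapply(x$tracks, function(m) {
    tot <- sum(m)
    if (tot == 0) return(rowSums(m) * 0)
    rowSums(m) / (span_kb * tot / 1e6)
  })
  ks <- sort(unique(cl))
  small <- ks[tabulate(cl)[ks] < 2]
  if (length(small)) {
    message("cluster(s) with n < 2 skipped: ", paste(small, collapse = ", "))
    ks <- setdiff(ks, small)
  }
  if (length(ks) < 2) stop("need >= 2 clusters with >= 2 regions", call. = FALSE)
  pairs <- utils::combn(ks, 2)
  rows <- purrr::imap_dfr(dens, function(d, tk) {
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      da <- d[cl == a]; db <- d[cl == b]
      tt <- tryCatch(stats::t.test(da, db), error = function(e) NULL)
      tibble(track = tk, cluster_a = a, cluster_b = b,
             mean_a = mean(da), mean_b = mean(db),
             statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
             p_value = if (is.null(tt)) NA_real_ else tt$p.value)
    })
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  cm <- purrr::imap_dfr(dens, function(d, tk) {
    tibble(track = tk, cluster = ks,
           mean_density = vapply(ks, function(k) mean(d[cl == k]), numeric(1)),
           n = vapply(ks, function(k) sum(cl == k), integer(1)))
  })
  attr(rows, "cluster_means") <- cm
  rows
}

#' Per-cluster correlation of two tracks
#'
#' Pearson correlation of per-region window sums of two tracks within each
#' cluster (e.g. chromatin accessibility versus factor occupancy), with the
#' two-sided t-distribution p-value. Clusters with fewer than 3 regions, or
#' with zero variance in either track, are skipped.
#'
#' @param x A `signal_matrix`.
#' @param clusters A `chromatin_clusters`.
#' @param track_a,track_b Track names to correlate.
#' @return Tibble with `cluster`, `n`, `r`, `p_value`.
#' @export
cluster_signal_correlation <- function(x, clusters, track_a = "ATAC",
                                       track_b = "TCF3HLF") {
  stopifnot(inherits(x, "signal_matrix"))
  for (tk in c(track_a, track_b)) {
    if (!tk %in% names(x$tracks)) stop("track '", tk, "' not present",
                                       call. = FALSE)
  }
  a <- rowSums(x$tracks[[track_a]])
  b <- rowSums(x$tracks[[track_b]])
  cl <- clusters$cluster
  purrr::map_dfr(sort(unique(cl)), function(k) {
    sel <- cl == k
    if (sum(sel) < 3 || stats::sd(a[sel]) == 0 || stats::sd(b[sel]) == 0) {
      return(tibble(cluster = k, n = sum(sel), r = NA_real_,
                    p_value = NA_real_))
    }
    ct <- stats::cor.test(a[sel], b[sel])
    tibble(cluster = k, n = sum(sel), r = unname(ct$estimate),
           p_value = ct$p.value)
  })
}

#' Write a signal matrix as TSV
#' @param x A `signal_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
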