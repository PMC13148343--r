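#' Read narrowPeak / broadPeak files
#'
#' ENCODE narrowPeak (10 columns) or broadPeak (9 columns); coordinates are
#' already 0-based half-open.
#'
#' @param path Path to the peak file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal`, `p`, `q` and (narrowPeak only) `peak`.
#' @export
read_narrowpeak <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (!ncol(d) %in% c(9, 10)) {
    stop("expected 9 (broadPeak) or 10 (narrowPeak) columns", call. = FALSE)
  }
  nm <- c("chrom", "start", "end", "name", "score", "strand", "signal", "p", "q")
  if (ncol(d) == 10) nm <- c(nm, "peak")
  names(d) <- nm
  as_tibble(d)
}

#' Write peaks in narrowPeak format
#' @param peaks Tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks[["name"]] %||% sprintf("peak_%d", seq_len(n)),
    score = peaks[["score"]] %||% 0,
    strand = peaks[["strand"]] %||% ".",
    signal = peaks[["signal"]] %||% 0,
    p = peaks[["p"]] %||% -1,
    q = peaks[["q"]] %||% -1,
    peak = peaks[["peak"]] %||% -1
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       comment = "#", show_col_types = FALSE, progress = FALSE)
  as_tibble(d)
}

#' Write a bedGraph signal track
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Stitch peaks into enhancer clusters
#'
#' ROSE-style gap stitching: peaks whose gaps are at most `stitch_gap` bp are
#' merged transitively per chromosome. When `tss_exclusion > 0` (and gene
#' models are supplied), peaks lying fully within +/-`tss_exclusion` bp of any
#' TSS are kept out of stitching and returned as singletons.
#'
#' @param peaks Interval tibble (sorted or not).
#' @param stitch_gap Maximum gap in bp merged across (ROSE default 12,500).
#' @param tss_exclusion Half-width of the promoter exclusion zone, bp
#'   (0 disables, the ROSE default used here).
#' @param genes Gene models from [read_gtf()], required when
#'   `tss_exclusion > 0`.
#' @return Tibble of stitched regions: `chrom`, `start`, `end`, `n_peaks`,
#'   `members` (list of input row indices), sorted by coordinate.
#' @export
stitch_peaks <- function(peaks, stitch_gap = 12500, tss_exclusion = 0,
                         genes = NULL) {
  assert_intervals(peaks)
  peaks <- as_tibble(peaks)
  n <- nrow(peaks)
  excluded <- rep(FALSE, n)
  if (tss_exclusion > 0) {
    if (is.null(genes)) stop("tss_exclusion > 0 requires gene models",
                             call. = FALSE)
    zones <- tibble(chrom = genes$chrom,
                    start = pmax(0, genes$tss - tss_exclusion),
                    end = genes$tss + tss_exclusion + 1)
    ov <- overlap_pairs(peaks, zones)
    # fully contained, not merely overlapping
    cont <- ov[peaks$start[ov$query] >= zones$start[ov$subject] &
                 peaks$end[ov$query] <= zones$end[ov$subject], , drop = FALSE]
    excluded[unique(cont$query)] <- TRUE
  }
  stitch_one <- function(idx) {
    idx <- idx[order(peaks$start[idx], peaks$end[idx])]
    s <- peaks$start[idx]; e <- peaks$end[idx]
    grp <- cumsum(c(1, as.integer(s[-1] - cummax(e[-length(e)]) > stitch_gap)))
    tibble(chrom = peaks$chrom[idx[1]],
           start = as.numeric(tapply(s, grp, min)),
           end = as.numeric(tapply(cummax(e), grp, max)),
           n_peaks = as.integer(table(grp)),
           members = unname(split(idx, grp)))
  }
  keep <- which(!excluded)
  parts <- list()
  if (length(keep)) {
    parts <- lapply(split(keep, peaks$chrom[keep]), stitch_one)
  }
  singles <- which(excluded)
  if (length(singles)) {
    parts <- c(parts, list(tibble(chrom = peaks$chrom[singles],
                                  start = peaks$start[singles],
                                  end = peaks$end[singles],
                                  n_peaks = 1L,
                                  members = as.list(singles))))
  }
  dplyr::arrange(dplyr::bind_rows(parts), .data$chrom, .data$start, .data$end)
}

#' Score and rank stitched enhancers by signal
#'
#' Signal is the area of the (optionally control-subtracted) bedGraph track
#' over each stitched interval, floored at zero. Rank 1 is the highest
#' signal; ties break by wider interval, then lower coordinate.
#'
#' @param stitched Output of [stitch_peaks()].
#' @param signal bedGraph tibble (e.g. an H3K27ac coverage track).
#' @param control Optional control/input bedGraph tibble to subtract.
#' @return `stitched` with `signal` and `rank` columns.
#' @export
score_and_rank <- function(stitched, signal, control = NULL) {
  sig <- track_area(track_index(signal), stitched$chrom, stitched$start,
                    stitched$end, missing_chrom_warn = TRUE)
  if (!is.null(control)) {
    sig <- sig - track_area(track_index(control), stitched$chrom,
                            stitched$start, stitched$end)
  }
  out <- stitched
  out$signal <- pmax(0, sig)
  ord <- order(-out$signal, -(out$end - out$start), out$chrom, out$start)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Call super-enhancers by the ranked-signal elbow
#'
#' The classic hockey-stick cutoff: regions are ordered by ascending signal,
#' rank and signal are both scaled to `[0, 1]`, and the cutoff is the signal
#' at the point where the slope of the scaled curve first reaches 1 (scanning
#' from low to high). Regions with signal strictly above the cutoff are
#' super-enhancers (SE); the rest are typical enhancers (TE). The SE set is
#' invariant under positive rescaling of all signals. Degenerate profiles
#' (all-equal signals, or no elbow so that most regions would be called SE)
#' yield no SE with a warning.
#'
#' @param ranked Output of [score_and_rank()].
#' @return `ranked` with an `is_super` logical column and a
#'   `cutoff_signal` attribute.
#' @export
call_super_enhancers <- function(ranked) {
  out <- ranked
  n <- nrow(out)
  if (n < 3) stop("need >= 3 regions to call an elbow", call. = FALSE)
  v <- sort(out$signal)
  if (max(v) == min(v)) {
    warning("all signals equal: no super-enhancers called", call. = FALSE)
    out$is_super <- FALSE
    attr(out, "cutoff_signal") <- NA_real_
    return(out)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - min(v)) / (max(v) - min(v))
  slope <- diff(y) / diff(x)
  i <- which(slope >= 1)[1]
  if (is.na(i)) i <- n - 1L
  cutoff <- v[i]
  is_super <- out$signal > cutoff
  if (mean(is_super) > 0.5) {
    warning("no clear elbow (", sum(is_super), "/", n,
            " regions above cutoff): treating profile as degenerate, ",
            "no super-enhancers called", call. = FALSE)
    is_super <- rep(FALSE, n)
    cutoff <- NA_real_
  }
  out$is_super <- is_super
  attr(out, "cutoff_signal") <- cutoff
  out
}

#' Classify regions by enhancer overlap
#'
#' Any-overlap against the ROSE table and an optional external enhancer BED
#' (FANTOM5-style), with precedence SE > TE > external_only > none.
#'
#' @param regions Interval tibble.
#' @param rose Output of [call_super_enhancers()].
#' @param external_bed Optional interval tibble of externally annotated
#'   enhancers.
#' @return `regions` with an `enhancer_class` factor column with levels
#'   `SE`, `TE`, `external_only`, `none`.
#' @export
annotate_enhancer_class <- function(regions, rose, external_bed = NULL) {
  assert_intervals(regions)
  cls <- rep("none", nrow(regions))
  if (!is.null(external_bed) && nrow(external_bed) > 0) {
    ov <- overlap_pairs(regions, external_bed)
    cls[unique(ov$query)] <- "external_only"
  }
  if (!is.null(rose) && nrow(rose) > 0) {
    te <- rose[!rose$is_super, , drop = FALSE]
    se <- rose[rose$is_super, , drop = FALSE]
    if (nrow(te)) cls[unique(overlap_pairs(regions, te)$query)] <- "TE"
    if (nrow(se)) cls[unique(overlap_pairs(regions, se)$query)] <- "SE"
  }
  out <- as_tibble(regions)
  out$enhancer_class <- factor(cls, levels = c("SE", "TE", "external_only",
                                               "none"))
  out
}

#' Write a ROSE-style enhancer table
#' @param rose Output of [call_super_enhancers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rose_table <- function(rose, path) {
  out <- tibble(chrom = rose$chrom, start = rose$start, end = rose$end,
                n_peaks = rose$n_peaks, signal = rose$signal,
                rank = rose$rank, isSuper = as.integer(rose$is_super))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
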