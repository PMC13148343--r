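#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# All internal coordinates are 0-based half-open [start, end); GTF is converted
# at the boundary. See the methods vignette.

assert_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$start < 0 | df$start >= df$end)) {
    stop(what, ": require 0 <= start < end", call. = FALSE)
  }
  invisible(df)
}

#' Pair up overlapping intervals between two tables
#'
#' Any-overlap join between two interval tables in the package's 0-based
#' half-open convention. Backed by [IRanges::findOverlaps()] per chromosome.
#'
#' @param query,subject Data frames with `chrom`, `start`, `end` columns.
#' @return A tibble with integer columns `query` and `subject` holding row
#'   indices of overlapping pairs, sorted by `query` then `subject`.
#' @keywords internal
overlap_pairs <- function(query, subject) {
  assert_intervals(query, "query")
  assert_intervals(subject, "subject")
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  qs <- split(seq_len(nrow(query)), query$chrom)
  ss <- split(seq_len(nrow(subject)), subject$chrom)
  shared <- intersect(names(qs), names(ss))
  out <- purrr::map(shared, function(ch) {
    qi <- qs[[ch]]
    si <- ss[[ch]]
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    h <- IRanges::findOverlaps(q, s)
    tibble(query = qi[S4Vectors::queryHits(h)],
           subject = si[S4Vectors::subjectHits(h)])
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$query, .data$subject)
}

# Build an interval index for a bedGraph-style coverage table so that the
# integral of the (piecewise-constant) signal over any [a, b) can be evaluated
# in O(log n). Intervals must be non-overlapping within a chromosome.
track_index <- function(track) {
  assert_intervals(track, "bedGraph track")
  stopifnot("value" %in% names(track))
  idx <- lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("bedGraph intervals overlap within a chromosome", call. = FALSE)
    }
    list(start = d$start, end = d$end, value = d$value,
         cum = cumsum(d$value * (d$end - d$start)))
  })
  structure(idx, class = "track_index")
}

# Cumulative integral of an indexed track from 0 to x (vectorised over x).
track_cum <- function(idx1, x) {
  i <- findInterval(x, idx1$start)
  out <- numeric(length(x))
  pos <- i > 0
  ii <- i[pos]
  base <- ifelse(ii > 1, idx1$cum[ii - 1L], 0)
  inside <- pmax(0, pmin(x[pos], idx1$end[ii]) - idx1$start[ii])
  out[pos] <- base + idx1$value[ii] * inside
  out
}

#' Integrate a signal track over intervals
#'
#' Area under a bedGraph-style piecewise-constant track over each query
#' interval; uncovered bases contribute zero.
#'
#' @param idx A track index from `track_index()`, or a bedGraph tibble.
#' @param chrom,start,end Parallel vectors describing the query intervals.
#' @param missing_chrom_warn Warn when a queried chromosome has no coverage.
#' @return Numeric vector of areas (signal x bp).
#' @keywords internal
track_area <- function(idx, chrom, start, end, missing_chrom_warn = FALSE) {
  if (!inherits(idx, "track_index")) idx <- track_index(idx)
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (is.null(idx[[ch]])) {
      if (missing_chrom_warn) {
        warning("track has no coverage on chromosome '", ch,
                "'; signal set to 0", call. = FALSE)
      }
      next
    }
    out[sel] <- track_cum(idx[[ch]], end[sel]) - track_cum(idx[[ch]], start[sel])
  }
  out
}

# Deterministic per-stage seed derivation: a single user seed fans out to
# independent small-integer seeds so adding a stage never perturbs earlier
# stages. Kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, genes = 23L, loops = 37L, chromatin = 53L,
               tracks = 67L, de = 79L, subtypes = 97L, cells = 113L,
               tf = 127L, motif = 139L, cluster = 151L, score = 163L,
               gsea = 179L, scc = 191L, pipeline = 211L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage '", stage, "'", call. = FALSE)
  (as.integer(seed) %% 1000000L) * 1000L + off
}

#' Write intervals as BED6
#'
#' @param df Interval tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  assert_intervals(df)
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = df[["name"]] %||% ".",
    score = df[["score"]] %||% 0,
    strand = df[["strand"]] %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  # locale-stable numeric formatting for hand-written writers
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}
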