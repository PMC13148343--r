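DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  unname(DNA_CODE[v])  # anything outside ACGT (e.g. N) becomes NA
}

#' Construct a position weight matrix
#'
#' Holds base counts with a pseudocount and background model; scores are
#' log2 odds in bits. The motif's maximal attainable score is the sum of
#' per-position row maxima and defines the relative score used for hit
#' thresholding.
#'
#' @param counts L x 4 non-negative matrix, columns A, C, G, T (L >= 4).
#' @param name Motif name.
#' @param pseudocount Added to every count before normalisation.
#' @param background Length-4 probability vector over A, C, G, T.
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.1,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, nrow(counts) >= 4, all(counts >= 0),
            pseudocount > 0, length(background) == 4)
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1",
                                            call. = FALSE)
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts, pseudocount = pseudocount,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$name, " width", nrow(x$counts),
      " consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Log-odds score matrix of a PWM
#' @param x A `pwm`.
#' @return L x 4 matrix of log2-odds scores (bits).
#' @export
pwm_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  cc <- x$counts + x$pseudocount
  p <- cc / rowSums(cc)
  log2(sweep(p, 2, x$background, "/"))
}

#' @rdname pwm_log_odds
#' @export
pwm_max_score <- function(x) sum(apply(pwm_log_odds(x), 1, max))

#' @rdname pwm_log_odds
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$counts)[apply(x$counts, 1, which.max)], collapse = "")
}

# reverse-complement the log-odds matrix: reverse positions, swap A<->T, C<->G
revcomp_matrix <- function(lom) {
  lom[rev(seq_len(nrow(lom))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Reverse-complement a DNA string
#' @param seq DNA string over A, C, G, T, N.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

score_positions <- function(code, lom) {
  # score of every window start against lom; NA where a window contains N
  L <- nrow(lom)
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + lom[j, ][code[j:(j + nw - 1L)]]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every window of length L on both strands (the reverse strand is
#' scored by the reverse-complemented matrix, equivalent to scoring the
#' reverse complement of the window against the PWM) and reports windows with
#' relative score `score / max-attainable` at or above `threshold`. Windows
#' containing N are skipped; overlapping hits are allowed.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param motif A [pwm()].
#' @param threshold Minimum relative score in (0, 1].
#' @param offset Added to hit coordinates (0-based position of `seq`'s first
#'   base), convenient when scanning an excised region.
#' @param chrom Optional chromosome label carried into the output.
#' @return Tibble of hits: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score` (bits), `rel_score`; sorted by position.
#' @export
scan_sequence <- function(seq, motif, threshold = 0.8, offset = 0L,
                          chrom = NA_character_) {
  stopifnot(inherits(motif, "pwm"))
  lom <- unname(pwm_log_odds(motif))
  L <- nrow(lom)
  code <- encode_dna(seq)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(),
                  rel_score = numeric())
  if (length(code) < L) return(empty)
  mx <- pwm_max_score(motif)
  fw <- score_positions(code, lom)
  rv <- score_positions(code, revcomp_matrix(lom))
  hits <- function(sc, strand) {
    rel <- sc / mx
    keep <- which(!is.na(rel) & rel >= threshold)
    tibble(chrom = chrom, start = offset + keep - 1L,
           end = offset + keep + L - 1L, strand = strand,
           score = sc[keep], rel_score = rel[keep])
  }
  out <- dplyr::bind_rows(hits(fw, "+"), hits(rv, "-"))
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Flag regions that contain a motif
#'
#' Scans each region's sequence and records whether it carries at least one
#' PWM hit at the given relative-score threshold. Regions extending past a
#' chromosome end are clipped with a warning. Scanning concatenates all
#' regions of a chromosome with N spacers so the scanner runs once per
#' chromosome; N-containing windows are never hits, so spacers cannot create
#' spurious matches.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`).
#' @param genome Named character vector from [read_fasta()].
#' @param motif A [pwm()].
#' @param threshold Minimum relative score.
#' @return The input regions with `has_motif`, `n_hits` and a `hits`
#'   list-column of per-region hit tibbles.
#' @export
flag_motif_regions <- function(regions, genome, motif, threshold = 0.8) {
  assert_intervals(regions)
  n <- nrow(regions)
  regions <- as_tibble(regions)
  clipped <- FALSE
  start <- regions$start
  end <- regions$end
  for (i in seq_len(n)) {
    len <- nchar(genome[[regions$chrom[i]]])
    if (is.null(len)) stop("region on unknown chromosome ", regions$chrom[i],
                           call. = FALSE)
    if (end[i] > len) { end[i] <- len; clipped <- TRUE }
    if (start[i] < 0) { start[i] <- 0L; clipped <- TRUE }
  }
  if (clipped) warning("regions extending past a chromosome end were clipped",
                       call. = FALSE)
  L <- nrow(motif$counts)
  spacer <- strrep("N", L)
  hit_list <- rep(list(NULL), n)
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    seqs <- substr(rep(genome[[ch]], length(idx)), start[idx] + 1, end[idx])
    cat_seq <- paste(seqs, collapse = spacer)
    cat_off <- cumsum(c(0, head(nchar(seqs), -1) + L))
    allhits <- scan_sequence(cat_seq, motif, threshold, chrom = ch)
    region_of <- findInterval(allhits$start, cat_off)
    for (k in seq_along(idx)) {
      h <- allhits[region_of == k, , drop = FALSE]
      h$start <- h$start - cat_off[k] + start[idx[k]]
      h$end <- h$end - cat_off[k] + start[idx[k]]
      hit_list[[idx[k]]] <- h
    }
  }
  regions$has_motif <- vapply(hit_list, function(h) !is.null(h) && nrow(h) > 0,
                              logical(1))
  regions$n_hits <- vapply(hit_list, function(h) if (is.null(h)) 0L else nrow(h),
                           integer(1))
  regions$hits <- hit_list
  regions
}

#' Motif enrichment between two region sets
#'
#' One-sided Fisher's exact test on the 2x2 table of motif presence in
#' foreground versus background regions, with a Haldane correction (+0.5 per
#' cell) for the odds ratio when any cell is zero.
#'
#' @param fg,bg Foreground and background interval tibbles.
#' @param genome Named character vector from [read_fasta()].
#' @param motif A [pwm()].
#' @param threshold Minimum relative score.
#' @return A tibble with `odds_ratio`, `p_value` and the table cells.
#' @export
motif_enrichment <- function(fg, bg, genome, motif, threshold = 0.8) {
  if (nrow(fg) == 0 || nrow(bg) == 0) {
    stop("foreground and background must be non-empty", call. = FALSE)
  }
  fg_flag <- flag_motif_regions(fg, genome, motif, threshold)$has_motif
  bg_flag <- flag_motif_regions(bg, genome, motif, threshold)$has_motif
  a <- sum(fg_flag); b <- sum(!fg_flag)
  c0 <- sum(bg_flag); d <- sum(!bg_flag)
  tab <- matrix(c(a, b, c0, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (c0 + h))
  tibble(odds_ratio = or, p_value = p,
         fg_with = a, fg_without = b, bg_with = c0, bg_without = d)
}

#' Read a motif in JASPAR PFM text format
#'
#' Expects a `>name` header followed by four lines `A [ 1 2 3 ... ]` (brackets
#' optional), rows A, C, G, T.
#'
#' @param path Path to a JASPAR-style PFM file.
#' @inheritParams pwm
#' @return A [pwm()].
#' @export
read_jaspar <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (!length(header)) stop("no JASPAR header line", call. = FALSE)
  name <- sub("^>\\s*", "", lines[header[1]])
  rows <- lines[(header[1] + 1):(header[1] + 4)]
  parse_row <- function(x) {
    x <- gsub("^[ACGTacgt]\\s*|\\[|\\]", "", x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  }
  m <- t(vapply(rows, parse_row, numeric(length(parse_row(rows[1])))))
  pwm(t(m), name = name, pseudocount = pseudocount, background = background)
}

#' Write a motif in JASPAR PFM text format
#' @param motif A [pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motif, path) {
  m <- t(motif$counts)
  rownames(m) <- c("A", "C", "G", "T")
  writeLines(c(paste0(">", motif$name),
               vapply(1:4, function(i) {
                 paste0(rownames(m)[i], " [ ",
                        paste(fmt_num(m[i, ]), collapse = " "), " ]")
               }, character(1))), path)
  invisible(path)
}

#' Read a motif in MEME minimal format
#'
#' Parses the first motif of a MEME minimal file: the `MOTIF` line, the
#' `letter-probability matrix` header (using `nsites` to recover counts, 100
#' when absent) and an optional `Background letter frequencies` section.
#'
#' @param path Path to a MEME minimal motif file.
#' @param pseudocount Passed to [pwm()].
#' @return A [pwm()].
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- unname(vals[c("A", "C", "G", "T")])
  }
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("no MOTIF record", call. = FALSE)
  name <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  hi <- grep("^letter-probability matrix", lines)
  hdr <- lines[hi[1]]
  grab <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.]+)"), hdr))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else default
  }
  w <- grab("w", NA)
  nsites <- grab("nsites", 100)
  rows <- list()
  i <- hi[1] + 1
  while (i <= length(lines) && grepl("^\\s*[0-9.]", lines[i])) {
    rows[[length(rows) + 1]] <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    i <- i + 1
  }
  probs <- do.call(rbind, rows)
  if (!is.na(w) && nrow(probs) != w) stop("matrix width mismatch", call. = FALSE)
  pwm(probs * nsites, name = name, pseudocount = pseudocount, background = bg)
}

#' Write motif hits as BED6
#'
#' score = relative score x 1000, rounded.
#'
#' @param hits Hit tibble from [scan_sequence()] (with `chrom` filled in).
#' @param path Output path.
#' @param name Feature name for the BED name column.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(hits, path, name = "motif") {
  df <- hits
  df$name <- name
  df$score <- round(df$rel_score * 1000)
  write_bed(df, path)
}
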