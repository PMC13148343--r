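#' Read a FASTA genome
#'
#' Reads a (toy or real) genome into a named character vector of uppercased
#' sequences. Chromosome names are taken from the header up to the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 demo", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty FASTA record", call. = FALSE)
  names(seqs) <- nm
  seqs
}

#' Write a FASTA genome
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses gene/exon (and optionally UTR) features into one record per gene.
#' GTF 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention at this boundary. The TSS is the start of the first
#' exon on the + strand and the final base of the last exon on the - strand;
#' one TSS per gene (alternative transcripts are not modelled).
#'
#' @param path Path to a GTF file with `gene_id` (and ideally `gene_name`)
#'   attributes.
#' @param genome Optional genome (named character vector, as from
#'   [read_fasta()]); genes on undeclared chromosomes are dropped with a
#'   warning.
#' @return A tibble with one row per gene: `gene_id`, `symbol`, `chrom`,
#'   `strand`, `start`, `end`, `tss` (0-based bp) and list-columns `exons`,
#'   `utr5`, `utr3` of interval tibbles.
#' @export
read_gtf <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  d <- tibble(
    chrom = as.character(GenomicRanges_seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  )
  if (anyNA(d$gene_id)) stop("GTF record without gene_id", call. = FALSE)
  if (!is.null(genome)) {
    bad <- !(d$chrom %in% names(genome))
    if (any(bad)) {
      warning("dropping ", length(unique(d$gene_id[bad])),
              " gene(s) on chromosomes absent from the genome", call. = FALSE)
      drop_ids <- unique(d$gene_id[bad])
      d <- d[!(d$gene_id %in% drop_ids), , drop = FALSE]
    }
  }
  ex <- d[d$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) {
    # fall back to gene bodies as single exons
    ex <- d[d$type == "gene", , drop = FALSE]
  }
  per_gene <- function(type_sel) {
    sub <- d[d$type %in% type_sel, c("gene_id", "start", "end"), drop = FALSE]
    split(sub[c("start", "end")], sub$gene_id)
  }
  exl <- lapply(split(ex[c("start", "end")], ex$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    as_tibble(e)
  })
  u5 <- per_gene(c("five_prime_utr", "5UTR", "five_prime_UTR"))
  u3 <- per_gene(c("three_prime_utr", "3UTR", "three_prime_UTR"))
  meta <- dplyr::distinct(
    ex[, c("gene_id", "symbol", "chrom", "strand")], .data$gene_id,
    .keep_all = TRUE
  )
  genes <- meta |>
    dplyr::mutate(
      exons = exl[.data$gene_id],
      start = purrr::map_dbl(.data$exons, ~ min(.x$start)),
      end = purrr::map_dbl(.data$exons, ~ max(.x$end)),
      tss = ifelse(.data$strand == "-", .data$end - 1, .data$start),
      utr5 = purrr::map(.data$gene_id, ~ as_tibble(u5[[.x]] %||%
        tibble(start = numeric(), end = numeric()))),
      utr3 = purrr::map(.data$gene_id, ~ as_tibble(u3[[.x]] %||%
        tibble(start = numeric(), end = numeric())))
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
  as_tibble(genes)
}

# rtracklayer loads GenomicRanges as a dependency; seqnames() lives there but
# importing the whole package is unnecessary for one accessor.
GenomicRanges_seqnames <- function(gr) {
  methods::slot(gr, "seqnames")
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()] (0-based half-open back to 1-based inclusive);
#' emits `gene` and `exon` rows plus UTR rows when present.
#'
#' @param genes Gene-model tibble from [read_gtf()] or the synthetic generator.
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "epregulome") {
  attr_str <- function(id, sym) {
    sprintf('gene_id "%s"; gene_name "%s";', id, sym)
  }
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    a <- attr_str(g$gene_id, g$symbol)
    row <- function(type, s, e) {
      paste(g$chrom, source, type, fmt_num(s + 1), fmt_num(e), ".", g$strand,
            ".", a, sep = "\t")
    }
    lines <- c(lines, row("gene", g$start, g$end))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) lines <- c(lines, row("exon", ex$start[j], ex$end[j]))
    for (fld in c("utr5", "utr3")) {
      u <- g[[fld]][[1]]
      if (!is.null(u) && nrow(u) > 0) {
        type <- if (fld == "utr5") "five_prime_utr" else "three_prime_utr"
        for (j in seq_len(nrow(u))) lines <- c(lines, row(type, u$start[j], u$end[j]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Annotate intervals with genomic features
#'
#' Assigns each interval a single category by its midpoint, with precedence
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic. The promoter
#' window is `promoter_up` bp upstream to `promoter_down` bp downstream of
#' the TSS on the gene strand (HOMER-like defaults). This window is distinct
#' from, and much narrower than, the +/-10 kb loop-anchor promoter window used
#' by [classify_anchors()]. `distance_to_tss` is the signed midpoint distance
#' to the nearest TSS (negative = upstream of the TSS on the gene strand);
#' ties between equidistant TSSs resolve to the lexicographically smaller
#' `gene_id`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param genes Gene models from [read_gtf()].
#' @param promoter_up,promoter_down Promoter window around the TSS, bp.
#' @return The input with `category`, `gene_id` and `distance_to_tss` columns
#'   appended.
#' @export
annotate_intervals <- function(intervals, genes, promoter_up = 1000,
                               promoter_down = 100) {
  assert_intervals(intervals)
  n <- nrow(intervals)
  mid <- floor((intervals$start + intervals$end) / 2)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (is.null(genes) || nrow(genes) == 0) {
    return(dplyr::mutate(as_tibble(intervals), category = category,
                         gene_id = gene_id, distance_to_tss = dist))
  }

  pts <- tibble(chrom = intervals$chrom, start = mid, end = mid + 1)

  # nearest TSS (signed on gene strand); ties -> smaller gene_id
  for (ch in unique(pts$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    sel <- which(pts$chrom == ch)
    g <- genes[gi, ]
    for (i in sel) {
      d_raw <- mid[i] - g$tss
      d_signed <- ifelse(g$strand == "-", -d_raw, d_raw)
      ord <- order(abs(d_signed), g$gene_id)
      gene_id[i] <- g$gene_id[ord[1]]
      dist[i] <- d_signed[ord[1]]
    }
  }

  hit_category <- function(feat_tbl) {
    # feat_tbl: chrom/start/end/gene_id; midpoint-in-feature overlaps
    if (nrow(feat_tbl) == 0) return(NULL)
    overlap_pairs(pts, feat_tbl)
  }

  # promoter windows on the gene strand
  prom <- genes |>
    dplyr::transmute(
      .data$chrom, .data$gene_id, .data$tss, .data$strand,
      start = pmax(0, ifelse(.data$strand == "-", .data$tss - promoter_down,
                             .data$tss - promoter_up)),
      end = ifelse(.data$strand == "-", .data$tss + promoter_up + 1,
                   .data$tss + promoter_down + 1)
    )
  unnest_feat <- function(col) {
    genes |>
      dplyr::select("chrom", "gene_id", dplyr::all_of(col)) |>
      tidyr::unnest(dplyr::all_of(col))
  }
  exon_tbl <- unnest_feat("exons")
  u5_tbl <- unnest_feat("utr5")
  u3_tbl <- unnest_feat("utr3")
  body_tbl <- genes |> dplyr::select("chrom", "gene_id", "start", "end")

  assign_cat <- function(feat_tbl, label) {
    ov <- hit_category(feat_tbl)
    if (is.null(ov) || nrow(ov) == 0) return(invisible(NULL))
    open <- category == "intergenic"
    keep <- ov[open[ov$query], , drop = FALSE]
    if (nrow(keep) == 0) return(invisible(NULL))
    # midpoint may fall in several genes' features: nearest TSS wins, then id
    for (q in unique(keep$query)) {
      cand <- feat_tbl$gene_id[keep$subject[keep$query == q]]
      g <- genes[match(cand, genes$gene_id), ]
      d_raw <- mid[q] - g$tss
      d_signed <- ifelse(g$strand == "-", -d_raw, d_raw)
      ord <- order(abs(d_signed), g$gene_id)
      category[q] <<- label
      gene_id[q] <<- g$gene_id[ord[1]]
      dist[q] <<- d_signed[ord[1]]
    }
    invisible(NULL)
  }

  assign_cat(prom, "promoter")
  assign_cat(u5_tbl, "utr5")
  assign_cat(u3_tbl, "utr3")
  assign_cat(exon_tbl, "exon")
  assign_cat(body_tbl, "intron")

  dplyr::mutate(as_tibble(intervals), category = category, gene_id = gene_id,
                distance_to_tss = dist)
}

#' Write annotated intervals as BED6
#'
#' name = category, score = distance to TSS (0 when undefined).
#'
#' @param annotated Output of [annotate_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotated, path) {
  df <- annotated
  df$name <- df$category
  df$score <- ifelse(is.na(df$distance_to_tss), 0, df$distance_to_tss)
  df$strand <- "."
  write_bed(df, path)
}
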