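# Independent brute-force oracles used across the suite. These deliberately
# take naive paths (per-window loops, double loops, per-base classification)
# so they share no code with the implementations they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-window PWM rescoring: returns data.frame(start, strand, score)
naive_scan_oracle <- function(seq, motif, threshold = 0.8) {
  lom <- pwm_log_odds(motif)
  L <- nrow(lom)
  mx <- pwm_max_score(motif)
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(code)
  out <- list()
  for (i in seq_len(max(0, n - L + 1))) {
    w <- code[i:(i + L - 1)]
    if (anyNA(w)) next
    fs <- sum(lom[cbind(seq_len(L), w)])
    rs <- sum(lom[cbind(seq_len(L), rev(5L - w))])  # revcomp of the window
    if (fs / mx >= threshold) {
      out[[length(out) + 1]] <- data.frame(start = i - 1, strand = "+",
                                           score = fs)
    }
    if (rs / mx >= threshold) {
      out[[length(out) + 1]] <- data.frame(start = i - 1, strand = "-",
                                           score = rs)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$strand), , drop = FALSE]
}

# test PWM: sharp 6-mer so only the consensus clears the 0.8 threshold
test_pwm <- function(consensus = "ACGTCA") {
  L <- nchar(consensus)
  m <- matrix(2, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(strsplit(consensus, "")[[1]], colnames(m))
  m[cbind(seq_len(L), idx)] <- 94
  pwm(m, name = "test")
}

# direct per-base midpoint classifier used against annotate_intervals()
annotate_oracle_one <- function(chrom, mid, genes, up = 1000, down = 100) {
  cand <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) return("intergenic")
  in_prom <- vapply(seq_len(nrow(cand)), function(i) {
    g <- cand[i, ]
    if (g$strand == "-") mid >= g$tss - down && mid <= g$tss + up
    else mid >= g$tss - up && mid <= g$tss + down
  }, logical(1))
  if (any(in_prom)) return("promoter")
  in_feat <- function(col) {
    any(vapply(seq_len(nrow(cand)), function(i) {
      f <- cand[[col]][[i]]
      nrow(f) > 0 && any(mid >= f$start & mid < f$end)
    }, logical(1)))
  }
  if (in_feat("utr5")) return("utr5")
  if (in_feat("utr3")) return("utr3")
  if (in_feat("exons")) return("exon")
  if (any(mid >= cand$start & mid < cand$end)) return("intron")
  "intergenic"
}

# union-find over the "gap <= threshold" graph, the stitching oracle
stitch_oracle <- function(peaks, gap) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
      g <- max(peaks$start[i], peaks$start[j]) -
        min(peaks$end[i], peaks$end[j])
      if (g <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  d <- do.call(rbind, lapply(comp, function(ii) {
    data.frame(chrom = peaks$chrom[ii[1]], start = min(peaks$start[ii]),
               end = max(peaks$end[ii]), n_peaks = length(ii))
  }))
  d[order(d$chrom, d$start), , drop = FALSE]
}

# geometric elbow: the ranked point with maximum distance below the diagonal
elbow_distance_oracle <- function(signal) {
  v <- sort(signal)
  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - min(v)) / (max(v) - min(v))
  which.min(y - x)  # ascending rank of the elbow point
}

# small deterministic gene-model table without touching GTF I/O
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    symbol = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    start = c(10000, 50000),
    end = c(20000, 60000),
    exons = list(tibble::tibble(start = c(10000, 15000),
                                end = c(12000, 20000)),
                 tibble::tibble(start = c(50000, 56000),
                                end = c(54000, 60000))),
    utr5 = list(tibble::tibble(start = 10000, end = 10200),
                tibble::tibble(start = numeric(), end = numeric())),
    utr3 = list(tibble::tibble(start = numeric(), end = numeric()),
                tibble::tibble(start = 50000, end = 50200)),
    tss = c(10000, 59999)
  )
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_len = 2e6, n_genes = 50,
             n_loops = 300, n_planted_ep_genes = 10, n_motif_regions = 80,
             n_subtypes = 6, samples_per_subtype = 5, n_specific_genes = 8,
             n_cells = 80, n_expr_genes = 300, module_size = 20, ...)
}
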