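#' Configuration for the synthetic regulome generator
#'
#' Defaults echo the scale of a motif-anchored HiChIP study: 5-kb loop bins,
#' a 0.01 loop FDR split, three chromatin archetypes, 24 expression subtypes
#' with a 22-gene specific set. See the methods vignette for the rationale of
#' each default.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_chroms,chrom_len Genome shape (chromosomes x bp).
#' @param n_genes Genes placed uniformly without overlap.
#' @param bin_size Loop anchor width, bp.
#' @param n_loops Total loops (planted + background).
#' @param n_planted_ep_genes Genes given planted I-P loops; the first is the
#'   designated top gene (lowest q, highest contacts).
#' @param loops_per_gene Range of planted loops per gene.
#' @param frac_both_anchor_motif Fraction of planted pairs that also carry a
#'   motif at the promoter anchor.
#' @param archetype_fractions Mixing fractions of the three chromatin
#'   archetypes over motif regions.
#' @param n_motif_regions Total motif-centered regions (standalone + planted
#'   anchors).
#' @param noise_sd Relative (log-normal sigma) noise on track amplitudes.
#' @param de_alpha Adjusted-p threshold the DE table is planted around.
#' @param n_subtypes,samples_per_subtype,n_specific_genes Subtype expression
#'   matrix shape and planted specific set size.
#' @param n_cells,n_expr_genes Cell x gene matrix shape.
#' @param module_size,module_delta Planted module size and its expression
#'   shift in the labelled cell subset.
#' @param hard_mode When `TRUE`, background loop q-values overlap the
#'   significance threshold (power studies); when `FALSE` (default), the
#'   planted/background split is exact at q = 0.01.
#' @return A `sim_config` list, validated for feasibility.
#' @export
sim_config <- function(seed = 0, n_chroms = 3, chrom_len = 5e6, n_genes = 200,
                       bin_size = 5000, n_loops = 2000,
                       n_planted_ep_genes = 30, loops_per_gene = c(1, 3),
                       frac_both_anchor_motif = 0.01,
                       archetype_fractions = c(0.5, 0.3, 0.2),
                       n_motif_regions = 300, noise_sd = 0.1,
                       de_alpha = 0.05, n_subtypes = 24,
                       samples_per_subtype = 8, n_specific_genes = 22,
                       n_cells = 500, n_expr_genes = 1000,
                       module_size = 30, module_delta = 1,
                       hard_mode = FALSE) {
  cfg <- as.list(environment())
  stopifnot(n_chroms >= 1, chrom_len >= 2e5, n_genes >= 10, bin_size >= 100,
            n_loops >= 1, n_planted_ep_genes >= 1,
            frac_both_anchor_motif >= 0, frac_both_anchor_motif <= 1,
            length(archetype_fractions) == 3,
            abs(sum(archetype_fractions) - 1) < 1e-8,
            de_alpha > 0, de_alpha < 1, n_subtypes >= 2,
            n_specific_genes >= 1, n_cells >= 2, module_size >= 1)
  if (n_planted_ep_genes > n_genes) {
    stop("more planted E-P genes than genes", call. = FALSE)
  }
  if (n_specific_genes > n_genes) {
    stop("more specific genes than genes", call. = FALSE)
  }
  if (module_size > n_expr_genes) {
    stop("module larger than the expression gene universe", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' The generator's motif: a sharp HLF-like 8-mer
#'
#' A synthetic consensus matrix around the PAR-bZIP-like core TTACGCAA. It is
#' deliberately sharp: at the default pseudocount only exact consensus
#' matches reach relative score 0.8, which makes planted motif truth exact.
#' It is NOT a claim about the biological motif.
#'
#' @return A [pwm()].
#' @export
hlf_like_pwm <- function() {
  consensus <- "TTACGCAA"
  L <- nchar(consensus)
  m <- matrix(3, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(strsplit(consensus, "")[[1]], colnames(m))
  m[cbind(seq_len(L), idx)] <- 91
  pwm(m, name = "HLF_like_synthetic")
}

# Replace every occurrence of a k-mer (and its reverse complement) in a
# sequence by mutating its middle base, iterating until none remain.
scrub_kmer <- function(seq, kmer) {
  targets <- unique(c(kmer, revcomp(kmer)))
  k <- nchar(kmer)
  repeat {
    found <- FALSE
    for (t in targets) {
      pos <- gregexpr(t, seq, fixed = TRUE)[[1]]
      if (pos[1] != -1) {
        found <- TRUE
        mid <- pos + (k %/% 2)
        cur <- substring(seq, mid, mid)
        repl <- vapply(cur, function(b) {
          setdiff(c("A", "C", "G", "T"), b)[1]
        }, character(1))
        for (i in seq_along(mid)) {
          substr(seq, mid[i], mid[i]) <- repl[i]
        }
      }
    }
    if (!found) return(seq)
  }
}

insert_kmer <- function(seq, kmer, pos0) {
  # write kmer at 0-based position pos0
  substr(seq, pos0 + 1, pos0 + nchar(kmer)) <- kmer
  seq
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# archetype amplitude table (rows: archetype; cols: tracks). Archetype 1:
# active (high H3K27ac/H3K4me1/accessibility); 2: primed (H3K4me1-high,
# H3K27ac-low); 3: repressed-yet-accessible (H3K27me3-high, elevated ATAC,
# strong factor occupancy).
archetype_amplitudes <- function() {
  tracks <- c("TCF3HLF", "H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3", "ATAC")
  m <- rbind(
    c(8, 10, 8, 4, 0.5, 8),
    c(5, 2, 9, 1, 1.0, 4),
    c(9, 0.5, 1, 0.5, 8, 6)
  )
  colnames(m) <- tracks
  m
}

#' Generate a synthetic regulome dataset with planted ground truth
#'
#' Writes every input the pipeline consumes - genome FASTA with planted motif
#' instances (all chance consensus occurrences scrubbed first, so motif truth
#' is exact), GTF gene models, factor narrowPeak, loops BEDPE with planted
#' I-P structure over a distance-decaying background, six bedGraph chromatin
#' tracks realising three archetypes, a DE table with planted directions, a
#' subtype expression matrix with planted specific genes, a cell x gene
#' matrix with a shifted planted module, a GMT of planted sets, a TF list and
#' the motif itself - plus a `ground_truth.json` describing what was planted.
#' Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return The ground-truth list, invisibly; `$files` maps logical names to
#'   paths.
#' @export
simulate_regulome <- function(config = sim_config(), outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  motif <- hlf_like_pwm()
  consensus <- pwm_consensus(motif)
  L <- nchar(consensus)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))

  ## genome ------------------------------------------------------------------
  genome <- withr::with_seed(stage_seed(config$seed, "genome"), {
    g <- vapply(chroms, function(ch) rand_dna(config$chrom_len), character(1))
    vapply(g, scrub_kmer, character(1), kmer = consensus)
  })
  names(genome) <- chroms

  ## genes -------------------------------------------------------------------
  genes <- withr::with_seed(stage_seed(config$seed, "genes"), {
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chroms + 1)))
    margin <- 60000
    rows <- list()
    gi <- 0
    for (ci in seq_along(chroms)) {
      taken <- matrix(numeric(0), ncol = 2)
      placed <- 0
      while (placed < per_chrom[ci]) {
        len <- round(stats::runif(1, 4000, 20000))
        s <- round(stats::runif(1, margin, config$chrom_len - margin - len))
        if (nrow(taken) &&
            any(s < taken[, 2] + 1000 & s + len > taken[, 1] - 1000)) next
        taken <- rbind(taken, c(s, s + len))
        placed <- placed + 1
        gi <- gi + 1
        n_ex <- sample(2:4, 1)
        cuts <- sort(sample(seq(200, len - 200, by = 50), 2 * (n_ex - 1)))
        bounds <- c(0, cuts, len)
        ex <- tibble(start = s + bounds[seq(1, length(bounds), by = 2)],
                     end = s + bounds[seq(2, length(bounds), by = 2)])
        rows[[gi]] <- tibble(
          gene_id = sprintf("G%03d", gi), symbol = sprintf("G%03d", gi),
          chrom = chroms[ci], strand = sample(c("+", "-"), 1),
          start = s, end = s + len, exons = list(ex),
          utr5 = list(tibble(start = numeric(), end = numeric())),
          utr3 = list(tibble(start = numeric(), end = numeric()))
        )
      }
    }
    d <- dplyr::bind_rows(rows)
    d$tss <- ifelse(d$strand == "-", d$end - 1, d$start)
    dplyr::arrange(d, .data$chrom, .data$start)
  })

  ## planted loops + motif placement ----------------------------------------
  bin <- config$bin_size
  bin_of <- function(x) floor(x / bin) * bin
  tss_windows <- tibble(chrom = genes$chrom,
                        start = pmax(0, genes$tss - 10000),
                        end = genes$tss + 10001)
  loopres <- withr::with_seed(stage_seed(config$seed, "loops"), {
    # planted genes need an isolated TSS so recovered gene sets are exact
    iso <- vapply(seq_len(nrow(genes)), function(i) {
      same <- genes$chrom == genes$chrom[i]
      sum(same & abs(genes$tss - genes$tss[i]) < 25000) == 1
    }, logical(1))
    cand <- which(iso)
    if (length(cand) < config$n_planted_ep_genes) {
      stop("not enough isolated genes to plant", call. = FALSE)
    }
    planted_idx <- sample(cand, config$n_planted_ep_genes)
    top_gene <- genes$gene_id[planted_idx[1]]

    motif_positions <- list()   # chrom, pos (0-based insertion start)
    planted_loops <- list()
    anchor_used <- character(0)
    k <- 0
    for (j in seq_along(planted_idx)) {
      g <- genes[planted_idx[j], ]
      p_bin <- bin_of(g$tss)
      n_lp <- sample(seq(config$loops_per_gene[1], config$loops_per_gene[2]), 1)
      tries <- 0
      placed <- 0
      while (placed < n_lp && tries < 500) {
        tries <- tries + 1
        d_bins <- sample(seq(50000 / bin, min(3e6, config$chrom_len / 2) / bin), 1)
        side <- sample(c(-1, 1), 1)
        i_bin <- p_bin + side * d_bins * bin
        if (i_bin < 0 || i_bin + bin > config$chrom_len) next
        key <- paste(g$chrom, i_bin)
        if (key %in% anchor_used) next
        # motif anchor must not touch any promoter window
        iv <- tibble(chrom = g$chrom, start = i_bin, end = i_bin + bin)
        if (nrow(overlap_pairs(iv, tss_windows)) > 0) next
        anchor_used <- c(anchor_used, key)
        placed <- placed + 1
        k <- k + 1
        mpos <- i_bin + bin %/% 2
        motif_positions[[k]] <- tibble(chrom = g$chrom, pos = mpos,
                                       anchor_start = i_bin,
                                       gene_id = g$gene_id)
        is_top <- g$gene_id == top_gene
        planted_loops[[k]] <- tibble(
          chrom1 = g$chrom, start1 = i_bin, end1 = i_bin + bin,
          chrom2 = g$chrom, start2 = p_bin, end2 = p_bin + bin,
          contact_count = stats::rpois(1, if (is_top) 40 else 15) + 1,
          q_value = if (is_top) 1e-8 * stats::runif(1, 0.5, 1)
                    else 10^stats::runif(1, -6, -3),
          gene_id = g$gene_id
        )
      }
    }
    planted <- dplyr::bind_rows(planted_loops)
    motif_pos <- dplyr::bind_rows(motif_positions)

    # both-anchor-motif planting: also drop a consensus into the P anchor.
    # Restricted to genes with a single planted loop - pairs of one gene share
    # its promoter anchor, so planting there marks all of them at once.
    n_both <- round(config$frac_both_anchor_motif * nrow(planted))
    single <- which(planted$gene_id %in%
                      names(which(table(planted$gene_id) == 1)))
    n_both <- min(n_both, length(single))
    both_idx <- if (n_both > 0) sample(single, n_both) else integer(0)
    both_pos <- purrr::map_dfr(both_idx, function(i) {
      pg <- genes[match(planted$gene_id[i], genes$gene_id), ]
      # inside the promoter bin but clear of the TSS itself
      cand <- planted$start2[i] + c(500, bin - 500 - L)
      pos <- cand[which.max(abs(cand - pg$tss))]
      tibble(chrom = planted$chrom2[i], pos = pos, anchor_start = planted$start2[i],
             gene_id = planted$gene_id[i])
    })

    # background loops: q above threshold (easy mode) or overlapping (hard)
    n_bg <- config$n_loops - nrow(planted)
    bg <- purrr::map_dfr(seq_len(n_bg), function(i) {
      ch <- sample(chroms, 1)
      d_bins <- round(stats::rexp(1, rate = bin / 2e5)) + 50000 / bin
      d_bp <- min(d_bins * bin, 3e6, config$chrom_len - 2 * bin)
      s1 <- bin_of(stats::runif(1, 0, config$chrom_len - d_bp - bin))
      tibble(chrom1 = ch, start1 = s1, end1 = s1 + bin,
             chrom2 = ch, start2 = s1 + d_bp, end2 = s1 + d_bp + bin,
             contact_count = stats::rpois(1, max(1, 15 * 50000 / d_bp)) + 1,
             q_value = if (config$hard_mode) 10^stats::runif(1, -4, 0)
                       else stats::runif(1, 0.0101, 1),
             gene_id = NA_character_)
    })
    list(planted = planted, background = bg, motif_pos = motif_pos,
         both_pos = both_pos, top_gene = top_gene,
         planted_gene_ids = genes$gene_id[planted_idx])
  })

  loops <- dplyr::bind_rows(
    loopres$planted[, 1:8],
    loopres$background[, 1:8]
  )
  loops <- canonicalize_loops(loops)

  ## standalone motif regions + archetypes ----------------------------------
  chrstate <- withr::with_seed(stage_seed(config$seed, "chromatin"), {
    planted_centers <- dplyr::bind_rows(loopres$motif_pos, loopres$both_pos)
    n_extra <- max(0, config$n_motif_regions - nrow(planted_centers))
    # standalone motif regions stay clear of planted promoter-anchor bins so
    # the both-anchor-motif fraction remains exactly as planted
    p_bins <- unique(paste(loopres$planted$chrom2, loopres$planted$start2))
    extra <- purrr::map_dfr(seq_len(n_extra), function(i) {
      repeat {
        ch <- sample(chroms, 1)
        pos <- round(stats::runif(1, 3000, config$chrom_len - 3000))
        if (!paste(ch, bin_of(pos)) %in% p_bins &&
            !paste(ch, bin_of(pos + L)) %in% p_bins) {
          return(tibble(chrom = ch, pos = pos, anchor_start = NA_real_,
                        gene_id = NA_character_))
        }
      }
    })
    centers <- dplyr::bind_rows(planted_centers, extra)
    arch <- sample(1:3, nrow(centers), replace = TRUE,
                   prob = config$archetype_fractions)
    centers$archetype <- arch
    centers
  })

  # insert planted motif instances into the genome
  for (i in seq_len(nrow(chrstate))) {
    ch <- chrstate$chrom[i]
    genome[[ch]] <- insert_kmer(genome[[ch]], consensus, chrstate$pos[i])
  }

  ## chromatin tracks --------------------------------------------------------
  amp <- archetype_amplitudes()
  track_names <- colnames(amp)
  bw <- 50
  half <- 2500
  tracks <- withr::with_seed(stage_seed(config$seed, "tracks"), {
    nb <- 2 * half / bw
    offsets <- seq(-half, half - bw, by = bw) + bw / 2
    shape <- exp(-(offsets^2) / (2 * 400^2))
    latent <- stats::runif(nrow(chrstate), -1, 1)  # archetype-2 see-saw
    out <- lapply(track_names, function(tk) {
      rows <- vector("list", nrow(chrstate))
      for (i in seq_len(nrow(chrstate))) {
        a <- chrstate$archetype[i]
        base_amp <- amp[a, tk]
        if (a == 2) {
          if (tk == "ATAC") base_amp <- base_amp * (1 - 0.3 * latent[i])
          if (tk == "TCF3HLF") base_amp <- base_amp * (1 + 0.3 * latent[i])
        }
        noise <- stats::rlnorm(nb, 0, config$noise_sd)
        vals <- pmax(0, base_amp * (0.15 + shape) * noise)
        s <- chrstate$pos[i] + L %/% 2 - half
        rows[[i]] <- tibble(chrom = chrstate$chrom[i],
                            start = s + seq(0, by = bw, length.out = nb),
                            end = s + seq(bw, by = bw, length.out = nb),
                            value = round(vals, 4))
      }
      d <- dplyr::bind_rows(rows)
      # drop rare overlapping windows (two centers < 5 kb apart): keep first
      d <- dplyr::arrange(d, .data$chrom, .data$start)
      keep <- unlist(lapply(split(seq_len(nrow(d)), d$chrom), function(ii) {
        e <- d$end[ii]; s <- d$start[ii]
        ii[c(TRUE, s[-1] >= cummax(e[-length(e)]))]
      }))
      d[sort(keep), , drop = FALSE]
    })
    names(out) <- track_names
    # super-enhancer structure on H3K27ac: boost the top gene's anchors and
    # a few archetype-1 standalones far above the typical range
    se_centers <- which(chrstate$gene_id %in% loopres$top_gene)
    extra_se <- utils::head(which(chrstate$archetype == 1 &
                                    is.na(chrstate$gene_id)), 4)
    boost <- union(se_centers, extra_se)
    k27 <- out$H3K27ac
    for (i in boost) {
      sel <- k27$chrom == chrstate$chrom[i] &
        k27$start >= chrstate$pos[i] - half & k27$end <= chrstate$pos[i] + half
      k27$value[sel] <- k27$value[sel] * 50
    }
    out$H3K27ac <- k27
    attr(out, "se_centers") <- boost
    out
  })

  ## peak files --------------------------------------------------------------
  tf_peaks <- tibble(chrom = chrstate$chrom,
                     start = pmax(0, chrstate$pos - 250),
                     end = chrstate$pos + 250 + L)
  k27_centers <- chrstate[chrstate$archetype %in% c(1, 2), , drop = FALSE]
  k27_peaks <- tibble(chrom = k27_centers$chrom,
                      start = pmax(0, k27_centers$pos - 500),
                      end = k27_centers$pos + 500 + L)

  ## DE table ----------------------------------------------------------------
  de <- withr::with_seed(stage_seed(config$seed, "de"), {
    planted_ids <- loopres$planted_gene_ids
    gene_arch <- chrstate |>
      dplyr::filter(!is.na(.data$gene_id)) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(cluster = {
        tab <- table(.data$archetype)
        as.integer(names(tab)[tab == max(tab)][1])
      }, .groups = "drop")
    dir_of <- vapply(planted_ids, function(g) {
      cl <- gene_arch$cluster[match(g, gene_arch$gene_id)]
      p_down <- if (!is.na(cl) && cl == 1) 0.7 else 0.5
      if (g == loopres$top_gene) "down"
      else sample(c("down", "up"), 1, prob = c(p_down, 1 - p_down))
    }, character(1))
    d <- tibble(gene_id = genes$gene_id)
    planted <- d$gene_id %in% planted_ids
    d$adj_p <- stats::runif(nrow(d), 0.06, 1)
    d$adj_p[planted] <- 10^stats::runif(sum(planted), -8, -2)
    d$adj_p[d$gene_id == loopres$top_gene] <- 1e-9
    d$log2fc <- stats::rnorm(nrow(d), 0, 0.3)
    sgn <- ifelse(dir_of[d$gene_id[planted]] == "up", 1, -1)
    d$log2fc[planted] <- sgn * stats::runif(sum(planted), 1, 3)
    attr(d, "directions") <- dir_of
    attr(d, "gene_clusters") <- gene_arch
    d
  })

  ## subtype expression matrix -----------------------------------------------
  subty <- withr::with_seed(stage_seed(config$seed, "subtypes"), {
    subtypes <- c("TCF3HLF", sprintf("subtype%02d", seq_len(config$n_subtypes - 1)))
    samples <- paste0(rep(subtypes, each = config$samples_per_subtype), "_",
                      seq_len(config$samples_per_subtype))
    lab <- rep(subtypes, each = config$samples_per_subtype)
    specific <- sample(genes$gene_id, config$n_specific_genes)
    mu <- stats::runif(nrow(genes), 1, 4)
    m <- matrix(stats::rlnorm(nrow(genes) * length(samples),
                              meanlog = rep(mu, length(samples)),
                              sdlog = 0.25),
                nrow = nrow(genes), dimnames = list(genes$gene_id, samples))
    tgt <- lab == "TCF3HLF"
    # deterministic planting: specific genes exactly 3.5x the max other
    # subtype median; everything else capped safely below the 3x rule
    for (g in genes$gene_id) {
      med_other <- vapply(subtypes[-1], function(s) {
        stats::median(m[g, lab == s])
      }, numeric(1))
      mo <- max(med_other)
      mt <- stats::median(m[g, tgt])
      target <- if (g %in% specific) 3.5 * mo else min(mt, 2.5 * mo)
      m[g, tgt] <- m[g, tgt] * (target / mt)
    }
    list(expr = m, labels = tibble(sample = samples, subtype = lab),
         specific = sort(specific))
  })

  ## cell x gene matrix with planted module ----------------------------------
  cells <- withr::with_seed(stage_seed(config$seed, "cells"), {
    gene_names <- sprintf("SG%04d", seq_len(config$n_expr_genes))
    cell_names <- sprintf("cell%03d", seq_len(config$n_cells))
    mu <- stats::runif(config$n_expr_genes, 0.5, 3)
    m <- matrix(stats::rnorm(config$n_expr_genes * config$n_cells,
                             mean = rep(mu, config$n_cells), sd = 0.5),
                nrow = config$n_expr_genes,
                dimnames = list(gene_names, cell_names))
    # plant the module among mid-range baseline genes: after the shift its
    # genes remain inside the bulk expression range, so bin-matched controls
    # stay representative of the background rather than of the module itself
    module <- sample(gene_names[mu <= 2], config$module_size)
    shifted <- sample(cell_names, config$n_cells %/% 2)
    m[module, shifted] <- m[module, shifted] + config$module_delta
    list(expr = round(m, 4), module = sort(module), shifted = sort(shifted))
  })

  ## TF list -----------------------------------------------------------------
  tf_list <- withr::with_seed(stage_seed(config$seed, "tf"), {
    n_tf_planted <- min(10, length(loopres$planted_gene_ids))
    sort(unique(c(sample(loopres$planted_gene_ids, n_tf_planted),
                  sample(genes$gene_id, 30))))
  })

  ## write everything --------------------------------------------------------
  files <- c(
    genome = p("genome.fa"), gtf = p("genes.gtf"),
    loops = p("loops.bedpe"), tf_peaks = p("tf_peaks.narrowPeak"),
    k27_peaks = p("h3k27ac_peaks.narrowPeak"),
    de = p("de_table.tsv"), motif = p("motif.jaspar"),
    subtype_expr = p("subtype_expression.tsv"),
    subtype_labels = p("subtype_labels.tsv"),
    cell_expr = p("cell_expression.tsv"),
    cell_labels = p("cell_labels.tsv"),
    gene_sets = p("gene_sets.gmt"), tf_list = p("tf_list.txt"),
    ground_truth = p("ground_truth.json")
  )
  track_files <- stats::setNames(p(paste0(track_names, ".bedgraph")),
                                 track_names)

  write_fasta(genome, files[["genome"]])
  write_gtf(genes, files[["gtf"]])
  write_bedpe(loops, files[["loops"]])
  write_narrowpeak(tf_peaks, files[["tf_peaks"]])
  write_narrowpeak(k27_peaks, files[["k27_peaks"]])
  for (tk in track_names) write_bedgraph(tracks[[tk]], track_files[[tk]])
  readr::write_tsv(de[, c("gene_id", "log2fc", "adj_p")], files[["de"]],
                   progress = FALSE)
  write_jaspar(motif, files[["motif"]])
  expr_out <- dplyr::bind_cols(tibble(gene_id = rownames(subty$expr)),
                               as_tibble(round(subty$expr, 4)))
  readr::write_tsv(expr_out, files[["subtype_expr"]], progress = FALSE)
  readr::write_tsv(subty$labels, files[["subtype_labels"]], progress = FALSE)
  cell_out <- dplyr::bind_cols(tibble(gene_id = rownames(cells$expr)),
                               as_tibble(cells$expr))
  readr::write_tsv(cell_out, files[["cell_expr"]], progress = FALSE)
  readr::write_tsv(tibble(cell = colnames(cells$expr),
                          shifted = colnames(cells$expr) %in% cells$shifted),
                   files[["cell_labels"]], progress = FALSE)
  write_gmt(list(planted_module = cells$module,
                 planted_specific = subty$specific,
                 planted_ep_genes = sort(loopres$planted_gene_ids)),
            files[["gene_sets"]])
  writeLines(tf_list, files[["tf_list"]])

  truth <- list(
    seed = config$seed,
    top_gene = loopres$top_gene,
    planted_genes = tibble(
      gene_id = loopres$planted_gene_ids,
      direction = unname(attr(de, "directions")[loopres$planted_gene_ids])
    ),
    planted_pairs = loopres$planted,
    motif_regions = chrstate,
    both_anchor_positions = loopres$both_pos,
    gene_clusters = attr(de, "gene_clusters"),
    specific_genes = subty$specific,
    module_genes = cells$module,
    shifted_cells = cells$shifted,
    tf_list = tf_list,
    se_center_idx = attr(tracks, "se_centers"),
    track_files = as.list(track_files),
    files = as.list(files)
  )
  # serialize with paths relative to outdir so identical seeds give
  # byte-identical trees regardless of where they are written
  truth_json <- truth
  truth_json$files <- lapply(truth$files, basename)
  truth_json$track_files <- lapply(truth$track_files, basename)
  jsonlite::write_json(truth_json, files[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Simulate a motif-centered signal matrix with planted archetype labels
#'
#' A lightweight companion to [simulate_regulome()] for clustering studies:
#' regions are drawn from the three chromatin archetypes and per-bin signal
#' generated directly (no genome or files involved).
#'
#' @param n_regions Number of regions.
#' @param noise_sd Log-normal sigma of the multiplicative noise.
#' @param archetype_fractions Mixing fractions.
#' @param seed RNG seed.
#' @param span,bin_width Window geometry, bp.
#' @return List with `matrix` (a `signal_matrix`) and `labels` (planted
#'   archetypes).
#' @export
simulate_archetype_matrix <- function(n_regions = 300, noise_sd = 0.1,
                                      archetype_fractions = c(0.5, 0.3, 0.2),
                                      seed = 0, span = 2000, bin_width = 50) {
  amp <- archetype_amplitudes()
  nb <- as.integer(2 * span / bin_width)
  offsets <- seq(-span, span - bin_width, by = bin_width) + bin_width / 2
  shape <- exp(-(offsets^2) / (2 * 400^2))
  withr::with_seed(seed, {
    labels <- sample(1:3, n_regions, replace = TRUE,
                     prob = archetype_fractions)
    mats <- lapply(colnames(amp), function(tk) {
      t(vapply(seq_len(n_regions), function(i) {
        amp[labels[i], tk] * (0.15 + shape) *
          stats::rlnorm(nb, 0, noise_sd)
      }, numeric(nb)))
    })
    names(mats) <- colnames(amp)
    regions <- tibble(chrom = "sim", start = seq_len(n_regions) * 10000,
                      end = seq_len(n_regions) * 10000 + 1,
                      strand = "+",
                      center = seq_len(n_regions) * 10000, edge = FALSE)
    sm <- structure(list(regions = regions, tracks = mats, span = span,
                         bin_width = bin_width),
                    class = "signal_matrix")
    list(matrix = sm, labels = labels)
  })
}
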