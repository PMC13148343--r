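# compact constructor for anchor/loop fixtures on one chromosome
mk_anchors <- function(starts, bin = 5000) {
  tibble::tibble(chrom = "chr1", start = starts, end = starts + bin)
}

mk_flags <- function(anchors, with_motif) {
  anchors$has_motif <- seq_len(nrow(anchors)) %in% with_motif
  anchors
}

test_that("anchor classification applies promoter precedence", {
  genes <- toy_genes()  # TSSs at 10000 (+) and 59999 (-)
  anchors <- mk_anchors(c(10000, 100000, 200000, 300000))
  flags <- mk_flags(anchors, with_motif = c(1, 2, 3))
  tf_peaks <- mk_anchors(c(10000, 100000, 300000))
  cls <- classify_anchors(anchors, genes, flags, tf_peaks)
  # promoter-overlapping anchor with motif is P, keeping its motif flag
  expect_equal(cls$klass, c("P", "I_HLF", "other", "I_plain"))
  expect_true(cls$has_motif[1])
  expect_equal(cls$promoter_genes[[1]], "gA")
  # every anchor receives exactly one class
  expect_false(anyNA(cls$klass))
})

test_that("anchor classes match an exhaustive per-anchor oracle", {
  genes <- toy_genes()
  withr::local_seed(53)
  anchors <- mk_anchors(sort(sample(seq(0, 490000, by = 5000), 60)))
  flags <- mk_flags(anchors, with_motif = sample(60, 25))
  tf_peaks <- mk_anchors(anchors$start[sample(60, 40)])
  cls <- classify_anchors(anchors, genes, flags, tf_peaks)
  oracle <- vapply(seq_len(60), function(i) {
    a <- anchors[i, ]
    is_p <- any(genes$chrom == a$chrom &
                  a$start < genes$tss + 10001 & a$end > genes$tss - 10000)
    has_m <- flags$has_motif[i]
    has_pk <- any(tf_peaks$start < a$end & tf_peaks$end > a$start)
    if (is_p) "P" else if (has_m && has_pk) "I_HLF"
    else if (has_pk) "I_plain" else "other"
  }, character(1))
  expect_identical(cls$klass, oracle)
})

test_that("pair building keeps exactly the heterotypic I-P loops", {
  genes <- toy_genes()
  anchors <- mk_anchors(c(10000, 55000, 100000, 200000))
  flags <- mk_flags(anchors, with_motif = c(3, 4))
  cls <- classify_anchors(anchors, genes, flags, tf_peaks = NULL)
  expect_equal(cls$klass, c("P", "P", "I_HLF", "I_HLF"))
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(10000, 100000, 10000),
    end1 = c(15000, 105000, 15000),
    chrom2 = "chr1", start2 = c(100000, 200000, 55000),
    end2 = c(105000, 205000, 60000),
    contact_count = c(4, 9, 2), q_value = c(0.001, 0.002, 0.003)
  )
  pairs <- build_ep_pairs(loops, cls)
  # loop 1 is P-I_HLF, loop 2 I_HLF-I_HLF, loop 3 P-P
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$loop_id, 1L)
  expect_equal(pairs$i_start, 100000)
  expect_equal(pairs$p_start, 10000)
  expect_equal(pairs$genes[[1]], "gA")
})

test_that("pair counts equal a double-loop enumeration oracle", {
  withr::local_seed(59)
  n_anchor <- 120
  anchors <- mk_anchors(seq(0, by = 5000, length.out = n_anchor))
  klass <- sample(c("P", "I_HLF", "I_plain", "other"), n_anchor,
                  replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
  cls <- anchors
  cls$klass <- klass
  cls$has_motif <- klass == "I_HLF"
  cls$promoter_genes <- lapply(seq_len(n_anchor), function(i) {
    if (klass[i] == "P") sprintf("g%03d", i) else character(0)
  })
  idx <- matrix(sample(n_anchor, 2000, replace = TRUE), ncol = 2)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = anchors$start[idx[, 1]],
    end1 = anchors$end[idx[, 1]],
    chrom2 = "chr1", start2 = anchors$start[idx[, 2]],
    end2 = anchors$end[idx[, 2]],
    contact_count = sample(1:30, nrow(idx), replace = TRUE),
    q_value = runif(nrow(idx), 0, 0.01)
  )
  pairs <- build_ep_pairs(loops, cls)
  oracle_n <- sum((klass[idx[, 1]] == "P" & klass[idx[, 2]] == "I_HLF") |
                    (klass[idx[, 1]] == "I_HLF" & klass[idx[, 2]] == "P"))
  expect_equal(nrow(pairs), oracle_n)

  # sumCC equals a brute-force double loop over (gene, pair)
  de <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_anchor)),
                       log2fc = 1, adj_p = 0.001)
  tab <- ep_gene_table(pairs, de)
  for (g in tab$gene_id[1:10]) {
    manual <- 0
    for (j in seq_len(nrow(pairs))) {
      if (g %in% pairs$genes[[j]]) manual <- manual + pairs$contact_count[j]
    }
    expect_equal(tab$sumCC[tab$gene_id == g], manual)
  }
})

test_that("both-anchor motif fraction reflects planted flags", {
  pairs <- tibble::tibble(loop_id = 1:500, both_anchors_motif = FALSE)
  expect_equal(both_anchor_motif_fraction(pairs), 0)
  pairs$both_anchors_motif[sample(500, 5)] <- TRUE
  expect_equal(both_anchor_motif_fraction(pairs), 0.01)
  pairs$both_anchors_motif <- TRUE
  expect_equal(both_anchor_motif_fraction(pairs), 1)
  expect_error(both_anchor_motif_fraction(pairs[0, ]), "no pairs")
})

mk_pairs <- function(genes, counts, qs, i_start = NULL) {
  n <- length(genes)
  tibble::tibble(
    loop_id = seq_len(n), chrom = "chr1",
    i_start = i_start %||% (seq_len(n) * 10000),
    i_end = (i_start %||% (seq_len(n) * 10000)) + 5000,
    p_start = 0, p_end = 5000,
    contact_count = counts, q_value = qs,
    genes = lapply(genes, identity), both_anchors_motif = FALSE
  )
}

test_that("the E-P table aggregates, thresholds and sorts deterministically", {
  pairs <- mk_pairs(genes = list("gX", "gX", "gX", "gY", "gZ"),
                    counts = c(4, 7, 9, 100, 5),
                    qs = c(0.003, 0.001, 0.002, 0.005, 0.001))
  de <- tibble::tibble(gene_id = c("gX", "gY"),
                       log2fc = c(-2, 1.5), adj_p = c(0.01, 0.2))
  tab <- ep_gene_table(pairs, de, tf_list = "gX")
  gx <- tab[tab$gene_id == "gX", ]
  expect_equal(gx$sumCC, 20)
  expect_equal(gx$n_pairs, 3L)
  expect_equal(gx$best_q, 0.001)
  expect_equal(gx$de_direction, "down")
  expect_true(gx$is_tf)
  # adj_p above alpha -> ns, excluded from the E-P gene subset
  expect_equal(tab$de_direction[tab$gene_id == "gY"], "ns")
  # absent from DE -> retained as absent
  expect_equal(tab$de_direction[tab$gene_id == "gZ"], "absent")
  expect_identical(sort(ep_genes(tab)$gene_id), "gX")

  # sorted by best_q then descending sumCC then gene_id
  expect_equal(tab$gene_id, c("gX", "gZ", "gY"))

  # permutation invariance of the inputs
  tab2 <- ep_gene_table(pairs[c(3, 5, 1, 4, 2), ], de[2:1, ],
                        tf_list = "gX")
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("tightening alpha never flips ns calls to significant", {
  pairs <- mk_pairs(list("a", "b", "c"), c(1, 2, 3), c(0.1, 0.2, 0.3))
  de <- tibble::tibble(gene_id = c("a", "b", "c"), log2fc = c(1, -1, 2),
                       adj_p = c(0.001, 0.04, 0.2))
  t_wide <- ep_gene_table(pairs, de, alpha = 0.05)
  t_narrow <- ep_gene_table(pairs, de, alpha = 0.01)
  sig_wide <- t_wide$gene_id[t_wide$de_direction %in% c("up", "down")]
  sig_narrow <- t_narrow$gene_id[t_narrow$de_direction %in% c("up", "down")]
  expect_true(all(sig_narrow %in% sig_wide))
})

test_that("enhancer class and chromatin cluster annotate via the I anchor", {
  pairs <- mk_pairs(list("g1", "g1", "g2"), c(1, 1, 1), c(0.001, 0.001, 0.001),
                    i_start = c(10000, 20000, 30000))
  de <- tibble::tibble(gene_id = c("g1", "g2"), log2fc = 1, adj_p = 0.001)
  ecl <- tibble::tibble(chrom = "chr1", start = c(10000, 20000, 30000),
                        end = c(15000, 25000, 35000),
                        enhancer_class = factor(c("TE", "SE", "none"),
                                                c("SE", "TE", "external_only",
                                                  "none")))
  ccl <- tibble::tibble(chrom = "chr1", start = c(10000, 20000, 30000),
                        end = c(15000, 25000, 35000), cluster = c(1L, 2L, 3L))
  tab <- ep_gene_table(pairs, de, anchor_enhancer_class = ecl,
                       anchor_cluster = ccl)
  # highest precedence class among g1's anchors is SE
  expect_equal(as.character(tab$enhancer_class[tab$gene_id == "g1"]), "SE")
  # modal cluster with a 1-1 tie resolves to the lowest number
  expect_equal(tab$chromatin_cluster[tab$gene_id == "g1"], 1L)
  expect_equal(tab$chromatin_cluster[tab$gene_id == "g2"], 3L)
})

test_that("cluster direction breakdown recovers planted fractions", {
  br <- cluster_direction_breakdown(tibble::tibble(
    gene_id = letters[1:4], chromatin_cluster = 1L,
    de_direction = c("up", "up", "down", "down")
  ))
  expect_equal(br$fraction_down, 0.5)

  # planted 70%-down cluster recovered within 3 points at n = 200
  withr::local_seed(61)
  n <- 200
  tab <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), chromatin_cluster = 1L,
    de_direction = sample(c("down", "up"), n, replace = TRUE,
                          prob = c(0.7, 0.3))
  )
  br2 <- cluster_direction_breakdown(tab)
  expect_lt(abs(br2$fraction_down - 0.7), 0.03)

  # genes without a cluster or without significance are excluded
  tab$de_direction[1:50] <- "ns"
  tab$chromatin_cluster[51:60] <- NA
  br3 <- cluster_direction_breakdown(tab)
  expect_equal(br3$n_up + br3$n_down, sum(tab$de_direction != "ns" &
                                            !is.na(tab$chromatin_cluster)))
})

test_that("the TF subset partitions significant TFs by direction", {
  tab <- tibble::tibble(
    gene_id = c("t1", "t2", "t3", "n1"),
    best_q = c(0.003, 0.001, 0.002, 0.004),
    is_tf = c(TRUE, TRUE, TRUE, FALSE),
    de_direction = c("down", "up", "ns", "down")
  )
  ts <- tf_subset(tab)
  expect_equal(ts$down_tfs, "t1")
  expect_equal(ts$up_tfs, "t2")

  # empty TF list -> both empty
  tab$is_tf <- FALSE
  ts0 <- tf_subset(tab)
  expect_length(ts0$down_tfs, 0)
  expect_length(ts0$up_tfs, 0)

  # all genes TFs -> partition equals the direction partition
  tab$is_tf <- TRUE
  ts1 <- tf_subset(tab)
  expect_setequal(c(ts1$down_tfs, ts1$up_tfs),
                  tab$gene_id[tab$de_direction %in% c("up", "down")])
})

test_that("subtype specificity applies the strict per-subtype fold rule", {
  expr <- rbind(
    pass = c(10, 10, 3, 3, 2, 2, 1, 1),
    fail = c(10, 10, 4, 4, 1, 1, 1, 1)
  )
  colnames(expr) <- paste0("s", 1:8)
  labels <- stats::setNames(rep(c("T", "o1", "o2", "o3"), each = 2),
                            colnames(expr))
  res <- subtype_specific_genes(expr, labels, "T", fold = 3)
  expect_true(res$specific[res$gene_id == "pass"])    # 10 >= 3 * 3
  expect_false(res$specific[res$gene_id == "fail"])   # 10 <  3 * 4

  # pooled comparison can rescue genes the strict rule rejects:
  # pooled other median of "fail" is 1, and 10 >= 3 * 1
  pooled <- subtype_specific_genes(expr, labels, "T", fold = 3,
                                   comparison = "pooled")
  expect_true(pooled$specific[pooled$gene_id == "fail"])
  expect_error(subtype_specific_genes(expr, labels, "missing"), "absent")
})

test_that("a planted specific set in a many-subtype matrix is exact", {
  withr::local_seed(67)
  n_genes <- 100
  n_sub <- 24
  per <- 6
  labels <- stats::setNames(
    rep(c("T", sprintf("o%02d", 1:(n_sub - 1))), each = per),
    sprintf("s%03d", seq_len(n_sub * per))
  )
  expr <- matrix(rlnorm(n_genes * length(labels), 2, 0.3),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", 1:n_genes), names(labels)))
  planted <- sample(rownames(expr), 22)
  for (g in planted) {
    mo <- max(vapply(unique(labels[labels != "T"]), function(s) {
      median(expr[g, labels == s])
    }, numeric(1)))
    expr[g, labels == "T"] <- expr[g, labels == "T"] *
      (3.5 * mo / median(expr[g, labels == "T"]))
  }
  res <- subtype_specific_genes(expr, labels, "T", fold = 3)
  expect_setequal(res$gene_id[res$specific], planted)
})

test_that("n_pairs sums to at least the pair count (multi-gene promoters)", {
  pairs <- mk_pairs(list(c("a", "b"), "a", "c"), c(1, 2, 3),
                    c(0.001, 0.002, 0.003))
  de <- tibble::tibble(gene_id = c("a", "b", "c"), log2fc = 1, adj_p = 0.01)
  tab <- ep_gene_table(pairs, de)
  expect_gte(sum(tab$n_pairs), nrow(pairs))
  # single-gene promoters give exact equality
  pairs1 <- mk_pairs(list("a", "b", "c"), c(1, 2, 3), c(0.001, 0.002, 0.003))
  expect_equal(sum(ep_gene_table(pairs1, de)$n_pairs), nrow(pairs1))
})
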