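make_loop_file <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

test_that("BEDPE parsing canonicalises anchors and validates the bin grid", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  make_loop_file(list(
    c("chr1", 0, 5000, "chr1", 100000, 105000, 12, 0.001),
    c("chr1", 200000, 205000, "chr1", 50000, 55000, 3, 0.5)
  ), f)
  loops <- read_bedpe(f)
  expect_equal(nrow(loops), 2)
  expect_true(all(loops$start1 < loops$start2))
  expect_equal(loops$distance[1], 100000)
  expect_true(all(loops$intra))

  # swapped input produces the identical canonical loop
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  make_loop_file(list(
    c("chr1", 100000, 105000, "chr1", 0, 5000, 12, 0.001)
  ), f2)
  expect_equal(read_bedpe(f2)$start1, 0)

  # missing q defaults to 0
  f3 <- withr::local_tempfile(fileext = ".bedpe")
  make_loop_file(list(c("chr1", 0, 5000, "chr1", 100000, 105000, 12)), f3)
  expect_equal(read_bedpe(f3)$q_value, 0)

  # off-grid anchor is a hard error naming the row
  f4 <- withr::local_tempfile(fileext = ".bedpe")
  make_loop_file(list(c("chr1", 0, 4000, "chr1", 100000, 105000, 12, 0.1)), f4)
  expect_error(read_bedpe(f4), "row 1")
})

test_that("a synthetic loop file round-trips byte-identically", {
  withr::local_seed(7)
  n <- 500
  s1 <- sample(0:400, n, replace = TRUE) * 5000
  d <- sample(10:300, n, replace = TRUE) * 5000
  loops <- tibble::tibble(
    chrom1 = sample(c("chr1", "chr2"), n, replace = TRUE),
    start1 = s1, end1 = s1 + 5000,
    chrom2 = "chr1", start2 = s1 + d, end2 = s1 + d + 5000,
    contact_count = sample(1:50, n, replace = TRUE),
    q_value = round(stats::runif(n), 6)
  )
  loops$chrom2 <- loops$chrom1
  f1 <- withr::local_tempfile(fileext = ".bedpe")
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(read_bedpe(make_loop_file(asplit(as.matrix(loops), 1), f1)), f2)
  l2 <- read_bedpe(f2)
  f3 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(l2, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("loop filtering matches exhaustive enumeration on a (q, d) grid", {
  grid <- expand.grid(q = c(0.001, 0.009, 0.01, 0.02, 0.5),
                      d = c(40000, 50000, 100000, 3000000, 3005000))
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = 0, end1 = 5000,
    chrom2 = "chr1", start2 = grid$d, end2 = grid$d + 5000,
    contact_count = 1, q_value = grid$q, intra = TRUE, distance = grid$d
  )
  kept <- filter_loops(loops)
  manual <- loops[loops$q_value <= 0.01 & loops$distance >= 50000 &
                    loops$distance <= 3000000, ]
  expect_equal(nrow(kept), nrow(manual))
  expect_equal(kept$q_value, manual$q_value)

  # boundary cases from the defaults
  expect_equal(nrow(filter_loops(loops[loops$q_value == 0.02, ])), 0)
  expect_equal(nrow(filter_loops(loops[loops$distance == 40000, ])), 0)

  # filters compose commutatively and output is a subset of input
  a <- filter_loops(filter_loops(loops, q_max = 1), d_min = 50000)
  b <- filter_loops(filter_loops(loops, d_min = 50000), q_max = 1)
  expect_identical(a, b)
  expect_true(all(paste(kept$start2, kept$q_value) %in%
                    paste(loops$start2, loops$q_value)))
})

test_that("inter-chromosomal loops are read but dropped by the filter", {
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = 0, end1 = 5000,
    chrom2 = "chr2", start2 = 100000, end2 = 105000,
    contact_count = 5, q_value = 0.001
  )
  loops <- epregulome:::canonicalize_loops(loops)
  expect_false(loops$intra)
  expect_equal(nrow(filter_loops(loops)), 0)
})

test_that("anchors_union equals a set oracle and tags touching loops", {
  # two loops sharing one anchor -> 3 anchors
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(0, 0), end1 = c(5000, 5000),
    chrom2 = "chr1", start2 = c(100000, 200000),
    end2 = c(105000, 205000),
    contact_count = c(1, 2), q_value = 0
  )
  u <- anchors_union(loops)
  expect_equal(nrow(u), 3)
  expect_equal(u$loop_ids[[which(u$start == 0)]], c(1L, 2L))

  expect_equal(nrow(anchors_union(loops[0, ])), 0)

  withr::local_seed(13)
  n <- 1000
  s1 <- sample(0:200, n, replace = TRUE) * 5000
  s2 <- s1 + sample(10:100, n, replace = TRUE) * 5000
  big <- tibble::tibble(chrom1 = sample(c("chr1", "chr2"), n, replace = TRUE),
                        start1 = s1, end1 = s1 + 5000,
                        chrom2 = "x", start2 = s2, end2 = s2 + 5000,
                        contact_count = 1, q_value = 0)
  big$chrom2 <- big$chrom1
  u2 <- anchors_union(big)
  oracle <- unique(c(paste(big$chrom1, big$start1),
                     paste(big$chrom2, big$start2)))
  expect_equal(nrow(u2), length(oracle))
})

test_that("contact matrices round-trip through triplet text", {
  withr::local_seed(3)
  m <- matrix(rpois(400, 3), 20)
  m <- m + t(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(m, f)
  m2 <- read_contact_matrix(f, n_bins = 20, resolution = 100000)
  expect_equal(unname(m2[, ]), unname(m[, ]), ignore_attr = TRUE)
})

test_that("SCC is 1 for identical matrices and bounded in [-1, 1]", {
  withr::local_seed(17)
  m <- matrix(rpois(2500, 5), 50)
  m <- m + t(m)
  attr(m, "resolution") <- 100000
  expect_equal(scc(m, m), 1)
  m2 <- matrix(rpois(2500, 5), 50)
  m2 <- m2 + t(m2)
  v <- scc(m, m2, resolution = 100000)
  expect_true(v >= -1 && v <= 1)
  # symmetric in its arguments
  expect_equal(scc(m, m2, resolution = 100000),
               scc(m2, m, resolution = 100000))
})

test_that("h = 0 reduces SCC to the unsmoothed stratified correlation", {
  withr::local_seed(19)
  n <- 30
  a <- matrix(rpois(n * n, 4), n); a <- a + t(a)
  b <- matrix(rpois(n * n, 4), n); b <- b + t(b)
  res <- 100000
  mine <- scc(a, b, h = 0, lb = 0, ub = 3e6, resolution = res)
  # independent restatement of the stratum-weighted formula
  num <- 0; den <- 0
  for (k in 0:(n - 1)) {
    if (k * res > 3e6) next
    i <- seq_len(n - k)
    x <- a[cbind(i, i + k)]; y <- b[cbind(i, i + k)]
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) next
    w <- length(x) * sd(x) * sd(y)
    num <- num + w * cor(x, y); den <- den + w
  }
  expect_equal(mine, num / den, tolerance = 1e-12)
})

test_that("independent Poisson matrices have near-zero unsmoothed SCC", {
  # h = 0 isolates the stratified-correlation null; the default smoothing
  # window widens (without biasing) the null spread on matrices this small
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      a <- matrix(rpois(10000, 5), 100); a <- a + t(a)
      b <- matrix(rpois(10000, 5), 100); b <- b + t(b)
      abs(scc(a, b, h = 0, resolution = 100000)) < 0.1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate constant matrices raise an error", {
  m <- matrix(1, 10, 10)
  expect_error(scc(m, m, resolution = 1e5), "degenerate")
})
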