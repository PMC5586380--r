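test_that("rate tables parse with the documented column and unit semantics", {
  f <- withr::local_tempfile(lines = c(
    "# left right rate extra", "100 200 0.01 0.9", "200 500 0.002 0.8"))
  m <- read_rho_map(f)
  expect_equal(m$positions, c(100, 200, 500))
  expect_equal(m$rates, c(0.01, 0.002))

  m_kb <- read_rho_map(f, rate_unit = "per_kbp")
  expect_equal(m_kb$rates, c(1e-5, 2e-6))
})

test_that("gaps between rows are rejected by row, or bridged with rate 0", {
  f <- withr::local_tempfile(lines = c("100 200 0.5", "300 400 0.25"))
  expect_error(read_rho_map(f), "row 2")
  m <- read_rho_map(f, gap_tolerant = TRUE)
  expect_equal(m$positions, c(100, 200, 300, 400))
  expect_equal(m$rates, c(0.5, 0, 0.25))
  expect_equal(m$provenance$gap_bridges, 200)
})

test_that("malformed rate tables are rejected with the offending row", {
  f1 <- withr::local_tempfile(lines = c("100 200 0.1", "200 150 0.1"))
  expect_error(read_rho_map(f1), "row 2")
  f2 <- withr::local_tempfile(lines = c("100 200 -0.1"))
  expect_error(read_rho_map(f2), "negative")
})

test_that("rho_map invariants are enforced at construction", {
  expect_error(rho_map("c", c(100), numeric(0)), "at least 2")
  expect_error(rho_map("c", c(100, 100), 0.1), "increasing")
  expect_error(rho_map("c", c(100, 200), c(0.1, 0.2)), "length")
  expect_error(rho_map("c", c(100, 200), -0.1), "non-negative")
})

test_that("rho map read/write round-trips exactly on randomized maps", {
  set.seed(11)
  for (k in 1:20) {
    m <- random_rho_map(n_int = sample(1:30, 1))
    f <- withr::local_tempfile()
    write_rho_map(m, f)
    m2 <- read_rho_map(f, chrom = m$chrom)
    expect_identical(m2$positions, m$positions)
    expect_identical(m2$rates, m$rates)
  }
  # 2-position map writes exactly one data row
  f <- withr::local_tempfile()
  expect_equal(write_rho_map(rho_map("c", c(1, 2), 0.5), f), 1)
  expect_length(grep("^[^#]", readLines(f)), 1)
})

test_that("BED intervals use 0-based half-open semantics and come back sorted", {
  f <- withr::local_tempfile(lines = c(
    "chr2\t50\t150\tfeatB", "chr1\t0\t100\tfeatA"))
  iv <- read_bed(f)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(0, 50))
  expect_equal(iv$V4, c("featA", "featB"))

  bad <- withr::local_tempfile(lines = "chr1\t100\t100")
  expect_error(read_bed(bad), "line 1")
})

test_that("interval sets round-trip through BED with extra columns intact", {
  set.seed(5)
  start <- sort(sample(0:10000, 15))
  iv <- interval_set(tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 15, TRUE),
    start = start, end = start + sample(1:50, 15, TRUE),
    score = round(runif(15), 3)))
  f <- withr::local_tempfile()
  write_bed(iv, f)
  iv2 <- read_bed(f)
  expect_equal(iv2$chrom, iv$chrom)
  expect_equal(iv2$start, iv$start)
  expect_equal(iv2$end, iv$end)
  expect_equal(iv2$V4, iv$score)
})

test_that("interval_set validates coordinates against chromosome lengths", {
  expect_error(interval_set(data.frame(chrom = "c", start = 5, end = 5)),
               "start < end")
  expect_error(
    interval_set(data.frame(chrom = "c", start = 0, end = 200),
                 chrom_lengths = c(c = 100)),
    "exceeds")
})

test_that("stitching removes overlap copies and keeps the midpoint tie-break", {
  wA <- rho_map("c", 1:10, rep(1, 9))
  wB <- rho_map("c", 9:18, rep(2, 9))
  s <- stitch_windows(list(wA, wB), overlap_snps = 2)
  expect_equal(s$positions, 1:18)
  # one shared interval [9,10): earlier window supplies it (midpoint rule)
  expect_equal(s$rates[9], 1)
  expect_equal(s$rates[10], 2)

  # identical rates in the overlap: result independent of the tie-break
  wC <- rho_map("c", 9:18, c(1, 1, rep(2, 7)))
  s2 <- stitch_windows(list(wA, wC), overlap_snps = 2)
  expect_equal(s2$rates[1:9], rep(1, 9))
})

test_that("stitched SNP count matches the closed form for any configuration", {
  set.seed(21)
  for (k in 1:10) {
    n_win <- sample(2:4, 1)
    n_snp <- sample(20:60, 1)
    ov <- sample(2:10, 1)
    pos <- cumsum(sample(1:20, n_win * n_snp, replace = TRUE))
    maps <- list()
    at <- 1
    for (w in seq_len(n_win)) {
      idx <- at:(at + n_snp - 1)
      maps[[w]] <- rho_map("c", pos[idx], runif(n_snp - 1))
      at <- at + n_snp - ov
    }
    s <- stitch_windows(maps, ov)
    expect_length(s$positions, n_win * n_snp - (n_win - 1) * ov)
  }
  # three windows of 4400 SNPs overlapping by 200 stitch to 12,800 positions
  pos <- seq_len(3 * 4400 - 2 * 200)
  maps <- lapply(0:2, function(w) {
    idx <- (w * 4200 + 1):(w * 4200 + 4400)
    rho_map("c", pos[idx], rep(1e-3, 4399))
  })
  expect_length(stitch_windows(maps, 200)$positions, 12800)
})

test_that("stitching rejects discordant overlap positions", {
  wA <- rho_map("c", 1:10, rep(1, 9))
  wB <- rho_map("c", c(9, 11:19), rep(2, 9))
  expect_error(stitch_windows(list(wA, wB), 2), "mismatch")
})
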