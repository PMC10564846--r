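aln_row <- function(id, target = "t1", start = 1, end = 150, alen = 150,
                    edits = 0, sample = "s1") {
  tibble::tibble(read_id = id, sample_id = sample, target_id = target,
                 start = start, end = end, aligned_length = alen,
                 edit_distance = edits)
}

test_that("identity filtering is inclusive at the 90% floor", {
  recs <- dplyr::bind_rows(
    aln_row("at_floor", edits = 15),   # 135/150 = 0.90 exactly
    aln_row("below", edits = 23),      # 0.8467
    aln_row("well_below", edits = 22), # 0.8533 -> 0.85 class decoy
    aln_row("perfect", edits = 0)
  )
  kept <- filter_by_identity(recs, 0.90)
  expect_setequal(kept$read_id, c("at_floor", "perfect"))
  # equals a brute-force list filter
  manual <- recs$read_id[(recs$aligned_length - recs$edit_distance) /
                           recs$aligned_length >= 0.90]
  expect_setequal(kept$read_id, manual)
  expect_error(filter_by_identity(aln_row("x", edits = NA)), "edit distance")
})

test_that("control subtraction removes exactly the listed reads", {
  recs <- dplyr::bind_rows(aln_row("a"), aln_row("b"), aln_row("c"))
  expect_equal(subtract_control_reads(recs, character()), recs)
  expect_message(out <- subtract_control_reads(recs, c("b")), "Removed 1")
  expect_setequal(out$read_id, c("a", "c"))
  expect_warning(subtract_control_reads(recs, c("a", "b", "c")), "empty")
})

test_that("coverage breadth and depth match per-base counting", {
  # uniform single-x coverage of the whole genome
  full <- tibble::tibble(target_id = "t1", start = 1, end = 1000)
  prof <- coverage_profile(full, c(t1 = 1000))
  expect_equal(prof$breadth, 1)
  expect_equal(prof$mean_depth, 1)
  # 7,500 of 10,000 bp covered sits exactly at breadth 0.75
  spans <- tibble::tibble(target_id = "t1", start = 1, end = 7500)
  expect_equal(coverage_profile(spans, c(t1 = 10000))$breadth, 0.75)
  # random span sets equal the position-set oracle
  set.seed(9)
  for (i in 1:5) {
    L <- 500
    n <- sample(5:30, 1)
    st <- sample(L, n, replace = TRUE)
    en <- pmin(L, st + sample(10:80, n, replace = TRUE))
    spans <- tibble::tibble(target_id = "t1", start = st, end = en)
    got <- coverage_profile(spans, c(t1 = L))
    ora <- oracle_coverage(st, en, L)
    expect_equal(got$breadth, ora$breadth)
    expect_equal(got$mean_depth, ora$mean_depth)
  }
})

test_that("depth-table input agrees with the span route and validates bounds", {
  set.seed(10)
  L <- 300
  st <- sample(L, 10, replace = TRUE)
  en <- pmin(L, st + 40)
  spans <- tibble::tibble(target_id = "t1", start = st, end = en)
  depth <- numeric(L)
  for (i in seq_along(st)) depth[st[i]:en[i]] <- depth[st[i]:en[i]] + 1
  dt <- tibble::tibble(target_id = "t1", pos = which(depth > 0),
                       depth = depth[depth > 0])
  expect_equal(coverage_profile(dt, c(t1 = L))$breadth,
               coverage_profile(spans, c(t1 = L))$breadth)
  expect_equal(coverage_profile(dt, c(t1 = L))$mean_depth,
               coverage_profile(spans, c(t1 = L))$mean_depth)
  bad <- tibble::tibble(target_id = "t1", pos = L + 5, depth = 1)
  expect_error(coverage_profile(bad, c(t1 = L)), "exceed")
})

test_that("presence thresholds are inclusive for viruses and MAGs", {
  prof <- tibble::tibble(target_id = c("a", "b", "c", "d"),
                         breadth = c(0.75, 0.7499, 0.90, 0.89))
  v <- call_viral_presence(prof)
  expect_equal(v$present, c(TRUE, FALSE, TRUE, TRUE))
  m <- call_mag_presence(prof)
  expect_equal(m$present, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("presence is monotone in coverage: adding reads never loses a call", {
  set.seed(3)
  L <- 400
  st <- sample(L - 50, 12); en <- st + 50
  base <- tibble::tibble(target_id = "t1", start = st, end = en)
  extra <- tibble::tibble(target_id = "t1", start = sample(L - 50, 6),
                          end = NA_integer_)
  extra$end <- extra$start + 50
  p1 <- call_viral_presence(coverage_profile(base, c(t1 = L)))$present
  p2 <- call_viral_presence(coverage_profile(dplyr::bind_rows(base, extra),
                                             c(t1 = L)))$present
  expect_true(!p1 || p2)
})

test_that("identity filter then breadth equals breadth on pre-filtered input", {
  set.seed(4)
  recs <- dplyr::bind_rows(lapply(1:40, function(i) {
    aln_row(paste0("r", i), start = sample(800, 1), end = NA,
            edits = sample(0:30, 1))
  }))
  recs$end <- pmin(1000L, recs$start + 149L)
  recs$aligned_length <- recs$end - recs$start + 1L
  a <- coverage_profile(filter_by_identity(recs, 0.9), c(t1 = 1000))
  pre <- recs[(recs$aligned_length - recs$edit_distance) /
                recs$aligned_length >= 0.9, ]
  b <- coverage_profile(pre, c(t1 = 1000))
  expect_equal(a, b)
})

test_that("sum normalization is linear per sample and matches the
           element-wise oracle", {
  ab <- tidyr::expand_grid(target_id = c("a", "b", "c"),
                           sample_id = c("s1", "s2"))
  set.seed(2)
  ab$mean_depth <- runif(6, 0, 10)
  libs <- c(s1 = 1e6, s2 = 2e6)
  out <- normalize_coverage(ab, libs)
  expect_equal(out$normalized,
               ab$mean_depth / unname(libs[ab$sample_id]) * 1e6)
  # doubling reads at identical raw coverage halves the normalized value
  one <- normalize_coverage(tibble::tibble(target_id = "a", sample_id = "s",
                                           mean_depth = 4), c(s = 1e6))
  two <- normalize_coverage(tibble::tibble(target_id = "a", sample_id = "s",
                                           mean_depth = 4), c(s = 2e6))
  expect_equal(two$normalized, one$normalized / 2)
  expect_error(normalize_coverage(ab, c(s1 = 1e6)), "s2")
  expect_error(normalize_coverage(ab, c(s1 = 1e6, s2 = 0)), "> 0")
})

test_that("the minimal SAM reader recovers span, identity and soft clips", {
  sam <- c(
    "@SQ\tSN:t1\tLN:1000",
    "r1\t0\tt1\t11\t42\t10S140M\t*\t0\t0\t*\t*\tNM:i:14",
    "r2\t16\tt1\t1\t42\t100M2D50M\t*\t0\t0\t*\t*\tNM:i:0",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  )
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, tf)
  recs <- read_sam_alignments(tf)
  expect_equal(nrow(recs), 2)
  r1 <- recs[recs$read_id == "r1", ]
  expect_equal(r1$aligned_length, 140)      # soft clip excluded
  expect_equal(r1$end, 11 + 140 - 1)
  expect_equal(r1$identity, (140 - 14) / 140)
  r2 <- recs[recs$read_id == "r2", ]
  expect_equal(r2$end, 1 + 152 - 1)         # deletion consumes reference
})
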