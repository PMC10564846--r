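test_that("arrays with verbatim viral DR hits are removed, near-misses kept", {
  dr1 <- strrep("ACGT", 8)                     # embedded verbatim
  dr2 <- paste0(strrep("ACGT", 7), "ACGA")     # 1 mismatch to best hit
  scaff <- c(s1 = paste0(rand_dna(50), dr1, rand_dna(50)))
  arrays <- tibble::tibble(array_id = c("a1", "a2"), dr = c(dr1, dr2))
  expect_message(kept <- remove_viral_dr(arrays, scaff), "a1")
  expect_equal(kept$array_id, "a2")
  # reverse-strand hits also count
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dr2)))
  scaff_rc <- c(s2 = paste0(rand_dna(30), rc, rand_dna(30)))
  expect_equal(nrow(suppressMessages(remove_viral_dr(arrays, scaff_rc))), 1)
  expect_error(remove_viral_dr(tibble::tibble(array_id = "x", dr = "ACGTACGT"),
                               scaff), ">= 16")
})

test_that("spacer extraction honors the Hamming budget and cassette layout", {
  set.seed(71)
  dr <- rand_dna(30)
  sp <- rand_dna(30)
  read <- paste0(rand_dna(10), dr, sp, dr, rand_dna(10))
  got <- extract_spacers(read, dr)
  expect_equal(got$spacer, sp)
  # DR copies carrying 4 mismatches are not recognized (d = 3 budget)
  mangle <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    at <- seq_len(n)
    v[at] <- vapply(v[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
    paste(v, collapse = "")
  }
  read4 <- paste0(rand_dna(10), mangle(dr, 4), sp, mangle(dr, 4), rand_dna(10))
  expect_equal(nrow(extract_spacers(read4, dr)), 0)
  # 3 mismatches still extract
  read3 <- paste0(rand_dna(10), mangle(dr, 3), sp, mangle(dr, 3), rand_dna(10))
  expect_equal(extract_spacers(read3, dr)$spacer, sp)
  # negative reads yield nothing
  expect_equal(nrow(extract_spacers(c(rand_dna(100), rand_dna(100)), dr)), 0)
  # spacers longer than the cap are not emitted
  long_read <- paste0(dr, rand_dna(61), dr)
  expect_equal(nrow(extract_spacers(long_read, dr)), 0)
  # multi-spacer cassettes emit every inter-DR segment
  sp2 <- rand_dna(25)
  multi <- paste0(dr, sp, dr, sp2, dr)
  expect_setequal(extract_spacers(multi, dr)$spacer, c(sp, sp2))
})

test_that("extraction is strand-symmetric up to reverse complement", {
  set.seed(73)
  dr <- rand_dna(28)
  reads <- vapply(1:4, function(i) {
    paste0(rand_dna(8), dr, rand_dna(30), dr, rand_dna(8))
  }, "")
  fwd <- sort(extract_spacers(reads, dr)$spacer)
  rc_reads <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  rev <- extract_spacers(rc_reads, dr)$spacer
  expect_setequal(fwd, sort(rev))
})

test_that("length and homopolymer filters drop the right spacers before
           clustering", {
  set.seed(79)
  good <- rand_dna(30)
  sp <- c(good, rand_dna(19), strrep("A", 30),
          paste0(strrep("G", 16), rand_dna(14)))
  out <- filter_and_cluster_spacers(sp)
  expect_equal(out$spacer, good)
})

test_that("greedy clustering agrees with the all-pairs identity graph and
           never merges below the cutoff", {
  set.seed(83)
  base <- replicate(10, rand_dna(40))
  # duplicates of each base spacer plus one single-substitution variant
  variant <- function(s) {
    v <- strsplit(s, "")[[1]]
    v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
    paste(v, collapse = "")
  }
  sp <- c(base, base, vapply(base, variant, ""))
  out <- filter_and_cluster_spacers(sp, cluster_identity = 0.99)
  # oracle components at >= 0.99 identity (40 bp: only exact duplicates)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      same <- out$cluster_id[i] == out$cluster_id[j]
      ident <- ungapped_identity_oracle(out$spacer[i], out$spacer[j])
      if (same && i != j) expect_gte(ident, 0.99)
      if (ident >= 0.995 && !same) fail("exact duplicates not merged")
    }
  }
  expect_equal(length(unique(out$cluster_id)), 20)  # 10 exact + 10 variants
})

test_that("protospacer matching sits exactly on the inclusive 0.80 boundary
           and equals the exhaustive-offset oracle", {
  set.seed(89)
  scaffold <- rand_dna(400)
  sp <- substr(scaffold, 101, 130)
  mangle_at <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- vapply(v[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
    paste(v, collapse = "")
  }
  six <- mangle_at(sp, seq(1, 30, length.out = 6))    # identity 0.80
  seven <- mangle_at(sp, seq(1, 30, length.out = 7))  # identity 0.767
  hits6 <- match_protospacers(c(s6 = six), c(sc = scaffold))
  expect_equal(nrow(hits6), 1)
  expect_equal(hits6$identity, 0.80)
  expect_equal(hits6$position, 101)
  expect_equal(nrow(match_protospacers(c(s7 = seven), c(sc = scaffold))), 0)
  # reverse-strand protospacers are found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
  hrc <- match_protospacers(c(r = rc), c(sc = scaffold))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$identity, 1)
  # random spacer/scaffold pairs agree with the oracle scan
  for (i in 1:4) {
    spacer <- rand_dna(25)
    scaf <- rand_dna(300)
    ora <- oracle_protospacer(spacer, scaf)
    got <- match_protospacers(c(q = spacer), c(t = scaf), min_identity = 0.5)
    if ((25 - ora$mism) / 25 >= 0.5) {
      expect_equal(got$mismatches, ora$mism)
      expect_equal(got$position, ora$pos)
    } else {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("synthetic cassettes round-trip: truth spacers are recovered and
           matched at the expected identities", {
  g <- sim_genomes(n_viral = 4, n_host = 2, length_range = c(10000, 12000),
                   seed = 97)
  cr <- sim_crispr_reads(g$viruses, n_spacers = 9,
                         divergence = c(0, 0, 0, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2),
                         seed = 101)
  raw <- extract_spacers(cr$reads, cr$dr)
  expect_setequal(raw$spacer, cr$truth$spacer)
  clustered <- filter_and_cluster_spacers(raw)
  matches <- match_protospacers(clustered, g$viruses, min_identity = 0.80)
  by_seq <- setNames(cr$truth$expected_identity, cr$truth$spacer)
  for (i in seq_len(nrow(clustered))) {
    m <- matches[matches$spacer_id == clustered$spacer_id[i], ]
    expected <- by_seq[[clustered$spacer[i]]]
    expect_true(any(abs(m$identity - expected) < 1e-9),
                info = sprintf("spacer %d (expected identity %.2f)",
                               i, expected))
  }
  # zero-divergence spacers match at exactly 1.0
  zero <- cr$truth$spacer[cr$truth$divergence == 0]
  ids <- clustered$spacer_id[clustered$spacer %in% zero]
  expect_true(all(matches$identity[matches$spacer_id %in% ids &
                                     matches$identity > 0.99] == 1))
})

test_that("the bipartite network flags cross-ecosystem edges", {
  matches <- tibble::tibble(spacer_id = c("sp1", "sp2"),
                            scaffold_id = c("v1", "v2"),
                            strand = "+", position = 1L, mismatches = 0L,
                            identity = 1)
  net <- build_spacer_network(
    matches,
    spacer_origin = tibble::tibble(spacer_id = c("sp1", "sp2"),
                                   ecosystem = c("SML", "rain")),
    scaffold_origin = tibble::tibble(scaffold_id = c("v1", "v2"),
                                     ecosystem = c("rain_only", "rain_only")))
  expect_true(net$cross_ecosystem[net$spacer_id == "sp1"])
  expect_false(net$cross_ecosystem[net$spacer_id == "sp2"])
  expect_error(build_spacer_network(
    matches, tibble::tibble(spacer_id = "sp1", ecosystem = "SML"),
    tibble::tibble(scaffold_id = c("v1", "v2"), ecosystem = "rain")),
    "unknown spacer")
})
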