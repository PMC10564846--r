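toy_sheet <- function() {
  validate_sample_sheet(tibble::tibble(
    sample_id = c("f1", "m1", "m2", "w1", "a1", "r1", "sn1"),
    ecosystem = c("foam", "SML", "SML", "SSW", "aerosol", "rain", "snow"),
    fraction = "na", station = NA_character_, date = "2020-02-10"
  ))
}

test_that("occupancy aggregates presence by any-sample OR per ecosystem", {
  presence <- tibble::tibble(
    sample_id = c("m1", "m2", "f1", "r1"),
    target_id = c("v1", "v1", "v2", "v2"),
    present = c(TRUE, FALSE, TRUE, TRUE)
  )
  occ <- occupancy_matrix(presence, toy_sheet())
  v1 <- occ[occ$target_id == "v1", ]
  expect_true(v1$SML)
  expect_false(any(unlist(v1[, c("foam", "SSW", "aerosol", "rain", "snow")])))
  v2 <- occ[occ$target_id == "v2", ]
  expect_true(v2$foam && v2$rain)
  expect_error(occupancy_matrix(presence %>%
                                  dplyr::mutate(sample_id = "nope"),
                                toy_sheet()), "missing from the sheet")
})

test_that("venn regions match direct expectations and the subset
           enumeration oracle", {
  # disjoint 3 + 4
  occ <- tibble::tibble(target_id = paste0("v", 1:7),
                        A = c(rep(TRUE, 3), rep(FALSE, 4)),
                        B = c(rep(FALSE, 3), rep(TRUE, 4)))
  venn <- ecosystem_venn(occ, c("A", "B"))
  expect_equal(venn$count[venn$region == "A"], 3L)
  expect_equal(venn$count[venn$region == "B"], 4L)
  expect_equal(venn$count[venn$region == "A&B"], 0L)
  # identical occupancy over three sets: everything in the triple core
  occ3 <- tibble::tibble(target_id = paste0("v", 1:5),
                         A = TRUE, B = TRUE, C = TRUE)
  venn3 <- ecosystem_venn(occ3, c("A", "B", "C"))
  expect_equal(venn3$count[venn3$region == "A&B&C"], 5L)
  expect_equal(sum(venn3$count), 5L)
  # random 5-set occupancy vs enumeration oracle
  set.seed(13)
  memb <- matrix(runif(50 * 5) < 0.4, ncol = 5)
  colnames(memb) <- paste0("e", 1:5)
  occ5 <- dplyr::bind_cols(tibble::tibble(target_id = paste0("v", 1:50)),
                           tibble::as_tibble(memb))
  venn5 <- ecosystem_venn(occ5, colnames(memb))
  ora <- oracle_venn(memb)
  for (reg in ora) {
    idx <- which(apply(venn5[, colnames(memb)], 1,
                       function(r) all(r == reg$pattern)))
    expect_equal(venn5$count[idx], reg$count)
  }
  expect_equal(sum(venn5$count), sum(rowSums(memb) > 0))
  expect_error(ecosystem_venn(occ5, "e1"), "at least 2")
})

test_that("exclusivity requires absence from every other ecosystem", {
  occ <- tibble::tibble(target_id = c("only_rain", "rain_air", "marine"),
                        rain = c(TRUE, TRUE, FALSE),
                        aerosol = c(FALSE, TRUE, FALSE),
                        SML = c(FALSE, FALSE, TRUE))
  expect_equal(exclusive_viruses(occ, "rain"), "only_rain")
  expect_equal(exclusive_viruses(occ, "SML"), "marine")
})

test_that("shared fractions reproduce the published 6.2% arithmetic", {
  occ <- tibble::tibble(target_id = paste0("v", 1:120),
                        rain = c(rep(TRUE, 112), rep(FALSE, 8)),
                        SML = c(rep(TRUE, 112), rep(FALSE, 8)))
  got <- shared_fraction(occ, "rain", "SML", total = 1813)
  expect_equal(got$shared, 112)
  expect_equal(got$percent_display, 6.2)
  disjoint <- tibble::tibble(target_id = c("a", "b"),
                             rain = c(TRUE, FALSE), SML = c(FALSE, TRUE))
  expect_equal(shared_fraction(disjoint, "rain", "SML", 10)$percent, 0)
  expect_error(shared_fraction(disjoint, "rain", "SML", 0), ">= 1")
})

test_that("enrichment ratios follow the max-over-ecosystem definition", {
  sheet <- validate_sample_sheet(tibble::tibble(
    sample_id = c("r1", "r2", "sml_v", "sml_02", "f_v"),
    ecosystem = c("rain", "rain", "SML", "SML", "foam"),
    fraction = c("na", "na", "virome_lt02um", "um5_02", "virome_lt02um"),
    station = NA_character_, date = "2020-02-10"
  ))
  ab <- tibble::tibble(
    target_id = "v1",
    sample_id = c("r1", "r2", "sml_v", "sml_02", "f_v"),
    normalized = c(14, 3, 2, 7, 0)
  )
  er <- enrichment_ratios(ab, sheet)
  rs_vir <- er[er$pairing == "R/S" & er$fraction == "virome_lt02um", ]
  expect_equal(rs_vir$ratio, 7.0)        # rain max 14 over SML virome max 2
  expect_true(rs_vir$reported)
  rs_02 <- er[er$pairing == "R/S" & er$fraction == "um5_02", ]
  expect_equal(rs_02$ratio, 2.0)
  # absent denominator (foam has zero coverage) -> undefined, not zero
  rf <- er[er$pairing == "R/F" & er$fraction == "virome_lt02um", ]
  expect_true(is.na(rf$ratio))
  # equal maxima sit on the reported boundary
  ab2 <- ab; ab2$normalized <- c(2, 1, 2, 1, 0)
  er2 <- enrichment_ratios(ab2, sheet)
  eq <- er2[er2$pairing == "R/S" & er2$fraction == "virome_lt02um", ]
  expect_equal(eq$ratio, 1.0)
  expect_true(eq$reported)
})

test_that("enrichment ratios equal a brute-force oracle and are
           normalization-scale invariant", {
  sheet <- validate_sample_sheet(tibble::tibble(
    sample_id = c("r1", "r2", "a1", "s1", "s2", "f1"),
    ecosystem = c("rain", "rain", "aerosol", "SML", "SML", "foam"),
    fraction = c("na", "na", "na", "um5_02", "um5_02", "um5_02"),
    station = NA_character_, date = "2020-02-10"
  ))
  set.seed(17)
  raw <- tidyr::expand_grid(target_id = paste0("v", 1:8),
                            sample_id = sheet$sample_id)
  raw$mean_depth <- rpois(nrow(raw), 3) * runif(nrow(raw))
  libs <- setNames(runif(6, 1e5, 1e6), sheet$sample_id)
  er6 <- enrichment_ratios(normalize_coverage(raw, libs, scale = 1e6), sheet)
  er3 <- enrichment_ratios(normalize_coverage(raw, libs, scale = 1e3), sheet)
  expect_equal(er6$ratio, er3$ratio)
  # oracle: max-then-divide with detection = positive coverage
  norm <- normalize_coverage(raw, libs, scale = 1e6)
  for (v in unique(norm$target_id)) {
    sub <- norm[norm$target_id == v, ]
    mx <- function(ids) {
      x <- sub$normalized[sub$sample_id %in% ids & sub$normalized > 0]
      if (length(x) == 0) NA_real_ else max(x)
    }
    expected <- mx(c("r1", "r2")) / mx(c("s1", "s2"))
    got <- er6$ratio[er6$target_id == v & er6$pairing == "R/S" &
                       er6$fraction == "um5_02"]
    expect_equal(got, expected)
  }
})

test_that("G/C percentages match a character-tally oracle and complement AT", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_error(gc_percent(""), "Empty")
  set.seed(19)
  for (i in 1:5) {
    s <- rand_dna(200)
    chars <- strsplit(s, "")[[1]]
    expect_equal(gc_percent(s), 100 * sum(chars %in% c("G", "C")) / 200)
    at <- 100 * sum(chars %in% c("A", "T")) / 200
    expect_equal(gc_percent(s) + at, 100)
  }
  # ambiguity codes excluded from numerator and denominator
  expect_equal(gc_percent("GCNNAT"), 100 * 2 / 4)
})
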