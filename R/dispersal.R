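#' Ecosystem occupancy matrix from per-sample presence calls
#'
#' Aggregates per-(virus, sample) presence calls to per-(virus, ecosystem)
#' occupancy by OR over the ecosystem's samples. Control samples never
#' contribute. The result is one row per virus with one logical column per
#' ecosystem observed in the sheet.
#'
#' @param presence Tibble with `sample_id`, `target_id`, `present`.
#' @param sheet Validated sample sheet (see [read_sample_sheet()]).
#' @return A tibble: `target_id` plus one logical column per ecosystem.
#' @export
occupancy_matrix <- function(presence, sheet) {
  assert_columns(presence, c("sample_id", "target_id", "present"), "presence calls")
  sheet <- validate_sample_sheet(sheet)
  unknown <- setdiff(unique(presence$sample_id), sheet$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("Presence calls reference sample(s) missing from the sheet: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  joined <- presence %>%
    left_join(sheet %>% select("sample_id", "ecosystem", "excluded"),
              by = "sample_id") %>%
    filter(!.data$excluded)
  ecos <- sort(unique(sheet$ecosystem[!sheet$excluded]))
  occ <- joined %>%
    group_by(.data$target_id, .data$ecosystem) %>%
    summarise(occupied = any(.data$present), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "ecosystem", values_from = "occupied",
                       values_fill = FALSE)
  for (e in setdiff(ecos, names(occ))) occ[[e]] <- FALSE
  occ %>% select("target_id", dplyr::all_of(ecos)) %>% arrange(.data$target_id)
}

#' Venn region counts over ecosystem occupancy sets
#'
#' Counts viruses in every region of the set algebra over the named
#' ecosystems (2^m - 1 regions; viruses occupying none of the sets are not
#' counted, so region counts sum to the number of occupying viruses).
#'
#' @param occupancy Occupancy matrix (see [occupancy_matrix()]).
#' @param sets Character vector (length >= 2) of ecosystem column names.
#' @return A tibble with one logical membership column per set, a `region`
#'   label, and `count`.
#' @export
ecosystem_venn <- function(occupancy, sets) {
  if (length(sets) < 2) abort("Need at least 2 sets for a Venn partition.")
  missing <- setdiff(sets, names(occupancy))
  if (length(missing) > 0) {
    abort(sprintf("Unknown ecosystem(s): %s", paste(missing, collapse = ", ")))
  }
  memb <- as.matrix(occupancy[, sets, drop = FALSE])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(grid) <- sets
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  pattern_key <- apply(memb, 1, paste, collapse = ".")
  grid_key <- apply(as.matrix(grid), 1, paste, collapse = ".")
  counts <- table(factor(pattern_key, levels = grid_key))
  as_tibble(grid) %>%
    mutate(
      region = purrr::map_chr(seq_len(nrow(grid)), function(i) {
        paste(sets[unlist(grid[i, ])], collapse = "&")
      }),
      count = as.integer(counts)
    )
}

#' Viruses exclusive to one ecosystem
#'
#' Viruses present in the named ecosystem and absent from every other
#' ecosystem column of the occupancy matrix. "Exclusively detected in rain"
#' means no other studied ecosystem reached the presence criterion (90%
#' identical reads covering 75% of the scaffold at >= 1x) for that virus.
#'
#' @param occupancy Occupancy matrix.
#' @param ecosystem Ecosystem column name.
#' @return Character vector of virus ids.
#' @export
exclusive_viruses <- function(occupancy, ecosystem) {
  eco_cols <- setdiff(names(occupancy), "target_id")
  if (!ecosystem %in% eco_cols) {
    abort(sprintf("Ecosystem '%s' not in occupancy matrix.", ecosystem))
  }
  others <- setdiff(eco_cols, ecosystem)
  keep <- occupancy[[ecosystem]] &
    rowSums(as.matrix(occupancy[, others, drop = FALSE])) == 0
  occupancy$target_id[keep]
}

#' Fraction of the viral catalog shared between two ecosystem groups
#'
#' Percentage of all catalogued viruses occupying at least one ecosystem of
#' each group (e.g. precipitation = rain + snow versus seawater including
#' foam).
#'
#' @param occupancy Occupancy matrix.
#' @param set_a,set_b Character vectors of ecosystem column names.
#' @param total Denominator: the size of the dereplicated scaffold catalog.
#' @return A one-row tibble: `shared`, `total`, `percent`, `percent_display`
#'   (one decimal, half-up).
#' @export
#' @examples
#' # 112 of 1813 catalogued viruses shared -> 6.2%
shared_fraction <- function(occupancy, set_a, set_b, total) {
  if (!is.numeric(total) || total < 1) abort("`total` must be >= 1.")
  missing <- setdiff(c(set_a, set_b), names(occupancy))
  if (length(missing) > 0) {
    abort(sprintf("Unknown ecosystem(s): %s", paste(missing, collapse = ", ")))
  }
  in_a <- rowSums(as.matrix(occupancy[, set_a, drop = FALSE])) > 0
  in_b <- rowSums(as.matrix(occupancy[, set_b, drop = FALSE])) > 0
  shared <- sum(in_a & in_b)
  pct <- 100 * shared / total
  tibble(shared = shared, total = total, percent = pct,
         percent_display = round_half_up(pct, 1))
}

#' Rain/aerosol over foam/SML enrichment ratios
#'
#' For each virus, the maximum sum-normalized coverage across an ecosystem
#' is taken as its highest possible abundance there, and ratios are formed
#' for the pairings rain/foam (R/F), rain/SML (R/S), aerosol/foam (A/F) and
#' aerosol/SML (A/S), with the denominator split by size fraction (5-0.2 um
#' prokaryote fraction vs virome). A ratio is undefined (NA) when the virus
#' was not detected in the numerator or denominator ecosystem; ratios >= 1
#' carry a `reported` flag.
#'
#' @param abundance Normalized abundance tibble: `target_id`, `sample_id`,
#'   `normalized` (see [normalize_coverage()]).
#' @param sheet Validated sample sheet with `fraction` labels for foam/SML
#'   samples.
#' @param presence Optional presence tibble (`sample_id`, `target_id`,
#'   `present`); by default any normalized coverage > 0 counts as detected.
#' @return A tibble: `target_id`, `pairing`, `fraction`, `numerator`,
#'   `denominator`, `ratio`, `reported`.
#' @export
enrichment_ratios <- function(abundance, sheet, presence = NULL) {
  assert_columns(abundance, c("target_id", "sample_id", "normalized"),
                 "abundance matrix")
  sheet <- validate_sample_sheet(sheet)
  ab <- abundance %>%
    left_join(sheet %>% select("sample_id", "ecosystem", "fraction", "excluded"),
              by = "sample_id") %>%
    filter(!.data$excluded)
  if (is.null(presence)) {
    ab <- ab %>% mutate(present = .data$normalized > 0)
  } else {
    ab <- ab %>%
      left_join(presence %>% select("sample_id", "target_id", "present"),
                by = c("sample_id", "target_id")) %>%
      mutate(present = dplyr::coalesce(.data$present, FALSE))
  }
  eco_max <- function(eco, frac = NULL) {
    sub <- ab %>% filter(.data$ecosystem == eco, .data$present)
    if (!is.null(frac)) sub <- sub %>% filter(.data$fraction == frac)
    if (nrow(sub) == 0) {
      return(tibble(target_id = character(), mx = double()))
    }
    sub %>% group_by(.data$target_id) %>%
      summarise(mx = max(.data$normalized), .groups = "drop")
  }
  viruses <- sort(unique(abundance$target_id))
  pairings <- tidyr::expand_grid(
    num = c("rain", "aerosol"), den = c("foam", "SML"),
    fraction = c("um5_02", "virome_lt02um")
  )
  purrr::pmap_dfr(pairings, function(num, den, fraction) {
    nm <- eco_max(num)
    dn <- eco_max(den, fraction)
    tibble(target_id = viruses) %>%
      left_join(nm, by = "target_id") %>% rename(numerator = "mx") %>%
      left_join(dn, by = "target_id") %>% rename(denominator = "mx") %>%
      mutate(
        pairing = paste0(toupper(substr(num, 1, 1)), "/",
                         ifelse(den == "foam", "F", "S")),
        fraction = fraction,
        ratio = .data$numerator / .data$denominator,
        reported = !is.na(.data$ratio) & .data$ratio >= 1
      ) %>%
      select("target_id", "pairing", "fraction", "numerator", "denominator",
             "ratio", "reported")
  })
}

#' Percent G/C base content
#'
#' 100 * (G + C) / (A + C + G + T); ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param x A character vector of nucleotide sequences or a
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' gc_percent(c("GGCC", "ATAT", "GCAT")) # 100, 0, 50
gc_percent <- function(x) {
  if (!methods::is(x, "DNAStringSet")) {
    if (any(!nzchar(x))) abort("Empty sequence.")
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  if (any(Biostrings::width(x) == 0)) abort("Empty sequence.")
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  if (any(denom == 0)) abort("Sequence contains no unambiguous A/C/G/T bases.")
  unname(100 * (counts[, "G"] + counts[, "C"]) / denom)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-square approximation, df = g - 1)
#' followed by Dunn's pairwise z tests on rank means with the tie-corrected
#' pooled variance. Raw two-sided p values are adjusted by multiplying by
#' the number of comparisons (Bonferroni), capped at 1; other `p.adjust`
#' methods are selectable. Identical values across all groups give H = 0,
#' p = 1 rather than an error.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) of the response and grouping
#'   variable.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return A list of class `kw_dunn`: `$kw` (one-row tibble `H`, `df`, `p`)
#'   and `$dunn` (tibble `group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @export
compare_groups_kw_dunn <- function(data, value, group, p_adjust = "bonferroni") {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Need >= 2 groups.")
  if (any(table(g) < 1)) abort("Each group needs >= 1 value.")
  N <- length(v)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)

  if (length(unique(v)) == 1) {
    kw <- tibble(H = 0, df = nlevels(g) - 1L, p = 1)
    dunn <- tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = 0, p_raw = 1, p_adj = 1)
    return(structure(list(kw = kw, dunn = dunn), class = "kw_dunn"))
  }

  kt <- kruskal.test(v, g)
  kw <- tibble(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)

  r <- rank(v)
  tie_sizes <- table(v)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  z <- purrr::map2_dbl(pairs[1, ], pairs[2, ], function(a, b) {
    (rbar[[a]] - rbar[[b]]) / sqrt(sigma2 * (1 / ns[[a]] + 1 / ns[[b]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  dunn <- tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                 p_raw = p_raw, p_adj = p.adjust(p_raw, method = p_adjust))
  structure(list(kw = kw, dunn = dunn), class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$kw$H, x$kw$df, x$kw$p))
  cat("Dunn post hoc (adjusted p):\n")
  print(as.data.frame(x$dunn), row.names = FALSE, digits = 4)
  invisible(x)
}
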