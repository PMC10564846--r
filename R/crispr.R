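#' Drop CRISPR arrays whose direct repeat occurs in a viral scaffold
#'
#' A consensus direct repeat (DR) with a 100%-identity, full-length hit in
#' any viral scaffold (either strand) indicates a virus-encoded repeat; such
#' arrays are removed before spacer extraction. Hits with any mismatch leave
#' the array in place.
#'
#' @param arrays Tibble with `array_id` and `dr` (consensus DR, >= 16 bp).
#' @param scaffolds Named character vector or [Biostrings::DNAStringSet] of
#'   viral scaffolds.
#' @return The array tibble without virus-matching arrays; dropped ids are
#'   reported in a message.
#' @export
remove_viral_dr <- function(arrays, scaffolds) {
  assert_columns(arrays, c("array_id", "dr"), "CRISPR array table")
  check_dr(arrays$dr)
  if (!methods::is(scaffolds, "DNAStringSet")) {
    scaffolds <- Biostrings::DNAStringSet(toupper(scaffolds))
  }
  hit <- purrr::map_lgl(arrays$dr, function(dr) {
    pat <- Biostrings::DNAString(dr)
    fwd <- sum(Biostrings::vcountPattern(pat, scaffolds, max.mismatch = 0))
    rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                         scaffolds, max.mismatch = 0))
    (fwd + rev) > 0
  })
  if (any(hit)) {
    message(sprintf("Dropped %d array(s) with viral DR hits: %s", sum(hit),
                    paste(arrays$array_id[hit], collapse = ", ")))
  }
  arrays[!hit, , drop = FALSE]
}

check_dr <- function(dr) {
  if (any(nchar(dr) < 16)) abort("Direct repeats must be >= 16 bp.")
  if (any(grepl("[^ACGT]", toupper(dr)))) {
    abort("Direct repeats must be unambiguous A/C/G/T.")
  }
  invisible(dr)
}

#' Extract CRISPR spacers from reads guided by a direct repeat
#'
#' Scans each read for occurrences of the DR with at most `max_mismatch`
#' Hamming mismatches (no indels) and emits the substrings between
#' consecutive DR hits whose length does not exceed `max_spacer_len`.
#' Reverse-oriented cassettes are caught by also scanning with the
#' reverse-complemented DR; their spacers are reported reverse-complemented
#' back into DR orientation. Partial cassettes at read ends are ignored.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of reads.
#' @param dr Consensus direct repeat (>= 16 bp, unambiguous).
#' @param max_mismatch Maximum Hamming mismatches per DR hit (default 3).
#' @param max_spacer_len Maximum emitted spacer length (default 60).
#' @return A tibble: `read_id`, `spacer`, `strand` (`+`/`-`).
#' @export
extract_spacers <- function(reads, dr, max_mismatch = 3, max_spacer_len = 60) {
  check_dr(dr)
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(toupper(reads))
  }
  ids <- names(reads) %||% paste0("read_", seq_along(reads))
  pat_f <- Biostrings::DNAString(toupper(dr))
  pat_r <- Biostrings::reverseComplement(pat_f)

  scan_one <- function(read, pat) {
    m <- Biostrings::matchPattern(pat, read, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    if (length(st) < 2) return(character())
    o <- order(st); st <- st[o]; en <- en[o]
    out <- character()
    for (i in seq_len(length(st) - 1)) {
      from <- en[i] + 1; to <- st[i + 1] - 1
      if (to >= from && (to - from + 1) <= max_spacer_len) {
        out <- c(out, as.character(Biostrings::subseq(read, from, to)))
      }
    }
    out
  }

  purrr::map_dfr(seq_along(reads), function(i) {
    fwd <- scan_one(reads[[i]], pat_f)
    rev <- scan_one(reads[[i]], pat_r)
    if (length(rev) > 0) {
      rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rev)))
      rev <- rev(rev)
    }
    bind_rows(
      if (length(fwd)) tibble(read_id = ids[i], spacer = fwd, strand = "+"),
      if (length(rev)) tibble(read_id = ids[i], spacer = rev, strand = "-")
    )
  })
}

longest_run <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

max_base_fraction <- function(s) {
  max(table(strsplit(s, "", fixed = TRUE)[[1]])) / nchar(s)
}

#' Length- and homopolymer-filter spacers, then cluster at high identity
#'
#' Drops spacers outside the length window or failing the homopolymer rule
#' (any single base making up >= 90% of the sequence, or a single-base run
#' of >= 15), then clusters greedily longest-first: a spacer joins the first
#' centroid with identity >= `cluster_identity`, where identity is matches
#' over the shorter length at the best ungapped offset; otherwise it founds
#' a new cluster.
#'
#' @param spacers Tibble from [extract_spacers()], or a character vector.
#' @param min_len,max_len Retained length window (default 20-60 bp).
#' @param cluster_identity Clustering identity (default 0.99).
#' @return A tibble: `spacer_id`, `spacer`, `cluster_id`, `is_centroid`,
#'   plus any input metadata columns.
#' @export
filter_and_cluster_spacers <- function(spacers, min_len = 20, max_len = 60,
                                       cluster_identity = 0.99) {
  if (is.character(spacers)) spacers <- tibble(spacer = spacers)
  assert_columns(spacers, "spacer", "spacer table")
  kept <- spacers %>%
    filter(nchar(.data$spacer) >= min_len, nchar(.data$spacer) <= max_len) %>%
    filter(purrr::map_lgl(.data$spacer, function(s) {
      max_base_fraction(s) < 0.9 && longest_run(s) < 15
    }))
  if (nrow(kept) == 0) {
    return(kept %>% mutate(spacer_id = character(), cluster_id = integer(),
                           is_centroid = logical()))
  }
  kept <- kept %>%
    arrange(dplyr::desc(nchar(.data$spacer)), .data$spacer) %>%
    mutate(spacer_id = paste0("sp_", dplyr::row_number()))
  centroids <- character()
  assign <- integer(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    s <- kept$spacer[i]
    found <- 0L
    for (ci in seq_along(centroids)) {
      if (ungapped_identity(s, centroids[ci]) >= cluster_identity) {
        found <- ci; break
      }
    }
    if (found == 0L) {
      centroids <- c(centroids, s)
      found <- length(centroids)
    }
    assign[i] <- found
  }
  kept %>%
    mutate(cluster_id = assign,
           is_centroid = .data$spacer == centroids[assign])
}

# Ungapped identity: matches over the shorter length, maximized over all
# offsets placing the shorter sequence fully inside the longer one.
ungapped_identity <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  for (off in 0:(la - lb)) {
    m <- sum(av[(off + 1):(off + lb)] == bv)
    if (m > best) best <- m
  }
  best / lb
}

#' Match clustered spacers to viral protospacers
#'
#' Scans both strands of every scaffold for the best ungapped full-length
#' placement of each spacer and reports hits with identity (matches over
#' spacer length) at or above the floor, inclusive: a 30-bp spacer with 6
#' mismatches sits exactly at 0.80 and is reported. One best position per
#' scaffold is emitted.
#'
#' @param spacers Tibble with `spacer_id` and `spacer` (e.g. from
#'   [filter_and_cluster_spacers()]), or a named character vector.
#' @param scaffolds Named character vector or [Biostrings::DNAStringSet].
#' @param min_identity Identity floor (default 0.80).
#' @return A tibble: `spacer_id`, `scaffold_id`, `strand`, `position`,
#'   `mismatches`, `identity`.
#' @export
match_protospacers <- function(spacers, scaffolds, min_identity = 0.80) {
  if (is.character(spacers)) {
    spacers <- tibble(spacer_id = names(spacers) %||%
                        paste0("sp_", seq_along(spacers)),
                      spacer = unname(spacers))
  }
  assert_columns(spacers, c("spacer_id", "spacer"), "spacer table")
  if (!methods::is(scaffolds, "DNAStringSet")) {
    scaffolds <- Biostrings::DNAStringSet(toupper(scaffolds))
  }
  sc_ids <- names(scaffolds) %||% paste0("scaffold_", seq_along(scaffolds))

  purrr::map_dfr(seq_len(nrow(spacers)), function(si) {
    sp <- spacers$spacer[si]
    len <- nchar(sp)
    mm_allow <- floor((1 - min_identity) * len + 1e-9)
    pat_f <- Biostrings::DNAString(toupper(sp))
    pat_r <- Biostrings::reverseComplement(pat_f)
    purrr::map_dfr(seq_along(scaffolds), function(ti) {
      best <- NULL
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        m <- Biostrings::matchPattern(pat, scaffolds[[ti]],
                                      max.mismatch = mm_allow,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        mm <- purrr::map_int(seq_along(m), function(h) {
          Biostrings::neditStartingAt(pat, scaffolds[[ti]],
                                      starting.at = Biostrings::start(m)[h])
        })
        b <- which.min(mm)
        cand <- list(strand = strand, position = Biostrings::start(m)[b],
                     mismatches = mm[b])
        if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
      }
      if (is.null(best)) return(NULL)
      tibble(spacer_id = spacers$spacer_id[si], scaffold_id = sc_ids[ti],
             strand = best$strand, position = best$position,
             mismatches = best$mismatches,
             identity = (len - best$mismatches) / len)
    })
  })
}

#' Bipartite spacer-virus network with cross-ecosystem flags
#'
#' Joins protospacer matches to the ecosystems of the spacer's source array
#' and of the matched scaffold, flagging edges that cross the marine /
#' atmospheric boundary (e.g. a spacer from a marine prokaryote array
#' matching a rain-only virus).
#'
#' @param matches Tibble from [match_protospacers()].
#' @param spacer_origin Tibble: `spacer_id`, `ecosystem` (of the source
#'   array's sample).
#' @param scaffold_origin Tibble: `scaffold_id`, `ecosystem` (detection
#'   group of the virus, e.g. `rain_only`).
#' @return An edge tibble: `spacer_id`, `scaffold_id`, `identity`,
#'   `spacer_ecosystem`, `scaffold_ecosystem`, `cross_ecosystem`.
#' @export
build_spacer_network <- function(matches, spacer_origin, scaffold_origin) {
  assert_columns(spacer_origin, c("spacer_id", "ecosystem"), "spacer origin")
  assert_columns(scaffold_origin, c("scaffold_id", "ecosystem"), "scaffold origin")
  unknown <- setdiff(matches$spacer_id, spacer_origin$spacer_id)
  if (length(unknown) > 0) {
    abort(sprintf("Match references unknown spacer/array: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  side <- function(e) {
    dplyr::case_when(e %in% .MARINE ~ "marine",
                     e %in% c(.PRECIP, "aerosol", "rain_only") ~ "atmospheric",
                     TRUE ~ e)
  }
  matches %>%
    left_join(spacer_origin %>% rename(spacer_ecosystem = "ecosystem"),
              by = "spacer_id") %>%
    left_join(scaffold_origin %>% rename(scaffold_ecosystem = "ecosystem"),
              by = "scaffold_id") %>%
    mutate(cross_ecosystem = side(.data$spacer_ecosystem) !=
             side(.data$scaffold_ecosystem)) %>%
    select("spacer_id", "scaffold_id", "identity", "spacer_ecosystem",
           "scaffold_ecosystem", "cross_ecosystem")
}
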