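#' Frequency-based variant calling from pileup counts
#'
#' At every pileup column with depth at or above `min_depth`, every
#' non-reference base whose frequency and count clear the floors is emitted
#' as a substitution call. The reference base comes from the scaffold
#' sequence, not the pileup majority. Thresholds are explicit and
#' conservative; indels are out of scope.
#'
#' @param pileup Tibble: `scaffold`, `pos` (1-based), `A`, `C`, `G`, `T`
#'   counts, optionally `sample_id`.
#' @param reference Named character vector or [Biostrings::DNAStringSet]
#'   with the scaffold sequence(s).
#' @param min_depth Minimum column depth (default 10).
#' @param min_alt_freq Minimum alternate-base frequency (default 0.1).
#' @param min_alt_count Minimum alternate-base count (default 4).
#' @return A tibble: (`sample_id`,) `scaffold`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `alt_freq`.
#' @export
call_variants <- function(pileup, reference, min_depth = 10,
                          min_alt_freq = 0.1, min_alt_count = 4) {
  assert_columns(pileup, c("scaffold", "pos", "A", "C", "G", "T"), "pileup")
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(toupper(reference))
  }
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(pileup[, bases])
  if (any(counts < 0)) abort("Negative base counts in pileup.")
  depth <- rowSums(counts)
  if ("depth" %in% names(pileup) && any(pileup$depth != depth)) {
    abort("Pileup depth column inconsistent with base counts.")
  }
  ref_seq <- purrr::map_chr(seq_len(nrow(pileup)), function(i) {
    sc <- pileup$scaffold[i]
    if (!sc %in% names(reference)) abort(sprintf("Unknown scaffold: %s", sc))
    as.character(Biostrings::subseq(reference[[sc]], pileup$pos[i], pileup$pos[i]))
  })
  keys <- intersect("sample_id", names(pileup))
  out <- purrr::map_dfr(seq_len(nrow(pileup)), function(i) {
    if (depth[i] < min_depth) return(NULL)
    alt <- setdiff(bases, ref_seq[i])
    cnt <- counts[i, alt]
    frq <- cnt / depth[i]
    sel <- cnt >= min_alt_count & frq >= min_alt_freq
    if (!any(sel)) return(NULL)
    row <- tibble(scaffold = pileup$scaffold[i], pos = pileup$pos[i],
                  ref = ref_seq[i], alt = alt[sel],
                  alt_count = unname(cnt[sel]), depth = depth[i],
                  alt_freq = unname(frq[sel]))
    if (length(keys)) row$sample_id <- pileup$sample_id[i]
    row
  })
  if (nrow(out) == 0) {
    out <- tibble(scaffold = character(), pos = integer(), ref = character(),
                  alt = character(), alt_count = integer(), depth = integer(),
                  alt_freq = double())
    if (length(keys)) out$sample_id <- character()
  }
  out %>% arrange(.data$scaffold, .data$pos)
}

#' Variant-site overlap between samples
#'
#' A variant site is shared between samples when position and alternate
#' base are identical on the same scaffold. Returns Venn region counts over
#' the given samples and a per-site membership table.
#'
#' @param calls A variant-call tibble with `sample_id`, `scaffold`, `pos`,
#'   `alt` (e.g. from [call_variants()] run per sample and row-bound).
#' @param samples Character vector of sample ids to intersect (default: all
#'   in `calls`).
#' @return A list: `$regions` (tibble with one logical membership column per
#'   sample, `region`, `count`) and `$sites` (tibble `scaffold`, `pos`,
#'   `alt`, one logical column per sample, `n_samples`).
#' @export
overlap_variants <- function(calls, samples = NULL) {
  assert_columns(calls, c("sample_id", "scaffold", "pos", "alt"), "variant calls")
  if (length(unique(calls$scaffold)) > 1) {
    abort("Variant overlap requires calls on a single scaffold coordinate system.")
  }
  samples <- samples %||% sort(unique(calls$sample_id))
  calls <- calls %>% filter(.data$sample_id %in% samples)
  sites <- calls %>%
    distinct(.data$sample_id, .data$scaffold, .data$pos, .data$alt) %>%
    mutate(present = TRUE) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "present",
                       values_fill = FALSE)
  for (s in setdiff(samples, names(sites))) sites[[s]] <- FALSE
  sites <- sites %>%
    mutate(n_samples = rowSums(as.matrix(sites[, samples, drop = FALSE]))) %>%
    arrange(.data$pos, .data$alt)

  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(samples)))
  names(grid) <- samples
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  key <- apply(as.matrix(sites[, samples, drop = FALSE]), 1, paste, collapse = ".")
  gkey <- apply(as.matrix(grid), 1, paste, collapse = ".")
  counts <- table(factor(key, levels = gkey))
  regions <- as_tibble(grid) %>%
    mutate(region = purrr::map_chr(seq_len(nrow(grid)), function(i) {
      paste(samples[unlist(grid[i, ])], collapse = "&")
    }),
    count = as.integer(counts))
  list(regions = regions, sites = sites)
}
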