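#' Read a per-base depth table
#'
#' Three-column TSV as emitted by common depth tools: target id, 1-based
#' position, depth, no header. Positions absent from the table are depth 0.
#' An optional fourth column `sample_id` extends the dialect to multi-sample
#' tables.
#'
#' @param path Path to the TSV.
#' @return A tibble with `target_id`, `pos`, `depth` (and `sample_id` if
#'   present in the file).
#' @export
read_depth_table <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) abort("Depth table needs >= 3 columns: target, pos, depth.")
  names(raw)[1:3] <- c("target_id", "pos", "depth")
  if (ncol(raw) >= 4) names(raw)[4] <- "sample_id"
  raw %>% mutate(pos = as.integer(.data$pos), depth = as.numeric(.data$depth))
}

#' Read a minimal SAM alignment subset
#'
#' Parses the plain-text SAM fields needed for identity-filtered coverage:
#' target, 1-based position, CIGAR (aligned length = sum of M/=/X; soft
#' clips excluded), and the NM edit-distance tag. Unmapped records and
#' header lines are dropped.
#'
#' @param path Path to a SAM file.
#' @return An alignment tibble: `read_id`, `target_id`, `start`, `end`,
#'   `aligned_length`, `edit_distance`, `identity`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), target_id = character(),
                  start = integer(), end = integer(),
                  aligned_length = integer(), edit_distance = integer(),
                  identity = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  recs <- purrr::map_dfr(fields, function(f) {
    if (f[3] == "*") return(NULL)
    cig <- f[6]
    ops <- stringr::str_match_all(cig, "(\\d+)([MIDNSHP=X])")[[1]]
    len <- as.integer(ops[, 2])
    op <- ops[, 3]
    aln <- sum(len[op %in% c("M", "=", "X")])
    ref_span <- sum(len[op %in% c("M", "=", "X", "D", "N")])
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    nm <- if (length(nm_tag)) as.integer(sub("^NM:i:", "", nm_tag[1])) else NA_integer_
    start <- as.integer(f[4])
    tibble(read_id = f[1], target_id = f[3], start = start,
           end = start + ref_span - 1L, aligned_length = aln,
           edit_distance = nm)
  })
  recs %>% mutate(identity = (.data$aligned_length - .data$edit_distance) /
                    .data$aligned_length)
}

#' Remove reads that mapped to negative controls
#'
#' Any alignment whose read id occurs in the control hit set is dropped;
#' the removal count is reported via a message. An empty set is valid.
#'
#' @param alignments An alignment tibble with a `read_id` column.
#' @param control_read_ids Character vector of read ids seen in control
#'   assemblies.
#' @return The filtered alignment tibble.
#' @export
subtract_control_reads <- function(alignments, control_read_ids) {
  assert_columns(alignments, "read_id", "alignment table")
  hit <- alignments$read_id %in% control_read_ids
  if (all(hit) && nrow(alignments) > 0) {
    warn("All alignments matched the control read set; output is empty.")
  } else if (any(hit)) {
    message(sprintf("Removed %d control-matching alignment(s).", sum(hit)))
  }
  alignments[!hit, , drop = FALSE]
}

#' Filter alignments by read identity
#'
#' Keeps records whose identity, defined as
#' (aligned_length - edit_distance) / aligned_length over the aligned
#' portion (soft clips excluded), is at least `min_identity`. The threshold
#' is inclusive, matching the "at least 90% identical" mapping contract.
#'
#' @param alignments Alignment tibble; `identity` is computed from
#'   `aligned_length` and `edit_distance` when absent.
#' @param min_identity Identity floor in (0, 1]; default 0.90.
#' @return The filtered tibble, with an `identity` column.
#' @export
filter_by_identity <- function(alignments, min_identity = 0.90) {
  assert_fraction(min_identity, "min_identity")
  if (!"identity" %in% names(alignments)) {
    assert_columns(alignments, c("aligned_length", "edit_distance"),
                   "alignment table")
    if (anyNA(alignments$edit_distance)) {
      abort("Records lacking edit distance cannot be identity-filtered.")
    }
    alignments <- alignments %>%
      mutate(identity = (.data$aligned_length - .data$edit_distance) /
               .data$aligned_length)
  }
  alignments %>% filter(.data$identity >= min_identity)
}

#' Coverage breadth and mean depth per target
#'
#' Builds per-target coverage summaries from either identity-filtered
#' alignment spans (columns `target_id`, `start`, `end`) or a per-base depth
#' table (columns `target_id`, `pos`, `depth`). Breadth is the fraction of
#' positions covered by at least one read; mean depth is total depth over
#' target length. A `sample_id` column, when present, is kept as a grouping
#' dimension.
#'
#' @param x Alignment or depth tibble.
#' @param target_lengths Named numeric vector, or tibble with `target_id`
#'   and `length`, giving target lengths in bp.
#' @return A tibble: (`sample_id`,) `target_id`, `length`, `covered_bp`,
#'   `breadth`, `mean_depth`.
#' @export
coverage_profile <- function(x, target_lengths) {
  lens <- if (is.data.frame(target_lengths)) {
    setNames(target_lengths$length, target_lengths$target_id)
  } else {
    target_lengths
  }
  assert_columns(x, "target_id", "coverage input")
  unknown <- setdiff(unique(x$target_id), names(lens))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown target(s) in coverage input: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  has_sample <- "sample_id" %in% names(x)
  keys <- if (has_sample) c("sample_id", "target_id") else "target_id"
  from_depth <- all(c("pos", "depth") %in% names(x))

  if (from_depth) {
    bad <- x$pos < 1 | x$pos > lens[x$target_id]
    if (any(bad)) abort("Depth table positions exceed target length.")
    if (any(x$depth < 0)) abort("Depths must be nonnegative.")
    prof <- x %>%
      group_by(across(dplyr::all_of(keys))) %>%
      summarise(covered_bp = sum(.data$depth >= 1),
                total_depth = sum(.data$depth), .groups = "drop")
  } else {
    assert_columns(x, c("start", "end"), "alignment coverage input")
    prof <- x %>%
      group_by(across(dplyr::all_of(keys))) %>%
      summarise(
        covered_bp = {
          L <- lens[.data$target_id[1]]
          ir <- IRanges::IRanges(start = pmax(.data$start, 1L),
                                 end = pmin(.data$end, as.integer(L)))
          sum(IRanges::width(IRanges::reduce(ir)))
        },
        total_depth = {
          L <- lens[.data$target_id[1]]
          sum(pmin(.data$end, L) - pmax(.data$start, 1) + 1)
        },
        .groups = "drop"
      )
  }
  prof %>%
    mutate(length = unname(lens[.data$target_id]),
           breadth = .data$covered_bp / .data$length,
           mean_depth = .data$total_depth / .data$length) %>%
    select(dplyr::all_of(keys), "length", "covered_bp", "breadth", "mean_depth")
}

#' Presence calls from coverage breadth
#'
#' A viral scaffold counts as present in a sample if at least 75% of its
#' genome is covered by reads at >= 90% identity (the breadth definition
#' already implies >= 1x depth on covered positions); a MAG counts as
#' present at >= 90% breadth under the 2%-error mapping contract. Both
#' thresholds are inclusive.
#'
#' @param profiles A coverage profile tibble (see [coverage_profile()]).
#' @param min_breadth Breadth threshold in (0, 1].
#' @return The profile tibble with a logical `present` column.
#' @export
call_viral_presence <- function(profiles, min_breadth = 0.75) {
  assert_fraction(min_breadth, "min_breadth")
  assert_columns(profiles, "breadth", "coverage profile")
  profiles %>% mutate(present = .data$breadth >= min_breadth)
}

#' @rdname call_viral_presence
#' @export
call_mag_presence <- function(profiles, min_breadth = 0.90) {
  call_viral_presence(profiles, min_breadth = min_breadth)
}

#' Sum-normalize a coverage matrix by sequencing depth
#'
#' Divides each sample's mean-coverage values by the sample's library size
#' (reads sequenced) and rescales to a per-million convention. Normalization
#' is linear per sample, so within-sample rankings are preserved and
#' cross-sample ratios are scale-invariant.
#'
#' @param abundance Tibble with `target_id`, `sample_id`, `mean_depth` (or a
#'   `value` column).
#' @param library_sizes Named numeric vector of reads per sample.
#' @param scale Per-sample scale factor (default 1e6).
#' @return The tibble with a `normalized` column.
#' @export
normalize_coverage <- function(abundance, library_sizes, scale = 1e6) {
  assert_columns(abundance, "sample_id", "abundance matrix")
  val_col <- if ("mean_depth" %in% names(abundance)) "mean_depth" else "value"
  assert_columns(abundance, val_col, "abundance matrix")
  missing <- setdiff(unique(abundance$sample_id), names(library_sizes))
  if (length(missing) > 0) {
    abort(sprintf("No library size for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(library_sizes <= 0)) {
    bad <- names(library_sizes)[library_sizes <= 0]
    abort(sprintf("Library size must be > 0 (sample %s).", bad[1]))
  }
  abundance %>%
    mutate(normalized = .data[[val_col]] /
             unname(library_sizes[.data$sample_id]) * scale)
}
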