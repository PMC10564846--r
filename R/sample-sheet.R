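#' Read and validate a sample sheet
#'
#' The sample sheet is a TSV with one row per metagenome sample and fixed
#' header names: `sample_id`, `ecosystem`, `fraction`, `station`, `date`, and
#' optionally `volume` and `volume_unit`. Unknown extra columns are preserved
#' but ignored by downstream stages. Ecosystems follow the study vocabulary:
#' `foam`, `SML` (surface microlayer), `SSW` (1-m subsurface water),
#' `aerosol`, `rain`, `snow`, and `control`. Control samples are carried
#' through with `excluded = TRUE` and never contribute to occupancy or
#' abundance outputs.
#'
#' @param path Path to a tab-separated sample sheet with a header line.
#' @return A tibble with one row per sample, the validated columns above,
#'   logical flags `marine` (foam/SML/SSW), `precipitation` (rain/snow), and
#'   `excluded` (controls), in file order.
#' @export
#' @examples
#' sheet <- tibble::tibble(
#'   sample_id = c("s1", "s2"), ecosystem = c("SML", "rain"),
#'   fraction = c("um5_02", "virome_lt02um"), station = c("1", NA),
#'   date = c("2020-02-03", "2020-02-10")
#' )
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(sheet, tf)
#' read_sample_sheet(tf)
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("Sample sheet not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_sample_sheet(raw)
}

#' Validate an in-memory sample sheet
#'
#' @param sheet A data frame with at least `sample_id`, `ecosystem`,
#'   `fraction`, `station`, `date`.
#' @return The validated tibble (see [read_sample_sheet()]).
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  assert_columns(sheet, c("sample_id", "ecosystem", "fraction", "station", "date"),
                 "sample sheet")
  bad_eco <- setdiff(unique(sheet$ecosystem), .ECOSYSTEMS)
  if (length(bad_eco) > 0) {
    abort(sprintf("Unknown ecosystem value(s): %s (allowed: %s)",
                  paste(bad_eco, collapse = ", "),
                  paste(.ECOSYSTEMS, collapse = ", ")))
  }
  frac <- ifelse(is.na(sheet$fraction) | sheet$fraction == "", "na", sheet$fraction)
  bad_frac <- setdiff(unique(frac), .FRACTIONS)
  if (length(bad_frac) > 0) {
    abort(sprintf("Unknown fraction value(s): %s (allowed: %s)",
                  paste(bad_frac, collapse = ", "),
                  paste(.FRACTIONS, collapse = ", ")))
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate sample_id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  sheet %>%
    mutate(
      fraction = frac,
      marine = .data$ecosystem %in% .MARINE,
      precipitation = .data$ecosystem %in% .PRECIP,
      excluded = .data$ecosystem == "control"
    )
}

#' Write a sample sheet
#'
#' Strict writer for the tolerant reader: fixed column order, tab-separated,
#' '.' decimal separator.
#'
#' @param sheet A validated sample sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  core <- c("sample_id", "ecosystem", "fraction", "station", "date")
  extra <- setdiff(names(sheet), c(core, "marine", "precipitation", "excluded"))
  readr::write_tsv(sheet[, c(core, extra)], path)
  invisible(path)
}
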