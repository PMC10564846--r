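#' Read a station count table
#'
#' Reads a CSV of flow-cytometry concentrations per station and compartment:
#' virus-like particles (`vlp_*`), prokaryotes (`prok_*`) and small
#' phototrophic eukaryotes (`euk_*`) for the compartments foam, SML, SSW and
#' precipitation (`prc`). Cells marked `n.d.` (not determined) become `NA`.
#' Columns prefixed `printed_` carry the display values of the source table
#' (EFs rounded to one decimal, virus-host ratios to one decimal) and are
#' optional.
#'
#' A station table from a Skagerrak winter field campaign ships with the
#' package:
#' `system.file("extdata", "station_counts.csv", package = "aerovirome")`.
#'
#' @param path Path to the CSV.
#' @return A tibble, one row per station/date, concentrations as numerics.
#' @export
read_station_counts <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("n.d.", "NA", ""))
  assert_columns(raw, c("station", "date", "vlp_sml", "vlp_ssw",
                        "prok_sml", "prok_ssw", "euk_sml", "euk_ssw"),
                 "station count table")
  num_cols <- setdiff(names(raw), c("station", "date"))
  raw %>% mutate(across(dplyr::all_of(num_cols), as.numeric))
}

#' Compute SML/SSW enrichment factors for a station table
#'
#' One row per station and specimen (vlp, prok, euk) with the raw EF and its
#' one-decimal display value (half-up rounding, the table presentation
#' convention).
#'
#' @param counts A station count tibble (see [read_station_counts()]).
#' @return A tibble: `station`, `date`, `specimen`, `sml`, `ssw`, `ef`,
#'   `ef_display`.
#' @export
station_ef_table <- function(counts) {
  purrr::map_dfr(c("vlp", "prok", "euk"), function(sp) {
    sml <- counts[[paste0(sp, "_sml")]]
    ssw <- counts[[paste0(sp, "_ssw")]]
    res <- enrichment_factor(sml, ssw)
    tibble(station = counts$station, date = counts$date, specimen = sp,
           sml = sml, ssw = ssw, ef = res$ef, ef_display = res$ef_display)
  })
}

#' Compute virus-host ratios for a station table
#'
#' VLP / prokaryote ratios per compartment (foam, SML, SSW, precipitation),
#' long format.
#'
#' @param counts A station count tibble.
#' @return A tibble: `station`, `date`, `compartment`, `vlp`, `prok`, `ratio`.
#' @export
station_ratio_table <- function(counts) {
  comps <- c(foam = "foam", sml = "sml", ssw = "ssw", prc = "prc")
  purrr::map_dfr(names(comps), function(cp) {
    vcol <- paste0("vlp_", cp); pcol <- paste0("prok_", cp)
    if (!vcol %in% names(counts)) return(NULL)
    tibble(station = counts$station, date = counts$date, compartment = cp,
           vlp = counts[[vcol]], prok = counts[[pcol]],
           ratio = virus_host_ratio(counts[[vcol]], counts[[pcol]]))
  })
}

#' Summarise concentration ranges per specimen and compartment
#'
#' @param counts A station count tibble.
#' @return A tibble with `specimen`, `compartment`, `n`, `min`, `max`.
#' @export
summarize_station_counts <- function(counts) {
  long <- counts %>%
    tidyr::pivot_longer(
      cols = dplyr::matches("^(vlp|prok|euk)_(foam|sml|ssw|prc)$"),
      names_to = c("specimen", "compartment"), names_sep = "_",
      values_to = "value"
    ) %>%
    filter(!is.na(.data$value))
  long %>%
    group_by(.data$specimen, .data$compartment) %>%
    summarise(n = dplyr::n(), min = min(.data$value), max = max(.data$value),
              .groups = "drop")
}
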