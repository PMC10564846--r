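#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its study default, a
#' global seed, and optional input paths. Fractional thresholds live in
#' (0, 1]. The defaults encode the detection and linkage contract used
#' throughout: reads at >= 90% identity, viral presence at >= 75% genome
#' breadth, MAG presence at >= 90% breadth, d2* host assignment at <= 0.3,
#' protospacer matches at >= 80% identity, CRISPR direct repeats matched with
#' <= 3 mismatches and spacers of 20-60 bp, marine loading where surface wind
#' exceeds 3 m s^-1 inside the mixing layer, scored over the first 96 h of
#' 5-day backward trajectories.
#'
#' @param min_identity Read identity floor for viral mapping (default 0.90).
#' @param viral_breadth Breadth threshold for viral presence (default 0.75).
#' @param mag_breadth Breadth threshold for MAG presence (default 0.90).
#' @param mag_identity Read identity floor for MAG mapping (default 0.98,
#'   i.e. a 2% error allowance).
#' @param d2star_threshold d2* cutoff for host assignment (default 0.3).
#' @param protospacer_identity Spacer-protospacer identity floor (default 0.80).
#' @param spacer_len Length window for retained spacers (default c(20, 60)).
#' @param dr_mismatches Maximum Hamming mismatches for direct-repeat hits
#'   (default 3).
#' @param max_spacer_len Maximum extracted spacer length (default 60).
#' @param loading_wind Wind threshold in m s^-1, exceeded strictly, for
#'   loading conditions (default 3).
#' @param trajectory_window Scoring window in hours before arrival (default 96).
#' @param loading_requires_sea Should loading additionally require the point
#'   to be over sea? Default `FALSE`: the two stated criteria only.
#' @param precipitation Ecosystems grouped as precipitation
#'   (default c("rain", "snow")).
#' @param catalog_size Denominator for shared-fraction percentages; `NULL`
#'   means the number of catalogued scaffolds in the run.
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @param paths Named list of input paths (optional; synthetic runs need none).
#' @return A list of class `virome_config`.
#' @export
virome_config <- function(min_identity = 0.90,
                          viral_breadth = 0.75,
                          mag_breadth = 0.90,
                          mag_identity = 0.98,
                          d2star_threshold = 0.3,
                          protospacer_identity = 0.80,
                          spacer_len = c(20, 60),
                          dr_mismatches = 3,
                          max_spacer_len = 60,
                          loading_wind = 3,
                          trajectory_window = 96,
                          loading_requires_sea = FALSE,
                          precipitation = c("rain", "snow"),
                          catalog_size = NULL,
                          seed = 1L,
                          paths = list()) {
  for (nm in c("min_identity", "viral_breadth", "mag_breadth", "mag_identity",
               "d2star_threshold", "protospacer_identity")) {
    assert_fraction(get(nm), nm)
  }
  stopifnot(length(spacer_len) == 2, spacer_len[1] <= spacer_len[2],
            dr_mismatches >= 0, loading_wind > 0, trajectory_window >= 1)
  cfg <- list(
    min_identity = min_identity, viral_breadth = viral_breadth,
    mag_breadth = mag_breadth, mag_identity = mag_identity,
    d2star_threshold = d2star_threshold,
    protospacer_identity = protospacer_identity,
    spacer_len = as.numeric(spacer_len), dr_mismatches = dr_mismatches,
    max_spacer_len = max_spacer_len, loading_wind = loading_wind,
    trajectory_window = trajectory_window,
    loading_requires_sea = loading_requires_sea,
    precipitation = precipitation, catalog_size = catalog_size,
    seed = as.integer(seed), paths = paths
  )
  structure(cfg, class = "virome_config")
}

#' @export
print.virome_config <- function(x, ...) {
  cat("<virome_config>\n")
  for (nm in setdiff(names(x), "paths")) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  if (length(x$paths)) cat("  paths:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config A `virome_config`.
#' @param path File path.
#' @return `read_virome_config()` returns the restored `virome_config`.
#' @export
write_virome_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_virome_config
#' @export
read_virome_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$paths <- as.list(raw$paths)
  do.call(virome_config, raw)
}
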