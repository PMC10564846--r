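#' Run the full dispersal analysis on synthetic or file inputs
#'
#' Orchestrates every stage — presence detection, cross-ecosystem
#' dispersal synthesis, virus-host linkage (d2* and CRISPR), variant
#' overlap, trajectory scoring, INP estimation, and station field
#' statistics — into one reproducible run. Without input paths in the
#' configuration the pipeline runs in synthetic mode: the generators
#' produce a ground-truth-bearing study at the configured seed, and the
#' bundle carries the truth tables alongside the results. Per-stage seeds
#' derive deterministically from the global seed, so identical
#' configurations reproduce identical outputs.
#'
#' @param config A [virome_config()].
#' @param n_viral,n_host Synthetic community size (defaults 20 and 4).
#' @param sheet Sample sheet tibble; default [sim_sample_sheet()].
#' @return A list of class `virome_report` with one element per stage and a
#'   `manifest` tibble (stage, rows) plus `config_hash` and `seed`.
#' @export
run_virome_pipeline <- function(config = virome_config(), n_viral = 20,
                                n_host = 4, sheet = sim_sample_sheet()) {
  synthetic <- length(config$paths) == 0
  if (!synthetic && is.null(config$paths$depth) && is.null(config$paths$alignments)) {
    abort("Configuration error: detection enabled but no depth/alignment input given.")
  }
  if (!synthetic) {
    abort("File-based runs are assembled from the exported stage functions; see the vignette. `run_virome_pipeline()` orchestrates the synthetic study.")
  }
  sheet <- validate_sample_sheet(sheet)
  seed_of <- function(stage) derive_seed(config$seed, stage)

  # Stage 1: community genomes
  gen <- sim_genomes(n_viral = n_viral, n_host = n_host, seed = seed_of("genomes"))

  # Stage 2: coverage and presence detection
  design <- sim_coverage_design(gen$truth, sheet, seed = seed_of("design"))
  cov <- sim_read_coverage(gen$viruses, design, seed = seed_of("coverage"))
  aln <- subtract_control_reads(cov$alignments, cov$control_read_ids)
  aln <- filter_by_identity(aln, config$min_identity)
  profiles <- coverage_profile(aln, cov$target_lengths)
  presence <- call_viral_presence(profiles, config$viral_breadth)

  # Stage 3: dispersal synthesis
  occ <- occupancy_matrix(presence, sheet)
  ecos <- setdiff(names(occ), "target_id")
  venn <- ecosystem_venn(occ, intersect(c("foam", "SML", "SSW"), ecos))
  exclusive <- purrr::map(setNames(ecos, ecos), ~ exclusive_viruses(occ, .x))
  total <- config$catalog_size %||% n_viral
  shared <- shared_fraction(occ, intersect(config$precipitation, ecos),
                            intersect(.MARINE, ecos), total = total)
  lib_sizes <- table(cov$alignments$sample_id)
  lib_sizes <- setNames(as.numeric(lib_sizes), names(lib_sizes))
  abundance <- profiles %>%
    select("sample_id", "target_id", "mean_depth") %>%
    normalize_coverage(lib_sizes)
  ratios <- enrichment_ratios(abundance, sheet,
                              presence = presence %>%
                                select("sample_id", "target_id", "present"))
  gc_tab <- gc_detection_groups(occ, gen$viruses)
  gc_test <- if (length(unique(gc_tab$group)) >= 2) {
    compare_groups_kw_dunn(gc_tab, .data$gc_percent, .data$group)
  } else NULL

  # Stage 4: d2* virus-host linkage
  links <- assign_hosts(gen$viruses, gen$hosts,
                        threshold = config$d2star_threshold)

  # Stage 5: CRISPR spacers
  cr <- sim_crispr_reads(gen$viruses, n_spacers = 6,
                         divergence = c(0, 0, 0.1, 0.1, 0.2, 0.2),
                         seed = seed_of("crispr"))
  spacers_raw <- extract_spacers(cr$reads, cr$dr,
                                 max_mismatch = config$dr_mismatches,
                                 max_spacer_len = config$max_spacer_len)
  spacers <- filter_and_cluster_spacers(spacers_raw,
                                        min_len = config$spacer_len[1],
                                        max_len = config$spacer_len[2])
  matches <- if (nrow(spacers) > 0) {
    match_protospacers(spacers, gen$viruses,
                       min_identity = config$protospacer_identity)
  } else NULL

  # Stage 6: variant overlap on the first shared virus
  cand <- gen$truth$virus_id[gen$truth$class == "shared"]
  variant <- NULL
  if (length(cand) > 0) {
    vp <- sim_variant_pileups(gen$viruses[cand[1]],
                              samples = c("foam_1_02", "aerosol_1", "rain_1_02"),
                              seed = seed_of("variants"))
    calls <- call_variants(vp$pileups, gen$viruses[cand[1]])
    variant <- list(calls = calls, overlap = overlap_variants(calls),
                    truth = vp$truth)
  }

  # Stage 7: trajectories for the two rain events
  tj1 <- sim_trajectories(10, sea_frac = 0.64, loading_frac = 0.10,
                          event = "event_1", seed = seed_of("tj1"))
  tj2 <- sim_trajectories(10, sea_frac = 0.72, loading_frac = 0.35,
                          event = "event_2", seed = seed_of("tj2"))
  tj_pts <- classify_points(bind_rows(tj1$points, tj2$points),
                            loading_wind = config$loading_wind,
                            loading_requires_sea = config$loading_requires_sea)
  tj_summary <- event_summary(tj_pts, window_hours = config$trajectory_window)

  # Stage 8: ice-nucleating particles
  spec_grid <- tibble(temp_c = seq(-4, -15, by = -0.1))
  spec_grid$lambda <- 0.5 * exp(0.45 * (-4 - spec_grid$temp_c)) - 0.5
  fa <- sim_freezing_assay(spec_grid, wells = 24, n_assays = 1,
                           seed = seed_of("inp"))
  inp <- inp_spectrum(fa$assays %>% select("temp_c", "frozen"),
                      total_wells = 24, v_filtered_ml = 500)

  # Stage 9: station field statistics
  ct <- sim_count_table(n_stations = 10, seed = seed_of("counts"))
  ef <- station_ef_table(ct$counts)
  vh <- station_ratio_table(ct$counts)
  corr <- correlate(ct$counts, .data$euk_sml, .data$vlp_sml, method = "pearson")

  bundle <- list(
    sheet = sheet, genomes = gen, presence = presence, occupancy = occ,
    venn = venn, exclusive = exclusive, shared = shared, abundance = abundance,
    enrichment = ratios, gc_table = gc_tab, gc_test = gc_test,
    host_links = links, crispr = list(truth = cr$truth, spacers = spacers,
                                      matches = matches),
    variants = variant,
    trajectories = list(points = tj_pts, summary = tj_summary,
                        truth = bind_rows(tj1$truth, tj2$truth)),
    inp = list(assays = fa$assays, spectrum = inp, truth = fa$truth),
    field = list(counts = ct$counts, ef = ef, ratios = vh, correlation = corr)
  )
  bundle$manifest <- build_manifest(bundle, config)
  structure(bundle, class = "virome_report")
}

#' Per-virus G/C content by detection group
#'
#' Assigns each virus its single catalog G/C percentage once per group it
#' is detected in (rain_total, rain_only, aerosol, foam, SML, SSW);
#' rain_only is the exclusive subset of rain_total.
#'
#' @param occupancy Occupancy matrix (see [occupancy_matrix()]).
#' @param sequences Named [Biostrings::DNAStringSet] of the scaffolds.
#' @return A tibble: `target_id`, `group`, `gc_percent`.
#' @export
gc_detection_groups <- function(occupancy, sequences) {
  gc <- setNames(gc_percent(sequences), names(sequences))
  ecos <- setdiff(names(occupancy), "target_id")
  groups <- purrr::map_dfr(ecos, function(e) {
    ids <- occupancy$target_id[occupancy[[e]]]
    if (length(ids) == 0) return(NULL)
    grp <- if (e == "rain") "rain_total" else e
    tibble(target_id = ids, group = grp)
  })
  if ("rain" %in% ecos) {
    ro <- exclusive_viruses(occupancy, "rain")
    if (length(ro) > 0) {
      groups <- bind_rows(groups, tibble(target_id = ro, group = "rain_only"))
    }
  }
  groups %>% mutate(gc_percent = unname(gc[.data$target_id]))
}

build_manifest <- function(bundle, config) {
  count_rows <- function(x) {
    if (is.data.frame(x)) nrow(x)
    else if (is.list(x)) sum(purrr::map_int(x, count_rows))
    else 0L
  }
  stages <- c("presence", "occupancy", "venn", "enrichment", "gc_table",
              "host_links", "crispr", "variants", "trajectories", "inp",
              "field")
  manifest <- tibble(
    stage = stages,
    rows = purrr::map_int(stages, ~ count_rows(bundle[[.x]]))
  )
  attr(manifest, "config_hash") <- rlang::hash(unclass(config))
  attr(manifest, "seed") <- config$seed
  manifest
}

#' @export
print.virome_report <- function(x, ...) {
  cat("<virome_report>\n")
  cat(sprintf("  %d viruses, %d samples (%d excluded controls)\n",
              nrow(x$genomes$truth), nrow(x$sheet), sum(x$sheet$excluded)))
  cat(sprintf("  presence calls: %d; shared precipitation/marine: %s%%\n",
              sum(x$presence$present), format(x$shared$percent_display)))
  cat(sprintf("  host links: %d; spacer matches: %d\n",
              nrow(x$host_links),
              if (is.null(x$crispr$matches)) 0L else nrow(x$crispr$matches)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each tabular section as a TSV ('.' decimal separator, no locale
#' dependence, shortest-round-trip numeric representation) plus a JSON
#' summary with per-section row counts, the configuration hash, and the
#' seed. Re-running an identical configuration reproduces byte-identical
#' files.
#'
#' @param bundle A `virome_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_virome_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory: %s", dir))
  tables <- list(
    presence = bundle$presence, occupancy = bundle$occupancy,
    venn = bundle$venn, enrichment = bundle$enrichment,
    gc_table = bundle$gc_table, host_links = bundle$host_links,
    spacer_matches = bundle$crispr$matches,
    variant_sites = bundle$variants$overlap$sites,
    trajectory_events = bundle$trajectories$summary$events,
    inp_spectrum = bundle$inp$spectrum,
    station_ef = bundle$field$ef
  )
  paths <- character()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb) || nrow(tb) == 0) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, p)
    paths <- c(paths, p)
  }
  summary <- list(
    sections = purrr::map(tables, ~ if (is.null(.x)) 0L else nrow(.x)),
    config_hash = attr(bundle$manifest, "config_hash"),
    seed = attr(bundle$manifest, "seed"),
    manifest = bundle$manifest
  )
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
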