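# Synthetic-data generators. Every generator takes an explicit seed and is
# fully deterministic given it; every generated entity is described in a
# returned truth table so downstream stages can be scored against ground
# truth.

BASES <- c("A", "C", "G", "T")

# Sample one sequence from an order-o Markov chain over A/C/G/T.
# trans: 4^o x 4 matrix of conditional probabilities (contexts in
# lexicographic order, first base most significant); init: length-4
# marginal for the first o bases.
sample_markov_chain <- function(trans, o, length, init) {
  stopifnot(nrow(trans) == 4^o)
  cum <- t(apply(trans, 1, cumsum))
  init_cum <- cumsum(init)
  s <- integer(length)
  u <- runif(length)
  for (i in seq_len(o)) {
    s[i] <- (u[i] > init_cum[1]) + (u[i] > init_cum[2]) + (u[i] > init_cum[3])
  }
  ctx <- 0L
  for (i in seq_len(o)) ctx <- ctx * 4L + s[i]
  mod <- 4L^(o - 1)
  for (i in (o + 1):length) {
    row <- cum[ctx + 1L, ]
    b <- (u[i] > row[1]) + (u[i] > row[2]) + (u[i] > row[3])
    s[i] <- b
    ctx <- (ctx %% mod) * 4L + b
  }
  paste(BASES[s + 1L], collapse = "")
}

# A random order-o chain whose every conditional distribution carries
# exactly `gc` probability mass on G+C, so the realized G/C content
# concentrates tightly on the target. `signal` controls how idiosyncratic
# the within-class splits are (higher = more distinctive genome signature).
random_gc_chain <- function(gc, o, signal) {
  n_ctx <- 4^o
  a <- max(0.05, 2 / signal)
  g_share <- stats::rbeta(n_ctx, a, a)
  a_share <- stats::rbeta(n_ctx, a, a)
  cbind(
    (1 - gc) * a_share,        # A
    gc * (1 - g_share),        # C
    gc * g_share,              # G
    (1 - gc) * (1 - a_share)   # T
  )
}

# G/C-preserving point mutations: swap A<->T and C<->G at `rate`.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(v)) < rate
  swap <- c(A = "T", C = "G", G = "C", T = "A")
  v[hit] <- swap[v[hit]]
  paste(v, collapse = "")
}

#' Simulate viral and host genomes with controllable composition
#'
#' Hosts are order-3 Markov chains whose conditional distributions carry a
#' fixed G+C probability mass, giving each host a distinctive composition
#' signature at a controlled G/C content. Each virus is sampled from its
#' assigned host's chain and then perturbed with G/C-preserving point
#' mutations, so the virus shares its host's higher-order word composition
#' — the signal d2* (word length 6, order-2 background) exploits — while
#' the realized G/C stays within 0.02 of target. Viruses fall in three
#' classes: a marine core (occupying foam, SML and SSW), a small subset
#' shared with aerosols and rain, and a rain-only subset with elevated G/C.
#'
#' @param n_viral,n_host Number of viral scaffolds and host genomes (>= 1).
#' @param class_fractions Named fractions for classes `marine`, `shared`,
#'   `rain_only` (summing to 1).
#' @param gc_marine Range of G/C targets for marine-class viruses/hosts.
#' @param gc_rain_only G/C target for rain-only viruses and their hosts.
#' @param k_signal Composition-signature strength (higher = more
#'   distinctive hosts; default 5).
#' @param length_range Viral genome length range in bp (default 10-50 kb).
#' @param host_length Host genome length in bp (default 40 kb).
#' @param mutation_rate Per-base G/C-preserving mutation rate applied to
#'   viruses (default 0.05).
#' @param seed Integer seed.
#' @return A list: `$viruses`, `$hosts` (named [Biostrings::DNAStringSet]),
#'   `$truth` (tibble: `virus_id`, `class`, `host_id`, `gc_target`,
#'   `gc_realized`, `length`, and the true ecosystem occupancy as a
#'   comma-separated `occupancy` string), `$host_truth`.
#' @export
sim_genomes <- function(n_viral = 20, n_host = 4,
                        class_fractions = c(marine = 0.55, shared = 0.2,
                                            rain_only = 0.25),
                        gc_marine = c(0.35, 0.47), gc_rain_only = 0.60,
                        k_signal = 5, length_range = c(10000, 50000),
                        host_length = 40000, mutation_rate = 0.05,
                        seed = 1L) {
  stopifnot(n_viral >= 1, n_host >= 1)
  if (any(c(gc_marine, gc_rain_only) <= 0) || any(c(gc_marine, gc_rain_only) >= 1)) {
    abort("G/C targets must lie in (0, 1).")
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) abort("class_fractions must sum to 1.")
  set.seed(seed)

  # Host classes: at least one rain-class host when rain-only viruses exist.
  n_rain_host <- if (class_fractions["rain_only"] > 0 && n_host > 1) {
    max(1, round(n_host * class_fractions["rain_only"]))
  } else if (class_fractions["rain_only"] > 0) 1 else 0
  host_class <- c(rep("marine", n_host - n_rain_host), rep("rain", n_rain_host))
  host_gc <- ifelse(host_class == "marine",
                    runif(n_host, gc_marine[1], gc_marine[2]), gc_rain_only)
  o <- 3
  chains <- purrr::map(seq_len(n_host), function(h) {
    random_gc_chain(host_gc[h], o, k_signal)
  })
  host_seqs <- purrr::map_chr(seq_len(n_host), function(h) {
    q <- colMeans(chains[[h]])
    sample_markov_chain(chains[[h]], o, host_length, q)
  })
  host_ids <- sprintf("host_%02d", seq_len(n_host))

  # Virus classes in fixed order, counts rounded to the catalog size.
  n_rain <- round(n_viral * class_fractions["rain_only"])
  n_shared <- round(n_viral * class_fractions["shared"])
  n_marine <- n_viral - n_rain - n_shared
  v_class <- c(rep("marine", n_marine), rep("shared", n_shared),
               rep("rain_only", n_rain))
  occ_of <- c(marine = "foam,SML,SSW", shared = "foam,SML,SSW,aerosol,rain",
              rain_only = "rain")
  marine_hosts <- which(host_class == "marine")
  rain_hosts <- which(host_class == "rain")
  if (length(marine_hosts) == 0) marine_hosts <- seq_len(n_host)
  if (length(rain_hosts) == 0) rain_hosts <- seq_len(n_host)

  lens <- round(runif(n_viral, length_range[1], length_range[2]))
  host_of <- integer(n_viral)
  v_seqs <- character(n_viral)
  for (i in seq_len(n_viral)) {
    pool <- if (v_class[i] == "rain_only") rain_hosts else marine_hosts
    host_of[i] <- pool[1 + (i - 1) %% length(pool)]
    raw <- sample_markov_chain(chains[[host_of[i]]], o, lens[i],
                               colMeans(chains[[host_of[i]]]))
    v_seqs[i] <- mutate_sequence(raw, mutation_rate)
  }
  virus_ids <- sprintf("virus_%02d", seq_len(n_viral))
  viruses <- Biostrings::DNAStringSet(v_seqs); names(viruses) <- virus_ids
  hosts <- Biostrings::DNAStringSet(host_seqs); names(hosts) <- host_ids

  truth <- tibble(
    virus_id = virus_ids, class = v_class, host_id = host_ids[host_of],
    gc_target = host_gc[host_of], gc_realized = gc_percent(viruses) / 100,
    length = lens, occupancy = unname(occ_of[v_class])
  )
  host_truth <- tibble(host_id = host_ids, class = host_class, gc = host_gc)
  list(viruses = viruses, hosts = hosts, truth = truth, host_truth = host_truth)
}

#' Build a coverage design from genome truth and a sample sheet
#'
#' Expands the per-virus ecosystem occupancy truth over the samples of a
#' sheet: a virus is designed present in every non-control sample of an
#' occupied ecosystem. Optionally plants decoys on absent pairs that pin
#' the inclusive threshold semantics: breadth decoys just below the 0.75
#' presence cut at high identity, and identity decoys with ample breadth
#' but sub-threshold (0.85) read identity.
#'
#' @param truth Genome truth table from [sim_genomes()].
#' @param sheet Validated sample sheet.
#' @param breadth,mean_depth Coverage targets for present pairs.
#' @param decoys Add boundary decoys on a subset of absent pairs
#'   (default `TRUE`).
#' @param seed Integer seed (decoy placement).
#' @return A design tibble: `target_id`, `sample_id`, `present`, `breadth`,
#'   `mean_depth`, `identity` (NA = per-read uniform in the >= 0.90 band).
#' @export
sim_coverage_design <- function(truth, sheet, breadth = 0.85, mean_depth = 5,
                                decoys = TRUE, seed = 1L) {
  set.seed(seed)
  sheet <- validate_sample_sheet(sheet) %>% filter(!.data$excluded)
  occ <- strsplit(truth$occupancy, ",", fixed = TRUE)
  names(occ) <- truth$virus_id
  grid <- tidyr::expand_grid(target_id = truth$virus_id,
                             sample_id = sheet$sample_id) %>%
    left_join(sheet %>% select("sample_id", "ecosystem"), by = "sample_id") %>%
    mutate(present = purrr::map2_lgl(.data$target_id, .data$ecosystem,
                                     function(v, e) e %in% occ[[v]]))
  grid <- grid %>%
    mutate(breadth = if_else(.data$present, breadth, 0),
           mean_depth = if_else(.data$present, mean_depth, 0),
           identity = NA_real_, status = if_else(.data$present, "present", "absent"))
  if (decoys) {
    absent_idx <- which(!grid$present)
    n_decoy <- min(length(absent_idx), 4L)
    if (n_decoy >= 2) {
      pick <- sample(absent_idx, n_decoy)
      half <- ceiling(n_decoy / 2)
      grid$status[pick[seq_len(half)]] <- "decoy_breadth"
      grid$breadth[pick[seq_len(half)]] <- 0.74
      grid$mean_depth[pick[seq_len(half)]] <- mean_depth
      grid$identity[pick[seq_len(half)]] <- 0.95
      rest <- pick[-seq_len(half)]
      grid$status[rest] <- "decoy_identity"
      grid$breadth[rest] <- 0.90
      grid$mean_depth[rest] <- mean_depth
      grid$identity[rest] <- 0.85
    }
  }
  grid %>% select("target_id", "sample_id", "present", "status", "breadth",
                  "mean_depth", "identity")
}

#' Simulate identity-annotated read alignments for a coverage design
#'
#' For every designed (virus, sample) pair with nonzero breadth, emits
#' pseudo-read alignment spans tiling a contiguous block of exactly
#' round(breadth * length) positions, with extra randomly placed reads to
#' reach the target mean depth. Read identities are the design's fixed
#' value, or drawn uniformly from [0.90, 1] when unset; edit distances are
#' derived so identity = (aligned_length - edit_distance)/aligned_length.
#' Optional contaminant reads (ids listed in `$control_read_ids`) emulate
#' reads that also map to the handling controls.
#'
#' @param genomes Named [Biostrings::DNAStringSet] of viral scaffolds.
#' @param design Design tibble from [sim_coverage_design()].
#' @param read_length Pseudo-read span length (default 150).
#' @param n_contaminants Contaminant reads added per sample to random
#'   targets (default 0).
#' @param seed Integer seed.
#' @return A list: `$alignments` (tibble `sample_id`, `read_id`,
#'   `target_id`, `start`, `end`, `aligned_length`, `edit_distance`,
#'   `identity`), `$control_read_ids`, `$target_lengths`, `$truth` (the
#'   design).
#' @export
sim_read_coverage <- function(genomes, design, read_length = 150,
                              n_contaminants = 0, seed = 1L) {
  set.seed(seed)
  lens <- setNames(Biostrings::width(genomes), names(genomes))
  unknown <- setdiff(unique(design$target_id), names(lens))
  if (length(unknown) > 0) {
    abort(sprintf("Design references unknown genome(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  counter <- 0L
  rows <- purrr::pmap(design, function(target_id, sample_id, present, status,
                                       breadth, mean_depth, identity, ...) {
    if (breadth <= 0) return(NULL)
    L <- lens[[target_id]]
    cov_len <- round(breadth * L)
    block_start <- sample.int(L - cov_len + 1, 1)
    block_end <- block_start + cov_len - 1
    starts <- seq(block_start, block_end, by = read_length)
    ends <- pmin(starts + read_length - 1, block_end)
    n_extra <- max(0, round(mean_depth * cov_len / read_length) - length(starts))
    if (n_extra > 0) {
      es <- sample(block_start:max(block_start, block_end - read_length + 1),
                   n_extra, replace = TRUE)
      starts <- c(starts, es)
      ends <- c(ends, pmin(es + read_length - 1, block_end))
    }
    alen <- ends - starts + 1
    id_val <- if (is.na(identity)) runif(length(starts), 0.90, 1) else
      rep(identity, length(starts))
    # Edit counts are rounded toward the design intent so that every
    # realized read identity stays on the designed side of the 0.90 floor,
    # including short clipped tile reads.
    edits <- ifelse(id_val >= 0.90, floor((1 - id_val) * alen),
                    ceiling((1 - id_val) * alen))
    counter <<- counter + length(starts)
    tibble(sample_id = sample_id, target_id = target_id,
           read_id = sprintf("%s|r%07d", sample_id,
                             counter - length(starts) + seq_along(starts)),
           start = as.integer(starts), end = as.integer(ends),
           aligned_length = as.integer(alen), edit_distance = as.integer(edits),
           identity = (alen - edits) / alen)
  })
  aln <- bind_rows(rows)
  control_ids <- character()
  if (n_contaminants > 0) {
    samples <- unique(design$sample_id)
    cont <- purrr::map_dfr(samples, function(s) {
      tg <- sample(names(lens), n_contaminants, replace = TRUE)
      st <- purrr::map_int(tg, function(t) sample.int(max(1, lens[[t]] - read_length), 1))
      tibble(sample_id = s, target_id = tg,
             read_id = sprintf("%s|contam%04d", s, seq_len(n_contaminants)),
             start = st, end = as.integer(st + read_length - 1),
             aligned_length = read_length, edit_distance = 0L, identity = 1)
    })
    control_ids <- cont$read_id
    aln <- bind_rows(aln, cont)
  }
  list(alignments = aln, control_read_ids = control_ids,
       target_lengths = lens, truth = design)
}

#' Simulate CRISPR cassette reads from viral protospacers
#'
#' Builds reads containing direct-repeat/spacer cassettes
#' (DR-spacer-DR...), with each spacer copied from a random position in a
#' viral genome and diverged by a prescribed Hamming fraction (0, 0.1 or
#' 0.2 substitutions per base, giving protospacer identities of 1.0, 0.9
#' and exactly the 0.80 boundary for 30-bp spacers). Negative reads without
#' any DR are included.
#'
#' @param viruses Named [Biostrings::DNAStringSet] of viral scaffolds.
#' @param n_spacers Number of spacers (default 10).
#' @param divergence Vector of per-spacer divergences recycled over
#'   spacers (values in `{0, 0.1, 0.2}` mirror the design; default 0).
#' @param dr Direct repeat sequence; `NULL` draws a random 30-mer.
#' @param spacer_length Spacer length in bp (default 30; divisible lengths
#'   keep divergences exact).
#' @param flank Random flank length around cassettes (default 10).
#' @param n_negative Reads without DRs (default 5).
#' @param seed Integer seed.
#' @return A list: `$reads` (named [Biostrings::DNAStringSet]), `$dr`,
#'   `$truth` (tibble `spacer_id`, `virus_id`, `position`, `divergence`,
#'   `spacer`, `original`, `expected_identity`).
#' @export
sim_crispr_reads <- function(viruses, n_spacers = 10, divergence = 0,
                             dr = NULL, spacer_length = 30, flank = 10,
                             n_negative = 5, seed = 1L) {
  set.seed(seed)
  if (is.null(dr)) dr <- paste(sample(BASES, 30, replace = TRUE), collapse = "")
  check_dr(dr)
  if (spacer_length < 20 || spacer_length > 60) {
    abort("Spacer length must lie in [20, 60].")
  }
  div <- rep_len(divergence, n_spacers)
  vlens <- Biostrings::width(viruses)
  truth <- purrr::map_dfr(seq_len(n_spacers), function(i) {
    vi <- sample(length(viruses), 1)
    pos <- sample.int(vlens[vi] - spacer_length + 1, 1)
    orig <- as.character(Biostrings::subseq(viruses[[vi]], pos,
                                            pos + spacer_length - 1))
    n_mut <- round(div[i] * spacer_length)
    mut <- strsplit(orig, "", fixed = TRUE)[[1]]
    if (n_mut > 0) {
      at <- sample(spacer_length, n_mut)
      mut[at] <- purrr::map_chr(mut[at], function(b) sample(setdiff(BASES, b), 1))
    }
    tibble(spacer_id = sprintf("truth_sp_%02d", i),
           virus_id = names(viruses)[vi], position = pos,
           divergence = div[i], spacer = paste(mut, collapse = ""),
           original = orig,
           expected_identity = (spacer_length - n_mut) / spacer_length)
  })
  rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  reads <- purrr::map_chr(seq_len(n_spacers), function(i) {
    paste0(rand_seq(flank), dr, truth$spacer[i], dr, rand_seq(flank))
  })
  neg <- purrr::map_chr(seq_len(n_negative), function(i) {
    rand_seq(2 * flank + 2 * nchar(dr) + spacer_length)
  })
  all_reads <- Biostrings::DNAStringSet(c(reads, neg))
  names(all_reads) <- c(sprintf("cassette_%02d", seq_len(n_spacers)),
                        sprintf("negative_%02d", seq_len(n_negative)))
  list(reads = all_reads, dr = dr, truth = truth)
}

#' Simulate backward trajectories with prescribed sea and loading fractions
#'
#' Each trajectory has 120 hourly points; within the scoring window (the
#' first 96 h) the number of over-sea points is exactly
#' round(sea_frac * 96) and of loading points exactly
#' round(loading_frac * 96). Loading points sit inside the mixing layer
#' (altitude below boundary-layer height) with surface wind above the
#' loading threshold; all other points either sit above the mixing layer or
#' see calm wind, so classification recovers the prescription exactly.
#' Loading points are placed over sea whenever enough sea points exist.
#'
#' @param n_tj Number of trajectories.
#' @param sea_frac,loading_frac Prescribed fractions in `[0, 1]`.
#' @param event Event label (default `"event"`).
#' @param window Scoring window in hours (default 96).
#' @param n_hours Trajectory length (default 120).
#' @param seed Integer seed.
#' @return A list: `$points` (trajectory point tibble, see
#'   [read_trajectories()]), `$truth` (per-trajectory prescribed fractions).
#' @export
sim_trajectories <- function(n_tj = 10, sea_frac = 0.72, loading_frac = 0.35,
                             event = "event", window = 96, n_hours = 120,
                             seed = 1L) {
  assert_fraction(sea_frac, "sea_frac", allow_zero = TRUE)
  assert_fraction(loading_frac, "loading_frac", allow_zero = TRUE)
  set.seed(seed)
  n_sea <- round(sea_frac * window)
  n_load <- round(loading_frac * window)
  pts <- purrr::map_dfr(seq_len(n_tj), function(t) {
    sea_at <- sample(window, n_sea)
    load_pool <- if (n_load <= n_sea) sea_at else seq_len(window)
    load_at <- if (n_load > 0) sample(load_pool, n_load) else integer()
    hrs <- seq_len(n_hours)
    sea <- hrs %in% sea_at
    load <- hrs %in% load_at
    # Beyond the window: arbitrary but deterministic flags.
    beyond <- hrs > window
    sea[beyond] <- runif(sum(beyond)) < sea_frac
    tibble(
      trajectory_id = sprintf("%s_tj%03d", event, t), event = event,
      hours_before = hrs,
      lat = 58.9 + cumsum(rnorm(n_hours, 0, 0.05)),
      lon = 11.0 + cumsum(rnorm(n_hours, 0, 0.08)),
      altitude = if_else(load, 300, 1200),
      blh = 800,
      wind = if_else(load, 6, 2),
      land = !sea
    )
  })
  truth <- tibble(event = event, n_tj = n_tj,
                  sea_fraction = n_sea / window,
                  loading_fraction = n_load / window)
  list(points = pts, truth = truth)
}

#' Simulate droplet-freezing assays from an INP spectrum
#'
#' Cools a plate of wells along a 0.1 K grid; at each step every unfrozen
#' well freezes with probability 1 - exp(-dLambda), where dLambda is the
#' increment of the cumulative expected INP per well given by the spectrum.
#' Cumulative frozen counts are nondecreasing by construction.
#'
#' @param spectrum Tibble with `temp_c` (0.1 K grid, decreasing) and
#'   `lambda` (cumulative expected INP per well, nondecreasing with
#'   cooling, nonnegative).
#' @param wells Wells per assay (default 24).
#' @param n_assays Number of replicate assays (default 1).
#' @param seed Integer seed.
#' @return A list: `$assays` (tibble `assay_id`, `temp_c`, `frozen`),
#'   `$truth` (the spectrum).
#' @export
sim_freezing_assay <- function(spectrum, wells = 24, n_assays = 1, seed = 1L) {
  assert_columns(spectrum, c("temp_c", "lambda"), "INP spectrum")
  stopifnot(wells >= 1)
  if (any(spectrum$lambda < 0)) abort("Spectrum values must be nonnegative.")
  spectrum <- spectrum %>% arrange(dplyr::desc(.data$temp_c))
  if (is.unsorted(spectrum$lambda)) {
    abort("Cumulative spectrum must be nondecreasing with cooling.")
  }
  set.seed(seed)
  d_lambda <- diff(c(0, spectrum$lambda))
  p_freeze <- 1 - exp(-d_lambda)
  assays <- purrr::map_dfr(seq_len(n_assays), function(a) {
    unfrozen <- wells
    frozen <- integer(nrow(spectrum))
    for (i in seq_len(nrow(spectrum))) {
      newly <- rbinom(1, unfrozen, p_freeze[i])
      unfrozen <- unfrozen - newly
      frozen[i] <- wells - unfrozen
    }
    tibble(assay_id = sprintf("assay_%03d", a),
           temp_c = spectrum$temp_c, frozen = frozen)
  })
  list(assays = assays, truth = spectrum)
}

#' Simulate a station count table with prescribed correlations
#'
#' Log-normal VLP, prokaryote and eukaryote concentrations for SML and SSW
#' compartments whose raw-scale Pearson correlations converge to the
#' targets as the number of stations grows. Targets are mapped exactly to
#' the latent Gaussian scale through the log-normal moment formula; an
#' infeasible (non-positive-definite) latent structure is an error.
#'
#' @param n_stations Number of stations.
#' @param target_corr Named targets `vlp_prok`, `vlp_euk`, `prok_euk` on
#'   the raw concentration scale.
#' @param log_sd Log-scale standard deviations (length 3, vlp/prok/euk).
#' @param means Raw-scale medians (length 3, vlp/prok/euk per mL).
#' @param seed Integer seed.
#' @return A list: `$counts` (tibble in station-count layout, see
#'   [read_station_counts()]), `$truth` (targets and latent correlations).
#' @export
sim_count_table <- function(n_stations = 10,
                            target_corr = c(vlp_prok = 0.70, vlp_euk = 0.74,
                                            prok_euk = 0.88),
                            log_sd = c(0.3, 0.3, 0.3),
                            means = c(2e7, 8.5e5, 3.5e3),
                            seed = 1L) {
  set.seed(seed)
  s <- log_sd
  latent_rho <- function(r, s1, s2) {
    log(1 + r * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))) / (s1 * s2)
  }
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- latent_rho(target_corr[["vlp_prok"]], s[1], s[2])
  R[1, 3] <- R[3, 1] <- latent_rho(target_corr[["vlp_euk"]], s[1], s[3])
  R[2, 3] <- R[3, 2] <- latent_rho(target_corr[["prok_euk"]], s[2], s[3])
  if (anyNA(R) || any(!is.finite(R))) {
    abort("Infeasible correlation structure (not positive definite).")
  }
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    abort("Infeasible correlation structure (not positive definite).")
  }
  # Eigen factor rather than Cholesky so exactly collinear (singular
  # positive-semi-definite) targets are representable.
  fac <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  draw <- function(n) {
    z <- matrix(rnorm(n * 3), ncol = 3) %*% fac
    sweep(exp(sweep(z, 2, s, `*`)), 2, means, `*`)
  }
  sml <- draw(n_stations)
  ssw <- draw(n_stations)
  counts <- tibble(
    station = as.character(seq_len(n_stations)),
    date = as.character(seq.Date(as.Date("2020-02-01"), by = "2 days",
                                 length.out = n_stations)),
    vlp_foam = NA_real_, vlp_sml = sml[, 1], vlp_ssw = ssw[, 1],
    vlp_prc = NA_real_,
    prok_foam = NA_real_, prok_sml = sml[, 2], prok_ssw = ssw[, 2],
    prok_prc = NA_real_,
    euk_foam = NA_real_, euk_sml = sml[, 3], euk_ssw = ssw[, 3]
  )
  list(counts = counts,
       truth = tibble(pair = names(target_corr),
                      target = unname(target_corr),
                      latent = c(R[1, 2], R[1, 3], R[2, 3])))
}

#' Simulate per-sample pileups with a prescribed variant-overlap structure
#'
#' Builds pileup columns for one scaffold across several samples from a
#' haplotype-mixture model: a set of variant sites shared by all samples,
#' sites shared by each sample pair, and sites private to single samples,
#' all at callable depth and frequency. Remaining sampled positions are
#' monomorphic reference columns.
#'
#' @param reference A single named sequence (character or
#'   [Biostrings::DNAStringSet]).
#' @param samples Character vector of sample ids (>= 2).
#' @param n_shared_all Sites shared by every sample (default 5).
#' @param n_shared_pair Sites per sample pair (default 2).
#' @param n_private Sites private to each sample (default 3).
#' @param depth Column depth (default 50).
#' @param alt_freq Alternate-allele frequency at variant sites (default 0.4).
#' @param seed Integer seed.
#' @return A list: `$pileups` (tibble `sample_id`, `scaffold`, `pos`, `A`,
#'   `C`, `G`, `T`), `$truth` (tibble `pos`, `alt`, `samples`
#'   comma-separated).
#' @export
sim_variant_pileups <- function(reference, samples, n_shared_all = 5,
                                n_shared_pair = 2, n_private = 3,
                                depth = 50, alt_freq = 0.4, seed = 1L) {
  if (length(samples) < 2) abort("Need >= 2 samples.")
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(toupper(reference))
  }
  stopifnot(length(reference) == 1)
  set.seed(seed)
  sc <- names(reference) %||% "scaffold_1"
  names(reference) <- sc
  L <- Biostrings::width(reference)[1]
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  n_sites <- n_shared_all + n_shared_pair * length(pairs) +
    n_private * length(samples)
  pos <- sort(sample.int(L, n_sites + 10))  # +10 monomorphic columns
  ref_at <- function(p) as.character(Biostrings::subseq(reference[[1]], p, p))
  alt_at <- function(p) sample(setdiff(BASES, ref_at(p)), 1)
  take <- function(n) { out <- pos[seq_len(n)]; pos <<- pos[-seq_len(n)]; out }
  site_list <- list()
  if (n_shared_all > 0) {
    for (p in take(n_shared_all)) {
      site_list[[length(site_list) + 1]] <-
        tibble(pos = p, alt = alt_at(p), samples = paste(samples, collapse = ","))
    }
  }
  for (pr in pairs) {
    if (n_shared_pair > 0) {
      for (p in take(n_shared_pair)) {
        site_list[[length(site_list) + 1]] <-
          tibble(pos = p, alt = alt_at(p), samples = paste(pr, collapse = ","))
      }
    }
  }
  for (s in samples) {
    if (n_private > 0) {
      for (p in take(n_private)) {
        site_list[[length(site_list) + 1]] <-
          tibble(pos = p, alt = alt_at(p), samples = s)
      }
    }
  }
  truth <- bind_rows(site_list)
  mono <- pos  # leftover columns stay monomorphic
  alt_n <- round(alt_freq * depth)
  pileups <- purrr::map_dfr(samples, function(s) {
    site_pos <- truth$pos[purrr::map_lgl(strsplit(truth$samples, ","),
                                         function(x) s %in% x)]
    all_pos <- sort(c(truth$pos, mono))
    purrr::map_dfr(all_pos, function(p) {
      rb <- ref_at(p)
      cnt <- setNames(c(0L, 0L, 0L, 0L), BASES)
      if (p %in% site_pos) {
        ab <- truth$alt[truth$pos == p]
        cnt[ab] <- alt_n
        cnt[rb] <- depth - alt_n
      } else {
        cnt[rb] <- depth
      }
      tibble(sample_id = s, scaffold = sc, pos = p,
             A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]])
    })
  })
  list(pileups = pileups, truth = truth %>% arrange(.data$pos))
}

#' Default synthetic sample sheet
#'
#' A compact study layout covering all ecosystems: three stations of foam /
#' SML / SSW (SML and foam split into the 5-0.2 um and virome fractions),
#' two aerosol samples, two rain samples (one per fraction), one snow
#' sample, and one handling control.
#'
#' @return A validated sample sheet tibble.
#' @export
sim_sample_sheet <- function() {
  rows <- tibble(
    sample_id = c("foam_1_02", "foam_1_vir", "SML_1_02", "SML_1_vir", "SSW_1",
                  "SML_2_02", "SML_2_vir", "SSW_2", "SML_3_02", "SSW_3",
                  "aerosol_1", "aerosol_2", "rain_1_02", "rain_2_vir",
                  "snow_1", "control_1"),
    ecosystem = c("foam", "foam", "SML", "SML", "SSW", "SML", "SML", "SSW",
                  "SML", "SSW", "aerosol", "aerosol", "rain", "rain", "snow",
                  "control"),
    fraction = c("um5_02", "virome_lt02um", "um5_02", "virome_lt02um", "um5_02",
                 "um5_02", "virome_lt02um", "um5_02", "um5_02", "um5_02",
                 "na", "na", "um5_02", "virome_lt02um", "na", "na"),
    station = c("1", "1", "1", "1", "1", "2", "2", "2", "3", "3",
                NA, NA, NA, NA, NA, NA),
    date = as.character(seq.Date(as.Date("2020-02-03"), by = "day",
                                 length.out = 16))
  )
  validate_sample_sheet(rows)
}
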