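#' Oligonucleotide profile with Markov-background expectations
#'
#' Counts words of length `k` over the sequence (by default concatenated
#' with its reverse complement, the both-strand convention) and computes
#' expected counts under an order-`r` Markov chain fitted to the same
#' sequence: E_w = N * P(w), with P(w) the chain's word probability (initial
#' r-mer probability times stepwise transition probabilities) and N the
#' total word count. A pseudocount on transition counts keeps expectations
#' positive on short sequences.
#'
#' @param sequence A single character string, [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param k Word length (default 6).
#' @param r Markov background order (default 2); must satisfy `r <= k - 2`.
#' @param both_strands Count on the sequence and its reverse complement
#'   (default `TRUE`).
#' @param pseudocount Added to transition and initial counts (default 0.5).
#' @param id Sequence identifier stored in the profile.
#' @return A list of class `kmer_profile`: `id`, `k`, `r`, `both_strands`,
#'   `x` (observed counts, length 4^k, lexicographic ACGT order), `e`
#'   (expected counts).
#' @export
kmer_profile <- function(sequence, k = 6, r = 2, both_strands = TRUE,
                         pseudocount = 0.5, id = NULL) {
  if (r > k - 2) abort("Markov order must satisfy r <= k - 2.")
  if (r < 0) abort("Markov order must be >= 0.")
  seq <- as_dna_string(sequence)
  if (length(seq) <= k) abort("Sequence must be longer than k.")
  strands <- if (both_strands) {
    Biostrings::DNAStringSet(list(seq, Biostrings::reverseComplement(seq)))
  } else {
    Biostrings::DNAStringSet(list(seq))
  }
  x <- colSums(Biostrings::oligonucleotideFrequency(strands, width = k))
  n_words <- sum(x)

  # Order-r background fitted to the same strand set.
  if (r == 0) {
    base_counts <- colSums(Biostrings::oligonucleotideFrequency(strands, width = 1)) +
      pseudocount
    log_init <- 0
    log_trans <- matrix(log(base_counts / sum(base_counts)), nrow = 1)
  } else {
    c_r1 <- colSums(Biostrings::oligonucleotideFrequency(strands, width = r + 1)) +
      pseudocount
    ctx_tot <- rowSums(matrix(c_r1, ncol = 4, byrow = TRUE))
    log_trans <- log(matrix(c_r1, ncol = 4, byrow = TRUE) / ctx_tot)
    c_r <- colSums(Biostrings::oligonucleotideFrequency(strands, width = r)) +
      pseudocount
    log_init <- log(c_r / sum(c_r))
  }

  # log P(w) for all 4^k words, vectorized over word indices (A=0 ... T=3,
  # first character most significant, matching Biostrings' ordering).
  j <- seq_len(4^k) - 1
  logp <- if (r == 0) rep(0, length(j)) else log_init[j %/% 4^(k - r) + 1]
  for (t in seq_len(k - r)) {
    ctx <- if (r == 0) rep(0L, length(j)) else (j %/% 4^(k - (t + r - 1))) %% 4^r
    nxt <- (j %/% 4^(k - (t + r))) %% 4
    logp <- logp + log_trans[cbind(ctx + 1, nxt + 1)]
  }
  e <- n_words * exp(logp)

  structure(list(id = id %||% "seq", k = k, r = r, both_strands = both_strands,
                 x = as.numeric(x), e = e),
            class = "kmer_profile")
}

as_dna_string <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1) abort("Provide a single sequence.")
    return(x[[1]])
  }
  Biostrings::DNAString(toupper(as.character(x)))
}

#' d2* dissimilarity between two oligonucleotide profiles
#'
#' Markov-background-corrected word-count dissimilarity: with centered
#' counts X~_w = X_w - E^A_w and Y~_w = Y_w - E^B_w (each profile uses its
#' own fitted background),
#' \deqn{D_2^* = \sum_w \frac{\tilde X_w \tilde Y_w}{\sqrt{E^A_w E^B_w}}}
#' \deqn{d_2^* = \frac{1}{2}\left(1 - \frac{D_2^*}{\sqrt{\sum \tilde X_w^2/E^A_w}\sqrt{\sum \tilde Y_w^2/E^B_w}}\right)}
#' clamped to `[0, 1]`. Self-dissimilarity is 0; unrelated i.i.d. sequences
#' score near 0.5.
#'
#' @param profile_a,profile_b `kmer_profile` objects with identical `k`,
#'   `r`, and strand convention.
#' @return The d2* dissimilarity, a scalar in `[0, 1]`.
#' @export
d2star <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "kmer_profile"), inherits(profile_b, "kmer_profile"))
  if (profile_a$k != profile_b$k || profile_a$r != profile_b$r ||
      profile_a$both_strands != profile_b$both_strands) {
    abort("Profiles must share k, Markov order, and strand convention.")
  }
  xt <- profile_a$x - profile_a$e
  yt <- profile_b$x - profile_b$e
  num <- sum(xt * yt / sqrt(profile_a$e * profile_b$e))
  na <- sqrt(sum(xt^2 / profile_a$e))
  nb <- sqrt(sum(yt^2 / profile_b$e))
  if (na == 0 || nb == 0) abort("Undefined distance: zero normalization term.")
  min(1, max(0, 0.5 * (1 - num / (na * nb))))
}

#' Assign candidate hosts to viruses by d2*
#'
#' Computes d2* between every virus and host, emits all pairs at or below
#' the threshold (default 0.3, the customary host-matching cutoff), and
#' flags the minimum-d2* edge per virus as `is_best`. Ties break
#' lexicographically on host id.
#'
#' @param viruses,hosts Named [Biostrings::DNAStringSet] objects (or named
#'   character vectors), or lists of `kmer_profile`s.
#' @param threshold Maximum d2* for an edge (default 0.3).
#' @param k,r,both_strands,pseudocount Profile parameters, used when raw
#'   sequences are supplied.
#' @return A tibble: `virus_id`, `host_id`, `d2star`, `is_best`.
#' @export
assign_hosts <- function(viruses, hosts, threshold = 0.3, k = 6, r = 2,
                         both_strands = TRUE, pseudocount = 0.5) {
  vp <- as_profiles(viruses, k, r, both_strands, pseudocount)
  hp <- as_profiles(hosts, k, r, both_strands, pseudocount)
  if (length(hp) == 0) {
    warn("Empty host set; no edges.")
    return(tibble(virus_id = character(), host_id = character(),
                  d2star = double(), is_best = logical()))
  }
  edges <- purrr::map_dfr(vp, function(v) {
    purrr::map_dfr(hp, function(h) {
      tibble(virus_id = v$id, host_id = h$id, d2star = d2star(v, h))
    })
  }) %>% filter(.data$d2star <= threshold)
  edges %>%
    arrange(.data$virus_id, .data$d2star, .data$host_id) %>%
    group_by(.data$virus_id) %>%
    mutate(is_best = dplyr::row_number() == 1) %>%
    ungroup()
}

as_profiles <- function(x, k, r, both_strands, pseudocount) {
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "kmer_profile")) return(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  ids <- names(x) %||% paste0("seq_", seq_along(x))
  purrr::map(seq_along(x), function(i) {
    kmer_profile(x[[i]], k = k, r = r, both_strands = both_strands,
                 pseudocount = pseudocount, id = ids[i])
  })
}
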