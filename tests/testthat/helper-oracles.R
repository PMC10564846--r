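# Independent brute-force oracles, deliberately written with plain loops and
# string operations so they share no code path with the package.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Count all k-mers of a string by explicit substring extraction.
oracle_kmer_counts <- function(s, k) {
  words <- character(0)
  for (i in 1:(nchar(s) - k + 1)) words <- c(words, substr(s, i, i + k - 1))
  all_w <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
                 1, paste, collapse = "")
  all_w <- sort(all_w)
  tab <- table(factor(words, levels = all_w))
  as.numeric(tab)
}

# Direct-formula d2* for small k, independent of the package implementation.
oracle_d2star <- function(sa, sb, k, r, both_strands = TRUE, pc = 0.5) {
  prof <- function(s) {
    strands <- if (both_strands) c(s, revcomp_chr(s)) else s
    x <- Reduce(`+`, lapply(strands, oracle_kmer_counts, k = k))
    all_w <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
                        1, paste, collapse = ""))
    # Markov fit
    pw <- numeric(length(all_w))
    if (r == 0) {
      b1 <- Reduce(`+`, lapply(strands, oracle_kmer_counts, k = 1)) + pc
      p1 <- b1 / sum(b1)
      names(p1) <- c("A", "C", "G", "T")
      for (wi in seq_along(all_w)) {
        p <- 1
        for (j in 1:k) p <- p * p1[[substr(all_w[wi], j, j)]]
        pw[wi] <- p
      }
    } else {
      cr1 <- Reduce(`+`, lapply(strands, oracle_kmer_counts, k = r + 1)) + pc
      wr1 <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), r + 1))[, (r + 1):1, drop = FALSE],
                        1, paste, collapse = ""))
      names(cr1) <- wr1
      cr <- Reduce(`+`, lapply(strands, oracle_kmer_counts, k = r)) + pc
      wr <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), r))[, r:1, drop = FALSE],
                       1, paste, collapse = ""))
      names(cr) <- wr
      pinit <- cr / sum(cr)
      trans <- function(ctx, b) {
        tot <- sum(cr1[paste0(ctx, c("A", "C", "G", "T"))])
        cr1[[paste0(ctx, b)]] / tot
      }
      for (wi in seq_along(all_w)) {
        w <- all_w[wi]
        p <- pinit[[substr(w, 1, r)]]
        for (j in 1:(k - r)) {
          p <- p * trans(substr(w, j, j + r - 1), substr(w, j + r, j + r))
        }
        pw[wi] <- p
      }
    }
    e <- sum(x) * pw
    list(x = x, e = e)
  }
  pa <- prof(sa); pb <- prof(sb)
  xt <- pa$x - pa$e; yt <- pb$x - pb$e
  num <- sum(xt * yt / sqrt(pa$e * pb$e))
  den <- sqrt(sum(xt^2 / pa$e)) * sqrt(sum(yt^2 / pb$e))
  0.5 * (1 - num / den)
}

# Per-base breadth/mean-depth by filling a position vector.
oracle_coverage <- function(starts, ends, L) {
  depth <- numeric(L)
  for (i in seq_along(starts)) {
    a <- max(1, starts[i]); b <- min(L, ends[i])
    depth[a:b] <- depth[a:b] + 1
  }
  list(breadth = mean(depth >= 1), mean_depth = sum(depth) / L)
}

# Venn region counts by full subset enumeration over the membership matrix.
oracle_venn <- function(memb) {
  m <- ncol(memb)
  out <- list()
  for (code in 1:(2^m - 1)) {
    patt <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    cnt <- 0
    for (i in seq_len(nrow(memb))) {
      if (all(memb[i, ] == patt)) cnt <- cnt + 1
    }
    out[[length(out) + 1]] <- list(pattern = patt, count = cnt)
  }
  out
}

# Best ungapped full-length placement of a spacer in a scaffold, both
# strands, by scanning every offset.
oracle_protospacer <- function(spacer, scaffold) {
  best <- list(mism = Inf)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else revcomp_chr(spacer)
    qv <- strsplit(q, "")[[1]]
    sv <- strsplit(scaffold, "")[[1]]
    for (off in 0:(length(sv) - length(qv))) {
      mm <- sum(sv[(off + 1):(off + length(qv))] != qv)
      if (mm < best$mism) best <- list(mism = mm, pos = off + 1, strand = strand)
    }
  }
  best
}

# Ungapped identity (matches over the shorter length, best offset), by
# explicit character comparison at every placement.
ungapped_identity_oracle <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (off in 0:(length(av) - length(bv))) {
    m <- sum(av[(off + 1):(off + length(bv))] == bv)
    if (m > best) best <- m
  }
  best / length(bv)
}

# Kruskal-Wallis H by the rank formula with tie correction.
oracle_kw_h <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(r[idx]) - (N + 1) / 2)^2
  }
  h <- 12 / (N * (N + 1)) * h
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Spearman rho through explicit average ranks and the Pearson formula.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
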