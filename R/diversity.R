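#' Alpha- and beta-diversity suite for a community matrix
#'
#' Shannon-Wiener index H' = -sum(p_i log p_i) (natural log) on per-sample
#' relative abundances, Bray-Curtis dissimilarities, and a PERMANOVA on the
#' Bray-Curtis matrix against a grouping factor with 999 label permutations.
#' Samples with zero total abundance are excluded with a warning.
#'
#' @param abundance A tidy tibble (`sample_id`, `target_id`, and a value
#'   column `normalized` or `value`) or a numeric matrix with samples as
#'   rows.
#' @param groups Named character vector or factor mapping sample ids to
#'   groups (required for PERMANOVA; `NULL` skips it).
#' @param n_perm Number of PERMANOVA permutations (default 999).
#' @return A list of class `diversity_result`: `$shannon` (tibble
#'   `sample_id`, `shannon`), `$bray` (a `dist`), `$permanova` (one-row
#'   tibble `pseudo_f`, `p`, `n_perm`, `df_between`, `df_within`, or `NULL`).
#' @export
diversity_suite <- function(abundance, groups = NULL, n_perm = 999) {
  mat <- if (is.matrix(abundance)) {
    abundance
  } else {
    val_col <- if ("normalized" %in% names(abundance)) "normalized" else "value"
    assert_columns(abundance, c("sample_id", "target_id", val_col),
                   "abundance input")
    wide <- abundance %>%
      tidyr::pivot_wider(id_cols = "sample_id", names_from = "target_id",
                         values_from = dplyr::all_of(val_col), values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$sample_id
    m
  }
  if (any(mat < 0)) abort("Abundances must be nonnegative.")
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    warn(sprintf("Excluding %d sample(s) with zero total abundance: %s",
                 sum(zero), paste(rownames(mat)[zero], collapse = ", ")))
    mat <- mat[!zero, , drop = FALSE]
  }
  shannon <- tibble(sample_id = rownames(mat),
                    shannon = unname(vegan::diversity(mat, index = "shannon")))
  bray <- vegan::vegdist(mat, method = "bray")
  perma <- NULL
  if (!is.null(groups)) {
    g <- groups[rownames(mat)]
    if (anyNA(g)) abort("`groups` must cover every retained sample.")
    perma <- permanova(bray, g, n_perm = n_perm)
  }
  structure(list(shannon = shannon, bray = bray, permanova = perma),
            class = "diversity_result")
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances:
#' SS_T = sum of squared distances over all pairs / n, SS_W the analogous
#' within-group sum, F = ((SS_T - SS_W)/(g - 1)) / (SS_W/(n - g)). The p
#' value counts permutations of the group labels with F at least the
#' observed value: p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1).
#'
#' @param d A `dist` object or square distance matrix.
#' @param groups Grouping vector, one entry per observation of `d`.
#' @param n_perm Number of label permutations (default 999).
#' @return One-row tibble: `pseudo_f`, `p`, `n_perm`, `df_between`,
#'   `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  g <- as.factor(groups)
  if (length(g) != n) abort("`groups` length must match the distance matrix.")
  if (nlevels(g) < 2) abort("Need >= 2 groups for PERMANOVA.")
  k <- nlevels(g)
  ss_total <- sum(dm2[upper.tri(dm2)]) / n
  within_ss <- function(gv) {
    s <- 0
    for (lev in levels(gv)) {
      idx <- which(gv == lev)
      if (length(idx) > 1) {
        sub <- dm2[idx, idx]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  f_stat <- function(gv) {
    ssw <- within_ss(gv)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_stat(g)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(g[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  }
  tibble(pseudo_f = f_obs, p = (exceed + 1) / (n_perm + 1),
         n_perm = n_perm, df_between = k - 1L, df_within = n - k)
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result>\n")
  cat(sprintf("  Shannon H' over %d samples (mean %.3f)\n",
              nrow(x$shannon), mean(x$shannon$shannon)))
  cat(sprintf("  Bray-Curtis matrix: %d x %d\n",
              attr(x$bray, "Size"), attr(x$bray, "Size")))
  if (!is.null(x$permanova)) {
    cat(sprintf("  PERMANOVA: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
                x$permanova$pseudo_f, x$permanova$p, x$permanova$n_perm))
  }
  invisible(x)
}
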