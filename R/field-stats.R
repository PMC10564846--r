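#' Enrichment factor of the surface microlayer over subsurface water
#'
#' The enrichment factor (EF) of a specimen (VLPs, prokaryotic cells, small
#' phototrophic eukaryotes) is the ratio of its concentration in the surface
#' microlayer (SML) to the subsurface-water (SSW) value: EF > 1 indicates
#' enrichment at the air-sea interface, EF < 1 depletion. Missing inputs
#' (`NA`, the table's "n.d.") propagate; an SSW value of zero yields an
#' undefined EF flagged in the output rather than an error.
#'
#' @param sml,ssw Numeric vectors of concentrations (same units).
#' @return A tibble with columns `ef` (the raw ratio), `ef_display` (rounded
#'   half-up to one decimal, the presentation convention of station tables)
#'   and `undefined` (`TRUE` where `ssw == 0`).
#' @export
#' @examples
#' enrichment_factor(3.4e7, 1.9e7) # 1.789..., displayed as 1.8
enrichment_factor <- function(sml, ssw) {
  stopifnot(length(sml) == length(ssw))
  if (any(sml < 0, na.rm = TRUE) || any(ssw < 0, na.rm = TRUE)) {
    abort("Concentrations must be >= 0 (or NA for n.d.).")
  }
  undefined <- !is.na(ssw) & ssw == 0 & !is.na(sml)
  ef <- ifelse(undefined, NA_real_, sml / ssw)
  tibble(ef = ef, ef_display = round_half_up(ef, 1), undefined = undefined)
}

#' Virus-host ratio
#'
#' Ratio of virus-like particles to prokaryotic cells (host = prokaryotes),
#' dimensionless. `NA` or zero host counts give `NA`.
#'
#' @param vlp,prok Numeric vectors of concentrations per mL.
#' @return Numeric vector of ratios.
#' @export
virus_host_ratio <- function(vlp, prok) {
  stopifnot(length(vlp) == length(prok))
  ifelse(is.na(prok) | prok == 0, NA_real_, vlp / prok)
}

#' Correlation with test statistics
#'
#' Pearson or Spearman correlation with the full reporting used in field
#' tables: the coefficient, t statistic (t = r * sqrt(n - 2) / sqrt(1 - r^2)
#' for Pearson), degrees of freedom n - 2, two-sided p, and n after pairwise
#' deletion of missing values. With `method = "auto"` the choice is gated on
#' Shapiro-Wilk normality of both variables (Pearson if both p > 0.05, else
#' Spearman), mirroring common practice; callers may force a method.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the two variables.
#' @param method `"pearson"`, `"spearman"`, or `"auto"`.
#' @return A one-row tibble: `method`, `estimate`, `t` (`NA` for Spearman),
#'   `df`, `p`, `n`, and the Shapiro-Wilk p values when `method = "auto"`.
#' @export
#' @examples
#' d <- data.frame(a = c(1, 2, 4, 3, 6), b = c(2, 3, 5, 5, 9))
#' correlate(d, a, b, method = "pearson")
correlate <- function(data, x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort("Correlation undefined: one variable has zero variance.")
  }
  sw_x <- sw_y <- NA_real_
  if (method == "auto") {
    sw_x <- stats::shapiro.test(xv)$p.value
    sw_y <- stats::shapiro.test(yv)$p.value
    method <- if (sw_x > 0.05 && sw_y > 0.05) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(
    method = method,
    estimate = unname(ct$estimate),
    t = if (method == "pearson") unname(ct$statistic) else NA_real_,
    df = if (method == "pearson") unname(ct$parameter) else n - 2,
    p = ct$p.value,
    n = n,
    shapiro_x_p = sw_x,
    shapiro_y_p = sw_y
  )
}

#' Fit a two-way interaction linear model
#'
#' Ordinary least squares of `response ~ a * b` (intercept, both main
#' effects, and their interaction), the model family used to test
#' combinatory effects of environmental drivers (e.g. wind speed and
#' salinity) on SML enrichment factors. Reported are the adjusted R^2,
#' overall F test, and AIC under the Gaussian-likelihood convention that
#' includes the 2*pi constant and counts the error variance as a parameter
#' (the convention of `stats::AIC()`).
#'
#' @param data A data frame.
#' @param response,a,b Column names (tidy-eval).
#' @return An object of class `interaction_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_interaction_model <- function(data, response, a, b) {
  df <- tibble(
    .y = dplyr::pull(data, {{ response }}),
    .a = dplyr::pull(data, {{ a }}),
    .b = dplyr::pull(data, {{ b }})
  ) %>% tidyr::drop_na()
  if (nrow(df) <= 4) abort("Need n > 4 observations for intercept + 2 mains + interaction.")
  fit <- lm(.y ~ .a * .b, data = df)
  if (fit$rank < 4) abort("Singular fit: rank-deficient design matrix.")
  structure(
    list(fit = fit, n = nrow(df),
         labels = c(a = rlang::as_name(rlang::enquo(a)),
                    b = rlang::as_name(rlang::enquo(b)),
                    response = rlang::as_name(rlang::enquo(response)))),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<interaction_fit> %s ~ %s * %s\n", x$labels["response"],
              x$labels["a"], x$labels["b"]))
  cat(sprintf("  adj. R2 = %.3f, F = %.3f on %d and %d df, p = %.4g, AIC = %.3f\n",
              g$adjusted_r2, g$f_value, g$df_model, g$df_error, g$p, g$aic))
  invisible(x)
}

#' Tidy an interaction model fit
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return Coefficient table: `term`, `estimate`, `std_error`, `statistic`, `p`.
#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  terms <- c("(Intercept)" = "intercept", ".a" = unname(x$labels["a"]),
             ".b" = unname(x$labels["b"]),
             ".a:.b" = paste0(x$labels["a"], ":", x$labels["b"]))
  tibble(
    term = unname(terms[rownames(sm)]),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p = sm[, 4]
  )
}

#' Glance at an interaction model fit
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return One-row tibble: `adjusted_r2`, `f_value`, `df_model`, `df_error`,
#'   `p`, `aic`, `n`.
#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble(
    adjusted_r2 = sm$adj.r.squared,
    f_value = unname(f[1]),
    df_model = as.integer(f[2]),
    df_error = as.integer(f[3]),
    p = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
    aic = AIC(x$fit),
    n = x$n
  )
}

#' @export
generics::tidy

#' @export
generics::glance
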