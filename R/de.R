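#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with input validation; a thin, checked front end to
#' [stats::p.adjust()]. Output is componentwise `>=` the input p-values and
#' equals `min over j >= i of p_(j) * m / j` for each sorted position.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values (FDR), same order as input.
#' @examples
#' bh_adjust(c(0.005, 0.05, 0.5))  # 0.015 0.075 0.500
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (anyNA(p)) abort("`p` must not contain NA.")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

# Vectorized Newton inversion of the trigamma function (y = trigamma(x)).
trigamma_inverse <- function(y) {
  if (any(y <= 0)) abort("trigamma_inverse needs positive input.")
  x <- ifelse(y > 1e7, 1 / sqrt(y), 0.5 + 1 / y)
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' the hierarchical model in which true gene variances follow a scaled
#' inverse chi-square prior and observed residual variances `s_g^2` are
#' scaled chi-square about them (so marginally `s_g^2 ~ s0^2 F(d_g, d0)`).
#' Fitting matches the first two moments of `log(s_g^2)` to the scaled-F
#' log-moments; `d0` comes from inverting the trigamma function. With
#' `trend = TRUE`, `s0^2` becomes a function of average glog2 intensity,
#' estimated by a locally weighted (lowess) smooth of the log-variances, and
#' `d0` from the residual spread about the smooth.
#'
#' @param s2 Residual variances per gene (`>= 0`; exact zeros are excluded
#'   from moment estimation with a warning).
#' @param df Residual degrees of freedom (scalar or per-gene, `>= 1`).
#' @param amean Average glog2 intensity per gene; required when
#'   `trend = TRUE`.
#' @param trend Make the prior variance a smooth function of `amean`.
#' @param span Lowess span for the trend smooth.
#' @return Object of class `variance_prior`: `df_prior` (`Inf` when the
#'   log-variance spread is no larger than chi-square sampling alone implies),
#'   `var_prior` (scalar, or per-gene vector when `trend`), plus the trend
#'   curve. `tidy()` gives per-gene prior variances, `glance()` the scalars.
#' @export
fit_variance_prior <- function(s2, df, amean = NULL, trend = FALSE, span = 0.5) {
  if (!is.numeric(s2) || length(s2) < 30L) {
    abort("need at least 30 residual variances to fit the prior.")
  }
  if (any(s2 < 0)) abort("variances must be non-negative.")
  if (any(df < 1)) abort("residual df must be >= 1.")
  if (all(s2 == 0)) abort("all residual variances are zero; nothing to fit.")
  df <- rep_len(df, length(s2))
  if (trend) {
    if (is.null(amean)) abort("`amean` is required when trend = TRUE.")
    if (length(amean) != length(s2)) abort("`amean` must match `s2` in length.")
  }

  ok <- s2 > 0
  if (!all(ok)) {
    warn(sprintf("%d zero variance(s) excluded from prior estimation.", sum(!ok)))
  }
  z <- log(s2[ok])
  dfo <- df[ok]
  # E[log s^2 | sigma^2] = log sigma^2 + digamma(d/2) - log(d/2);
  # Var[log s^2 | sigma^2] = trigamma(d/2).
  e <- z - digamma(dfo / 2) + log(dfo / 2)

  if (trend) {
    am <- amean[ok]
    sm <- lowess(am, e, f = span)
    e_fit <- approx(sm$x, sm$y, xout = am, rule = 2, ties = mean)$y
    resid_e <- e - e_fit
    evar <- var(resid_e)
    e_center <- e_fit
  } else {
    evar <- var(e)
    e_center <- rep(mean(e), length(e))
  }

  rhs <- evar - mean(trigamma(dfo / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    if (!trend && stats::sd(z) == 0) {
      # all variances identical: infinitely informative prior at that value
      df_prior <- Inf
      log_s0 <- z
    } else {
      warn("trigamma inversion failed (no excess log-variance spread); using df_prior = Inf.")
      df_prior <- Inf
      log_s0 <- e_center
    }
  } else {
    half_d0 <- trigamma_inverse(rhs)
    df_prior <- 2 * half_d0
    log_s0 <- e_center + digamma(half_d0) - log(half_d0)
  }

  # map back onto the full gene vector (zeros get the nearest available prior)
  var_prior_vec <- numeric(length(s2))
  var_prior_vec[ok] <- exp(log_s0)
  if (any(!ok)) var_prior_vec[!ok] <- exp(mean(log_s0))

  trend_fun <- NULL
  if (trend) {
    sm_full <- lowess(amean[ok], log_s0, f = span)
    trend_fun <- stats::approxfun(sm_full$x, sm_full$y, rule = 2, ties = mean)
  }

  structure(
    list(
      df_prior = df_prior,
      var_prior = if (trend) var_prior_vec else exp(log_s0[1L]),
      trend = trend,
      span = if (trend) span else NA_real_,
      trend_fun = trend_fun,
      n_genes = length(s2)
    ),
    class = "variance_prior"
  )
}

#' @export
glance.variance_prior <- function(x, ...) {
  tibble::tibble(
    df_prior = x$df_prior,
    var_prior = if (x$trend) NA_real_ else x$var_prior,
    trend = x$trend,
    n_genes = x$n_genes
  )
}

#' @export
print.variance_prior <- function(x, ...) {
  if (x$trend) {
    cat(sprintf("<variance_prior> d0 = %.3g; s0^2 = intensity trend (range %.3g-%.3g); n = %d\n",
                x$df_prior, min(x$var_prior), max(x$var_prior), x$n_genes))
  } else {
    cat(sprintf("<variance_prior> d0 = %.3g; s0^2 = %.4g; n = %d\n",
                x$df_prior, x$var_prior, x$n_genes))
  }
  invisible(x)
}

#' Moderated t-test between two conditions
#'
#' Per-probeset two-sample comparison on glog2-normalized data with
#' empirical-Bayes variance moderation: the posterior variance
#' `s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` shrinks each gene's
#' pooled residual variance toward the prior, and the moderated t statistic
#' `log2FC / (s~_g * sqrt(1/n1 + 1/n2))` is referred to a t distribution on
#' `d0 + d_g` degrees of freedom (normal when `d0 = Inf`; the classical
#' pooled t when `d0 = 0`). Two-sided p-values; BH FDR across probesets.
#'
#' @param data Normalized intensity table (id column + one column per sample),
#'   or numeric matrix, on the glog2 scale.
#' @param samples Sample sheet tibble with columns `sample_id` and
#'   `condition` covering every array column.
#' @param contrast Length-2 character: conditions compared as
#'   `mean(contrast[1]) - mean(contrast[2])` (default injured - naive).
#' @param prior A `variance_prior`, or `NULL` to fit one from this data.
#' @param trend Passed to [fit_variance_prior()] when `prior` is `NULL`.
#' @param fraction Optional label copied into the result.
#' @return A `differential_result` tibble: probeset_id, avg_expr, log2fc, s2,
#'   df_resid, s2_post, t, df_total, p, fdr, fraction. The fitted prior is
#'   attached as attribute `"prior"`.
#' @export
moderated_t_test <- function(data, samples,
                             contrast = c("injured", "naive"),
                             prior = NULL, trend = TRUE, fraction = NA_character_) {
  x <- as_intensity_matrix(data)
  require_columns(samples, c("sample_id", "condition"), "samples")
  if (length(contrast) != 2L) abort("`contrast` must name exactly 2 conditions.")
  cond <- samples$condition[match(colnames(x), samples$sample_id)]
  if (anyNA(cond)) {
    abort(sprintf("sample sheet does not cover column(s): %s.",
                  paste(colnames(x)[is.na(cond)], collapse = ", ")))
  }
  i1 <- which(cond == contrast[1L])
  i2 <- which(cond == contrast[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    abort(sprintf("need >= 2 samples in each condition ('%s': %d, '%s': %d).",
                  contrast[1L], length(i1), contrast[2L], length(i2)))
  }
  n1 <- length(i1); n2 <- length(i2)

  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  fc <- m1 - m2
  avg <- rowMeans(x[, c(i1, i2), drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df_resid

  if (is.null(prior)) {
    prior <- fit_variance_prior(s2, df_resid, amean = avg, trend = trend)
  }
  stopifnot(inherits(prior, "variance_prior"))
  d0 <- prior$df_prior
  s0 <- if (prior$trend) {
    if (length(prior$var_prior) == length(s2)) prior$var_prior
    else prior$trend_fun(avg) |> exp()
  } else prior$var_prior

  if (is.infinite(d0)) {
    s2_post <- s0 + 0 * s2
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0 + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(fc == 0, 0, fc / se)
  tstat[se == 0 & fc != 0] <- sign(fc[se == 0 & fc != 0]) * Inf
  p <- 2 * pt(-abs(tstat), df = df_total)

  out <- tibble::tibble(
    probeset_id = rownames(x),
    avg_expr = unname(avg),
    log2fc = unname(fc),
    s2 = unname(s2),
    df_resid = df_resid,
    s2_post = unname(s2_post),
    t = unname(tstat),
    df_total = df_total,
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    fraction = fraction
  )
  class(out) <- c("differential_result", class(out))
  attr(out, "prior") <- prior
  attr(out, "contrast") <- contrast
  out
}

#' Filter a probeset mapping table to unique mappers
#'
#' Retains only probesets that map to exactly one target identifier (gene or
#' transcript); multi-mapping probesets are excluded, as required before
#' gene-level interpretation of probeset statistics. The number excluded is
#' reported via a message and the `"n_excluded"` attribute.
#'
#' @param mapping Tibble with a `probeset_id` column and the target id column.
#' @param target `"gene"` (uses `gene_id`) or `"transcript"`
#'   (uses `transcript_id`).
#' @return Filtered mapping tibble (one row per retained probeset).
#' @export
map_probesets <- function(mapping, target = c("gene", "transcript")) {
  target <- match.arg(target)
  if (!is.data.frame(mapping) || nrow(mapping) == 0L) {
    abort("`mapping` must be a non-empty data frame.")
  }
  id_col <- paste0(target, "_id")
  require_columns(mapping, c("probeset_id", id_col), "mapping")
  counts <- mapping |>
    dplyr::distinct(.data$probeset_id, .data[[id_col]]) |>
    dplyr::count(.data$probeset_id, name = "n_targets")
  unique_ps <- counts$probeset_id[counts$n_targets == 1L]
  n_excluded <- nrow(counts) - length(unique_ps)
  out <- mapping |>
    dplyr::filter(.data$probeset_id %in% unique_ps) |>
    dplyr::distinct(.data$probeset_id, .data[[id_col]], .keep_all = TRUE)
  if (nrow(out) == 0L) {
    warn(sprintf("all %d probesets were multi-mapping; result is empty.", n_excluded))
  } else {
    inform(sprintf("map_probesets: excluded %d multi-mapping probeset(s), kept %d.",
                   n_excluded, nrow(out)))
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Normalize both fractions and test differential expression
#'
#' Convenience pipeline: splits the sample sheet by fraction, runs
#' [glog_normalize()] on each raw matrix separately (fractions are never
#' coupled), then [moderated_t_test()] per fraction.
#'
#' @param raw_total,raw_polysome Raw intensity tibbles (probeset_id + sample
#'   columns).
#' @param samples Sample sheet with `sample_id`, `fraction`
#'   (`total`/`polysome`), `condition`, `replicate`.
#' @param ... Passed to [moderated_t_test()].
#' @return Named list with `total` and `polysome` `differential_result`
#'   tibbles and the two `glog_fit` objects under `$fits`.
#' @export
run_tsaa <- function(raw_total, raw_polysome, samples, ...) {
  require_columns(samples, c("sample_id", "fraction", "condition"), "samples")
  fits <- list(
    total = glog_normalize(raw_total),
    polysome = glog_normalize(raw_polysome)
  )
  res <- lapply(names(fits), function(fr) {
    moderated_t_test(fits[[fr]]$normalized,
                     samples[samples$fraction == fr, , drop = FALSE],
                     fraction = fr, ...)
  })
  names(res) <- names(fits)
  res$fits <- fits
  res
}
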