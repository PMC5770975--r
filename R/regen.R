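#' Estimate total regenerating axons per distance
#'
#' Converts per-section axon counts at a distance `d` from the lesion into an
#' estimated total number of axons crossing that distance:
#' `sum_a_d = pi * r^2 * (average axons per mm / t)`, where `r` is half the
#' nerve width at the counting site (averaged over the sections at that
#' site), "average axons per mm" is the mean of `count / width` over the
#' sections, and `t` is the section thickness. All lengths must share one
#' unit (mm internally; the estimate is invariant to a consistent unit
#' change because count/width x width^2 / t is dimensionally length-free in
#' the ratio used).
#'
#' @param sections Tibble with columns `animal_id`, `group`, `distance_mm`,
#'   `axon_count` (integer `>= 0`), `nerve_width_mm` (`> 0`), and optionally
#'   `thickness_mm` (default filled with 0.008, i.e. 8 micrometres); at least
#'   one section per animal x distance, thickness constant within a site.
#' @return Tibble: animal_id, group, distance_mm, n_sections, axons_total.
#' @examples
#' s <- tibble::tibble(animal_id = "m1", group = "treated", distance_mm = 0.5,
#'                     axon_count = 4, nerve_width_mm = 0.4)
#' estimate_axons(s)  # pi * 0.2^2 * (10 / 0.008) = 50 * pi
#' @export
estimate_axons <- function(sections) {
  require_columns(sections,
                  c("animal_id", "group", "distance_mm", "axon_count", "nerve_width_mm"),
                  "sections")
  if (!"thickness_mm" %in% names(sections)) sections$thickness_mm <- 0.008
  if (any(sections$axon_count < 0)) abort("axon counts must be >= 0.")
  if (any(sections$nerve_width_mm <= 0)) abort("nerve widths must be > 0.")
  if (any(sections$thickness_mm <= 0)) abort("section thickness must be > 0.")
  sections |>
    dplyr::group_by(.data$animal_id, .data$group, .data$distance_mm) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      thickness = {
        th <- unique(.data$thickness_mm)
        if (length(th) > 1L) {
          abort(sprintf("mixed section thickness within animal %s at distance %g.",
                        .data$animal_id[1L], .data$distance_mm[1L]))
        }
        th
      },
      r = mean(.data$nerve_width_mm) / 2,
      axons_per_mm = mean(.data$axon_count / .data$nerve_width_mm),
      .groups = "drop"
    ) |>
    dplyr::mutate(axons_total = pi * .data$r^2 * .data$axons_per_mm / .data$thickness) |>
    dplyr::select("animal_id", "group", "distance_mm", "n_sections", "axons_total")
}

#' Compare axon regrowth between groups with an exponential-decrease model
#'
#' Fits `N(d) = N0 * exp(-k * d)` per group to animal-level axon estimates by
#' least squares on the log scale: `log(N) ~ distance * group`, with the
#' animal x distance estimate as the observational unit. The group main
#' effect tests a difference in starting axon number `N0` (curve height at
#' the lesion) and the `distance:group` interaction tests a difference in
#' the decrease rate `k`; both are Wald t-tests from the linear model. Zero
#' estimates cannot enter the log fit and are excluded with a reported
#' count; a sensitivity refit using `log(N + 0.5)` on all rows is stored
#' alongside.
#'
#' @param estimates Output of [estimate_axons()] (or any tibble with
#'   `animal_id`, `group` [exactly 2 levels], `distance_mm`, `axons_total`).
#' @return Object of class `regrowth_fit`. `tidy()` gives per-group `n0` and
#'   `k`; `glance()` the comparison p-values (`p_n0`, `p_k`), fit
#'   diagnostics, and the number of excluded zeros; `autoplot()` draws the
#'   data and fitted curves.
#' @export
fit_exponential_decrease <- function(estimates) {
  require_columns(estimates, c("animal_id", "group", "distance_mm", "axons_total"),
                  "estimates")
  groups <- sort(unique(as.character(estimates$group)))
  if (length(groups) != 2L) {
    abort(sprintf("exactly 2 groups required, got %d (%s).",
                  length(groups), paste(groups, collapse = ", ")))
  }
  zero <- estimates$axons_total <= 0
  n_zero <- sum(zero)
  if (n_zero > 0L) {
    inform(sprintf("fit_exponential_decrease: excluding %d zero estimate(s) from the log fit; see $sensitivity for an offset refit.", n_zero))
  }
  dat <- estimates[!zero, , drop = FALSE]
  for (g in groups) {
    nd <- length(unique(dat$distance_mm[dat$group == g]))
    if (nd < 2L) {
      abort(sprintf("group '%s' has %d distinct distance(s) with positive estimates; need >= 2.", g, nd))
    }
  }
  dat$group <- factor(dat$group, levels = groups)
  fit <- lm(log(axons_total) ~ distance_mm * group, data = dat)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  g2 <- paste0("group", groups[2L])
  int2 <- paste0("distance_mm:", g2)

  params <- tibble::tibble(
    group = groups,
    n0 = c(exp(cf[["(Intercept)"]]), exp(cf[["(Intercept)"]] + cf[[g2]])),
    k = c(-cf[["distance_mm"]], -(cf[["distance_mm"]] + cf[[int2]]))
  )

  sens <- lm(log(axons_total + 0.5) ~ distance_mm * group,
             data = transform(estimates, group = factor(group, levels = groups)))

  structure(
    list(
      params = params,
      p_n0 = sm[g2, "Pr(>|t|)"],
      p_k = sm[int2, "Pr(>|t|)"],
      model = fit,
      sensitivity = sens,
      n_excluded_zeros = n_zero,
      groups = groups,
      data = dat
    ),
    class = "regrowth_fit"
  )
}

#' @export
tidy.regrowth_fit <- function(x, ...) x$params

#' @export
glance.regrowth_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble::tibble(
    p_n0 = x$p_n0,
    p_k = x$p_k,
    n0_ratio = x$params$n0[2L] / x$params$n0[1L],
    sigma = sm$sigma,
    r_squared = sm$r.squared,
    n_obs = nrow(x$data),
    n_excluded_zeros = x$n_excluded_zeros
  )
}

#' @export
print.regrowth_fit <- function(x, ...) {
  cat("<regrowth_fit> N(d) = N0 * exp(-k d) per group\n")
  print(x$params)
  cat(sprintf("difference in starting number N0: p = %.4g\n", x$p_n0))
  cat(sprintf("difference in decrease rate k:   p = %.4g\n", x$p_k))
  if (x$n_excluded_zeros > 0L) {
    cat(sprintf("(%d zero estimate(s) excluded; $sensitivity holds a log(N + 0.5) refit)\n",
                x$n_excluded_zeros))
  }
  invisible(x)
}

#' @export
autoplot.regrowth_fit <- function(object, ...) {
  dd <- object$data
  grid <- tidyr::expand_grid(
    group = object$groups,
    distance_mm = seq(min(dd$distance_mm), max(dd$distance_mm), length.out = 100)
  ) |>
    dplyr::left_join(object$params, by = "group") |>
    dplyr::mutate(axons_total = .data$n0 * exp(-.data$k * .data$distance_mm))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$distance_mm, y = .data$axons_total,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from lesion (mm)", y = "estimated axons",
                  title = "Exponential-decrease fit of axon regrowth") +
    ggplot2::theme_minimal()
}

#' Summarize regenerated sprout metrics between two groups
#'
#' Per metric: group means with standard errors (`sd / sqrt(n)`) and a
#' two-tailed Student t-test with pooled variance.
#'
#' @param data Tibble with a `group` column (exactly 2 levels, `>= 2`
#'   observations each) and one numeric column per metric (e.g. sprout
#'   count, length, displacement per brain).
#' @return Tibble with one row per metric: per-group mean and SEM, pooled-t
#'   statistic, df, two-sided p.
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
#'                     length_um = c(10, 12, 11, 20, 22, 21))
#' sprout_summary(d)
#' @export
sprout_summary <- function(data) {
  require_columns(data, "group", "data")
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2L) abort("exactly 2 groups required.")
  metrics <- names(data)[vapply(data, is.numeric, logical(1))]
  metrics <- setdiff(metrics, "group")
  if (!length(metrics)) abort("no numeric metric columns found.")
  purrr::map_dfr(metrics, function(m) {
    v1 <- data[[m]][data$group == groups[1L]]
    v2 <- data[[m]][data$group == groups[2L]]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2L || length(v2) < 2L) {
      abort(sprintf("metric '%s': each group needs >= 2 observations.", m))
    }
    tt <- t.test(v1, v2, var.equal = TRUE)
    tibble::tibble(
      metric = m,
      group_1 = groups[1L], mean_1 = mean(v1), sem_1 = sd(v1) / sqrt(length(v1)),
      n_1 = length(v1),
      group_2 = groups[2L], mean_2 = mean(v2), sem_2 = sd(v2) / sqrt(length(v2)),
      n_2 = length(v2),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
}
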