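#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |ECDF_x - ECDF_y|` and a two-sided p-value: exact (by
#' enumeration over pooled-rank arrangements, via [stats::psmirnov()]) when
#' the combined sample size is at most 20, otherwise from the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(ne) * D` with effective size
#' `ne = n_x * n_y / (n_x + n_y)`.
#'
#' @param x,y Numeric vectors, each of length `>= 2`.
#' @param exact_max Combined-size threshold below which the exact null
#'   distribution is used (default 20).
#' @return One-row tibble: statistic (D), p_value, method, n_x, n_y.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # D = 1
#' @export
ks_two_sample <- function(x, y, exact_max = 20L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each sample needs at least 2 finite values.")
  }
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- ifelse(ord <= nx, 1 / nx, -1 / ny)
  d <- cumsum(steps)
  ws <- w[ord]
  eval_at <- c(diff(ws) != 0, TRUE)  # with ties, ECDF gap is defined after the tie group
  D <- max(abs(d[eval_at]))

  has_ties <- anyDuplicated(w) > 0L
  if (nx + ny <= exact_max) {
    p <- 1 - psmirnov(D, sizes = c(nx, ny), z = if (has_ties) w else NULL,
                      two.sided = TRUE, exact = TRUE)
    method <- "exact"
  } else {
    ne <- nx * ny / (nx + ny)
    t <- sqrt(ne) * D
    if (t < 1e-8) {
      p <- 1
    } else {
      k <- 1:100
      p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    }
    p <- min(max(p, 0), 1)
    method <- "asymptotic"
  }
  tibble::tibble(statistic = D, p_value = p, method = method, n_x = nx, n_y = ny)
}

# Shared core: given per-transcript log2fc and a logical presence split,
# run the KS comparison and build density-curve data.
association_core <- function(values, present, motif, fraction, subset_label,
                             density = TRUE, min_group = 10L) {
  x_with <- values[present]
  x_without <- values[!present]
  if (length(x_with) < 2L) abort(sprintf("motif group for '%s' has < 2 transcripts.", motif))
  if (length(x_without) < 2L) abort(sprintf("motif-free group for '%s' has < 2 transcripts.", motif))
  low_power <- length(x_with) < min_group || length(x_without) < min_group
  ks <- ks_two_sample(x_with, x_without)

  dens <- NULL
  if (density) {
    bw_w <- bw.nrd0(x_with)
    bw_o <- bw.nrd0(x_without)
    pad <- 3 * max(bw_w, bw_o)
    lo <- min(values) - pad
    hi <- max(values) + pad
    dw <- density(x_with, bw = bw_w, n = 512L, from = lo, to = hi)
    do <- density(x_without, bw = bw_o, n = 512L, from = lo, to = hi)
    dens <- tibble::tibble(log2fc = dw$x, density_with = dw$y, density_without = do$y)
  }

  structure(
    list(
      result = tibble::tibble(
        motif = motif,
        fraction = fraction,
        subset = subset_label,
        n_with = length(x_with),
        n_without = length(x_without),
        statistic = ks$statistic,
        p_value = ks$p_value,
        method = ks$method,
        median_with = median(x_with),
        median_without = median(x_without),
        low_power = low_power
      ),
      density = dens,
      rug = tibble::tibble(log2fc = values, present = present)
    ),
    class = "motif_association"
  )
}

#' @export
tidy.motif_association <- function(x, ...) x$result

#' @export
print.motif_association <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<motif_association> %s (%s, subset: %s)\n  n_with = %d, n_without = %d; KS D = %.4f, p = %.3g (%s)\n  median log2FC: with %.3f, without %.3f%s\n",
    r$motif, r$fraction, r$subset, r$n_with, r$n_without, r$statistic,
    r$p_value, r$method, r$median_with, r$median_without,
    if (r$low_power) "  [low power]" else ""))
  invisible(x)
}

#' @export
autoplot.motif_association <- function(object, ...) {
  r <- object$result
  if (is.null(object$density)) abort("association was computed with density = FALSE.")
  dd <- tidyr::pivot_longer(object$density, -"log2fc",
                            names_to = "group", values_to = "density")
  dd$group <- ifelse(dd$group == "density_with",
                     paste0(r$motif, "-containing"), paste0(r$motif, "-free"))
  rug <- object$rug
  rug$group <- ifelse(rug$present, paste0(r$motif, "-containing"), paste0(r$motif, "-free"))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$log2fc, y = .data$density,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_rug(data = rug,
                      ggplot2::aes(x = .data$log2fc, colour = .data$group),
                      inherit.aes = FALSE, alpha = 0.25, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(
      x = "log2 fold change (injured - naive)", y = "density",
      title = sprintf("%s association, %s fraction", r$motif, r$fraction),
      subtitle = sprintf("KS D = %.3f, p = %.2g", r$statistic, r$p_value),
      colour = NULL) +
    ggplot2::theme_minimal()
}

# Join a per-probeset DE table to per-transcript motif presence through a
# unique-transcript probeset mapping; returns transcript_id, log2fc, present.
de_presence_table <- function(de, scan, mapping, motif) {
  require_columns(de, c("probeset_id", "log2fc"), "de")
  require_columns(scan, c("transcript_id", "motif", "present"), "scan")
  map1 <- suppressMessages(map_probesets(mapping, target = "transcript"))
  motif_name <- motif
  pres <- scan |>
    dplyr::filter(.data$motif == motif_name) |>
    dplyr::distinct(.data$transcript_id, .data$present)
  if (nrow(pres) == 0L) abort(sprintf("motif '%s' not found in the scan result.", motif))
  de |>
    dplyr::inner_join(map1[, c("probeset_id", "transcript_id")], by = "probeset_id") |>
    dplyr::inner_join(pres, by = "transcript_id") |>
    dplyr::distinct(.data$transcript_id, .keep_all = TRUE) |>
    dplyr::select("transcript_id", "log2fc", "present")
}

#' Associate motif presence with injury-induced fold changes
#'
#' Partitions transcripts by 3'UTR (or 5'UTR) motif presence and compares the
#' two log2 fold-change distributions with a two-sided Kolmogorov-Smirnov
#' test. Only probesets mapping a unique transcript contribute (the unique-
#' transcript filter is applied internally via [map_probesets()]). Optionally
#' restricts to transcripts of genes in a supplied gene set (e.g. axon / CNS
#' development GO categories). Density-curve data (Gaussian KDE per group,
#' Silverman bandwidth, 512-point grid spanning the pooled range +- 3
#' bandwidths) and per-transcript rug values accompany the test.
#'
#' @param de `differential_result` (or any tibble with `probeset_id`,
#'   `log2fc`) for one fraction.
#' @param scan [scan_utrs()] output covering the relevant UTR region.
#' @param mapping Probeset-to-transcript table (`probeset_id`,
#'   `transcript_id`); multi-mappers are removed internally.
#' @param motif Motif name present in `scan`.
#' @param fraction Label recorded in the result (default taken from `de`).
#' @param subset_genes Optional gene ids restricting the analysis;
#'   requires `transcript2gene`.
#' @param transcript2gene Transcript-to-gene table, needed with
#'   `subset_genes`.
#' @param subset_label Label for the subset in the output.
#' @param density Compute density-curve data (default `TRUE`).
#' @param min_group Below this group size the result is flagged
#'   `low_power` (still computed).
#' @return A `motif_association` object: `$result` one-row tibble (n_with,
#'   n_without, KS D, p, medians, low_power flag), `$density`, `$rug`.
#'   `tidy()` extracts the result row; `autoplot()` draws the density curves.
#' @export
associate_motif <- function(de, scan, mapping, motif,
                            fraction = NULL, subset_genes = NULL,
                            transcript2gene = NULL, subset_label = NULL,
                            density = TRUE, min_group = 10L) {
  tab <- de_presence_table(de, scan, mapping, motif)
  if (is.null(fraction)) {
    fraction <- if ("fraction" %in% names(de)) as.character(de$fraction[1L]) else NA_character_
  }
  label <- subset_label %||% "all"
  if (!is.null(subset_genes)) {
    if (is.null(transcript2gene)) {
      abort("`transcript2gene` is required when `subset_genes` is given.")
    }
    require_columns(transcript2gene, c("transcript_id", "gene_id"), "transcript2gene")
    keep_tx <- transcript2gene$transcript_id[transcript2gene$gene_id %in% subset_genes]
    missing_genes <- setdiff(subset_genes, transcript2gene$gene_id)
    tab <- tab[tab$transcript_id %in% keep_tx, , drop = FALSE]
    if (nrow(tab) == 0L) {
      abort(sprintf("no analyzed transcripts for the given gene subset (%d gene(s) absent from the mapping: %s%s).",
                    length(missing_genes),
                    paste(head(missing_genes, 5L), collapse = ", "),
                    if (length(missing_genes) > 5L) ", ..." else ""))
    }
    if (is.null(subset_label)) label <- "gene_subset"
  }
  association_core(tab$log2fc, tab$present, motif, fraction, label,
                   density = density, min_group = min_group)
}

#' Motif co-occurrence test
#'
#' Tests whether two motifs co-occur in the same transcripts more often than
#' independence predicts: a 2x2 presence table over transcripts, a one-sided
#' exact hypergeometric tail for positive association, and the sample odds
#' ratio (with `Inf` when the off-diagonal is empty).
#'
#' @param scan [scan_utrs()] output containing both motifs (same UTR region).
#' @param motif_a,motif_b Motif names.
#' @return One-row tibble: motif_a, motif_b, n11, n10, n01, n00, odds_ratio,
#'   p_value. The 2x2 table is attached as attribute `"table"`.
#' @export
cooccurrence_test <- function(scan, motif_a, motif_b) {
  pres <- motif_presence(scan)
  for (m in c(motif_a, motif_b)) {
    if (!m %in% names(pres)) abort(sprintf("motif '%s' not in scan result.", m))
    if (!any(pres[[m]])) abort(sprintf("motif '%s' is absent from every transcript.", m))
  }
  pa <- pres[[motif_a]]
  pb <- pres[[motif_b]]
  n11 <- sum(pa & pb); n10 <- sum(pa & !pb)
  n01 <- sum(!pa & pb); n00 <- sum(!pa & !pb)
  N <- length(pa)
  # P(X >= n11) drawing |A| transcripts from an urn with |B| successes
  p <- phyper(n11 - 1L, sum(pb), N - sum(pb), sum(pa), lower.tail = FALSE)
  or <- if (n10 == 0L || n01 == 0L) {
    if (n11 > 0L && n00 > 0L) Inf else NaN
  } else (n11 * n00) / (n10 * n01)
  out <- tibble::tibble(
    motif_a = motif_a, motif_b = motif_b,
    n11 = n11, n10 = n10, n01 = n01, n00 = n00,
    odds_ratio = or, p_value = p
  )
  attr(out, "table") <- matrix(c(n11, n01, n10, n00), 2L, 2L,
                               dimnames = list(c("a+", "a-"), c("b+", "b-")))
  out
}

#' Combined-motif (ARE synergy) association
#'
#' Compares transcripts carrying both `motif` and the AU-rich element against
#' all other transcripts, testing whether the two elements act together on
#' injury-induced fold changes. With `require_are = FALSE` this reduces
#' exactly to [associate_motif()] for `motif` alone.
#'
#' @inheritParams associate_motif
#' @param are_motif Name of the ARE motif in the scan (default `"ARE"`).
#' @param require_are Require co-presence of the ARE in the "with" group.
#' @return A `motif_association` object (subset label records the
#'   combination).
#' @export
combined_motif_association <- function(de, scan, mapping, motif,
                                       are_motif = "ARE", require_are = TRUE,
                                       fraction = NULL, density = TRUE,
                                       min_group = 10L) {
  if (!require_are) {
    return(associate_motif(de, scan, mapping, motif, fraction = fraction,
                           density = density, min_group = min_group))
  }
  tab_m <- de_presence_table(de, scan, mapping, motif)
  tab_a <- de_presence_table(de, scan, mapping, are_motif)
  if (!any(tab_a$present)) {
    abort(sprintf("'%s' is absent from every analyzed transcript; empty combined group.", are_motif))
  }
  tab <- dplyr::inner_join(
    tab_m,
    dplyr::rename(tab_a[, c("transcript_id", "present")], present_are = "present"),
    by = "transcript_id"
  )
  combined <- tab$present & tab$present_are
  if (!any(combined)) {
    abort(sprintf("no transcript carries both '%s' and '%s'.", motif, are_motif))
  }
  if (is.null(fraction)) {
    fraction <- if ("fraction" %in% names(de)) as.character(de$fraction[1L]) else NA_character_
  }
  association_core(tab$log2fc, combined,
                   motif = sprintf("%s+%s", motif, are_motif),
                   fraction = fraction,
                   subset_label = sprintf("%s AND %s", motif, are_motif),
                   density = density, min_group = min_group)
}

#' Random-motif negative control
#'
#' Repeats the association analysis with `n_random` random motifs: literals
#' of the template motif's canonical-literal length, drawn from the empirical
#' mononucleotide composition of the scanned UTRs. A genuine sequence-specific
#' association should not reproduce under such controls; the summary reports
#' the fraction of controls rejecting at `alpha`.
#'
#' @inheritParams associate_motif
#' @param utrs UTR sequences to scan (same input forms as [scan_utrs()]).
#' @param template Template motif: a row of a motif tibble (or name found in
#'   `motifs`) whose canonical-literal length the random motifs copy.
#' @param motifs Motif table resolving `template` when given by name.
#' @param n_random Number of random motifs (`>= 1`).
#' @param seed RNG seed: the random motif set is reproducible.
#' @param alpha Rejection level summarized over controls.
#' @return List: `results` (tibble with one row per random motif: name,
#'   literal, n_with, n_without, statistic, p_value), `rejection_rate`,
#'   `alpha`, `seed`.
#' @export
control_random_motifs <- function(de, utrs, mapping, template = "CPE",
                                  motifs = default_motifs(), n_random = 100L,
                                  seed = 1L, alpha = 0.05, fraction = NULL,
                                  min_group = 10L) {
  if (n_random < 1L) abort("`n_random` must be >= 1.")
  seqs <- as_utr_vector(utrs)
  if (is.character(template) && length(template) == 1L) {
    row <- motifs[motifs$name == template, , drop = FALSE]
    if (nrow(row) == 0L) abort(sprintf("template motif '%s' not in `motifs`.", template))
  } else {
    row <- tibble::as_tibble(template)
  }
  len <- nchar(row$canonical_literal[1L])
  short <- nchar(seqs) < len
  if (any(short)) {
    warn(sprintf("%d UTR(s) shorter than the template literal (%d nt); they cannot contain a match.",
                 sum(short), len))
  }
  comp <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                       levels = c("A", "C", "G", "T")))
  comp <- comp / sum(comp)

  set.seed(seed)
  literals <- vapply(seq_len(n_random), function(i) {
    paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
  }, character(1))

  rand_motifs <- tibble::tibble(
    name = sprintf("random_%03d", seq_len(n_random)),
    region = row$region[1L] %||% "UTR3",
    regex = literals,
    canonical_literal = literals
  )
  scan <- scan_utrs(seqs, rand_motifs)
  results <- purrr::map_dfr(seq_len(n_random), function(i) {
    res <- tryCatch(
      tidy(associate_motif(de, scan, mapping, rand_motifs$name[i],
                           fraction = fraction, density = FALSE,
                           min_group = min_group)),
      error = function(e) NULL  # motif matched (almost) nothing; no test possible
    )
    if (is.null(res)) {
      return(tibble::tibble(name = rand_motifs$name[i], literal = literals[i],
                            n_with = NA_integer_, n_without = NA_integer_,
                            statistic = NA_real_, p_value = NA_real_))
    }
    tibble::tibble(name = rand_motifs$name[i], literal = literals[i],
                   n_with = res$n_with, n_without = res$n_without,
                   statistic = res$statistic, p_value = res$p_value)
  })
  tested <- !is.na(results$p_value)
  list(
    results = results,
    rejection_rate = if (any(tested)) mean(results$p_value[tested] < alpha) else NA_real_,
    n_tested = sum(tested),
    alpha = alpha,
    seed = seed
  )
}

#' 5'UTR negative control
#'
#' Runs the identical scan-and-associate pipeline on 5'UTR sequences. The
#' cis-elements under study act through the 3'UTR, so a sequence-specific
#' effect should vanish here; results are flagged as controls.
#'
#' @inheritParams associate_motif
#' @param utr5 5'UTR sequences (same input forms as [scan_utrs()]).
#' @param motifs Motif definition tibble to scan for.
#' @return Tibble with one row per motif (tidy association results plus a
#'   `control` column set to `"utr5"`).
#' @export
control_utr5 <- function(de, utr5, mapping, motifs = default_motifs(),
                         fraction = NULL, min_group = 10L) {
  scan <- scan_utrs(utr5, motifs)
  purrr::map_dfr(motifs$name, function(m) {
    res <- tryCatch(
      tidy(associate_motif(de, scan, mapping, m, fraction = fraction,
                           density = FALSE, min_group = min_group)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(motif = m, fraction = fraction %||% NA_character_,
                            subset = "all", n_with = NA_integer_,
                            n_without = NA_integer_, statistic = NA_real_,
                            p_value = NA_real_, method = NA_character_,
                            median_with = NA_real_, median_without = NA_real_,
                            low_power = NA, control = "utr5"))
    }
    res$control <- "utr5"
    res
  })
}
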