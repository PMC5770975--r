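#' Simulation configuration for a two-fraction injury study
#'
#' Assembles and validates the parameters of the synthetic-data generator,
#' which emulates the statistical structure of a polysome-profiling injury
#' experiment: 2 RNA fractions (total, polysome-bound) x 2 conditions
#' (naive, injured) x `n_replicates` arrays of log-normal probeset
#' intensities with per-array affine distortions, glog-scale replicate
#' noise, planted differential-expression categories, planted 3'UTR
#' cis-element motifs, and a motif-dependent attenuation of injury-induced
#' down-regulation in the total fraction.
#'
#' @param n_genes Number of genes (default 5000).
#' @param transcripts_per_gene Transcripts per gene (default 1).
#' @param n_replicates Arrays per condition per fraction (default 3, the
#'   study design; must be `>= 1`).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of latent
#'   baseline expression on the glog2 scale for expressed genes.
#' @param background_fraction,background_log2_mean,background_log2_sd A
#'   fraction of probesets sits at array background (low, barely expressed
#'   signal), as on real arrays where many genes are not expressed in the
#'   tissue; these low-intensity probesets are what identifies the per-array
#'   calibration offset.
#' @param noise_sd Replicate noise sd on the glog2 scale: a single number or
#'   a (monotone, positive) function of the latent mean. The default
#'   constant 0.3 yields strongly intensity-dependent variance on the raw
#'   scale.
#' @param affine_offsets,affine_scales Optional per-array distortions, in
#'   sample-sheet order (length `4 * n_replicates`); `NULL` draws offsets
#'   from Uniform(0, 20) and scales from exp(Normal(0, 0.15)).
#' @param category_fractions Named proportions over the 8 uncoupling
#'   categories; must sum to 1. The default puts most genes in `null`, makes
#'   total-fraction changes more numerous than polysome ones, and polysome
#'   changes mostly down.
#' @param effect_size_log2 Magnitude of planted injury effects (log2 units).
#' @param utr3_meanlog,utr3_sdlog,utr5_meanlog,utr5_sdlog Log-normal UTR
#'   length parameters (nucleotides).
#' @param min_utr_length Lower clamp on UTR lengths.
#' @param motifs Motif definitions used for planting and truth rescan.
#' @param motif_plant_prob Named per-motif probability of planting the
#'   canonical literal into a transcript's 3'UTR.
#' @param attenuation_motif Motif whose 3'UTR presence attenuates the total-
#'   fraction injury effect.
#' @param motif_attenuation_delta Positive log2 shift added to the total-
#'   fraction effect of transcripts carrying `attenuation_motif`.
#' @param loading_range Per-gene polysome loading factor range (fraction of
#'   the total-RNA signal engaged on polysomes; Uniform draw).
#' @param multi_map_frac Fraction of additional multi-mapping probesets
#'   (each mapped to two genes) planted to exercise unique-mapper filters.
#' @param noncoding_frac Fraction of genes labelled with a non-coding
#'   biotype (exercises the protein-coding filter).
#' @param n_go_terms,go_term_size_range Synthetic GO term count and size
#'   range.
#' @param go_special_terms Names of designated development terms into which
#'   motif-carrying genes are enriched.
#' @param go_special_size Size of each designated term.
#' @param go_motif_enrichment Odds multiplier for motif-carrying genes
#'   entering the designated terms.
#' @param iea_frac Fraction of annotations receiving the non-experimental
#'   IEA evidence code (the rest draw from the experimental codes).
#' @param n_marker_genes Number of cell-type marker genes (default 103),
#'   drawn from unaffected (null-category) genes.
#' @param seed RNG seed; fixes every output bit-for-bit.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000L,
                       transcripts_per_gene = 1L,
                       n_replicates = 3L,
                       baseline_log2_mean = 9,
                       baseline_log2_sd = 1.5,
                       background_fraction = 0.3,
                       background_log2_mean = 4,
                       background_log2_sd = 1,
                       noise_sd = 0.3,
                       affine_offsets = NULL,
                       affine_scales = NULL,
                       category_fractions = c(
                         total_up_only = 0.05, total_down_only = 0.05,
                         poly_up_only = 0.02, poly_down_only = 0.04,
                         concordant_up = 0.04, concordant_down = 0.04,
                         opposing = 0.03, null = 0.73),
                       effect_size_log2 = 1,
                       utr3_meanlog = log(300), utr3_sdlog = 0.35,
                       utr5_meanlog = log(120), utr5_sdlog = 0.35,
                       min_utr_length = 30L,
                       motifs = default_motifs(),
                       motif_plant_prob = c(CPE = 0.2, Hex = 0.15, PBE = 0.1,
                                            MBE = 0.1, ARE = 0.2),
                       attenuation_motif = "CPE",
                       motif_attenuation_delta = 0.3,
                       loading_range = c(0.2, 1),
                       multi_map_frac = 0.05,
                       noncoding_frac = 0.05,
                       n_go_terms = 30L,
                       go_term_size_range = c(20L, 150L),
                       go_special_terms = c("axon development", "CNS development"),
                       go_special_size = 150L,
                       go_motif_enrichment = 4,
                       iea_frac = 0.2,
                       n_marker_genes = 103L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1L) abort("`n_genes` must be positive.")
  if (cfg$transcripts_per_gene < 1L) abort("`transcripts_per_gene` must be positive.")
  if (cfg$n_replicates < 1L) abort("`n_replicates` must be >= 1 (zero replicates rejected).")
  cf <- cfg$category_fractions
  if (is.null(names(cf)) || !setequal(names(cf), uncoupling_categories)) {
    abort(sprintf("`category_fractions` must be named with exactly: %s.",
                  paste(uncoupling_categories, collapse = ", ")))
  }
  if (any(cf < 0) || abs(sum(cf) - 1) > 1e-8) {
    abort("`category_fractions` must be non-negative and sum to 1.")
  }
  if (is.function(cfg$noise_sd)) {
    probe <- cfg$noise_sd(c(2, 8, 14))
    if (any(probe <= 0)) abort("`noise_sd` function must be positive over its support.")
  } else if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("`noise_sd` must be positive.")
  }
  if (cfg$motif_attenuation_delta < 0) abort("`motif_attenuation_delta` must be >= 0.")
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1) {
    abort("`background_fraction` must be in [0, 1).")
  }
  validate_motifs(cfg$motifs)
  unknown <- setdiff(names(cfg$motif_plant_prob), cfg$motifs$name)
  if (length(unknown)) {
    abort(sprintf("`motif_plant_prob` names not in `motifs`: %s.",
                  paste(unknown, collapse = ", ")))
  }
  n_arrays <- 4L * cfg$n_replicates
  for (nm in c("affine_offsets", "affine_scales")) {
    v <- cfg[[nm]]
    if (!is.null(v) && length(v) != n_arrays) {
      abort(sprintf("`%s` must have length %d (one per array).", nm, n_arrays))
    }
  }
  if (!is.null(cfg$affine_scales) && any(cfg$affine_scales <= 0)) {
    abort("`affine_scales` must be positive.")
  }
  structure(cfg, class = "sim_config")
}

#' Plant a motif occurrence into a sequence
#'
#' Substitutes the motif's canonical literal at a uniformly chosen offset
#' (sequence length unchanged), guaranteeing at least one regex match.
#'
#' @param sequence A/C/G/T string at least as long as the literal.
#' @param motif One-row motif tibble (or list with `regex` and
#'   `canonical_literal`).
#' @param offset 1-based substitution offset; `NULL` draws uniformly.
#' @return The modified sequence.
#' @examples
#' plant_motif("GGGGGGGGGG", default_motifs()[1, ], offset = 2)  # "GTTTTAATGG"
#' @export
plant_motif <- function(sequence, motif, offset = NULL) {
  lit <- motif$canonical_literal[[1L]]
  if (grepl("[^ACGT]", sequence)) abort("sequence alphabet must be A/C/G/T.")
  L <- nchar(sequence)
  l <- nchar(lit)
  if (L < l) abort(sprintf("sequence (%d nt) shorter than motif literal (%d nt).", L, l))
  if (is.null(offset)) offset <- sample.int(L - l + 1L, 1L)
  if (offset < 1L || offset > L - l + 1L) abort("offset out of range.")
  paste0(substr(sequence, 1L, offset - 1L), lit,
         substr(sequence, offset + l, L))
}

random_sequences <- function(n, meanlog, sdlog, min_len, base_probs) {
  lens <- pmax(min_len, round(stats::rlnorm(n, meanlog, sdlog)))
  vapply(lens, function(L) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
}

category_effects <- function(category, effect, sign_draw) {
  total <- numeric(length(category))
  poly <- numeric(length(category))
  total[category == "total_up_only"] <- effect
  total[category == "total_down_only"] <- -effect
  poly[category == "poly_up_only"] <- effect
  poly[category == "poly_down_only"] <- -effect
  total[category == "concordant_up"] <- effect
  poly[category == "concordant_up"] <- effect
  total[category == "concordant_down"] <- -effect
  poly[category == "concordant_down"] <- -effect
  opp <- category == "opposing"
  total[opp] <- sign_draw[opp] * effect
  poly[opp] <- -sign_draw[opp] * effect
  list(total = total, poly = poly)
}

#' Generate a fully labelled synthetic two-fraction dataset
#'
#' Runs the generator described in [sim_config()]. The polysome-bound
#' fraction is derived from the same latent total-fraction expression
#' through a per-gene loading factor (so it is a subset-like signal, never
#' an independent redraw); injury effects are planted per the configured
#' uncoupling categories; motif canonical literals are planted into 3'UTRs
#' and the truth motif flags are defined by rescanning the emitted
#' sequences, so flags and sequences can never disagree; the attenuation
#' delta is added to the total-fraction effect of every transcript whose
#' emitted 3'UTR carries the attenuation motif.
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_experiment` list: `raw_total`, `raw_polysome`
#'   (tibbles, probeset_id + one column per sample), `samples`, `utr3`,
#'   `utr5` (tibbles: transcript_id, sequence), `probeset2transcript`,
#'   `transcript2gene` (with biotype), `go_annotations`, `go_terms`,
#'   `marker_panel`, and `truth` (per-transcript category, motif flags,
#'   planted effects, loading; per-array distortions).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  tpg <- config$transcripts_per_gene
  nr <- config$n_replicates
  noise_fun <- if (is.function(config$noise_sd)) config$noise_sd
               else local({s <- config$noise_sd; function(m) rep_len(s, length(m))})

  genes <- sprintf("G%05d", seq_len(ng))

  # -- stage 1: categories, effects, baselines, loading, biotypes
  set.seed(stage_seed(config$seed, 1L))
  category <- sample(names(config$category_fractions), ng, replace = TRUE,
                     prob = config$category_fractions)
  sign_draw <- sample(c(-1, 1), ng, replace = TRUE)
  eff <- category_effects(category, config$effect_size_log2, sign_draw)
  is_background <- runif(ng) < config$background_fraction
  baseline <- ifelse(
    is_background,
    rnorm(ng, config$background_log2_mean, config$background_log2_sd),
    rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd))
  loading <- runif(ng, config$loading_range[1L], config$loading_range[2L])
  biotype <- ifelse(runif(ng) < config$noncoding_frac, "lincRNA", "protein_coding")

  gene_tbl <- tibble::tibble(
    gene_id = genes, category = category, biotype = biotype,
    background = is_background,
    baseline_glog2 = baseline, loading = loading,
    total_effect_log2 = eff$total, poly_effect_log2 = eff$poly
  )

  transcripts <- tibble::tibble(
    transcript_id = sprintf("T%05d.%d", rep(seq_len(ng), each = tpg),
                            rep(seq_len(tpg), ng)),
    gene_id = rep(genes, each = tpg),
    biotype = rep(biotype, each = tpg)
  )
  nt <- nrow(transcripts)

  # -- stage 2: UTR sequences (3'UTRs AT-rich, 5'UTRs GC-rich)
  set.seed(stage_seed(config$seed, 2L))
  min_len <- max(config$min_utr_length, max(nchar(config$motifs$canonical_literal)))
  utr3_seq <- random_sequences(nt, config$utr3_meanlog, config$utr3_sdlog,
                               min_len, c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  utr5_seq <- random_sequences(nt, config$utr5_meanlog, config$utr5_sdlog,
                               min_len, c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))

  # -- stage 3: motif planting into 3'UTRs
  set.seed(stage_seed(config$seed, 3L))
  planted <- matrix(FALSE, nt, length(config$motif_plant_prob),
                    dimnames = list(NULL, names(config$motif_plant_prob)))
  for (m in names(config$motif_plant_prob)) {
    row <- config$motifs[config$motifs$name == m, , drop = FALSE]
    hit <- runif(nt) < config$motif_plant_prob[[m]]
    planted[, m] <- hit
    for (i in which(hit)) {
      utr3_seq[i] <- plant_motif(utr3_seq[i], row)
    }
  }

  # Truth flags come from rescanning what was actually emitted.
  scan3 <- scan_utrs(setNames(utr3_seq, transcripts$transcript_id), config$motifs)
  pres <- motif_presence(scan3)
  pres <- pres[match(transcripts$transcript_id, pres$transcript_id), , drop = FALSE]

  # Attenuation: genes whose transcript(s) carry the attenuation motif get a
  # positive shift in the total-fraction injury effect.
  atten_gene <- rep(FALSE, ng)
  if (config$motif_attenuation_delta > 0 &&
      config$attenuation_motif %in% names(pres)) {
    tx_flag <- pres[[config$attenuation_motif]]
    atten_gene <- vapply(split(tx_flag, transcripts$gene_id), any, logical(1))[genes]
  }
  total_effect <- gene_tbl$total_effect_log2 +
    ifelse(atten_gene, config$motif_attenuation_delta, 0)
  gene_tbl$total_effect_log2 <- total_effect

  # -- stage 4: probesets (one per transcript + multi-mappers)
  set.seed(stage_seed(config$seed, 4L))
  ps_unique <- tibble::tibble(
    probeset_id = sprintf("PS%05d_at", seq_len(nt)),
    transcript_id = transcripts$transcript_id
  )
  n_multi <- round(config$multi_map_frac * nt)
  p2t <- ps_unique
  if (n_multi > 0L && ng >= 2L) {
    multi_rows <- purrr::map_dfr(seq_len(n_multi), function(i) {
      gs <- sample.int(ng, 2L)
      tx <- transcripts$transcript_id[match(genes[gs], transcripts$gene_id)]
      tibble::tibble(
        probeset_id = sprintf("PSX%04d_x_at", i),
        transcript_id = tx
      )
    })
    p2t <- dplyr::bind_rows(ps_unique, multi_rows)
  }

  # -- stage 5: latent signal and glog-scale noise per array
  set.seed(stage_seed(config$seed, 5L))
  samples <- tidyr::expand_grid(
    fraction = c("total", "polysome"),
    condition = c("naive", "injured"),
    replicate = seq_len(nr)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_%d", .data$fraction,
                                      .data$condition, .data$replicate)) |>
    dplyr::select("sample_id", "fraction", "condition", "replicate")

  if (is.null(config$affine_offsets)) {
    offsets <- runif(nrow(samples), 0, 20)
  } else offsets <- config$affine_offsets
  if (is.null(config$affine_scales)) {
    scales <- exp(rnorm(nrow(samples), 0, 0.15))
  } else scales <- config$affine_scales

  # latent glog2 mean per probeset per (fraction, condition); a multi-mapping
  # probeset takes its signal from the first transcript it maps to
  ps_ids <- unique(p2t$probeset_id)
  first_tx <- p2t$transcript_id[match(ps_ids, p2t$probeset_id)]
  ps_gene_idx <- match(transcripts$gene_id[match(first_tx, transcripts$transcript_id)],
                       genes)
  np <- length(ps_ids)

  latent_mean <- function(fraction, condition) {
    g <- ps_gene_idx
    m <- gene_tbl$baseline_glog2[g]
    if (fraction == "polysome") m <- m + log2(gene_tbl$loading[g])
    if (condition == "injured") {
      m <- m + if (fraction == "total") gene_tbl$total_effect_log2[g]
               else gene_tbl$poly_effect_log2[g]
    }
    m
  }

  raw <- matrix(NA_real_, np, nrow(samples),
                dimnames = list(ps_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- latent_mean(samples$fraction[j], samples$condition[j])
    z <- mu + rnorm(np, 0, noise_fun(mu))
    raw[, j] <- offsets[j] + scales[j] * iglog2(z)
  }
  raw[raw < 0] <- 0  # affine distortions keep intensities physical

  tot_cols <- samples$sample_id[samples$fraction == "total"]
  pol_cols <- samples$sample_id[samples$fraction == "polysome"]

  # -- stage 6: synthetic GO annotation
  set.seed(stage_seed(config$seed, 6L))
  tx_atten <- if (config$attenuation_motif %in% names(pres)) {
    pres[[config$attenuation_motif]]
  } else rep(FALSE, nt)
  gene_motif <- vapply(split(tx_atten, transcripts$gene_id), any, logical(1))[genes]
  go_terms <- tibble::tibble(
    go_id = sprintf("GO:SYN%04d", seq_len(config$n_go_terms + length(config$go_special_terms))),
    go_name = c(config$go_special_terms,
                sprintf("synthetic process %d", seq_len(config$n_go_terms))),
    special = c(rep(TRUE, length(config$go_special_terms)),
                rep(FALSE, config$n_go_terms))
  )
  evidence_pool <- experimental_evidence_codes()
  annotations <- purrr::map_dfr(seq_len(nrow(go_terms)), function(i) {
    if (go_terms$special[i]) {
      size <- min(config$go_special_size, ng)
      w <- ifelse(gene_motif, config$go_motif_enrichment, 1)
      members <- sample(genes, size, prob = w)
    } else {
      size <- sample(seq(config$go_term_size_range[1L],
                         config$go_term_size_range[2L]), 1L)
      members <- sample(genes, min(size, ng))
    }
    tibble::tibble(gene_id = members, go_id = go_terms$go_id[i])
  })
  annotations$evidence_code <- ifelse(
    runif(nrow(annotations)) < config$iea_frac, "IEA",
    sample(evidence_pool, nrow(annotations), replace = TRUE))

  # -- stage 7: marker panel from unaffected genes
  set.seed(stage_seed(config$seed, 7L))
  null_genes <- genes[category == "null"]
  n_mark <- min(config$n_marker_genes, length(null_genes))
  marker_panel <- tibble::tibble(
    gene_id = sample(null_genes, n_mark),
    cell_type = rep_len(c("motor_neuron", "oligodendrocyte", "microglia",
                          "precursor", "blood"), n_mark)
  )

  truth_tx <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    gene_id = transcripts$gene_id,
    category = gene_tbl$category[match(transcripts$gene_id, gene_tbl$gene_id)],
    total_effect_log2 = gene_tbl$total_effect_log2[match(transcripts$gene_id, gene_tbl$gene_id)],
    poly_effect_log2 = gene_tbl$poly_effect_log2[match(transcripts$gene_id, gene_tbl$gene_id)],
    loading = gene_tbl$loading[match(transcripts$gene_id, gene_tbl$gene_id)]
  )
  for (m in setdiff(names(pres), "transcript_id")) {
    truth_tx[[paste0("motif_", m)]] <- pres[[m]]
    truth_tx[[paste0("planted_", m)]] <- if (m %in% colnames(planted)) planted[, m] else FALSE
  }

  structure(
    list(
      config = config,
      raw_total = matrix_to_tibble(raw[, tot_cols, drop = FALSE]),
      raw_polysome = matrix_to_tibble(raw[, pol_cols, drop = FALSE]),
      samples = samples,
      utr3 = tibble::tibble(transcript_id = transcripts$transcript_id, sequence = utr3_seq),
      utr5 = tibble::tibble(transcript_id = transcripts$transcript_id, sequence = utr5_seq),
      probeset2transcript = p2t,
      transcript2gene = transcripts,
      go_annotations = annotations,
      go_terms = go_terms,
      marker_panel = marker_panel,
      truth = list(
        transcripts = truth_tx,
        genes = gene_tbl,
        arrays = dplyr::bind_cols(samples, tibble::tibble(offset = offsets, scale = scales))
      )
    ),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment> %d genes, %d transcripts, %d probesets; %d arrays (2 fractions x 2 conditions x %d replicates)\n",
    x$config$n_genes, nrow(x$transcript2gene), nrow(x$raw_total),
    nrow(x$samples), x$config$n_replicates))
  counts <- table(x$truth$genes$category)
  cat("gene categories:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Score pipeline outputs against the simulation truth
#'
#' Compares predicted uncoupling categories with the planted truth and, when
#' association results are supplied, flags for each motif whether the
#' planted association was detected at `alpha`.
#'
#' @param truth `$truth` element of a [simulate_experiment()] result (or its
#'   `$genes`/`$transcripts` tibble with `gene_id` and `category`).
#' @param calls Predicted categories: tibble with `gene_id` (or first
#'   column) and `category`, e.g. from [classify_uncoupling()] after gene
#'   mapping. May be empty.
#' @param associations Optional tidy association results (`motif`,
#'   `fraction`, `p_value`).
#' @param alpha Detection level for motif associations.
#' @return List: `confusion` (truth x predicted contingency tibble),
#'   `category_metrics` (per-category sensitivity and specificity),
#'   `accuracy`, `no_calls` flag, and `motif_detection` when associations
#'   were given.
#' @export
truth_report <- function(truth, calls, associations = NULL, alpha = 0.05) {
  tt <- if (is.data.frame(truth)) truth
        else if (!is.null(truth$genes)) truth$genes
        else truth$transcripts
  require_columns(tt, c("gene_id", "category"), "truth")

  if (is.null(calls) || nrow(calls) == 0L) {
    metrics <- tibble::tibble(category = uncoupling_categories,
                              n_truth = as.integer(table(factor(tt$category, uncoupling_categories))),
                              sensitivity = 0, specificity = NA_real_)
    out <- list(confusion = NULL, category_metrics = metrics,
                accuracy = 0, no_calls = TRUE)
  } else {
    id_col <- if ("gene_id" %in% names(calls)) "gene_id" else names(calls)[1L]
    require_columns(calls, "category", "calls")
    missing <- setdiff(calls[[id_col]], tt$gene_id)
    extra <- setdiff(tt$gene_id, calls[[id_col]])
    if (length(missing)) {
      abort(sprintf("identifier mismatch: %d call id(s) absent from truth (e.g. %s).",
                    length(missing), paste(head(missing, 5L), collapse = ", ")))
    }
    merged <- tibble::tibble(gene_id = calls[[id_col]], predicted = calls$category) |>
      dplyr::inner_join(tt[, c("gene_id", "category")], by = "gene_id") |>
      dplyr::rename(truth = "category")
    conf <- merged |>
      dplyr::count(.data$truth, .data$predicted, name = "n")
    metrics <- purrr::map_dfr(uncoupling_categories, function(cc) {
      tp <- sum(merged$truth == cc & merged$predicted == cc)
      fn <- sum(merged$truth == cc & merged$predicted != cc)
      tn <- sum(merged$truth != cc & merged$predicted != cc)
      fp <- sum(merged$truth != cc & merged$predicted == cc)
      tibble::tibble(
        category = cc, n_truth = tp + fn,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
      )
    })
    out <- list(
      confusion = conf,
      category_metrics = metrics,
      accuracy = mean(merged$truth == merged$predicted),
      no_calls = FALSE,
      n_scored = nrow(merged),
      n_unscored_truth = length(extra)
    )
  }

  if (!is.null(associations)) {
    require_columns(associations, c("motif", "p_value"), "associations")
    det <- associations
    det$detected <- det$p_value < alpha
    out$motif_detection <- det[, intersect(c("motif", "fraction", "subset",
                                             "p_value", "detected"), names(det))]
    out$alpha <- alpha
  }
  out
}
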