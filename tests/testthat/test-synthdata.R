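test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_genes = 150, seed = 42)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(sim_config(n_genes = 150, seed = 43))
  expect_false(identical(s1$raw_total, s3$raw_total))
})

test_that("an all-null configuration plants no effects anywhere", {
  cfg <- null_sim_config(n_genes = 300, seed = 3)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$genes$category == "null"))
  expect_true(all(sim$truth$genes$total_effect_log2 == 0))
  expect_true(all(sim$truth$genes$poly_effect_log2 == 0))
  # expected group mean difference ~ 0 on the latent scale: raw group means
  # differ only by noise and array distortions, not systematically per gene
  fit <- glog_normalize(sim$raw_total)
  z <- as.matrix(fit$normalized[, -1])
  fc <- rowMeans(z[, 4:6]) - rowMeans(z[, 1:3])
  expect_lt(abs(mean(fc)), 0.05)
})

test_that("truth motif flags agree exactly with a rescan of the emitted FASTA", {
  cfg <- sim_config(n_genes = 600, seed = 8)
  sim <- simulate_experiment(cfg)
  rescan <- motif_presence(scan_utrs(sim$utr3, cfg$motifs))
  rescan <- rescan[match(sim$truth$transcripts$transcript_id,
                         rescan$transcript_id), ]
  for (m in cfg$motifs$name) {
    expect_identical(sim$truth$transcripts[[paste0("motif_", m)]],
                     rescan[[m]], info = m)
  }
  # every transcript appears exactly once in the FASTA
  expect_identical(sort(sim$utr3$transcript_id),
                   sort(sim$transcript2gene$transcript_id))
  expect_false(anyDuplicated(sim$utr3$transcript_id) > 0)
})

test_that("planting probability is a lower bound on scanned presence", {
  cfg <- sim_config(n_genes = 2000, seed = 21,
                    motif_plant_prob = c(CPE = 0.2))
  sim <- simulate_experiment(cfg)
  scan <- scan_utrs(sim$utr3, cfg$motifs[cfg$motifs$name == "CPE", ])
  frac <- mean(motif_presence(scan)$CPE)
  expect_gte(frac, 0.2)  # planting plus background chance
  # planted transcripts always match
  planted <- sim$truth$transcripts$planted_CPE
  expect_true(all(sim$truth$transcripts$motif_CPE[planted]))
})

test_that("plant_motif behaves per its contract", {
  cpe <- default_motifs()[default_motifs()$name == "CPE", ]
  out <- plant_motif("GGGGGGGGGG", cpe, offset = 2)
  expect_identical(out, "GTTTTAATGG")
  expect_identical(nchar(out), 10L)
  expect_gte(motif_count_oracle(out, cpe$regex), 1L)

  # planting into an already matching sequence keeps a match
  already <- plant_motif("TTTTAATGGG", cpe, offset = 4)
  expect_gte(motif_count_oracle(already, cpe$regex), 1L)

  # deterministic offsets under a fixed seed
  seqs <- replicate(50, paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  set.seed(99); r1 <- vapply(seqs, plant_motif, character(1), motif = cpe)
  set.seed(99); r2 <- vapply(seqs, plant_motif, character(1), motif = cpe)
  expect_identical(r1, r2)

  expect_error(plant_motif("ACGT", cpe), "shorter")
  expect_error(plant_motif("ACGTN", cpe), "alphabet")
})

test_that("polysome latent signal is total expression shifted by the loading factor", {
  base <- list(n_genes = 400, seed = 17, noise_sd = 0.01,
               affine_offsets = rep(0, 12), affine_scales = rep(1, 12))
  cfg1 <- do.call(null_sim_config, c(base, list(loading_range = c(1, 1))))
  sim1 <- simulate_experiment(cfg1)
  tot <- rowMeans(glog2(as.matrix(sim1$raw_total[, -1])))
  pol <- rowMeans(glog2(as.matrix(sim1$raw_polysome[, -1])))
  ps_gene <- probeset_to_gene(sim1)
  keep <- match(ps_gene$probeset_id, sim1$raw_total$probeset_id)
  # loading == 1 makes the two fractions identical in latent mean
  expect_lt(max(abs(tot[keep] - pol[keep])), 0.05)

  cfg2 <- do.call(null_sim_config, c(base, list(loading_range = c(0.25, 0.25))))
  sim2 <- simulate_experiment(cfg2)
  tot2 <- rowMeans(glog2(as.matrix(sim2$raw_total[, -1])))
  pol2 <- rowMeans(glog2(as.matrix(sim2$raw_polysome[, -1])))
  expect_equal(mean(tot2[keep] - pol2[keep]), -log2(0.25), tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(category_fractions = c(null = 0.9)), "named with exactly")
  bad <- null_category_fractions; bad["null"] <- 0.8
  expect_error(sim_config(category_fractions = bad), "sum to 1")
  expect_error(sim_config(n_replicates = 0), "zero replicates")
  expect_error(sim_config(noise_sd = -1), "positive")
  expect_error(sim_config(affine_scales = rep(-1, 12)), "positive")
  expect_error(sim_config(affine_offsets = c(1, 2)), "length 12")
})

test_that("truth_report scores calls and flags motif detections", {
  cfg <- sim_config(n_genes = 200, seed = 4)
  sim <- simulate_experiment(cfg)
  truth_genes <- sim$truth$genes

  perfect <- truth_genes[, c("gene_id", "category")]
  rep1 <- truth_report(sim$truth, perfect)
  expect_equal(rep1$accuracy, 1)
  expect_true(all(rep1$category_metrics$sensitivity[
    rep1$category_metrics$n_truth > 0] == 1))
  expect_false(rep1$no_calls)

  rep0 <- truth_report(sim$truth, perfect[0, ])
  expect_true(rep0$no_calls)
  expect_true(all(rep0$category_metrics$sensitivity == 0))

  bad <- perfect
  bad$gene_id[1] <- "NOT_A_GENE"
  expect_error(truth_report(sim$truth, bad), "NOT_A_GENE")

  assoc <- tibble::tibble(motif = c("CPE", "ARE"), fraction = "total",
                          p_value = c(1e-6, 0.4))
  rep2 <- truth_report(sim$truth, perfect, associations = assoc)
  expect_identical(rep2$motif_detection$detected, c(TRUE, FALSE))
})

test_that("random calls on a balanced two-category truth score near chance", {
  truth <- list(genes = tibble::tibble(
    gene_id = sprintf("G%03d", 1:400),
    category = rep(c("total_up_only", "null"), each = 200)
  ))
  set.seed(5)
  calls <- tibble::tibble(
    gene_id = truth$genes$gene_id,
    category = sample(c("total_up_only", "null"), 400, TRUE)
  )
  rep <- truth_report(truth, calls)
  sens <- rep$category_metrics$sensitivity[
    rep$category_metrics$category == "total_up_only"]
  expect_gt(sens, 0.5 - 1.96 * sqrt(0.25 / 200))
  expect_lt(sens, 0.5 + 1.96 * sqrt(0.25 / 200))
})

test_that("written simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(sim_config(n_genes = 60, seed = 12))
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "total.tsv", "polysome.tsv", "samples.tsv", "utr3.fa", "utr5.fa",
    "probeset2transcript.tsv", "transcript2gene.tsv", "go_annotations.tsv",
    "truth.json")))))
  utr3 <- read_utr_fasta(file.path(dir, "utr3.fa"))
  expect_identical(utr3$sequence, sim$utr3$sequence)
  tot <- read_intensity_tsv(file.path(dir, "total.tsv"))
  expect_equal(as.matrix(tot[, -1]), as.matrix(sim$raw_total[, -1]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(read_utr_fasta(file.path(dir, "nope.fa")), "nope.fa")
})
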