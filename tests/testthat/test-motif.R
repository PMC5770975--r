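test_that("scanning finds motif occurrences with 0-based half-open intervals", {
  scan <- scan_utrs(c(tx1 = "CCAATAAACC"),
                    default_motifs()[default_motifs()$name == "Hex", ],
                    intervals = TRUE)
  expect_identical(scan$count, 1L)
  expect_true(scan$present)
  iv <- scan$intervals[[1]]
  expect_identical(iv$start, 2L)
  expect_identical(iv$end, 8L)

  # CPE planted twice disjointly
  seq2 <- "GGTTTTAATGGGGTTTTAATGG"
  scan2 <- scan_utrs(c(tx = seq2), default_motifs()[1, ])
  expect_identical(scan2$count, 2L)
})

test_that("overlapping matches are counted by the advance-one convention", {
  motifs <- tibble::tibble(name = "AA", region = "UTR3", regex = "AA",
                           canonical_literal = "AA")
  scan <- scan_utrs(c(t1 = "AAAA"), motifs)
  expect_identical(scan$count, 3L)

  # all-offsets oracle over random sequences and the built-in regexes
  set.seed(3)
  mt <- default_motifs()
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    sc <- scan_utrs(setNames(s, "t"), mt)
    for (j in seq_len(nrow(mt))) {
      expect_identical(sc$count[sc$motif == mt$name[j]],
                       motif_count_oracle(s, mt$regex[j]),
                       info = paste(mt$name[j], s))
    }
  }
})

test_that("scanning normalizes case and U, is order-invariant, and rejects bad input", {
  mt <- default_motifs()[1, ]
  expect_identical(scan_utrs(c(a = "gguuuuaaugg"), mt)$count, 1L)
  seqs <- c(a = "GGTTTTAATGG", b = "CCCCCCCC", c = "TTTTAATTTTAAT")
  s1 <- scan_utrs(seqs, mt)
  s2 <- scan_utrs(rev(seqs), mt)
  expect_equal(dplyr::arrange(s1, transcript_id),
               dplyr::arrange(s2, transcript_id))
  # idempotent presence
  expect_identical(scan_utrs(seqs, mt)$present, s1$present)
  # N never matches
  expect_identical(scan_utrs(c(n = "TTTTNAT"), mt)$count, 0L)
  expect_error(scan_utrs(c(x = "ACGTZ"), mt), "invalid characters")
})

test_that("KS statistic and exact p match enumeration for small samples", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 1)
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  r2 <- ks_two_sample(c(1, 3), c(2, 4))
  expect_equal(r2$statistic, 0.5)
  expect_equal(r2$p_value, ks_p_oracle(c(1, 3), c(2, 4)))

  set.seed(29)
  for (i in 1:25) {
    nx <- sample(2:7, 1)
    ny <- sample(2:min(8 - nx + 2, 8), 1)
    if (nx + ny > 10) next
    x <- rnorm(nx); y <- rnorm(ny, sample(c(0, 1), 1))
    got <- ks_two_sample(x, y)
    expect_equal(got$statistic, ks_D_oracle(x, y), tolerance = 1e-12)
    expect_equal(got$p_value, ks_p_oracle(x, y), tolerance = 1e-12)
    expect_identical(got$method, "exact")
  }
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("the asymptotic KS branch matches the Kolmogorov series", {
  set.seed(97)
  x <- rnorm(150); y <- rnorm(120, 0.3)
  got <- ks_two_sample(x, y)
  expect_identical(got$method, "asymptotic")
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

# direct association fixture: identity probeset->transcript mapping
assoc_fixture <- function(n = 2000, shift = 0.3, seed = 1) {
  set.seed(seed)
  tx <- sprintf("t%04d", 1:(2 * n))
  present <- rep(c(TRUE, FALSE), each = n)
  fc <- rnorm(2 * n, 0, 0.4) + ifelse(present, shift, 0)
  list(
    de = make_de(paste0("ps_", tx), fc, runif(2 * n)),
    scan = tibble::tibble(transcript_id = tx, motif = "CPE", regex = "x",
                          count = as.integer(present), present = present),
    mapping = tibble::tibble(probeset_id = paste0("ps_", tx), transcript_id = tx)
  )
}

test_that("a planted location shift is detected with the motif group higher", {
  fx <- assoc_fixture(n = 2000, shift = 0.3)
  a <- associate_motif(fx$de, fx$scan, fx$mapping, "CPE")
  r <- tidy(a)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$median_with, r$median_without)
  expect_identical(r$n_with + r$n_without, 4000L)
})

test_that("the association is calibrated under the null", {
  rejections <- vapply(1:100, function(s) {
    fx <- assoc_fixture(n = 100, shift = 0, seed = s + 1000)
    tidy(associate_motif(fx$de, fx$scan, fx$mapping, "CPE",
                         density = FALSE))$p_value < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 10L)
})

test_that("density-curve data integrates to one per group", {
  fx <- assoc_fixture(n = 500, shift = 0.3)
  a <- associate_motif(fx$de, fx$scan, fx$mapping, "CPE")
  d <- a$density
  dx <- diff(d$log2fc)
  trap <- function(y) sum(dx * (head(y, -1) + y[-1]) / 2)
  expect_equal(trap(d$density_with), 1, tolerance = 0.01)
  expect_equal(trap(d$density_without), 1, tolerance = 0.01)
})

test_that("gene subsets restrict the analysis and absent subsets error", {
  fx <- assoc_fixture(n = 200, shift = 0.5)
  t2g <- tibble::tibble(transcript_id = fx$scan$transcript_id,
                        gene_id = toupper(fx$scan$transcript_id))
  sub <- t2g$gene_id[1:250]
  a <- associate_motif(fx$de, fx$scan, fx$mapping, "CPE",
                       subset_genes = sub, transcript2gene = t2g)
  expect_identical(tidy(a)$n_with + tidy(a)$n_without, 250L)
  expect_error(
    associate_motif(fx$de, fx$scan, fx$mapping, "CPE",
                    subset_genes = c("NOPE1", "NOPE2"), transcript2gene = t2g),
    "NOPE1")
})

test_that("small groups are flagged low-power but still computed", {
  fx <- assoc_fixture(n = 200, shift = 0)
  fx$scan$present <- c(rep(TRUE, 5), rep(FALSE, 395))
  fx$scan$count <- as.integer(fx$scan$present)
  a <- associate_motif(fx$de, fx$scan, fx$mapping, "CPE")
  expect_true(tidy(a)$low_power)
  expect_false(is.na(tidy(a)$p_value))
})

test_that("co-occurrence testing covers independence, nesting, and the exact tail", {
  set.seed(41)
  n <- 10000
  tx <- sprintf("t%05d", 1:n)
  pa <- runif(n) < 0.3
  pb <- runif(n) < 0.3
  scan <- dplyr::bind_rows(
    tibble::tibble(transcript_id = tx, motif = "A", regex = "x",
                   count = as.integer(pa), present = pa),
    tibble::tibble(transcript_id = tx, motif = "B", regex = "x",
                   count = as.integer(pb), present = pb))
  ind <- cooccurrence_test(scan, "A", "B")
  expect_gt(ind$p_value, 0.05)
  expect_lt(abs(ind$odds_ratio - 1), 0.25)

  # perfect nesting: B only where A
  pb2 <- pa & (runif(n) < 0.5)
  scan2 <- dplyr::bind_rows(
    tibble::tibble(transcript_id = tx, motif = "A", regex = "x",
                   count = as.integer(pa), present = pa),
    tibble::tibble(transcript_id = tx, motif = "B", regex = "x",
                   count = as.integer(pb2), present = pb2))
  nest <- cooccurrence_test(scan2, "A", "B")
  expect_identical(nest$odds_ratio, Inf)
  expect_lt(nest$p_value, 1e-6)

  # [[10,0],[0,10]] -> one-sided exact tail 1 / C(20,10)
  tx20 <- sprintf("s%02d", 1:20)
  p1 <- rep(c(TRUE, FALSE), each = 10)
  scan3 <- dplyr::bind_rows(
    tibble::tibble(transcript_id = tx20, motif = "A", regex = "x",
                   count = as.integer(p1), present = p1),
    tibble::tibble(transcript_id = tx20, motif = "B", regex = "x",
                   count = as.integer(p1), present = p1))
  exact <- cooccurrence_test(scan3, "A", "B")
  expect_equal(exact$p_value, 1 / choose(20, 10), tolerance = 1e-12)

  scan_none <- scan3
  scan_none$present[scan_none$motif == "B"] <- FALSE
  expect_error(cooccurrence_test(scan_none, "A", "B"), "absent")
})

test_that("combined ARE analysis reduces to the single-motif test when off", {
  set.seed(53)
  n <- 600
  tx <- sprintf("t%04d", 1:n)
  pm <- runif(n) < 0.4
  pare <- runif(n) < 0.5
  both <- pm & pare
  fc <- rnorm(n, 0, 0.4) + ifelse(both, 0.5, 0)  # synergy: shift only when both
  de <- make_de(paste0("ps_", tx), fc, runif(n))
  mapping <- tibble::tibble(probeset_id = paste0("ps_", tx), transcript_id = tx)
  scan <- dplyr::bind_rows(
    tibble::tibble(transcript_id = tx, motif = "PBE", regex = "x",
                   count = as.integer(pm), present = pm),
    tibble::tibble(transcript_id = tx, motif = "ARE", regex = "x",
                   count = as.integer(pare), present = pare))

  off <- combined_motif_association(de, scan, mapping, "PBE", require_are = FALSE)
  single <- associate_motif(de, scan, mapping, "PBE")
  expect_equal(tidy(off)$statistic, tidy(single)$statistic)
  expect_equal(tidy(off)$p_value, tidy(single)$p_value)

  on <- combined_motif_association(de, scan, mapping, "PBE", require_are = TRUE)
  expect_lt(tidy(on)$p_value, tidy(single)$p_value)

  scan_noare <- scan
  scan_noare$present[scan_noare$motif == "ARE"] <- FALSE
  expect_error(
    combined_motif_association(de, scan_noare, mapping, "PBE", require_are = TRUE),
    "absent")
})

test_that("random control motifs are reproducible with the template's length", {
  fx <- assoc_fixture(n = 150, shift = 0, seed = 11)
  utrs <- setNames(
    vapply(seq_len(nrow(fx$scan)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    }, character(1)),
    fx$scan$transcript_id)
  set.seed(2)
  c1 <- control_random_motifs(fx$de, utrs, fx$mapping, template = "CPE",
                              n_random = 12, seed = 7)
  c2 <- control_random_motifs(fx$de, utrs, fx$mapping, template = "CPE",
                              n_random = 12, seed = 7)
  expect_identical(c1$results$literal, c2$results$literal)
  expect_true(all(nchar(c1$results$literal) == 7L))  # CPE literal length
  expect_error(control_random_motifs(fx$de, utrs, fx$mapping, n_random = 0),
               "n_random")
})

test_that("5'UTR control reproduces the 3'UTR result on copied sequences", {
  cfg <- sim_config(n_genes = 500, seed = 19)
  sim <- simulate_experiment(cfg)
  fit <- glog_normalize(sim$raw_total)
  de <- suppressWarnings(
    moderated_t_test(fit$normalized, samples_for(sim, "total"),
                     fraction = "total"))
  scan3 <- scan_utrs(sim$utr3, cfg$motifs)
  a3 <- tidy(associate_motif(de, scan3, sim$probeset2transcript, "CPE",
                             density = FALSE))
  # feed the 3'UTR sequences through the 5'UTR control path
  copy <- sim$utr3
  ctrl <- control_utr5(de, copy, sim$probeset2transcript,
                       motifs = cfg$motifs[cfg$motifs$name == "CPE", ])
  expect_equal(ctrl$statistic, a3$statistic)
  expect_equal(ctrl$p_value, a3$p_value)
  expect_identical(ctrl$control, "utr5")
})
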