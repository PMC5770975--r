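test_that("hypergeometric tails match their analytic values", {
  r <- hypergeom_test(5, 5, 5, 10)
  expect_equal(r$p_over, 1 / choose(10, 5))
  expect_equal(r$p_under, 1)

  # draw exactly at expectation: neither tail small
  r2 <- hypergeom_test(2, 4, 5, 10)
  expect_gt(r2$p_over, 0.05)
  expect_gt(r2$p_under, 0.05)

  # degenerate urn: every gene annotated forces k = n
  r3 <- hypergeom_test(4, 4, 10, 10)
  expect_equal(r3$p_over, 1)
  expect_equal(r3$p_under, 1)

  expect_error(hypergeom_test(6, 5, 5, 10), "min")
  expect_error(hypergeom_test(2, 11, 5, 10), "universe")
  expect_error(hypergeom_test(0, 5, 9, 10), "feasible")
})

test_that("hypergeometric tails equal exhaustive enumeration for N <= 12", {
  set.seed(19)
  for (i in 1:12) {
    N <- sample(4:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    exact <- hypergeom_oracle(k, n, K, N)
    got <- hypergeom_test(k, n, K, N)
    expect_equal(got$p_over, unname(exact["p_over"]), tolerance = 1e-12)
    expect_equal(got$p_under, unname(exact["p_under"]), tolerance = 1e-12)
  }
})

# fixture: 100 DE genes, 50 up; one term holding 10 up-regulated genes
directional_fixture <- function() {
  genes <- sprintf("G%03d", 1:100)
  de <- tibble::tibble(
    gene_id = genes,
    log2fc = rep(c(1, -1), each = 50),
    fdr = 0.001
  )
  ann <- tibble::tibble(gene_id = genes[1:10], go_id = "GO:UP",
                        evidence_code = "IDA")
  list(de = de, ann = ann)
}

test_that("directional enrichment reproduces the exact hypergeometric formula", {
  fx <- directional_fixture()
  res <- directional_enrichment(fx$de, fx$ann)
  expect_identical(nrow(res), 1L)
  expect_equal(res$p_over, choose(50, 10) / choose(100, 10), tolerance = 1e-12)
  expect_identical(res$k, 10L)
  expect_identical(res$N, 100L)
  expect_identical(res$direction, "over")
})

test_that("swapping up and down labels swaps the enrichment tails", {
  fx <- directional_fixture()
  res_up <- directional_enrichment(fx$de, fx$ann)
  flipped <- fx$de
  flipped$log2fc <- -flipped$log2fc
  res_down <- directional_enrichment(flipped, fx$ann)
  expect_equal(res_up$p_over, res_down$p_under)
  expect_equal(res_up$p_under, res_down$p_over)
})

test_that("random term assignment yields calibrated enrichment p-values", {
  set.seed(7)
  genes <- sprintf("G%04d", 1:1000)
  de <- tibble::tibble(gene_id = genes,
                       log2fc = sample(c(1, -1), 1000, TRUE),
                       fdr = 0.001)
  ann <- purrr::map_dfr(1:200, function(i) {
    tibble::tibble(gene_id = sample(genes, 30), go_id = sprintf("GO:%04d", i))
  })
  res <- directional_enrichment(de, ann)
  expect_identical(nrow(res), 200L)
  expect_lte(mean(res$p_over < 0.05), 0.10)
})

test_that("no DE genes gives an empty table with a warning", {
  de <- tibble::tibble(gene_id = c("a", "b"), log2fc = c(1, -1), fdr = c(0.9, 0.9))
  expect_warning(res <- directional_enrichment(de, tibble::tibble(
    gene_id = "a", go_id = "GO:1")), "no differentially expressed")
  expect_identical(nrow(res), 0L)
})

test_that("gene collapsing distinguishes all/mixed/none motif classes", {
  scan <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    motif = "CPE", regex = "x",
    count = c(1L, 0L, 1L, 1L, 0L),
    present = c(TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  t2g <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    gene_id = c("gMix", "gMix", "gAll", "gCoding", "gNone"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA", "protein_coding")
  )
  cls <- classify_motif_genes(scan, t2g, "CPE")
  expect_identical(cls$class[cls$gene_id == "gMix"], "mixed")
  expect_identical(cls$class[cls$gene_id == "gAll"], "all")
  expect_identical(cls$class[cls$gene_id == "gNone"], "none")
  expect_false("gCoding" %in% cls$gene_id)  # non-coding excluded

  # single-transcript genes: all-motif set equals the transcript-level set
  single <- t2g[t2g$gene_id %in% c("gAll", "gNone"), ]
  cls2 <- classify_motif_genes(scan, single, "CPE")
  expect_setequal(cls2$gene_id[cls2$class == "all"], "gAll")
})

test_that("a planted motif-GO enrichment is detected genome-wide", {
  cfg <- sim_config(n_genes = 3000, seed = 27, go_motif_enrichment = 4)
  sim <- simulate_experiment(cfg)
  scan <- scan_utrs(sim$utr3, cfg$motifs[cfg$motifs$name == "CPE", ])
  res <- motif_genome_enrichment(scan, sim$transcript2gene,
                                 sim$go_annotations, "CPE")
  special <- sim$go_terms$go_id[sim$go_terms$special]
  hit <- res[res$go_id %in% special, ]
  expect_identical(nrow(hit), length(special))
  expect_true(all(hit$direction == "over"))
  expect_true(all(hit$fdr < 0.05))
  # non-special terms stay mostly unremarkable
  rest <- res[!res$go_id %in% special, ]
  expect_lte(mean(rest$fdr < 0.05), 0.1)
})

test_that("the evidence-code filter is applied before testing", {
  scan <- tibble::tibble(transcript_id = c("t1", "t2"), motif = "CPE",
                         regex = "x", count = c(1L, 0L),
                         present = c(TRUE, FALSE))
  t2g <- tibble::tibble(transcript_id = c("t1", "t2"),
                        gene_id = c("g1", "g2"), biotype = "protein_coding")
  ann_iea <- tibble::tibble(gene_id = c("g1", "g2"), go_id = "GO:1",
                            evidence_code = "IEA")
  expect_error(motif_genome_enrichment(scan, t2g, ann_iea, "CPE"),
               "evidence-code filter")
})

test_that("annotations propagate to ancestors through the edge table", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"), go_id = c("leaf", "mid"))
  edges <- tibble::tibble(child = c("leaf", "mid"), parent = c("mid", "root"))
  prop <- propagate_annotations(ann, edges)
  expect_setequal(prop$go_id[prop$gene_id == "g1"], c("leaf", "mid", "root"))
  expect_setequal(prop$go_id[prop$gene_id == "g2"], c("mid", "root"))
})

test_that("network export filters nodes and induces edges", {
  tab <- tibble::tibble(
    go_id = c("GO:A", "GO:B", "GO:C"),
    k = 1L, n = 10L, K = 5L, N = 100L,
    p_over = 1, p_under = 1, fdr_over = 1, fdr_under = 1,
    direction = c("over", "under", "over"),
    fdr = c(1e-6, 1e-5, 0.5)
  )
  edges <- tibble::tibble(child = c("GO:A", "GO:A", "GO:C"),
                          parent = c("GO:B", "GO:C", "GO:B"))
  net <- export_network(tab, display_fdr_threshold = 1e-4, edges = edges)
  expect_setequal(net$nodes$go_id, c("GO:A", "GO:B"))
  expect_identical(net$nodes$color[net$nodes$go_id == "GO:A"], "red")
  expect_identical(net$nodes$color[net$nodes$go_id == "GO:B"], "blue")
  # induced edges equal the brute-force filter of the full edge list
  keep <- c("GO:A", "GO:B")
  manual <- edges[edges$child %in% keep & edges$parent %in% keep, ]
  expect_equal(net$edges, tibble::as_tibble(manual))

  # all above threshold -> empty nodes; empty network allowed
  net0 <- export_network(tab, display_fdr_threshold = 1e-8, edges = edges)
  expect_identical(nrow(net0$nodes), 0L)
  expect_identical(nrow(net0$edges), 0L)

  # one significant term, no edges supplied
  net1 <- export_network(tab[1, ], display_fdr_threshold = 1e-4)
  expect_identical(nrow(net1$nodes), 1L)
  expect_identical(nrow(net1$edges), 0L)

  # FDR above 0.05 renders white even when displayed
  tab$fdr[1] <- 0.2
  net2 <- export_network(tab, display_fdr_threshold = 1)
  expect_identical(net2$nodes$color[net2$nodes$go_id == "GO:A"], "white")
})
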