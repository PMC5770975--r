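#' Experimental GO evidence codes
#'
#' Evidence codes denoting direct experimental support (EXP, IDA, IPI, IMP,
#' IGI, IEP). Restricting annotations to these avoids circularity when
#' comparing enrichment across genomes, since other codes can derive from
#' homology.
#' @return Character vector.
#' @export
experimental_evidence_codes <- function() c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Exact hypergeometric tail probabilities
#'
#' For `k` annotated hits among `n` drawn from a universe of `N` genes of
#' which `K` carry the annotation: `p_over = P(X >= k)` and
#' `p_under = P(X <= k)` under the hypergeometric null (vectorized, via
#' [stats::phyper()]).
#'
#' @param k,n,K,N Non-negative integer vectors with
#'   `max(0, n + K - N) <= k <= min(n, K) <= N`.
#' @return Tibble: k, n, K, N, p_over, p_under.
#' @examples
#' hypergeom_test(5, 5, 5, 10)  # p_over = 1 / choose(10, 5)
#' @export
hypergeom_test <- function(k, n, K, N) {
  args <- tibble::tibble(k = k, n = n, K = K, N = N)
  with(args, {
    if (any(k < 0 | n < 0 | K < 0 | N < 0)) abort("counts must be non-negative.")
    if (any(n > N | K > N)) abort("`n` and `K` cannot exceed the universe size `N`.")
    if (any(k > pmin(n, K))) abort("`k` cannot exceed min(n, K).")
    if (any(k < pmax(0, n + K - N))) abort("`k` below the feasible minimum n + K - N.")
  })
  args$p_over <- phyper(args$k - 1, args$K, args$N - args$K, args$n, lower.tail = FALSE)
  args$p_under <- phyper(args$k, args$K, args$N - args$K, args$n, lower.tail = TRUE)
  args
}

#' Propagate GO annotations to ancestor terms
#'
#' Given parent-child edges, annotates each gene with every ancestor of its
#' annotated terms (transitive closure), so that enrichment of a specific
#' term also counts toward its more general parents.
#'
#' @param annotations Tibble: `gene_id`, `go_id` (other columns preserved
#'   from the first occurrence).
#' @param edges Tibble: `child`, `parent`.
#' @return Deduplicated annotation tibble including propagated pairs.
#' @export
propagate_annotations <- function(annotations, edges) {
  require_columns(annotations, c("gene_id", "go_id"), "annotations")
  require_columns(edges, c("child", "parent"), "edges")
  pairs <- dplyr::distinct(annotations, .data$gene_id, .data$go_id)
  repeat {
    new_pairs <- pairs |>
      dplyr::inner_join(edges, by = c(go_id = "child"), relationship = "many-to-many") |>
      dplyr::transmute(gene_id = .data$gene_id, go_id = .data$parent) |>
      dplyr::distinct()
    added <- dplyr::anti_join(new_pairs, pairs, by = c("gene_id", "go_id"))
    if (nrow(added) == 0L) break
    pairs <- dplyr::bind_rows(pairs, added)
  }
  pairs
}

# Core per-term hypergeometric enrichment of `hits` within `universe`.
term_enrichment <- function(hits, universe, annotations, min_term_size) {
  ann <- annotations |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$go_id)
  sizes <- dplyr::count(ann, .data$go_id, name = "K")
  terms <- sizes$go_id[sizes$K >= min_term_size]
  if (!length(terms)) {
    return(tibble::tibble(go_id = character(0), k = integer(0), n = integer(0),
                          K = integer(0), N = integer(0), p_over = numeric(0),
                          p_under = numeric(0), fdr_over = numeric(0),
                          fdr_under = numeric(0), direction = character(0),
                          fdr = numeric(0)))
  }
  n <- length(hits)
  N <- length(universe)
  kk <- ann |>
    dplyr::filter(.data$go_id %in% terms, .data$gene_id %in% hits) |>
    dplyr::count(.data$go_id, name = "k")
  res <- tibble::tibble(go_id = terms) |>
    dplyr::left_join(sizes, by = "go_id") |>
    dplyr::left_join(kk, by = "go_id") |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L), n = n, N = N)
  ht <- hypergeom_test(res$k, res$n, res$K, res$N)
  res$p_over <- ht$p_over
  res$p_under <- ht$p_under
  res$fdr_over <- bh_adjust(res$p_over)
  res$fdr_under <- bh_adjust(res$p_under)
  res$direction <- ifelse(res$p_over <= res$p_under, "over", "under")
  res$fdr <- ifelse(res$direction == "over", res$fdr_over, res$fdr_under)
  dplyr::arrange(res[, c("go_id", "k", "n", "K", "N", "p_over", "p_under",
                         "fdr_over", "fdr_under", "direction", "fdr")],
                 .data$fdr)
}

#' Directional GO enrichment of up-regulated genes
#'
#' Tests, per GO term, whether up-regulated genes are over- or
#' under-represented among all differentially expressed genes of one
#' fraction: hits are up-regulated DE genes, the universe is every DE gene
#' regardless of direction. Over- and under-representation are separate
#' one-sided hypergeometric tests, each BH-adjusted across terms;
#' under-representation of up-regulated genes is reported as enrichment of
#' down-regulated genes (`direction = "under"`).
#'
#' @param de Gene-level differential result (`gene_id` or `probeset_id` used
#'   as gene ids, `log2fc`, `fdr`).
#' @param annotations GO annotation tibble: `gene_id`, `go_id`
#'   (+ optional `evidence_code`).
#' @param fdr_threshold DE significance cutoff defining hits/universe.
#' @param min_term_size Smallest in-universe term tested (default 3).
#' @param edges Optional parent-child edge tibble; when supplied (and
#'   `propagate = TRUE`), annotations are propagated to ancestors before
#'   testing.
#' @param propagate Whether to propagate annotations over `edges`.
#' @return Enrichment tibble: go_id, k, n, K, N, p_over, p_under, fdr_over,
#'   fdr_under, direction, fdr.
#' @export
directional_enrichment <- function(de, annotations, fdr_threshold = 0.05,
                                   min_term_size = 3L, edges = NULL,
                                   propagate = !is.null(edges)) {
  id_col <- intersect(c("gene_id", "probeset_id"), names(de))[1L]
  if (is.na(id_col)) abort("`de` needs a gene_id or probeset_id column.")
  require_columns(de, c("log2fc", "fdr"), "de")
  sig <- de$fdr < fdr_threshold
  universe <- unique(de[[id_col]][sig])
  hits <- unique(de[[id_col]][sig & de$log2fc > 0])
  if (!length(universe)) {
    warn("no differentially expressed genes at the threshold; empty enrichment table.")
    return(term_enrichment(character(0), character(0), annotations[0, ], min_term_size))
  }
  if (propagate) {
    if (is.null(edges)) abort("`edges` required to propagate annotations.")
    annotations <- propagate_annotations(annotations, edges)
  }
  term_enrichment(hits, universe, annotations, min_term_size)
}

#' Classify genes by motif content of their transcripts
#'
#' Collapses transcript-level motif presence to the gene level:
#' `all` (every protein-coding transcript carries the motif), `none`, or
#' `mixed` (both kinds). Mixed genes are excluded from the genome-wide
#' enrichment universe so a gene's call is unambiguous.
#'
#' @param scan [scan_utrs()] result.
#' @param transcript2gene Tibble: `transcript_id`, `gene_id`, and `biotype`
#'   (only `protein_coding` transcripts are used).
#' @param motif Motif name.
#' @return Tibble: gene_id, n_transcripts, n_with, class.
#' @export
classify_motif_genes <- function(scan, transcript2gene, motif) {
  require_columns(transcript2gene, c("transcript_id", "gene_id", "biotype"),
                  "transcript2gene")
  motif_name <- motif
  pres <- scan |>
    dplyr::filter(.data$motif == motif_name) |>
    dplyr::distinct(.data$transcript_id, .data$present)
  if (nrow(pres) == 0L) abort(sprintf("motif '%s' not in scan result.", motif))
  t2g <- transcript2gene |>
    dplyr::filter(.data$biotype == "protein_coding") |>
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  t2g |>
    dplyr::inner_join(pres, by = "transcript_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_transcripts = dplyr::n(),
      n_with = sum(.data$present),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_with == .data$n_transcripts ~ "all",
      .data$n_with == 0L ~ "none",
      .default = "mixed"
    ))
}

#' Genome-wide GO enrichment of motif-containing genes
#'
#' Tests which GO terms are enriched for genes whose protein-coding
#' transcripts all carry a given motif, against a universe of all
#' unambiguous genes (genes with both motif-containing and motif-free
#' transcripts are excluded). Annotations are restricted to the requested
#' evidence codes before testing, making the analysis comparable across
#' genomes annotated independently. Run separately per genome/annotation
#' set.
#'
#' @inheritParams classify_motif_genes
#' @param annotations GO annotations with `gene_id`, `go_id`,
#'   `evidence_code`.
#' @param evidence_codes Codes retained (default
#'   [experimental_evidence_codes()]); use `NULL` to keep all.
#' @param min_term_size,edges,propagate As in [directional_enrichment()].
#' @return Enrichment tibble (as [directional_enrichment()]), with the gene
#'   classification attached as attribute `"gene_classes"`.
#' @export
motif_genome_enrichment <- function(scan, transcript2gene, annotations, motif,
                                    evidence_codes = experimental_evidence_codes(),
                                    min_term_size = 3L, edges = NULL,
                                    propagate = !is.null(edges)) {
  classes <- classify_motif_genes(scan, transcript2gene, motif)
  hits <- classes$gene_id[classes$class == "all"]
  universe <- classes$gene_id[classes$class != "mixed"]
  if (!is.null(evidence_codes)) {
    require_columns(annotations, "evidence_code", "annotations")
    annotations <- annotations[annotations$evidence_code %in% evidence_codes, , drop = FALSE]
    if (nrow(annotations) == 0L) {
      abort("evidence-code filter removed every annotation.")
    }
  }
  if (propagate) {
    if (is.null(edges)) abort("`edges` required to propagate annotations.")
    annotations <- propagate_annotations(annotations, edges)
  }
  out <- term_enrichment(hits, universe, annotations, min_term_size)
  attr(out, "gene_classes") <- classes
  out
}

#' Export an enrichment network for visualization
#'
#' Builds node and edge tables importable by network-visualization software
#' (e.g. Cytoscape). Nodes are GO terms significant in at least one of the
#' supplied enrichment tables at the display threshold; each node carries its
#' best direction and FDR, a size field (`-log10` FDR) and a color: white
#' when `FDR > 0.05`, otherwise red for over- and blue for
#' under-representation. Edges are the parent-child pairs induced by the
#' retained nodes.
#'
#' @param tables A single enrichment tibble or a (optionally named) list of
#'   them (one per comparison).
#' @param display_fdr_threshold Display cutoff on the per-term FDR
#'   (`1e-4` and `1e-5` are the presets used for genome-scale figures).
#' @param edges Optional parent-child tibble (`child`, `parent`) for the GO
#'   subnetwork.
#' @param white_fdr FDR above which nodes are drawn white (default 0.05).
#' @return List with `nodes` (go_id, comparison, direction, fdr, size,
#'   color) and `edges` (child, parent restricted to retained nodes). Both
#'   may be empty.
#' @export
export_network <- function(tables, display_fdr_threshold = 1e-4, edges = NULL,
                           white_fdr = 0.05) {
  if (is.data.frame(tables)) tables <- list(enrichment = tables)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("comparison", seq_along(tables))
  }
  nodes <- purrr::imap_dfr(tables, function(tab, nm) {
    if (nrow(tab) == 0L) return(NULL)
    tibble::tibble(go_id = tab$go_id, comparison = nm,
                   direction = tab$direction, fdr = tab$fdr)
  })
  if (nrow(nodes) == 0L) {
    keep_terms <- character(0)
  } else {
    keep_terms <- unique(nodes$go_id[nodes$fdr < display_fdr_threshold])
  }
  nodes <- nodes[nodes$go_id %in% keep_terms, , drop = FALSE]
  nodes$size <- -log10(pmax(nodes$fdr, .Machine$double.xmin))
  nodes$color <- dplyr::case_when(
    nodes$fdr > white_fdr ~ "white",
    nodes$direction == "over" ~ "red",
    .default = "blue"
  )
  edge_out <- tibble::tibble(child = character(0), parent = character(0))
  if (!is.null(edges) && length(keep_terms)) {
    require_columns(edges, c("child", "parent"), "edges")
    edge_out <- edges[edges$child %in% keep_terms & edges$parent %in% keep_terms,
                      c("child", "parent"), drop = FALSE]
    edge_out <- tibble::as_tibble(edge_out)
  }
  list(nodes = tibble::as_tibble(nodes), edges = edge_out)
}
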