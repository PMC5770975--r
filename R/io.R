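# Readers and writers for the pipeline's plain-text interchange formats:
# intensity/sample/mapping/annotation TSVs, UTR FASTA, motif config
# (TSV or YAML), and the simulation truth as JSON.

#' Read and write intensity tables
#'
#' TSV with a `probeset_id` column followed by one numeric column per
#' sample.
#' @param path File path.
#' @param data Intensity tibble.
#' @return `read_intensity_tsv()` returns a tibble.
#' @export
read_intensity_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_intensity_tsv
#' @export
write_intensity_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read UTR sequences from FASTA
#'
#' Loads a FASTA file (headers are transcript ids) into the tibble form the
#' scanner accepts. Parsing is delegated to Biostrings; a failure is
#' re-raised naming the file.
#'
#' @param path FASTA file path.
#' @return Tibble: transcript_id, sequence.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: '%s'.", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(transcript_id = ids, sequence = unname(as.character(set)))
}

#' Write UTR sequences to FASTA
#' @param utrs Tibble with transcript_id, sequence (or named character).
#' @param path Output path.
#' @export
write_utr_fasta <- function(utrs, path) {
  seqs <- as_utr_vector(utrs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a motif configuration
#'
#' Accepts TSV (columns name, region, regex, canonical_literal) or YAML (a
#' list of motif records with those fields). Definitions are validated
#' (regex compiles; canonical literal matches it).
#'
#' @param path File path ending in `.tsv`, `.yaml`, or `.yml`.
#' @return Motif tibble.
#' @export
read_motif_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("motif config not found: '%s'.", path))
  motifs <- if (grepl("\\.ya?ml$", path)) {
    lst <- yaml::read_yaml(path)
    purrr::map_dfr(lst, tibble::as_tibble)
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  if (!"region" %in% names(motifs)) motifs$region <- "UTR3"
  validate_motifs(motifs)
  motifs
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors the [sim_config()] arguments; omitted fields take the
#' defaults. `motifs`, if present, is a list of motif records.
#'
#' @param path YAML path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$motifs)) {
    lst$motifs <- purrr::map_dfr(lst$motifs, tibble::as_tibble)
  }
  if (!is.null(lst$category_fractions)) {
    lst$category_fractions <- unlist(lst$category_fractions)
  }
  if (!is.null(lst$motif_plant_prob)) {
    lst$motif_plant_prob <- unlist(lst$motif_plant_prob)
  }
  do.call(sim_config, lst)
}

#' Write a synthetic experiment to a directory
#'
#' Emits the generator's plain-text interchange files: `total.tsv`,
#' `polysome.tsv`, `samples.tsv`, `utr3.fa`, `utr5.fa`,
#' `probeset2transcript.tsv`, `transcript2gene.tsv`, `go_annotations.tsv`,
#' `marker_panel.tsv`, and `truth.json`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(sim$raw_total, file.path(dir, "total.tsv"))
  readr::write_tsv(sim$raw_polysome, file.path(dir, "polysome.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_utr_fasta(sim$utr3, file.path(dir, "utr3.fa"))
  write_utr_fasta(sim$utr5, file.path(dir, "utr5.fa"))
  readr::write_tsv(sim$probeset2transcript, file.path(dir, "probeset2transcript.tsv"))
  readr::write_tsv(sim$transcript2gene, file.path(dir, "transcript2gene.tsv"))
  readr::write_tsv(sim$go_annotations, file.path(dir, "go_annotations.tsv"))
  readr::write_tsv(sim$marker_panel, file.path(dir, "marker_panel.tsv"))
  jsonlite::write_json(
    list(
      transcripts = sim$truth$transcripts,
      genes = sim$truth$genes,
      arrays = sim$truth$arrays
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}

#' Write enrichment network tables
#' @param network Output of [export_network()].
#' @param dir Output directory.
#' @export
write_network_tables <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(network$nodes, file.path(dir, "network_nodes.tsv"))
  readr::write_tsv(network$edges, file.path(dir, "network_edges.tsv"))
  invisible(dir)
}
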