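# End-to-end orchestration: count -> detect -> summarize -> enrich ->
# dynamics, with every result table written to disk alongside a JSON
# manifest of the configuration and input checksums, so a run can be
# reproduced byte for byte.

#' Run the full antisense-transcription pipeline
#'
#' Executes the whole analysis chain over one or more samples and writes
#' all result tables to `out_dir`: per-gene strand counts, per-gene calls,
#' per-species summaries, the antisense-only gene report, COG enrichment
#' (skipped with a warning when no COG map is given), and, with two or more
#' samples, the gene-sharing histogram. A `manifest.json` records the
#' configuration, package version, seed and MD5 checksums of the inputs.
#'
#' @param alignments Named character vector of SAM/BAM paths (names are
#'   sample ids), or a precomputed count tibble/`.tsv` path with a
#'   `sample_id` column.
#' @param annotations Annotation tibble or GFF3/GTF path.
#' @param cog_map Optional COG map tibble or TSV path.
#' @param out_dir Output directory.
#' @param protocol Library orientation for counting.
#' @param artifact_p Fixed artifact rate; ignored when `estimate_p` is
#'   `TRUE`.
#' @param estimate_p Estimate the artifact rate from the data as the lowest
#'   per-species antisense read ratio ([estimate_artifact_rate()]).
#' @param alpha Per-gene significance level.
#' @param min_mapq,min_expressed_genes,min_antisense_genes,min_length,min_antisense_reads
#'   Filter thresholds (see the stage functions).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return Invisibly, a list with `counts`, `calls`, `summaries`,
#'   `antisense_only`, `enrichment`, `sharing`, `artifact_p` and `manifest`.
#' @export
run_pipeline <- function(alignments, annotations, cog_map = NULL,
                         out_dir = ".",
                         protocol = c("forward", "reverse"),
                         artifact_p = 0.01, estimate_p = FALSE, alpha = 0.05,
                         min_mapq = 0, min_expressed_genes = 100,
                         min_antisense_genes = 30, min_length = 600,
                         min_antisense_reads = 3, seed = 1) {
  protocol <- match.arg(protocol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()

  if (is.character(annotations)) {
    checksums[[annotations]] <- unname(tools::md5sum(annotations))
    annotations <- read_gene_annotations(annotations)
  }
  if (is.character(cog_map)) {
    checksums[[cog_map]] <- unname(tools::md5sum(cog_map))
    cog_map <- read_cog_map(cog_map)
  }

  # stage 1: count
  if (is.character(alignments) &&
      all(grepl("\\.(sam|bam)$", alignments, ignore.case = TRUE))) {
    if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
      names(alignments) <- paste0("S", seq_along(alignments))
    }
    counts <- purrr::imap(alignments, function(path, sid) {
      checksums[[path]] <<- unname(tools::md5sum(path))
      aln <- read_alignments(path, min_mapq = min_mapq)
      cnt <- count_strands(aln, annotations, protocol, sample_id = sid)
      rep <- count_report(cnt)
      message(sprintf(
        "[count] %s: %d reads (%d assigned, %d no_feature, %d ambiguous)",
        sid, rep$total, rep$assigned, rep$no_feature, rep$ambiguous))
      cnt
    }) |> dplyr::bind_rows()
  } else if (is.character(alignments)) {
    checksums[[alignments]] <- unname(tools::md5sum(alignments))
    counts <- read_count_table(alignments)
    if (!"sample_id" %in% names(counts)) counts$sample_id <- "S1"
  } else {
    counts <- tibble::as_tibble(alignments)
    if (!"sample_id" %in% names(counts)) counts$sample_id <- "S1"
  }
  write_result_table(counts, file.path(out_dir, "strand_counts.tsv"),
                     key = c("sample_id", "gene_id"))

  # stage 2: detect (optionally after estimating the artifact rate)
  if (estimate_p) {
    pilot <- call_antisense(counts, annotations, artifact_p = 0.5,
                            alpha = alpha)
    model <- estimate_artifact_rate(summarize_species(pilot,
                                                      min_expressed_genes))
    artifact_p <- model$p
    message(sprintf("[detect] estimated artifact rate p = %.4g", artifact_p))
  }
  calls <- call_antisense(counts, annotations, artifact_p = artifact_p,
                          alpha = alpha)
  write_result_table(tidy(calls), file.path(out_dir, "gene_calls.tsv"),
                     key = c("sample_id", "gene_id"))

  # stage 3: summarize
  summaries <- summarize_species(calls, min_expressed_genes)
  write_result_table(summaries, file.path(out_dir, "species_summary.tsv"),
                     key = c("species_id", "sample_id"))
  aso <- antisense_only_report(calls, min_length, min_antisense_reads)
  write_result_table(tidy(aso), file.path(out_dir, "antisense_only.tsv"),
                     key = c("sample_id", "gene_id"))

  # stage 4: enrich
  enrichment <- NULL
  if (is.null(cog_map)) {
    warning("no COG map supplied; enrichment stage skipped", call. = FALSE)
  } else {
    enrichment <- calls |>
      dplyr::group_split(.data$sample_id) |>
      purrr::map(function(g) {
        enrich_cogs(g, cog_map, min_antisense_genes) |>
          dplyr::mutate(sample_id = g$sample_id[1], .before = 1)
      }) |>
      dplyr::bind_rows()
    write_result_table(enrichment, file.path(out_dir, "cog_enrichment.tsv"),
                       key = c("sample_id", "species_id", "cog_id"))
  }

  # stage 5: dynamics
  sharing <- NULL
  if (dplyr::n_distinct(counts$sample_id) >= 2) {
    sharing <- sharing_histogram(calls)
    write_result_table(sharing, file.path(out_dir, "sharing_histogram.tsv"),
                       key = "species_id")
  }

  manifest <- list(
    package = "antisensr",
    version = as.character(utils::packageVersion("antisensr")),
    seed = seed,
    protocol = protocol,
    artifact_p = artifact_p,
    estimate_p = estimate_p,
    alpha = alpha,
    thresholds = list(
      min_mapq = min_mapq,
      min_expressed_genes = min_expressed_genes,
      min_antisense_genes = min_antisense_genes,
      min_length = min_length,
      min_antisense_reads = min_antisense_reads
    ),
    input_md5 = checksums,
    output_md5 = local({
      f <- list.files(out_dir, "\\.tsv$", full.names = TRUE)
      setNames(as.list(unname(tools::md5sum(f))), basename(f))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, calls = calls, summaries = summaries,
                 antisense_only = aso, enrichment = enrichment,
                 sharing = sharing, artifact_p = artifact_p,
                 manifest = manifest))
}
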