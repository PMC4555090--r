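# Per-gene antisense calling. Library strandedness below 100% means a gene
# with no true antisense transcription still shows wrong-strand reads at a
# per-read artifact rate p; a gene is called antisense-transcribed when its
# antisense read count among all its reads is improbably large under
# Binomial(total, p), one-tailed.

#' Upper-tail binomial probability
#'
#' Exact one-tailed probability `P(X >= k)` for `X ~ Binomial(n, p)`,
#' evaluated through the survival function so it remains accurate far into
#' the tail for large `n`. Vectorised over `k` and `n`.
#'
#' @param k Number of successes (antisense reads), `0 <= k <= n`.
#' @param n Number of trials (all reads mapped to the gene).
#' @param p Per-trial success probability, in `(0, 1)`.
#' @return `P(X >= k)`.
#' @export
binomial_tail <- function(k, n, p) {
  check_count(k, "k")
  check_count(n, "n")
  check_prob(p, "p")
  if (any(k > n)) stop("`k` must not exceed `n`", call. = FALSE)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Estimate the strandedness artifact rate from species summaries
#'
#' The artifact rate p (probability of a wrong-strand read absent true
#' antisense transcription) is approximated by the lowest per-species ratio
#' of antisense reads among well-sampled species: the library's strandedness
#' is at least that good, so the minimum bounds the artifact rate from
#' above. A small floor guards against a degenerate zero estimate.
#'
#' @param summaries Species summary tibble ([summarize_species()]), needing
#'   columns `ratio_antisense_reads` and `reads_total`.
#' @param min_reads Minimum reads mapped to a species for it to inform the
#'   estimate (default 10000).
#' @param p_floor Lower bound on the estimate (default 0.001).
#' @return An `artifact_model` list with elements `p` and `source`.
#' @export
estimate_artifact_rate <- function(summaries, min_reads = 10000,
                                   p_floor = 0.001) {
  stopifnot(min_reads >= 0, p_floor > 0, p_floor < 1)
  ok <- !is.na(summaries$ratio_antisense_reads) &
    summaries$reads_total >= min_reads
  if (!any(ok)) {
    stop("no species with >= ", min_reads, " mapped reads; supply a fixed ",
         "artifact rate instead (e.g. artifact_p = 0.01)", call. = FALSE)
  }
  p <- max(min(summaries$ratio_antisense_reads[ok]), p_floor)
  artifact_model(p, source = "estimated")
}

#' @rdname estimate_artifact_rate
#' @param p A fixed artifact rate in `(0, 1)`.
#' @param source `"fixed"` or `"estimated"`.
#' @export
artifact_model <- function(p, source = "fixed") {
  check_prob(p, "p")
  structure(list(p = p, source = source), class = "artifact_model")
}

#' Call antisense transcription per gene
#'
#' For every gene, computes the one-tailed binomial p-value of its antisense
#' read count among all its reads under the artifact rate, flags antisense
#' transcription at `pvalue <= alpha`, classifies the gene's transcription
#' (`sense_only` / `antisense_only` / `both` / `silent`), and derives the
#' strand dominance statistic `d = (sense - antisense) / (sense + antisense)`
#' and, when gene lengths are available, FPKM of total transcription.
#'
#' No multiple-testing correction is applied across genes by default (the
#' per-gene test is the unit of inference); set `adjust = TRUE` for a
#' Benjamini-Hochberg-adjusted call within each species and sample.
#'
#' @param counts Count tibble with `gene_id`, `sense`, `antisense` and
#'   optionally `sample_id` ([count_strands()] or [read_count_table()]).
#' @param annotations Optional annotation tibble; supplies `length` and
#'   `species_id` for FPKM and species grouping.
#' @param artifact_p Artifact rate: a number in `(0, 1)` or an
#'   `artifact_model`. Default 0.01; 0.05 gives a conservative call set.
#' @param alpha Per-gene significance level (default 0.05).
#' @param total_mapped Reads used as the FPKM depth denominator; defaults to
#'   all reads assigned to any gene in the same sample.
#' @param adjust If `TRUE`, call on BH-adjusted p-values per species and
#'   sample instead of raw p-values.
#' @return An `antisense_calls` tibble: `gene_id`, (`sample_id`,) `sense`,
#'   `antisense`, `total`, `pvalue`, `antisense_called`, `category`, `d`,
#'   and `fpkm`, `length`, `species_id` when annotations are given. Silent
#'   genes (no reads) have `pvalue`, `d` of `NA` and are never called.
#' @export
call_antisense <- function(counts, annotations = NULL, artifact_p = 0.01,
                           alpha = 0.05, total_mapped = NULL, adjust = FALSE) {
  check_counts_table(counts)
  if (inherits(artifact_p, "artifact_model")) artifact_p <- artifact_p$p
  check_prob(artifact_p, "artifact_p")
  check_prob(alpha, "alpha")

  calls <- tibble::as_tibble(counts) |>
    dplyr::mutate(
      sense = as.integer(.data$sense),
      antisense = as.integer(.data$antisense),
      total = .data$sense + .data$antisense,
      pvalue = ifelse(.data$total > 0,
                      binomial_tail(.data$antisense, .data$total, artifact_p),
                      NA_real_),
      category = dplyr::case_when(
        .data$sense > 0 & .data$antisense > 0 ~ "both",
        .data$sense > 0 ~ "sense_only",
        .data$antisense > 0 ~ "antisense_only",
        TRUE ~ "silent"
      ),
      d = ifelse(.data$total > 0,
                 (.data$sense - .data$antisense) / .data$total, NA_real_)
    )

  if (!is.null(annotations)) {
    calls <- dplyr::left_join(
      calls,
      dplyr::select(annotations, "gene_id", "length", "species_id"),
      by = "gene_id"
    )
  }

  has_sample <- "sample_id" %in% names(calls)
  if (!is.null(annotations)) {
    grp <- if (has_sample) dplyr::group_by(calls, .data$sample_id) else calls
    calls <- grp |>
      dplyr::mutate(
        .depth = if (is.null(total_mapped)) sum(.data$total) else total_mapped,
        fpkm = ifelse(.data$.depth > 0 & !is.na(.data$length),
                      .data$total * 1e9 / (.data$length * .data$.depth), 0)
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-".depth")
  }

  test_p <- calls$pvalue
  if (adjust) {
    keys <- paste(
      if (has_sample) calls$sample_id else "",
      if ("species_id" %in% names(calls)) calls$species_id else ""
    )
    for (key in unique(keys)) {
      i <- which(keys == key & !is.na(test_p))
      test_p[i] <- bh_adjust(test_p[i])
    }
  }
  calls$antisense_called <- !is.na(test_p) & test_p <= alpha

  structure(calls, class = c("antisense_calls", class(tibble::tibble())),
            artifact_p = artifact_p, alpha = alpha, adjusted = adjust)
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count * 1e9 / (gene_length * total_mapped)`.
#'
#' @param count Reads mapped to the gene.
#' @param gene_length Gene length in bp (> 0).
#' @param total_mapped Total mapped reads in the dataset (> 0).
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(count, gene_length, total_mapped) {
  check_count(count, "count")
  if (any(gene_length <= 0)) stop("`gene_length` must be positive", call. = FALSE)
  if (any(total_mapped <= 0)) stop("`total_mapped` must be positive", call. = FALSE)
  count * 1e9 / (gene_length * total_mapped)
}

#' Summarise antisense transcription per species
#'
#' Aggregates gene calls to the two species-level statistics: the ratio of
#' antisense reads (over all reads mapped to the species' genes) and the
#' ratio of genes with antisense transcription (over genes with detectable
#' transcription, i.e. at least one read). Species with fewer expressed
#' genes than `min_expressed_genes` are flagged ineligible, which guards
#' range estimates against poorly sampled genomes.
#'
#' @param calls An `antisense_calls` tibble with `species_id` (i.e. built
#'   with annotations).
#' @param min_expressed_genes Eligibility threshold (default 100).
#' @return A tibble per species (and sample): `n_genes_total`,
#'   `n_genes_expressed`, `n_genes_antisense`, `reads_total`,
#'   `reads_antisense`, `ratio_antisense_reads`, `ratio_genes_antisense`,
#'   `eligible`. Ratios are `NA` when their denominator is zero.
#' @export
summarize_species <- function(calls, min_expressed_genes = 100) {
  if (!"species_id" %in% names(calls)) {
    stop("calls lack `species_id`; run call_antisense() with annotations",
         call. = FALSE)
  }
  grp_vars <- intersect(c("species_id", "sample_id"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::summarise(
      n_genes_total = dplyr::n(),
      n_genes_expressed = sum(.data$total > 0),
      n_genes_antisense = sum(.data$antisense_called),
      reads_total = sum(.data$total),
      reads_antisense = sum(.data$antisense),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_antisense_reads = ifelse(.data$reads_total > 0,
                                     .data$reads_antisense / .data$reads_total,
                                     NA_real_),
      ratio_genes_antisense = ifelse(.data$n_genes_expressed > 0,
                                     .data$n_genes_antisense / .data$n_genes_expressed,
                                     NA_real_),
      eligible = .data$n_genes_expressed >= min_expressed_genes
    )
}

#' Genes with exclusively antisense transcription
#'
#' Restricts the gene calls to high-confidence antisense-only genes: no
#' sense reads at all, a minimum number of antisense reads, and a minimum
#' gene length (longer genes are less likely to be annotation artifacts).
#'
#' @param calls An `antisense_calls` tibble with `length` (built with
#'   annotations).
#' @param min_length Minimum gene length in bp (default 600).
#' @param min_antisense_reads Minimum antisense reads (default 3).
#' @return The filtered calls tibble.
#' @export
antisense_only_report <- function(calls, min_length = 600,
                                  min_antisense_reads = 3) {
  if (!"length" %in% names(calls)) {
    stop("calls lack `length`; run call_antisense() with annotations",
         call. = FALSE)
  }
  dplyr::filter(calls,
                .data$sense == 0,
                .data$antisense >= min_antisense_reads,
                .data$length >= min_length)
}
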