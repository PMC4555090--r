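# Cross-sample dynamics: how antisense-transcribed gene sets are shared
# between individuals, how antisense profiles correlate between conditions,
# and the U-shaped relation between expression level and strand dominance.

#' Sharing of antisense-transcribed genes across samples
#'
#' For each species, counts how many genes are antisense-called in exactly
#' `j` of the `m` samples, for `j = 1..m`. Genes called in no sample are
#' excluded. A gene absent from a sample's calls counts as not called
#' there.
#'
#' @param calls An `antisense_calls` tibble with `sample_id` covering at
#'   least two samples (and `species_id` if per-species histograms are
#'   wanted).
#' @param use_raw_reads If `TRUE`, a gene counts as antisense-positive in a
#'   sample when it has at least one antisense read, rather than when the
#'   binomial test calls it.
#' @return A tibble with `species_id`, `n_shared` (j), `n_genes`; the
#'   number of samples `m` is in `attr(, "n_samples")`.
#' @export
sharing_histogram <- function(calls, use_raw_reads = FALSE) {
  if (!"sample_id" %in% names(calls)) {
    stop("calls lack `sample_id`", call. = FALSE)
  }
  m <- dplyr::n_distinct(calls$sample_id)
  if (m < 2) stop("sharing requires calls from >= 2 samples", call. = FALSE)
  if (!"species_id" %in% names(calls)) calls$species_id <- "all"
  positive <- if (use_raw_reads) calls$antisense > 0 else calls$antisense_called
  out <- calls |>
    dplyr::mutate(.pos = positive) |>
    dplyr::group_by(.data$species_id, .data$gene_id) |>
    dplyr::summarise(n_shared = sum(.data$.pos), .groups = "drop") |>
    dplyr::filter(.data$n_shared >= 1) |>
    dplyr::count(.data$species_id, .data$n_shared, name = "n_genes") |>
    tidyr::complete(species_id = unique(.env$calls$species_id),
                    n_shared = seq_len(m),
                    fill = list(n_genes = 0L))
  attr(out, "n_samples") <- m
  out
}

#' Correlation between two antisense-transcription profiles
#'
#' A profile is the set of per-(species, sample) ratios of genes with
#' antisense transcription, restricted to cells eligible in every compared
#' condition. The two profiles are matched on their (species, sample) keys
#' and compared by Pearson correlation, with a two-tailed p-value from the
#' t distribution on `length - 2` degrees of freedom.
#'
#' @param a,b Profile tibbles with columns `species_id`, `sample_id`,
#'   `ratio_genes_antisense` (e.g. eligible rows of
#'   [summarize_species()] output). Key sets must be identical.
#' @return A `profile_correlation` object (see [tidy()] / [glance()]) with
#'   elements `r`, `p`, `n` and the matched `data`.
#' @export
profile_correlation <- function(a, b) {
  key <- c("species_id", "sample_id")
  stopifnot(all(key %in% names(a)), all(key %in% names(b)))
  ka <- paste(a$species_id, a$sample_id)
  kb <- paste(b$species_id, b$sample_id)
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("profiles must cover identical (species_id, sample_id) keys",
         call. = FALSE)
  }
  merged <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(key), ratio_a = "ratio_genes_antisense"),
    dplyr::select(b, dplyr::all_of(key), ratio_b = "ratio_genes_antisense"),
    by = key
  )
  if (nrow(merged) < 3) stop("need >= 3 matched profile cells", call. = FALSE)
  if (stats::sd(merged$ratio_a) == 0 || stats::sd(merged$ratio_b) == 0) {
    stop("zero variance in a profile; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(merged$ratio_a, merged$ratio_b, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
         data = merged, htest = ct),
    class = "profile_correlation"
  )
}

#' Expression level versus strand dominance
#'
#' Tests the U-shaped relation between expression and strand dominance:
#' among well-supported genes from well-sampled species, genes dominated by
#' one strand (|d| near 1) tend to be highly expressed. Computes Spearman's
#' rank correlation between `log(FPKM)` and `|d|` over genes with at least
#' `min_reads` reads, excluding genes with `|d| = 1`, from species with at
#' least `min_genes_per_species` genes with read support.
#'
#' @param calls An `antisense_calls` tibble with `fpkm` and `species_id`
#'   (one sample).
#' @param min_reads Minimum reads per gene (default 20).
#' @param min_genes_per_species Minimum expressed genes per species for its
#'   genes to enter (default 100).
#' @return An `expression_dominance` object with `rho`, `p`, `n` and the
#'   filtered point set `data` (columns `gene_id`, `species_id`,
#'   `log_fpkm`, `abs_d`).
#' @export
expression_vs_dominance <- function(calls, min_reads = 20,
                                    min_genes_per_species = 100) {
  need <- c("fpkm", "species_id", "d", "total")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    stop("calls lack column(s) ", paste(miss, collapse = ", "),
         "; run call_antisense() with annotations", call. = FALSE)
  }
  ok_species <- calls |>
    dplyr::filter(.data$total > 0) |>
    dplyr::count(.data$species_id) |>
    dplyr::filter(.data$n >= min_genes_per_species) |>
    dplyr::pull("species_id")
  pts <- calls |>
    dplyr::filter(.data$species_id %in% ok_species,
                  .data$total >= min_reads,
                  abs(.data$d) < 1,
                  .data$fpkm > 0) |>
    dplyr::transmute(.data$gene_id, .data$species_id,
                     log_fpkm = log(.data$fpkm), abs_d = abs(.data$d))
  if (nrow(pts) < 3) {
    stop("fewer than 3 genes survive the filters", call. = FALSE)
  }
  if (length(unique(pts$abs_d)) < 2 || length(unique(pts$log_fpkm)) < 2) {
    stop("degenerate ranks: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    cor.test(pts$log_fpkm, pts$abs_d, method = "spearman", exact = FALSE)
  )
  structure(
    list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(pts), data = pts),
    class = "expression_dominance"
  )
}
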