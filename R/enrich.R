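# COG functional enrichment among antisense-transcribed genes, per genome:
# a one-tailed binomial test (background probability = the COG's frequency
# among the genome's genes) and a one-tailed Fisher's exact test, each with
# Benjamini-Hochberg FDR correction across the COGs tested in that genome.

#' Build the 2x2 enrichment contingency table
#'
#' Cross-classifies a genome's genes by antisense call and COG membership:
#' rows are (in COG, not in COG), columns are (antisense-called, not
#' called), giving `[(k, K - k), (n - k, N - K - n + k)]`.
#'
#' @param k Antisense-called genes in the COG.
#' @param n Antisense-called genes in the genome.
#' @param K Genes in the COG in the genome.
#' @param N Protein-coding genes in the genome.
#' @return A 2x2 integer matrix whose cells sum to `N`.
#' @export
build_contingency <- function(k, n, K, N) {
  check_count(c(k, n, K, N), "k, n, K, N")
  if (k > min(n, K) || n > N || K > N || N - K - n + k < 0) {
    stop("inconsistent counts: need k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  matrix(as.integer(c(k, n - k, K - k, N - K - n + k)), nrow = 2,
         dimnames = list(cog = c("in", "out"),
                         antisense = c("called", "not_called")))
}

#' One-tailed Fisher's exact test for enrichment
#'
#' Upper-tail hypergeometric probability of the observed table: with `K`
#' COG members among `N` genes and `n` antisense-called draws, the p-value
#' is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, evaluated through the
#' survival function.
#'
#' @param table A 2x2 contingency table from [build_contingency()].
#' @return The one-tailed (enrichment) p-value.
#' @export
fisher_one_tailed <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  check_count(as.vector(table), "table")
  if (sum(table) == 0) stop("all-zero contingency table", call. = FALSE)
  k <- table[1, 1]
  K <- k + table[1, 2]
  n <- k + table[2, 1]
  N <- sum(table)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on ascending p-values,
#' `q_(i) = min over j >= i of p_(j) * m / j`, clipped at 1 and mapped back
#' to the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  check_prob(pvalues, "pvalues", open = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' COG enrichment among antisense-transcribed genes
#'
#' For each genome (species) with at least `min_antisense_genes`
#' antisense-called genes, tests every COG with at least one member gene in
#' that genome for over-representation among the called genes, by both the
#' binomial test (success probability `K/N`) and the one-tailed Fisher's
#' exact test. BH correction is applied per genome and per test family.
#' Genes carrying several COG labels count toward each. Genomes below the
#' threshold are skipped with a message and contribute no rows.
#'
#' @param calls An `antisense_calls` tibble with `species_id`; restrict to
#'   one sample (or pool samples deliberately) before calling.
#' @param cog_map Tibble `gene_id`, `cog_id`, `category`
#'   ([read_cog_map()]).
#' @param min_antisense_genes Minimum called genes per genome (default 30).
#' @param q_threshold Significance threshold on q-values (default 0.05).
#' @return A `cog_enrichment` tibble: `species_id`, `cog_id`, `category`,
#'   `k`, `n`, `K`, `N`, `p_binomial`, `q_binomial`, `p_fisher`,
#'   `q_fisher`, `significant_binomial`, `significant_fisher`, sorted by
#'   `q_fisher` within genome.
#' @export
enrich_cogs <- function(calls, cog_map, min_antisense_genes = 30,
                        q_threshold = 0.05) {
  if (!"species_id" %in% names(calls)) {
    stop("calls lack `species_id`; run call_antisense() with annotations",
         call. = FALSE)
  }
  empty <- tibble::tibble(
    species_id = character(), cog_id = character(), category = character(),
    k = integer(), n = integer(), K = integer(), N = integer(),
    p_binomial = numeric(), q_binomial = numeric(),
    p_fisher = numeric(), q_fisher = numeric(),
    significant_binomial = logical(), significant_fisher = logical()
  )

  per_genome <- function(g) {
    n_total <- nrow(g)
    called <- g$gene_id[g$antisense_called]
    n_called <- length(called)
    species <- g$species_id[1]
    if (n_called < min_antisense_genes) {
      message("skipping ", species, ": only ", n_called,
              " genes with antisense transcription (< ", min_antisense_genes, ")")
      return(empty)
    }
    cogs <- dplyr::filter(cog_map, .data$gene_id %in% g$gene_id)
    if (nrow(cogs) == 0) {
      warning("no COG annotations for ", species, call. = FALSE)
      return(empty)
    }
    res <- cogs |>
      dplyr::group_by(.data$cog_id, .data$category) |>
      dplyr::summarise(
        K = dplyr::n_distinct(.data$gene_id),
        k = dplyr::n_distinct(intersect(.data$gene_id, called)),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        species_id = species,
        n = n_called,
        N = n_total,
        p_binomial = binomial_tail(.data$k, n_called, .data$K / n_total),
        p_fisher = purrr::map2_dbl(.data$k, .data$K, function(ki, Ki) {
          fisher_one_tailed(build_contingency(ki, n_called, Ki, n_total))
        }),
        q_binomial = bh_adjust(.data$p_binomial),
        q_fisher = bh_adjust(.data$p_fisher),
        significant_binomial = .data$q_binomial <= q_threshold,
        significant_fisher = .data$q_fisher <= q_threshold
      )
    dplyr::select(res, dplyr::all_of(names(empty)))
  }

  out <- calls |>
    dplyr::group_split(.data$species_id) |>
    purrr::map(per_genome) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$species_id, .data$q_fisher, .data$q_binomial,
                   .data$cog_id)
  structure(out, class = c("cog_enrichment", class(tibble::tibble())),
            q_threshold = q_threshold)
}

#' Summarise enriched COGs by functional category
#'
#' Counts significant (COG, genome) pairs per one-letter COG functional
#' category. A COG annotated with several category letters (e.g. "ER")
#' counts once under each letter.
#'
#' @param results A `cog_enrichment` tibble.
#' @param test Which test family's significance flag to use (default
#'   `"fisher"`).
#' @return A tibble with `category` and `n_enriched` (significant
#'   COG-genome pairs), sorted by decreasing count.
#' @export
summarize_categories <- function(results, test = c("fisher", "binomial")) {
  test <- match.arg(test)
  flag <- paste0("significant_", test)
  sig <- dplyr::filter(results, .data[[flag]])
  if (nrow(sig) == 0) {
    return(tibble::tibble(category = character(), n_enriched = integer()))
  }
  sig |>
    dplyr::distinct(.data$species_id, .data$cog_id, .data$category) |>
    dplyr::mutate(letter = stringr::str_extract_all(.data$category, "[A-Z]")) |>
    tidyr::unnest("letter") |>
    dplyr::distinct(.data$species_id, .data$cog_id, .data$letter) |>
    dplyr::count(.data$letter, name = "n_enriched") |>
    dplyr::rename(category = "letter") |>
    dplyr::arrange(dplyr::desc(.data$n_enriched), .data$category)
}
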