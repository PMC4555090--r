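test_that("binomial_tail matches closed forms and rejects bad arguments", {
  expect_equal(binomial_tail(0, 50, 0.01), 1.0)
  expect_equal(binomial_tail(5, 5, 0.1), 1e-5)
  # 1 - (0.9^10 + 10 * 0.1 * 0.9^9) = 0.2639010709...
  expect_equal(binomial_tail(2, 10, 0.1), 1 - 0.9^10 - 0.9^9,
               tolerance = 1e-12)
  expect_error(binomial_tail(11, 10, 0.1), "exceed")
  expect_error(binomial_tail(1, 10, 0), "\\(0, 1\\)")
  expect_error(binomial_tail(-1, 10, 0.1), "non-negative")
})

test_that("binomial_tail agrees with direct summation to 12 significant digits", {
  withr::local_seed(77)
  for (i in 1:200) {
    n <- sample.int(1000, 1)
    k <- sample.int(n + 1, 1) - 1L
    p <- runif(1, 0.001, 0.999)
    expect_equal(binomial_tail(k, n, p), binom_tail_oracle(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("binomial_tail stays finite and ordered deep in the tail at large n", {
  p <- binomial_tail(c(1000, 1500, 2000), 1e6, 0.001)
  expect_true(all(p > 0))
  expect_true(all(diff(p) < 0))
})

test_that("artifact rate estimation takes the lowest well-sampled ratio", {
  # the eight per-species antisense read ratios of a deeply sequenced cohort
  ratios <- c(0.0233, 0.0312, 0.0481, 0.0626, 0.0347, 0.0296, 0.0078, 0.0167)
  summaries <- tibble::tibble(
    species_id = paste0("sp", seq_along(ratios)),
    ratio_antisense_reads = ratios,
    reads_total = 1e6
  )
  model <- estimate_artifact_rate(summaries, min_reads = 1e5)
  expect_equal(model$p, 0.0078)
  expect_equal(model$source, "estimated")

  one <- tibble::tibble(species_id = "a", ratio_antisense_reads = 0.02,
                        reads_total = 2e5)
  expect_equal(estimate_artifact_rate(one, 1e5)$p, 0.02)

  zero <- dplyr::mutate(one, ratio_antisense_reads = 0)
  expect_equal(estimate_artifact_rate(zero, 1e5)$p, 0.001)

  shallow <- dplyr::mutate(one, reads_total = 10)
  expect_error(estimate_artifact_rate(shallow, 1e5), "fixed")
})

test_that("gene calls classify categories, d and the p-value correctly", {
  counts <- tibble::tibble(
    gene_id = c("inverted", "pure_sense", "mixed", "silent"),
    sense = c(0L, 10L, 9L, 0L),
    antisense = c(257L, 0L, 1L, 0L)
  )
  calls <- call_antisense(counts, artifact_p = 0.01, alpha = 0.05)
  inv <- calls[calls$gene_id == "inverted", ]
  expect_equal(inv$category, "antisense_only")
  expect_equal(inv$d, -1)
  expect_true(inv$antisense_called)

  ps <- calls[calls$gene_id == "pure_sense", ]
  expect_equal(ps$pvalue, 1.0)
  expect_equal(ps$d, 1)
  expect_false(ps$antisense_called)

  mx <- call_antisense(counts, artifact_p = 0.05)
  mixed <- mx[mx$gene_id == "mixed", ]
  expect_equal(mixed$pvalue, 1 - 0.95^10, tolerance = 1e-12)
  expect_false(mixed$antisense_called)
  expect_equal(mixed$category, "both")

  sil <- calls[calls$gene_id == "silent", ]
  expect_equal(sil$category, "silent")
  expect_true(is.na(sil$pvalue) && is.na(sil$d))
  expect_false(sil$antisense_called)
})

test_that("FPKM follows count * 1e9 / (length * depth)", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(5, 500, 2e6), 5)
  expect_error(compute_fpkm(5, 0, 1e6), "positive")
  expect_error(compute_fpkm(5, 100, 0), "positive")
})

test_that("species summaries compute both ratios and the eligibility flag", {
  ann <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:250),
    length = 900L,
    species_id = rep(c("big", "small"), c(200, 50))
  )
  counts <- tibble::tibble(
    gene_id = ann$gene_id,
    sense = 10L,
    antisense = c(rep(c(8L, 0L), c(20, 180)), rep(0L, 50))
  )
  calls <- call_antisense(counts, ann, artifact_p = 0.01)
  ss <- summarize_species(calls, min_expressed_genes = 100)
  big <- ss[ss$species_id == "big", ]
  expect_equal(big$n_genes_expressed, 200L)
  expect_equal(big$n_genes_antisense, 20L)
  expect_equal(big$ratio_genes_antisense, 0.10)
  expect_true(big$eligible)
  expect_false(ss$eligible[ss$species_id == "small"])

  none <- call_antisense(
    tibble::tibble(gene_id = ann$gene_id, sense = 0L, antisense = 0L), ann)
  ss0 <- summarize_species(none)
  expect_true(all(is.na(ss0$ratio_antisense_reads)))
  expect_true(all(is.na(ss0$ratio_genes_antisense)))
})

test_that("recovered antisense gene ratio tracks the simulated truth", {
  sim <- simulate_community(community_config(
    n_species = 2, genes_per_species = 500, antisense_fraction = 0.10,
    antisense_ratio_range = c(0.5, 10), strandedness = 0.99,
    total_reads = 1e6, n_samples = 1, seed = 31
  ))
  calls <- call_antisense(emit_counts(sim), sim$annotations,
                          artifact_p = 0.01, alpha = 0.05)
  ss <- summarize_species(calls)
  pooled <- sum(ss$n_genes_antisense) / sum(ss$n_genes_expressed)
  truth <- mean(dplyr::filter(sim$truth, sample_id == "S01")$true_antisense)
  expect_lt(abs(pooled - truth), 0.03)
})

test_that("antisense-only report enforces all three filters", {
  calls <- tibble::tibble(
    gene_id = c("short", "ok", "sensed", "few"),
    sense = c(0L, 0L, 1L, 0L),
    antisense = c(5L, 3L, 50L, 2L),
    length = c(500L, 700L, 700L, 700L)
  )
  out <- antisense_only_report(calls)
  expect_equal(out$gene_id, "ok")
})

test_that("calls at p = 0.05 are a subset of calls at p = 0.01", {
  sim <- small_sim(seed = 55)
  counts <- emit_counts(sim, "S01")
  liberal <- call_antisense(counts, sim$annotations, artifact_p = 0.01)
  conservative <- call_antisense(counts, sim$annotations, artifact_p = 0.05)
  called_lib <- liberal$gene_id[liberal$antisense_called]
  called_con <- conservative$gene_id[conservative$antisense_called]
  expect_true(all(called_con %in% called_lib))
  # and the per-gene p-values are monotone in the artifact rate
  expect_true(all(conservative$pvalue >= liberal$pvalue, na.rm = TRUE))
})

test_that("BH-adjusted calling is stricter than raw calling", {
  sim <- small_sim(seed = 56)
  counts <- emit_counts(sim, "S01")
  raw <- call_antisense(counts, sim$annotations)
  adj <- call_antisense(counts, sim$annotations, adjust = TRUE)
  expect_true(all(adj$gene_id[adj$antisense_called] %in%
                    raw$gene_id[raw$antisense_called]))
})
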