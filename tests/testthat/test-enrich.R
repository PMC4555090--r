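test_that("the contingency table reproduces the worked genome and conserves N", {
  tab <- build_contingency(10, 71, 33, 2204)
  expect_equal(unname(tab), matrix(c(10L, 61L, 23L, 2110L), nrow = 2))
  expect_equal(sum(tab), 2204)

  zero <- build_contingency(0, 40, 12, 500)
  expect_equal(unname(zero[1, ]), c(0L, 12L))
  expect_equal(unname(zero[2, ]), c(40L, 448L))

  withr::local_seed(5)
  for (i in 1:100) {
    N <- sample(50:5000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample.int(min(n, K) + 1, 1) - 1L
    if (N - K - n + k < 0) k <- n + K - N  # force feasibility
    expect_equal(sum(build_contingency(k, n, K, N)), N)
  }
  expect_error(build_contingency(10, 5, 33, 100), "inconsistent")
})

test_that("one-tailed Fisher p matches enumeration and hypergeometric oracle", {
  # (C(3,2)C(3,1) + C(3,3)C(3,0)) / C(6,3) = 10/20
  expect_equal(fisher_one_tailed(matrix(c(2, 1, 1, 2), 2)), 0.5)
  expect_equal(fisher_one_tailed(build_contingency(0, 40, 12, 500)), 1.0)
  expect_error(fisher_one_tailed(matrix(0, 2, 2)), "all-zero")

  withr::local_seed(6)
  for (i in 1:200) {
    N <- sample(20:5000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    lo <- max(0, n + K - N)
    k <- sample(lo:min(n, K), 1)
    tab <- build_contingency(k, n, K, N)
    expect_equal(fisher_one_tailed(tab), hyper_tail_oracle(k, n, K, N),
                 tolerance = 1e-12)
    # and agrees with the reference implementation of the exact test
    ft <- stats::fisher.test(tab, alternative = "greater")
    expect_equal(fisher_one_tailed(tab), ft$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand step-up and is idempotent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::local_seed(8)
  for (i in 1:50) {
    p <- runif(sample.int(100, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    # order-preserving: adjusted values never cross
    expect_true(all(diff(q[order(p)]) >= 0))
  }
})

# Deterministic genome fixture: 20 COGs over 300 genes, one COG's genes
# antisense-called at far above the background rate.
planted_genome <- function(seed = 13, background = 30) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", 1:300)
    cog_map <- tibble::tibble(
      gene_id = genes,
      cog_id = sample(sprintf("COG%04d", 1:20), 300, replace = TRUE)
    )
    cats <- setNames(strsplit("ABCDEFGHIJKLMNOPQRSX", "")[[1]],
                     sort(unique(cog_map$cog_id)))
    cog_map$category <- unname(cats[cog_map$cog_id])
    planted <- cog_map$gene_id[cog_map$cog_id == "COG0020"]
    called <- union(planted, sample(genes, background))
    calls <- tibble::tibble(
      gene_id = genes,
      sense = 100L,
      antisense = ifelse(genes %in% called, 60L, 0L),
      total = 160L,
      antisense_called = genes %in% called,
      species_id = "genomeA"
    )
    list(calls = calls, cog_map = cog_map, planted = "COG0020")
  })
}

test_that("a planted COG is the top enrichment hit in both test families", {
  fix <- planted_genome()
  enr <- enrich_cogs(fix$calls, fix$cog_map)
  expect_equal(enr$cog_id[which.min(enr$q_fisher)], fix$planted)
  expect_equal(enr$cog_id[which.min(enr$q_binomial)], fix$planted)
  top <- enr[enr$cog_id == fix$planted, ]
  expect_lte(top$q_fisher, 0.05)
  expect_lte(top$q_binomial, 0.05)
  expect_true(all(enr$q_binomial >= enr$p_binomial))
  expect_true(all(enr$q_fisher >= enr$p_fisher))
  # planted category X shows up in the category summary
  cats <- summarize_categories(enr)
  expect_true("X" %in% cats$category)
})

test_that("the worked genome's binomial p-value reproduces inside enrich_cogs", {
  # one COG of 33 genes among 2204; 71 called, 10 of them in the COG
  genes <- sprintf("g%04d", 1:2204)
  cog_map <- tibble::tibble(gene_id = genes[1:33], cog_id = "COG4974",
                            category = "L")
  called <- c(genes[1:10], genes[100:160])  # 10 in-COG + 61 outside
  calls <- tibble::tibble(
    gene_id = genes, sense = 10L,
    antisense = ifelse(genes %in% called, 10L, 0L),
    total = 20L, antisense_called = genes %in% called,
    species_id = "bsal"
  )
  enr <- enrich_cogs(calls, cog_map)
  expect_equal(enr$p_binomial, 1.14e-07, tolerance = 5e-3)
  expect_lte(enr$p_fisher, 1.78e-06)
})

test_that("genomes below the antisense-gene threshold are skipped", {
  fix <- planted_genome()
  few <- dplyr::mutate(fix$calls,
                       antisense_called = dplyr::row_number() <= 10)
  expect_message(out <- enrich_cogs(few, fix$cog_map), "skipping")
  expect_equal(nrow(out), 0)
})

test_that("a COG with no called genes is never significant", {
  fix <- planted_genome()
  enr <- enrich_cogs(fix$calls, fix$cog_map)
  k0 <- dplyr::filter(enr, k == 0)
  if (nrow(k0) > 0) {
    expect_true(all(k0$p_binomial == 1))
    expect_true(all(k0$p_fisher == 1))
    expect_false(any(k0$significant_fisher | k0$significant_binomial))
  }
  # multi-letter categories are split and counted once per letter
  multi <- dplyr::mutate(enr, category = ifelse(cog_id == fix$planted,
                                                "ER", category))
  class(multi) <- class(enr)
  cats <- summarize_categories(multi)
  expect_true(all(c("E", "R") %in% cats$category))
})

test_that("binomial and Fisher tests rank COGs nearly identically", {
  fix <- planted_genome(seed = 21, background = 60)
  enr <- enrich_cogs(fix$calls, fix$cog_map)
  expect_gt(cor(rank(enr$p_binomial), rank(enr$p_fisher),
                method = "spearman"), 0.95)
})

test_that("under the null the FDR is controlled on average", {
  withr::local_seed(99)
  frac <- replicate(30, {
    genes <- sprintf("g%03d", 1:300)
    cog_map <- tibble::tibble(
      gene_id = genes,
      cog_id = sample(sprintf("COG%04d", 1:20), 300, replace = TRUE),
      category = "R"
    )
    called <- sample(genes, 40)  # labels shuffled: no real association
    calls <- tibble::tibble(
      gene_id = genes, sense = 10L,
      antisense = ifelse(genes %in% called, 10L, 0L), total = 20L,
      antisense_called = genes %in% called, species_id = "null"
    )
    enr <- enrich_cogs(calls, cog_map)
    mean(enr$significant_fisher)
  })
  expect_lte(mean(frac), 0.05)
})
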