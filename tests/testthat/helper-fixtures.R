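# Shared fixtures, built in code at test time.

# Independent oracles: direct log-space summation of the binomial and
# hypergeometric upper tails, never touching pbinom/phyper.
binom_tail_oracle <- function(k, n, p) {
  if (k == 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

hyper_tail_oracle <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Hand-rolled BH step-up, used as an oracle against bh_adjust().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# A tiny hand-written annotation set: two contigs, genes on both strands.
toy_annotations <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    seq_id = c("chr1", "chr1", "chr1", "chr2"),
    start = c(101L, 1001L, 1400L, 201L),
    end = c(700L, 1500L, 1900L, 1000L),
    strand = c("+", "-", "+", "+"),
    length = c(600L, 500L, 501L, 800L),
    species_id = c("sp1", "sp1", "sp1", "sp2"),
    product = ""
  )
}

toy_alignment <- function(seq_id = "chr1", start = 150L, end = 249L,
                          strand = "+", mate_rank = "single",
                          read_id = "r1", mapq = 60L) {
  tibble::tibble(read_id = read_id, seq_id = seq_id, start = start,
                 end = end, strand = strand, mate_rank = mate_rank,
                 mapq = mapq)
}

# Writes a minimal SAM file and returns its path.
write_test_sam <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chr1\tLN:10000",
              "@SQ\tSN:chr2\tLN:10000")
  path <- file.path(dir, "test.sam")
  writeLines(c(header, lines), path)
  path
}

sam_line <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "50M") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
          qname, flag, rname, pos, mapq, cigar)
}

small_sim <- function(..., seed = 42) {
  simulate_community(community_config(
    n_species = 3, genes_per_species = 60, total_reads = 30000,
    n_samples = 3, seed = seed, ...
  ))
}
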