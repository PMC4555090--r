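# Strand-aware read-to-gene assignment: a single pass that replaces the two
# featureCounts runs (-s 1 / -s 2) classically used to separate sense from
# antisense reads.

#' Build an interval index over gene annotations
#'
#' Builds a query structure for overlap lookups of reads against genes.
#'
#' @param annotations Annotation tibble.
#' @return A `gene_index` object.
#' @export
build_gene_index <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end)
  )
  structure(
    list(gr = gr, annotations = annotations),
    class = "gene_index"
  )
}

#' Query a gene index for overlapping genes
#'
#' @param index A `gene_index`.
#' @param seq_id,start,end Query interval (1-based inclusive).
#' @return The annotation rows overlapping the query, as a tibble.
#' @export
query_gene_index <- function(index, seq_id, start, end) {
  stopifnot(inherits(index, "gene_index"))
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, index$gr)
  index$annotations[S4Vectors::subjectHits(hits), ]
}

opposite_strand <- function(s) ifelse(s == "+", "-", "+")

#' Assign reads to genes as sense or antisense
#'
#' Each read is matched against the gene index: reads overlapping no gene
#' are `no_feature`, reads overlapping two or more genes are `ambiguous`
#' (and discarded from counting, mirroring featureCounts' default), and
#' uniquely overlapping reads are oriented relative to the gene's strand.
#' With a `forward` protocol a read on the gene's strand is sense; with
#' `reverse` the comparison is inverted (as is the strand of a second mate,
#' whose template is the opposite strand of its fragment).
#'
#' @param alignments Alignment tibble ([read_alignments()] columns).
#' @param index A `gene_index` from [build_gene_index()], or an annotation
#'   tibble (indexed on the fly).
#' @param protocol `"forward"` or `"reverse"` library orientation.
#' @param min_overlap Minimum overlap in bp to assign a read (default 1).
#' @return The alignment tibble with `gene_id` (NA when unassigned) and
#'   `status` (`"sense"`, `"antisense"`, `"no_feature"` or `"ambiguous"`).
#' @export
assign_reads <- function(alignments, index, protocol = c("forward", "reverse"),
                         min_overlap = 1) {
  protocol <- match.arg(protocol)
  if (!inherits(index, "gene_index")) index <- build_gene_index(index)
  ann <- index$annotations

  n <- nrow(alignments)
  gene_id <- rep(NA_character_, n)
  status <- rep("no_feature", n)

  known <- unique(as.character(GenomicRanges::seqnames(index$gr)))
  orphan <- setdiff(unique(alignments$seq_id), known)
  if (length(orphan) > 0) {
    warning("reference sequence(s) absent from annotations, reads counted ",
            "as no_feature: ", paste(orphan, collapse = ", "), call. = FALSE)
  }

  if (n > 0) {
    onseq <- alignments$seq_id %in% known
    if (any(onseq)) {
      q <- GenomicRanges::GRanges(
        seqnames = alignments$seq_id[onseq],
        ranges = IRanges::IRanges(alignments$start[onseq], alignments$end[onseq])
      )
      hits <- GenomicRanges::findOverlaps(q, index$gr, minoverlap = min_overlap)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      nhits <- tabulate(qh, nbins = length(q))
      uniq <- which(nhits == 1)
      multi <- which(nhits >= 2)
      idx_all <- which(onseq)
      status[idx_all[multi]] <- "ambiguous"
      if (length(uniq) > 0) {
        g <- sh[match(uniq, qh)]
        rows <- idx_all[uniq]
        gene_id[rows] <- ann$gene_id[g]
        read_strand <- alignments$strand[rows]
        # a second mate reports the opposite strand of its fragment
        second <- alignments$mate_rank[rows] == "second"
        read_strand[second] <- opposite_strand(read_strand[second])
        same <- read_strand == ann$strand[g]
        if (protocol == "reverse") same <- !same
        status[rows] <- ifelse(same, "sense", "antisense")
      }
    }
  }
  dplyr::mutate(alignments, gene_id = gene_id, status = status)
}

#' Count sense and antisense reads per gene
#'
#' Runs [assign_reads()] and tallies, for every annotated gene, the reads
#' assigned to its coding strand (`sense`) and to the opposite strand
#' (`antisense`). Genes with no reads are present with zero counts. The
#' attached run report records totals of assigned, `no_feature` and
#' `ambiguous` reads, which always sum to the number of input reads.
#'
#' @inheritParams assign_reads
#' @param annotations Annotation tibble.
#' @param sample_id Optional sample label added as a column.
#' @return A tibble with `gene_id`, `sense`, `antisense` (plus `sample_id`
#'   if given), carrying the run report in `attr(, "report")` (see
#'   [count_report()]).
#' @export
count_strands <- function(alignments, annotations,
                          protocol = c("forward", "reverse"),
                          min_overlap = 1, sample_id = NULL) {
  protocol <- match.arg(protocol)
  assigned <- assign_reads(alignments, annotations, protocol, min_overlap)
  tallies <- assigned |>
    dplyr::filter(.data$status %in% c("sense", "antisense")) |>
    dplyr::count(.data$gene_id, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("sense", "antisense")) {
    if (!col %in% names(tallies)) tallies[[col]] <- 0L
  }
  out <- tibble::tibble(gene_id = annotations$gene_id) |>
    dplyr::left_join(tallies, by = "gene_id") |>
    dplyr::mutate(
      sense = dplyr::coalesce(.data$sense, 0L),
      antisense = dplyr::coalesce(.data$antisense, 0L)
    )
  if (!is.null(sample_id)) {
    out <- dplyr::mutate(out, sample_id = sample_id, .before = 1)
  }
  st <- assigned$status
  report <- tibble::tibble(
    total = nrow(alignments),
    assigned = sum(st %in% c("sense", "antisense")),
    no_feature = sum(st == "no_feature"),
    ambiguous = sum(st == "ambiguous")
  )
  attr(out, "report") <- report
  class(out) <- c("strand_counts", class(out))
  out
}

#' Run report of a counting pass
#'
#' @param counts A `strand_counts` tibble from [count_strands()].
#' @return A one-row tibble with `total`, `assigned`, `no_feature`,
#'   `ambiguous`.
#' @export
count_report <- function(counts) {
  rep <- attr(counts, "report")
  if (is.null(rep)) stop("no run report attached; was this produced by ",
                         "count_strands()?", call. = FALSE)
  rep
}

#' Per-base strand coverage over one gene
#'
#' Depth of sense- and antisense-oriented reads at every base of a gene's
#' span, for coverage plots of individual loci. All reads overlapping the
#' span contribute, regardless of assignments to neighbouring genes.
#'
#' @param alignments Alignment tibble.
#' @param gene A single annotation row (tibble or list with `seq_id`,
#'   `start`, `end`, `strand`).
#' @param protocol Library orientation, as in [assign_reads()].
#' @return A tibble with `pos` (genomic coordinate, one row per base of the
#'   gene) and depth columns `sense` and `antisense`.
#' @export
strand_coverage <- function(alignments, gene,
                            protocol = c("forward", "reverse")) {
  protocol <- match.arg(protocol)
  stopifnot(length(gene$start) == 1)
  span <- gene$start:gene$end
  sense_depth <- integer(length(span))
  anti_depth <- integer(length(span))
  ov <- dplyr::filter(alignments, .data$seq_id == gene$seq_id,
                      .data$start <= gene$end, .data$end >= gene$start)
  if (nrow(ov) > 0) {
    read_strand <- ov$strand
    second <- ov$mate_rank == "second"
    read_strand[second] <- opposite_strand(read_strand[second])
    same <- read_strand == gene$strand
    if (protocol == "reverse") same <- !same
    lo <- pmax(ov$start, gene$start) - gene$start + 1L
    hi <- pmin(ov$end, gene$end) - gene$start + 1L
    for (i in seq_len(nrow(ov))) {
      rng <- lo[i]:hi[i]
      if (same[i]) sense_depth[rng] <- sense_depth[rng] + 1L
      else anti_depth[rng] <- anti_depth[rng] + 1L
    }
  }
  tibble::tibble(pos = span, sense = sense_depth, antisense = anti_depth)
}
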