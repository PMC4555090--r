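# Readers and writers for the standard formats the pipeline touches:
# GFF3/GTF annotations, SAM/BAM alignments, count tables, COG maps and
# result TSVs. Internal coordinates are 1-based inclusive (the GFF
# convention); SAM/BAM positions are converted on read.

#' Read gene annotations from GFF3/GTF
#'
#' Reads a GFF3 or GTF file and returns one row per gene as a tibble. Rows of
#' the requested feature type that share a gene identifier (e.g. a CDS split
#' across lines) are merged into a single gene spanning the union of their
#' coordinates. Features with an unknown strand (`.`) or no usable identifier
#' are skipped with a warning.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param feature_type Feature type(s) to keep from column 3; the first type
#'   with any matching rows is used. Default `c("CDS", "gene")`.
#' @param species_of Optional named character vector mapping `seq_id` to a
#'   species identifier. Unmapped sequences (and the default) use the
#'   `seq_id` itself as `species_id`.
#' @return A tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`, `length`, `species_id`, `product` (coordinates 1-based
#'   inclusive, `length = end - start + 1`).
#' @export
read_gene_annotations <- function(path, feature_type = c("CDS", "gene"),
                                  species_of = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(gr) == 0) stop("no features in ", path, call. = FALSE)
  type <- as.character(gr$type)
  keep_type <- feature_type[feature_type %in% type][1]
  if (is.na(keep_type)) {
    stop("no features of type ", paste(feature_type, collapse = "/"),
         " in ", path, call. = FALSE)
  }
  gr <- gr[type == keep_type]

  meta <- S4Vectors::mcols(gr)
  pick <- function(cols) {
    for (col in cols) {
      if (col %in% names(meta)) {
        v <- as.character(meta[[col]])
        if (any(!is.na(v) & nzchar(v))) return(v)
      }
    }
    rep(NA_character_, length(gr))
  }
  gene_id <- pick(c("locus_tag", "gene_id", "ID", "Name"))
  product <- pick(c("product", "description"))
  product[is.na(product)] <- ""

  tbl <- tibble::tibble(
    gene_id = gene_id,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product
  )

  n_no_id <- sum(is.na(tbl$gene_id) | !nzchar(tbl$gene_id))
  if (n_no_id > 0) {
    warning(n_no_id, " feature(s) without a usable gene identifier skipped",
            call. = FALSE)
    tbl <- dplyr::filter(tbl, !is.na(.data$gene_id), nzchar(.data$gene_id))
  }
  n_no_strand <- sum(!tbl$strand %in% c("+", "-"))
  if (n_no_strand > 0) {
    warning(n_no_strand, " feature(s) with unknown strand skipped", call. = FALSE)
    tbl <- dplyr::filter(tbl, .data$strand %in% c("+", "-"))
  }

  tbl <- tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      seq_id = dplyr::first(.data$seq_id),
      start = min(.data$start),
      end = max(.data$end),
      strand = dplyr::first(.data$strand),
      product = dplyr::first(.data$product),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)

  species_id <- if (is.null(species_of)) {
    tbl$seq_id
  } else {
    out <- unname(species_of[tbl$seq_id])
    out[is.na(out)] <- tbl$seq_id[is.na(out)]
    out
  }
  tbl |>
    dplyr::mutate(species_id = species_id) |>
    dplyr::select("gene_id", "seq_id", "start", "end", "strand", "length",
                  "species_id", "product") |>
    dplyr::arrange(.data$seq_id, .data$start, .data$gene_id)
}

#' Write gene annotations as GFF3
#'
#' Serialises an annotation tibble (as produced by [read_gene_annotations()]
#' or [simulate_community()]) to a GFF3 file with one `CDS` feature per gene.
#' `read_gene_annotations()` on the result reproduces the input.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand
  )
  gr$type <- "CDS"
  gr$source <- "antisensr"
  gr$phase <- 0L
  gr$locus_tag <- annotations$gene_id
  gr$product <- annotations$product
  gr$species <- annotations$species_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read filtered alignments from SAM/BAM
#'
#' Loads primary mapped alignments; unmapped, secondary and supplementary
#' records are excluded, as are records below the MAPQ threshold. A `.sam`
#' text file is converted to BAM on the fly. Reported coordinates are the
#' 1-based inclusive reference span of the alignment (sum of M/D/N/=/X CIGAR
#' operations).
#'
#' @param path Path to a SAM or BAM file.
#' @param min_mapq Minimum mapping quality; default 0 (no filter).
#' @return A tibble with columns `read_id`, `seq_id`, `start`, `end`,
#'   `strand`, `mate_rank` (`single`, `first` or `second`) and `mapq`.
#' @export
read_alignments <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  stopifnot(min_mapq >= 0)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to read SAM ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "mapq", "flag"))
  aln <- tryCatch(
    GenomicAlignments::readGAlignments(bam, param = param),
    error = function(e) stop("failed to read alignments from ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  flags <- S4Vectors::mcols(aln)$flag
  mate_rank <- dplyr::case_when(
    bitwAnd(flags, 64L) > 0L ~ "first",
    bitwAnd(flags, 128L) > 0L ~ "second",
    TRUE ~ "single"
  )
  mapq <- S4Vectors::mcols(aln)$mapq
  mapq[is.na(mapq)] <- 255L
  tbl <- tibble::tibble(
    read_id = S4Vectors::mcols(aln)$qname,
    seq_id = as.character(GenomicAlignments::seqnames(aln)),
    start = GenomicAlignments::start(aln),
    end = GenomicAlignments::end(aln),
    strand = as.character(GenomicAlignments::strand(aln)),
    mate_rank = mate_rank,
    mapq = as.integer(mapq)
  )
  dplyr::filter(tbl, .data$mapq >= min_mapq)
}

#' Write alignments as SAM
#'
#' Serialises an alignment tibble (e.g. from [emit_reads()]) as a SAM text
#' file with an `@SQ` header per reference sequence. Reads carry a full-match
#' CIGAR over their reference span and no sequence (`*`), which is sufficient
#' for strand-aware counting.
#'
#' @param alignments Alignment tibble (columns as [read_alignments()]).
#' @param contigs Named integer vector of reference sequence lengths.
#' @param path Output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)), con)
  if (nrow(alignments) > 0) {
    a <- dplyr::arrange(alignments, .data$seq_id, .data$start)
    flag <- ifelse(a$strand == "-", 16L, 0L)
    flag <- flag +
      ifelse(a$mate_rank == "first", 1L + 64L, 0L) +
      ifelse(a$mate_rank == "second", 1L + 128L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                       a$read_id, flag, a$seq_id, a$start, a$mapq,
                       a$end - a$start + 1L), con)
  }
  invisible(path)
}

#' Read a precomputed strand count table
#'
#' Entry point for count tables produced by an external dual-strand counting
#' run. The file must be tab-separated with a header naming at least
#' `gene_id`, `sense` and `antisense`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `sense`, `antisense` (and
#'   `sample_id` if present in the file).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           sense = readr::col_double(),
                           antisense = readr::col_double()
                         ))
  need <- c("gene_id", "sense", "antisense")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("count table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("sense", "antisense")) {
    v <- tbl[[col]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      stop("count table ", path, ": non-integer or negative `", col,
           "` at data row ", bad[1], call. = FALSE)
    }
    tbl[[col]] <- as.integer(v)
  }
  key <- if ("sample_id" %in% names(tbl)) {
    paste(tbl$sample_id, tbl$gene_id)
  } else {
    tbl$gene_id
  }
  if (anyDuplicated(key)) {
    stop("count table ", path, ": duplicated gene_id at data row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  tbl
}

#' Read a gene-to-COG mapping table
#'
#' @param path TSV with columns `gene_id`, `cog_id`, `category` (one-letter
#'   COG functional category codes; a gene may appear on several rows, once
#'   per COG).
#' @return A tibble with those three columns.
#' @export
read_cog_map <- function(path) {
  if (!file.exists(path)) stop("COG map not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "cog_id", "category")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("COG map ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tbl$cog_id))) stop("COG map has empty cog_id", call. = FALSE)
  if (anyDuplicated(paste(tbl$gene_id, tbl$cog_id))) {
    stop("COG map lists the same (gene_id, cog_id) pair twice", call. = FALSE)
  }
  tbl
}

#' Write a result table as TSV
#'
#' Writes any of the pipeline's result tibbles tab-separated with a header
#' row, in a deterministic row order (sorted by `key`). Numeric columns keep
#' full precision, so a write-then-read round trip is the identity.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param key Character vector of columns to sort by; defaults to all
#'   character columns in order of appearance.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, key = NULL) {
  if (is.null(key)) key <- names(x)[vapply(x, is.character, logical(1))]
  if (length(key) > 0) {
    x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(key)))
  }
  tryCatch(
    readr::write_tsv(x, path, progress = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  invisible(path)
}
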