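#' Extract an intron catalog from a genome and exon annotation
#'
#' Enumerates the inter-exon gaps of every multi-exon transcript and returns
#' one record per intron with its strand-correct sequence (always in
#' transcript orientation, so the donor site is the 5' end of `sequence`),
#' its rank along the transcript, and its terminal dinucleotides.
#'
#' Coordinates are 0-based half-open internally (`start`/`end` columns);
#' 1-based inclusive GTF coordinates are converted on read. Zero-length
#' gaps between abutting exons contribute no intron.
#'
#' @param genome Genome sequence: a path to a FASTA file, a
#'   [Biostrings::DNAStringSet], or a named character vector of chromosome
#'   sequences.
#' @param annotation Exon annotation: a path to a GTF/GFF file, a
#'   [GenomicRanges::GRanges] with `gene_id` and `transcript_id` metadata
#'   columns, or a data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, `transcript_id` (and optionally `type`,
#'   filtered to `"exon"`).
#' @return A tibble with one row per intron: `intron_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `rank` (1 = 5'-most intron of the transcript), `sequence`,
#'   `donor_dinuc`, `acceptor_dinuc`.
#' @examples
#' genome <- c(chrT = paste(rep("ACGT", 25), collapse = ""))
#' ann <- tibble::tibble(
#'   chrom = "chrT", start = c(1, 41), end = c(20, 60),
#'   strand = "+", gene_id = "g1", transcript_id = "t1"
#' )
#' extract_introns(genome, ann)
#' @export
extract_introns <- function(genome, annotation) {
  genome <- as_genome(genome)
  exons <- as_exon_table(annotation)

  if (nrow(exons) == 0) {
    return(empty_catalog())
  }

  missing_chrom <- setdiff(unique(exons$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0(
      "Chromosome(s) absent from the genome: ",
      paste(missing_chrom, collapse = ", ")
    ))
  }

  introns <- exons %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    group_modify(function(ex, key) {
      if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        abort(paste0("Overlapping exons in transcript ", key$transcript_id))
      }
      if (nrow(ex) < 2) {
        return(tibble(
          gene_id = character(), chrom = character(),
          start = integer(), end = integer(), strand = character()
        ))
      }
      tibble(
        gene_id = ex$gene_id[-1],
        chrom = ex$chrom[-1],
        # GTF 1-based inclusive -> 0-based half-open intron coordinates
        start = as.integer(ex$end[-nrow(ex)]),
        end = as.integer(ex$start[-1] - 1L),
        strand = ex$strand[-1]
      )
    }) %>%
    ungroup() %>%
    filter(.data$end > .data$start)

  if (nrow(introns) == 0) {
    return(empty_catalog())
  }

  introns <- introns %>%
    group_by(.data$transcript_id) %>%
    mutate(rank = if (first(.data$strand) == "-") rev(row_number()) else row_number()) %>%
    ungroup() %>%
    mutate(
      sequence = fetch_sequence(genome, .data$chrom, .data$start, .data$end, .data$strand),
      intron_id = paste0(.data$transcript_id, ".i", .data$rank),
      donor_dinuc = toupper(substr(.data$sequence, 1L, 2L)),
      acceptor_dinuc = toupper(substr(
        .data$sequence, nchar(.data$sequence) - 1L, nchar(.data$sequence)
      ))
    ) %>%
    select(
      "intron_id", "gene_id", "transcript_id", "chrom", "start", "end",
      "strand", "rank", "sequence", "donor_dinuc", "acceptor_dinuc"
    ) %>%
    arrange(.data$transcript_id, .data$rank)

  introns
}

empty_catalog <- function() {
  tibble(
    intron_id = character(), gene_id = character(),
    transcript_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    rank = integer(), sequence = character(),
    donor_dinuc = character(), acceptor_dinuc = character()
  )
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    seqs <- setNames(as.character(gs), names(gs))
  } else if (is.character(genome) && !is.null(names(genome))) {
    seqs <- genome
  } else {
    abort("`genome` must be a FASTA path, a DNAStringSet, or a named character vector")
  }
  # FASTA headers may carry descriptions; keep the first word only
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

as_exon_table <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- rtracklayer::import(annotation)
  }
  if (inherits(annotation, "GRanges")) {
    meta <- S4Vectors::mcols(annotation)
    if (!all(c("gene_id", "transcript_id") %in% names(meta))) {
      abort("annotation must carry `gene_id` and `transcript_id` attributes")
    }
    tab <- tibble(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      gene_id = as.character(meta$gene_id),
      transcript_id = as.character(meta$transcript_id),
      type = if ("type" %in% names(meta)) as.character(meta$type) else "exon"
    )
  } else if (is.data.frame(annotation)) {
    req <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
    if (!all(req %in% names(annotation))) {
      abort(paste0(
        "annotation data frame needs columns: ", paste(req, collapse = ", ")
      ))
    }
    tab <- as_tibble(annotation)
    if (!"type" %in% names(tab)) tab$type <- "exon"
  } else {
    abort("`annotation` must be a GTF path, a GRanges, or a data frame")
  }
  tab %>%
    filter(.data$type == "exon") %>%
    select("chrom", "start", "end", "strand", "gene_id", "transcript_id")
}

fetch_sequence <- function(genome, chrom, start0, end0, strand) {
  seqs <- substr(genome[chrom], start0 + 1L, end0)
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])
    ))
  }
  unname(seqs)
}

#' Terminal dinucleotides of intron sequences
#'
#' The first and last two nucleotides of an intron (in transcript
#' orientation) are the canonical class diagnostics: GT...AG for U2-type and
#' U12 GT-AG introns, AT...AC for the U12 AT-AC subtype.
#'
#' @param sequence Character vector of intron sequences (5'->3' of the
#'   transcript), each at least 4 nt.
#' @return A tibble with columns `donor_dinuc` and `acceptor_dinuc`
#'   (uppercase 2-mers), one row per input sequence.
#' @examples
#' terminal_dinucleotides(c("GTAAGTTTTTAG", "atatcctttcac"))
#' @export
terminal_dinucleotides <- function(sequence) {
  if (any(nchar(sequence) < 4)) {
    abort("every sequence must be at least 4 nt long")
  }
  sequence <- toupper(sequence)
  tibble(
    donor_dinuc = substr(sequence, 1L, 2L),
    acceptor_dinuc = substr(sequence, nchar(sequence) - 1L, nchar(sequence))
  )
}

#' Rank distance from an intron to the nearest target intron in its gene
#'
#' Measures how far (in intron ranks along the transcript) a query intron
#' lies from the nearest member of a target set within the same gene.
#' Distance 1 means immediately upstream or downstream — the adjacency used
#' when asking whether affected U2 introns flank U12 introns.
#'
#' @param catalog Intron catalog tibble (needs `intron_id`, `gene_id`,
#'   `rank`).
#' @param query An `intron_id` present in the catalog.
#' @param targets Character vector of target `intron_id`s.
#' @return Integer minimum `|rank(query) - rank(target)|` over same-gene
#'   targets, or `NA_integer_` if no target shares the query's gene.
#' @export
intron_rank_distance <- function(catalog, query, targets) {
  ids <- c(query, targets)
  unknown <- setdiff(ids, catalog$intron_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "intron_id(s) not in catalog: ", paste(unknown, collapse = ", ")
    ))
  }
  qrow <- catalog[catalog$intron_id == query, ]
  trows <- catalog[catalog$intron_id %in% targets &
    catalog$gene_id %in% qrow$gene_id, ]
  trows <- trows[trows$intron_id != query, ]
  if (nrow(trows) == 0) {
    return(NA_integer_)
  }
  as.integer(min(abs(outer(qrow$rank, trows$rank, `-`))))
}

#' Deduplicate a catalog to one record per genomic intron per gene
#'
#' Different transcripts of a gene often share introns; classification and
#' gene-level adjacency work on the deduplicated set. Gene-level ranks
#' (`rank`) are reassigned 5'->3' in gene orientation over the distinct
#' introns.
#'
#' @param catalog Intron catalog tibble from [extract_introns()].
#' @return A tibble with one row per distinct (gene, chrom, start, end,
#'   strand) intron; `intron_id` keeps the first contributing transcript's
#'   id, `rank` is the gene-level rank.
#' @export
dedup_introns <- function(catalog) {
  if (nrow(catalog) == 0) {
    return(catalog)
  }
  catalog %>%
    group_by(.data$gene_id, .data$chrom, .data$start, .data$end, .data$strand) %>%
    arrange(.data$transcript_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(rank = if (first(.data$strand) == "-") rev(row_number()) else row_number()) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$rank)
}

#' Write / read an intron catalog
#'
#' `write_intron_catalog()` writes `<out_prefix>.catalog.tsv` (all fields)
#' and `<out_prefix>.introns.bed` (BED6, 0-based half-open, name =
#' `intron_id`, score = 0). `read_intron_catalog()` reads the TSV back with
#' the original column types so the round trip is exact.
#'
#' @param catalog Intron catalog tibble.
#' @param out_prefix Output path prefix.
#' @return `write_intron_catalog()` returns the two file paths invisibly;
#'   `read_intron_catalog()` returns the catalog tibble.
#' @export
write_intron_catalog <- function(catalog, out_prefix) {
  tsv <- paste0(out_prefix, ".catalog.tsv")
  bed <- paste0(out_prefix, ".introns.bed")
  readr::write_tsv(catalog, tsv)
  bed_tab <- tibble(
    chrom = catalog$chrom, start = catalog$start, end = catalog$end,
    name = catalog$intron_id, score = 0L, strand = catalog$strand
  )
  readr::write_tsv(bed_tab, bed, col_names = FALSE)
  invisible(c(tsv = tsv, bed = bed))
}

#' @rdname write_intron_catalog
#' @param path Path to a `.catalog.tsv` written by [write_intron_catalog()].
#' @export
read_intron_catalog <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    intron_id = readr::col_character(),
    gene_id = readr::col_character(),
    transcript_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    rank = readr::col_integer(),
    sequence = readr::col_character(),
    donor_dinuc = readr::col_character(),
    acceptor_dinuc = readr::col_character()
  ))
}
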