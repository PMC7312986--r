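#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the data regime the analysis targets: U12 introns are a
#' small minority (one per U12 gene), intron-retention effects are planted
#' with a configurable preference for U12 introns, and read counts are
#' binomial given the true PSI. The U12 gene fraction (3%) is deliberately
#' higher than the genomic ~0.4% so that test catalogs stay small; for that
#' reason enrichment nulls on synthetic data must use the realized catalog
#' U12 fraction, not the genomic constant.
#'
#' @param n_genes Number of genes (default 500).
#' @param introns_per_gene Introns per gene: a single integer or a
#'   `c(min, max)` range sampled uniformly (default 5).
#' @param u12_gene_fraction Fraction of genes carrying exactly one U12
#'   intron (default 0.03).
#' @param u12_atac_share Probability a U12 intron is of the AT-AC subtype
#'   (default 0.3, GT-AG being the commoner subtype).
#' @param read_depth Reads per event per sample (default 100).
#' @param n_replicates Samples per group (default 3).
#' @param planted_ir_effect Delta-PSI added in MU for planted events
#'   (default +25).
#' @param planted_u12_bias Probability a planted IR effect lands on a U12
#'   intron (default 0.5); `NA` plants uniformly over all introns (the
#'   no-bias null).
#' @param baseline_psi Baseline retention PSI in both groups (default 5).
#' @param n_planted_events Number of events with a planted effect
#'   (default 20).
#' @param intron_length_range,exon_length_range Sequence geometry.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, introns_per_gene = 5,
                       u12_gene_fraction = 0.03, u12_atac_share = 0.3,
                       read_depth = 100, n_replicates = 3,
                       planted_ir_effect = 25, planted_u12_bias = 0.5,
                       baseline_psi = 5, n_planted_events = 20,
                       intron_length_range = c(80L, 140L),
                       exon_length_range = c(60L, 120L),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config()")
  fracs <- c(u12_gene_fraction, u12_atac_share)
  stopifnot(all(fracs >= 0 & fracs <= 1), read_depth > 0, n_replicates >= 1)
  structure(
    list(
      n_genes = n_genes, introns_per_gene = introns_per_gene,
      u12_gene_fraction = u12_gene_fraction, u12_atac_share = u12_atac_share,
      read_depth = read_depth, n_replicates = n_replicates,
      planted_ir_effect = planted_ir_effect,
      planted_u12_bias = planted_u12_bias,
      baseline_psi = baseline_psi, n_planted_events = n_planted_events,
      intron_length_range = intron_length_range,
      exon_length_range = exon_length_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Sample sequences position-wise from a PWM's probability matrix
#' @param pwm A `splice_pwm`.
#' @param n Number of sequences.
#' @return Character vector of length `n`, each `pwm$width` nt.
#' @export
sample_from_pwm <- function(pwm, n = 1) {
  mat <- vapply(seq_len(pwm$width), function(i) {
    sample(DNA_BASES, n, replace = TRUE, prob = pwm$probs[i, ])
  }, character(n))
  if (n == 1) {
    paste(mat, collapse = "")
  } else {
    apply(matrix(mat, nrow = n), 1, paste, collapse = "")
  }
}

# one intron sequence of a given true class, in transcript orientation
build_intron_seq <- function(class, len, pwms) {
  s <- strsplit(random_dna(len), "")[[1]]
  if (class == "U2") {
    donor <- pwms$donor_u2
    s[seq_len(donor$width)] <- strsplit(sample_from_pwm(donor), "")[[1]]
    acc <- pwms$acceptor_u2
    s[(len - acc$width + 1):len] <- strsplit(sample_from_pwm(acc), "")[[1]]
    s[1:2] <- c("G", "T")
    s[(len - 1):len] <- c("A", "G")
  } else {
    donor <- if (class == "U12-ATAC") pwms$donor_u12_atac else pwms$donor_u12_gtag
    branch <- if (class == "U12-ATAC") pwms$branch_u12_atac else pwms$branch_u12_gtag
    s[seq_len(donor$width)] <- strsplit(sample_from_pwm(donor), "")[[1]]
    # branch window end offset in [-40, -8], kept clear of the donor block
    lo <- max(-40L, donor$width + branch$width - len)
    offset <- sample(seq(lo, -8L), 1)
    bstart <- len + offset - branch$width + 1
    s[bstart:(len + offset)] <- strsplit(sample_from_pwm(branch), "")[[1]]
    if (class == "U12-ATAC") {
      s[1:2] <- c("A", "T")
      s[(len - 1):len] <- c("A", "C")
    } else {
      s[1:2] <- c("G", "T")
      s[(len - 1):len] <- c("A", "G")
    }
  }
  paste(s, collapse = "")
}

#' Simulate a genome, annotation and intron truth catalog
#'
#' Generates `n_genes` gene models on a single synthetic chromosome
#' (alternating strands), each a chain of exons and introns. A configured
#' fraction of genes carries exactly one U12 intron (AT-AC or GT-AG) among
#' U2 introns; splice-site blocks are sampled position-wise from the
#' class's PWMs (donor at the 5' end, branch at a random feasible offset
#' near the 3' end for U12, acceptor at the 3' end for U2), terminal
#' dinucleotides are forced to the class-canonical pair, and interior
#' sequence is uniform random. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param pwms PWM set used for sampling (default [default_pwm_set()]).
#' @param sequences If `FALSE`, skip all sequence/coordinate generation and
#'   return only the `truth` table (fast path for statistical
#'   simulations).
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `annotation` (exon tibble in [extract_introns()] format),
#'   and `truth` (tibble `intron_id`, `gene_id`, `true_class`).
#'   `genome`/`annotation` are `NULL` when `sequences = FALSE`.
#' @export
simulate_intron_catalog <- function(config, pwms = default_pwm_set(),
                                    sequences = TRUE) {
  withr::local_seed(config$seed)
  ng <- config$n_genes
  if (ng == 0) {
    return(list(
      genome = if (sequences) character(0) else NULL,
      annotation = if (sequences) {
        tibble(
          chrom = character(0), start = integer(0), end = integer(0),
          strand = character(0), gene_id = character(0),
          transcript_id = character(0)
        )
      } else {
        NULL
      },
      truth = tibble(
        intron_id = character(0), gene_id = character(0),
        true_class = character(0)
      )
    ))
  }

  gene_ids <- sprintf("g%04d", seq_len(ng))
  ipg <- config$introns_per_gene
  n_introns <- if (length(ipg) == 2) {
    sample(seq(ipg[1], ipg[2]), ng, replace = TRUE)
  } else {
    rep(as.integer(ipg), ng)
  }
  n_u12_genes <- round(ng * config$u12_gene_fraction)
  u12_genes <- if (n_u12_genes > 0) sample(gene_ids, n_u12_genes) else character(0)

  # truth table, fully vectorized so the sequence-free path stays fast
  tx_ids <- paste0(gene_ids, ".t1")
  truth <- tibble(
    intron_id = paste0(
      rep(tx_ids, n_introns), ".i",
      unlist(lapply(n_introns, seq_len), use.names = FALSE)
    ),
    gene_id = rep(gene_ids, n_introns),
    true_class = "U2"
  )
  if (length(u12_genes) > 0) {
    for (gid in u12_genes) {
      idx <- which(truth$gene_id == gid)
      if (length(idx) == 0) next
      subtype <- if (runif(1) < config$u12_atac_share) "U12-ATAC" else "U12-GTAG"
      truth$true_class[idx[sample.int(length(idx), 1)]] <- subtype
    }
  }
  if (!sequences) {
    return(list(genome = NULL, annotation = NULL, truth = truth))
  }

  class_by_gene <- split(truth$true_class, truth$gene_id)
  gene_seqs <- character(ng)
  ann_list <- vector("list", ng)
  cursor <- 0L
  chrom <- "chrS"

  for (gi in seq_len(ng)) {
    gid <- gene_ids[gi]
    tid <- tx_ids[gi]
    k <- n_introns[gi]
    classes <- class_by_gene[[gid]]
    strand <- if (gi %% 2 == 1) "+" else "-"
    ex_len <- sample(
      seq(config$exon_length_range[1], config$exon_length_range[2]),
      k + 1, replace = TRUE
    )
    in_len <- if (k > 0) {
      sample(
        seq(config$intron_length_range[1], config$intron_length_range[2]),
        k, replace = TRUE
      )
    } else {
      integer(0)
    }
    blocks <- character(2 * k + 1)
    is_exon <- logical(2 * k + 1)
    for (j in seq_len(k + 1)) {
      blocks[2 * j - 1] <- random_dna(ex_len[j])
      is_exon[2 * j - 1] <- TRUE
      if (j <= k) {
        blocks[2 * j] <- build_intron_seq(classes[j], in_len[j], pwms)
      }
    }
    tx_seq <- paste(blocks, collapse = "")
    L <- nchar(tx_seq)
    # transcript-orientation block boundaries (0-based half-open)
    ends <- cumsum(nchar(blocks))
    starts <- c(0L, head(ends, -1))
    g0 <- cursor
    if (strand == "+") {
      gstart <- g0 + starts
      gend <- g0 + ends
      gene_seqs[gi] <- tx_seq
    } else {
      gstart <- g0 + L - ends
      gend <- g0 + L - starts
      gene_seqs[gi] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx_seq)
      ))
    }
    ann_list[[gi]] <- tibble(
      chrom = chrom,
      start = as.integer(gstart[is_exon] + 1L), # 1-based inclusive
      end = as.integer(gend[is_exon]),
      strand = strand, gene_id = gid, transcript_id = tid
    )
    cursor <- cursor + L + 100L # 100 nt intergenic spacer
  }

  spacer <- random_dna(100L)
  genome_seq <- paste(
    vapply(gene_seqs, function(s) paste0(s, spacer), character(1)),
    collapse = ""
  )
  list(
    genome = setNames(genome_seq, chrom),
    annotation = bind_rows(ann_list) %>% arrange(.data$start),
    truth = truth
  )
}

#' Simulate a two-condition IR event-count table with planted effects
#'
#' One intron-retention event per catalog intron. Per sample,
#' `inclusion_reads ~ Binomial(read_depth, PSI/100)` with
#' `PSI = baseline_psi` in both groups except for planted events, whose MU
#' PSI is `baseline_psi + planted_ir_effect` (clamped to `[0, 100]`).
#' Planted events land on U12 introns with probability
#' `planted_u12_bias` (capped by U12 availability); with
#' `planted_u12_bias = NA` they are drawn uniformly over all introns.
#'
#' @param truth Truth tibble from [simulate_intron_catalog()] (`intron_id`,
#'   `gene_id`, `true_class`).
#' @param config A [sim_config()].
#' @param seed RNG seed (default `config$seed + 1` so catalog and counts
#'   use distinct, reproducible streams).
#' @return A list with `counts` (long event-count tibble in the
#'   [call_differential()] input format) and `truth_events` (per event:
#'   `event_id`, `intron_id`, `gene_id`, `true_class`, `planted`,
#'   `true_psi_wt`, `true_psi_mu`).
#' @export
simulate_event_counts <- function(truth, config, seed = config$seed + 1L) {
  if (config$read_depth <= 0) abort("read_depth must be > 0")
  withr::local_seed(seed)

  n_events <- nrow(truth)
  events <- truth %>%
    mutate(
      event_id = paste0("IR_", .data$intron_id),
      planted = FALSE
    )

  n_plant <- min(config$n_planted_events, n_events)
  if (n_plant > 0) {
    u12_idx <- which(startsWith(events$true_class, "U12"))
    u2_idx <- setdiff(seq_len(n_events), u12_idx)
    if (is.na(config$planted_u12_bias)) {
      planted_idx <- sample(seq_len(n_events), n_plant)
    } else {
      n_u12 <- min(
        rbinom(1, n_plant, config$planted_u12_bias),
        length(u12_idx)
      )
      n_u2 <- min(n_plant - n_u12, length(u2_idx))
      planted_idx <- c(
        if (n_u12 > 0) sample(u12_idx, n_u12) else integer(0),
        if (n_u2 > 0) sample(u2_idx, n_u2) else integer(0)
      )
    }
    events$planted[planted_idx] <- TRUE
  }

  clamp <- function(x) pmin(100, pmax(0, x))
  events <- events %>%
    mutate(
      true_psi_wt = clamp(config$baseline_psi),
      true_psi_mu = clamp(
        config$baseline_psi + if_else(.data$planted, config$planted_ir_effect, 0)
      )
    )

  samples <- tibble(
    sample = c(
      paste0("WT_", seq_len(config$n_replicates)),
      paste0("MU_", seq_len(config$n_replicates))
    ),
    group = rep(c("WT", "MU"), each = config$n_replicates)
  )
  counts <- tidyr::expand_grid(
    events %>% select(
      "event_id", "intron_id", "gene_id", "true_psi_wt", "true_psi_mu"
    ),
    samples
  ) %>%
    mutate(
      true_psi = if_else(.data$group == "MU", .data$true_psi_mu, .data$true_psi_wt),
      inclusion_reads = rbinom(n(), config$read_depth, .data$true_psi / 100),
      exclusion_reads = as.integer(config$read_depth) - .data$inclusion_reads,
      event_class = "IR"
    ) %>%
    select(
      "event_id", "event_class", "gene_id", "intron_id", "sample", "group",
      "inclusion_reads", "exclusion_reads"
    )

  list(
    counts = counts,
    truth_events = events %>% select(
      "event_id", "intron_id", "gene_id", "true_class", "planted",
      "true_psi_wt", "true_psi_mu"
    )
  )
}

#' Simulate offspring draws from a cross
#'
#' i.i.d. draws from the enumerated outcome distribution of
#' [enumerate_offspring()], with non-viable outcomes recorded as
#' `"arrested"` rather than dropped.
#'
#' @param cross A `cross_result`.
#' @param n Number of offspring to draw (> 0).
#' @param seed RNG seed.
#' @return Tibble of `n` rows: the outcome columns plus `status`
#'   (`"live"` / `"arrested"`).
#' @export
simulate_cross_offspring <- function(cross, n, seed) {
  stopifnot(n > 0)
  withr::local_seed(seed)
  idx <- sample(nrow(cross$outcomes), n,
    replace = TRUE, prob = cross$outcomes$probability
  )
  cross$outcomes[idx, ] %>%
    mutate(status = if_else(.data$viable, "live", "arrested"))
}

#' Simulate a comparative-CT qPCR table with known fold changes
#'
#' Builds reference and target CT values so that [delta_delta_ct()]
#' recovers `true_fold_changes / min(true_fold_changes)` exactly at
#' `noise_sd = 0` (the comparative-CT method is calibrated to the
#' lowest-expressing sample, so only folds relative to that calibrator are
#' identifiable). Gaussian noise of sd `noise_sd` is added independently to
#' every CT.
#'
#' @param true_fold_changes Named (by sample) positive numeric vector of
#'   target fold changes relative to the calibrator.
#' @param noise_sd CT noise standard deviation.
#' @param seed RNG seed.
#' @param target_gene,reference_gene Gene labels used in the table.
#' @return A CT tibble (`sample_id`, `gene_id`, `ct`) ready for
#'   [delta_delta_ct()].
#' @export
simulate_ct_table <- function(true_fold_changes, noise_sd = 0, seed,
                              target_gene = "target", reference_gene = "H2afz") {
  if (any(true_fold_changes <= 0)) abort("fold changes must be positive")
  withr::local_seed(seed)
  samples <- names(true_fold_changes) %||%
    paste0("s", seq_along(true_fold_changes))
  ref_ct <- 20
  base_dct <- 8 # arbitrary target offset; cancels in the ddCT
  n <- length(true_fold_changes)
  tibble(
    sample_id = rep(samples, 2),
    gene_id = rep(c(target_gene, reference_gene), each = n),
    ct = c(
      ref_ct + base_dct - log2(true_fold_changes) + rnorm(n, 0, noise_sd),
      rep(ref_ct, n) + rnorm(n, 0, noise_sd)
    )
  )
}

#' Write a simulated genome / annotation to standard formats
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annotation Exon tibble from [simulate_intron_catalog()].
#' @param fasta_path,gtf_path Output paths.
#' @export
write_genome_fasta <- function(genome, fasta_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), fasta_path
  )
  invisible(fasta_path)
}

#' @rdname write_genome_fasta
#' @export
write_annotation_gtf <- function(annotation, gtf_path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "u12retain_sim"
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  S4Vectors::mcols(gr)$transcript_id <- annotation$transcript_id
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(gtf_path)
}
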