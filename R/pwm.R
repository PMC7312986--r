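#' Build a position weight matrix from aligned splice-site sequences
#'
#' Counts bases per position over an alignment of equal-length site
#' sequences and converts them to log2 odds against a background
#' composition, with a background-distributed pseudocount:
#' `logodds[i, b] = log2((count[i, b] + pseudocount * background[b]) /
#' (n + pseudocount) / background[b])`. `N` characters contribute 0.25 of a
#' count to each base at their position.
#'
#' @param aligned_sites Character vector of equal-length sequences over
#'   `A C G T N`.
#' @param site_kind One of `"donor"`, `"branch"`, `"acceptor"`.
#' @param subtype One of `"U12-ATAC"`, `"U12-GTAG"`, `"U2"`.
#' @param pseudocount Positive pseudocount mass (default 1), distributed
#'   across bases proportionally to the background.
#' @param background Length-4 probability vector (A, C, G, T order);
#'   default uniform.
#' @return A `splice_pwm` object: list with `site_kind`, `subtype`, `width`,
#'   `logodds` (width x 4 matrix), `probs` (width x 4 probability matrix),
#'   `background`, `pseudocount`, `n_training`.
#' @examples
#' build_pwm(c("GTATCCTT", "GTATCCTT", "GTGTCCTT"), "donor", "U12-GTAG")
#' @export
build_pwm <- function(aligned_sites, site_kind, subtype,
                      pseudocount = 1, background = rep(0.25, 4)) {
  site_kind <- match.arg(site_kind, c("donor", "branch", "acceptor"))
  subtype <- match.arg(subtype, c("U12-ATAC", "U12-GTAG", "U2"))
  if (length(aligned_sites) == 0) {
    abort("empty training set")
  }
  widths <- unique(nchar(aligned_sites))
  if (length(widths) != 1) {
    abort("training sequences must all have the same length")
  }
  if (pseudocount <= 0) {
    abort("pseudocount must be > 0")
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  background <- setNames(as.numeric(background), DNA_BASES)

  width <- widths
  chars <- matrix(
    unlist(strsplit(toupper(aligned_sites), "", fixed = TRUE)),
    nrow = length(aligned_sites), ncol = width, byrow = TRUE
  )
  bad <- setdiff(unique(as.vector(chars)), c(DNA_BASES, "N"))
  if (length(bad) > 0) {
    abort(paste0("invalid characters in training set: ", paste(bad, collapse = ", ")))
  }

  n <- length(aligned_sites)
  counts <- vapply(seq_len(width), function(i) {
    col <- chars[, i]
    cnt <- vapply(DNA_BASES, function(b) sum(col == b), numeric(1))
    cnt + sum(col == "N") * 0.25
  }, numeric(4))
  counts <- t(counts) # width x 4
  colnames(counts) <- DNA_BASES

  probs <- sweep(counts, 2, pseudocount * background, `+`) / (n + pseudocount)
  logodds <- log2(sweep(probs, 2, background, `/`))

  structure(
    list(
      site_kind = site_kind, subtype = subtype, width = width,
      logodds = logodds, probs = probs, background = background,
      pseudocount = pseudocount, n_training = n
    ),
    class = "splice_pwm"
  )
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf(
    "<splice_pwm> %s site, %s, width %d, n_training %d\n",
    x$site_kind, x$subtype, x$width, x$n_training
  ))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' @export
tidy.splice_pwm <- function(x, ...) {
  tibble(
    site_kind = x$site_kind, subtype = x$subtype,
    position = rep(seq_len(x$width), times = 4),
    base = rep(DNA_BASES, each = x$width),
    logodds = as.vector(x$logodds),
    prob = as.vector(x$probs)
  ) %>% arrange(.data$position, .data$base)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param pwm A `splice_pwm`.
#' @return A single string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$logodds, 1, which.max)], collapse = "")
}

#' Score a sequence window against a PWM
#'
#' Sums the per-position log2-odds of each base in the window. `N` scores 0
#' at its position (no evidence either way).
#'
#' @param pwm A `splice_pwm`.
#' @param window Character vector of sequences, each exactly `pwm$width` nt.
#' @return Numeric vector of log2-odds scores.
#' @export
score_window <- function(pwm, window) {
  if (any(nchar(window) != pwm$width)) {
    abort(paste0("window length must equal pwm width (", pwm$width, ")"))
  }
  score_windows_fast(pwm$logodds, toupper(window))
}

# Vectorized scoring core: windows is a character vector of equal-length
# strings matching nrow(logodds); N (and any non-ACGT) contributes 0.
score_windows_fast <- function(logodds, windows) {
  if (length(windows) == 0) {
    return(numeric(0))
  }
  w <- nrow(logodds)
  chars <- matrix(
    unlist(strsplit(windows, "", fixed = TRUE)),
    nrow = length(windows), ncol = w, byrow = TRUE
  )
  base_idx <- match(chars, DNA_BASES) # NA for N
  pos_idx <- rep(seq_len(w), each = length(windows))
  vals <- ifelse(is.na(base_idx), 0, logodds[cbind(pos_idx, base_idx)])
  rowSums(matrix(vals, nrow = length(windows)))
}

#' Locate the best-scoring branch-point placement in an intron
#'
#' Scans a branch-site PWM across a window near the intron's 3' end. A
#' placement is indexed by the offset of its 3'-most base relative to the
#' intron end: offset `-8` puts the last base of the branch window 8 nt
#' upstream of the final intron base. The default search range `-40..-8`
#' covers the region where U12 branch points concentrate; a placement is
#' feasible only if the whole window fits inside the intron, so introns
#' shorter than `width + |max(search_window)|` have no feasible placement
#' and get a `-Inf` sentinel score (they can never be called U12).
#'
#' @param pwm_branch Branch-site `splice_pwm`.
#' @param intron_sequence Single intron sequence (transcript orientation).
#' @param search_window Integer range of end offsets searched
#'   (default `c(-40, -8)`).
#' @return A list with `offset` (end offset of the best placement, ties
#'   broken toward the 3' end; `NA` if infeasible) and `score` (`-Inf` if
#'   infeasible).
#' @export
locate_branch_point <- function(pwm_branch, intron_sequence,
                                search_window = c(-40L, -8L)) {
  stopifnot(length(intron_sequence) == 1)
  len <- nchar(intron_sequence)
  w <- pwm_branch$width
  offsets <- seq(search_window[1], search_window[2])
  # window covers positions (len + offset - w + 1) .. (len + offset), 1-based
  offsets <- offsets[len + offsets - w + 1 >= 1 & len + offsets <= len]
  if (length(offsets) == 0) {
    return(list(offset = NA_integer_, score = -Inf))
  }
  starts <- len + offsets - w + 1
  windows <- substring(toupper(intron_sequence), starts, starts + w - 1)
  scores <- score_windows_fast(pwm_branch$logodds, windows)
  best <- max(scores)
  # tie -> placement closest to the 3' end (largest offset)
  best_offset <- max(offsets[scores == best])
  list(offset = as.integer(best_offset), score = best)
}

#' Default PWM set built from curated consensus-derived training sites
#'
#' Returns the six matrices used for classification: U12-ATAC and U12-GTAG
#' donor and branch sites, and U2 donor and acceptor sites. The training
#' alignments are small hand-curated sets encoding the canonical motifs
#' (U12 donor `RTATCCTT`, U12 branch `TTCCTTRAC`, U2 donor `GTAAGT`, U2
#' polypyrimidine tract + `YAG` acceptor); they ship with the package so the
#' classifier is usable and testable without any external motif database.
#' Users with their own site alignments should call [build_pwm()] directly.
#'
#' @param pseudocount,background Passed to [build_pwm()].
#' @return Named list of `splice_pwm` objects: `donor_u12_atac`,
#'   `branch_u12_atac`, `donor_u12_gtag`, `branch_u12_gtag`, `donor_u2`,
#'   `acceptor_u2`.
#' @export
default_pwm_set <- function(pseudocount = 1, background = rep(0.25, 4)) {
  tr <- training_sites()
  list(
    donor_u12_atac = build_pwm(tr$donor_u12_atac, "donor", "U12-ATAC",
      pseudocount, background),
    branch_u12_atac = build_pwm(tr$branch_u12, "branch", "U12-ATAC",
      pseudocount, background),
    donor_u12_gtag = build_pwm(tr$donor_u12_gtag, "donor", "U12-GTAG",
      pseudocount, background),
    branch_u12_gtag = build_pwm(tr$branch_u12, "branch", "U12-GTAG",
      pseudocount, background),
    donor_u2 = build_pwm(tr$donor_u2, "donor", "U2", pseudocount, background),
    acceptor_u2 = build_pwm(tr$acceptor_u2, "acceptor", "U2",
      pseudocount, background)
  )
}

# Hand-curated training alignments. Donor windows are the first 12 intronic
# nt; branch windows are 9 nt; U2 acceptor windows are the last 14 intronic
# nt. Highly conserved positions are near-invariant across the set, weak
# positions vary.
training_sites <- function() {
  list(
    # U12 donors: the intronic +1..+8 block (RTATCCTT) is nearly invariant
    # in real minor introns; only +9..+12 vary.
    donor_u12_gtag = c(
      "GTATCCTTTACT", "GTATCCTTAACT", "GTATCCTTTGAG", "GTATCCTTCACT",
      "GTATCCTTTACA", "GTATCCTTGATT", "GTATCCTTTCCT", "GTATCCTTTACT",
      "GTATCCTTAGCT", "GTATCCTTTTCT", "GTATCCTTTAGT", "GTATCCTTCGCT",
      "GTATCCTTGACT", "GTATCCTTATAC", "GTATCCTTCACT", "GTATCCTTTACG"
    ),
    donor_u12_atac = c(
      "ATATCCTTTACT", "ATATCCTTAACT", "ATATCCTTTGAG", "ATATCCTTCACT",
      "ATATCCTTTACA", "ATATCCTTGATT", "ATATCCTTTCCT", "ATATCCTTTACT",
      "ATATCCTTAGCT", "ATATCCTTTTCT", "ATATCCTTTAGT", "ATATCCTTCGCT",
      "ATATCCTTGACT", "ATATCCTTATAC", "ATATCCTTCACT", "ATATCCTTTACG"
    ),
    # U12 branch point: TTCCTTRAC with the branch adenosine invariant
    branch_u12 = c(
      "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC",
      "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC",
      "TTCCTTGAC", "TTCCTTGAC", "TTCCTTGAC", "TTCCTTGAC",
      "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC", "TTCCTTAAC"
    ),
    # U2 donors: GT invariant, AAGT core moderately conserved, tail diffuse
    donor_u2 = c(
      "GTAAGTATGTGT", "GTAAGTCTTAAC", "GTGAGTATCAGT", "GTAAGAATTCCC",
      "GTAAGTGCATGA", "GTATGTTTAGGA", "GTAAGTACTGAC", "GTGAGTGGGCTT",
      "GTAAGCAGTCAT", "GTAAGTTAGTGA", "GTCAGTACGGTT", "GTAAGTGTCCAA"
    ),
    # U2 acceptors: the polypyrimidine tract is genuinely low-information
    # (every base occurs at every tract position), only the terminal YAG is
    # strongly conserved
    acceptor_u2 = c(
      "TTTTTCTTTTCAAG", "TCTTTTTTCTGCAG", "TTTTCTTTTTACAG", "CTTTTCCTTCTTAG",
      "TATCTTTCCTTCAG", "TTGTTTCTCTGTAG", "TCTCTATTGTCCAG", "GTTTCCTTTCATAG",
      "CTTTGTTCTCTCAG", "TTCTTTTGCTACAG", "TTTATCTCTTGTAG", "TGTCTTCTATTAAG",
      "TGTTTTATTTCTAG", "TTTCATTTTCGCAG", "CTATTGTTGTACAG", "TTATTTGCTCTTAG",
      "ATTGTCTTCATCAG", "TTTCTGTTTATTAG", "TCTTTATCTTGGAG", "GTTTTCATCTTCAG",
      "TTGATTTCTCCAAG", "TATTCTTTTGTTAG", "CTTCTATTTCACAG", "TTTGTTCTTATCAG"
    )
  )
}

#' Classify one intron as U2 or U12 by PWM scoring
#'
#' Composite scores: for each U12 subtype, donor score plus the best branch
#' score (see [locate_branch_point()]); for U2, donor plus acceptor score.
#' The intron is called `U12-<subtype>` when the best U12 composite exceeds
#' the U2 composite by more than `margin_threshold` (log2 units) AND its
#' terminal dinucleotides match the winning subtype (`AT...AC` for U12-ATAC,
#' `GT...AG` for U12-GTAG); otherwise `U2`. When both subtypes tie on the
#' composite, the one whose termini match wins; a residual tie goes to
#' U12-GTAG (the commoner subtype).
#'
#' Sequences with more than 50% `N` are classified `U2` with a warning;
#' introns too short to hold the donor + acceptor windows score `-Inf` and
#' fall through to `U2`.
#'
#' @param sequence A single intron sequence (transcript orientation).
#' @param pwms PWM set as from [default_pwm_set()].
#' @param margin_threshold Minimum log2 advantage of the U12 composite over
#'   the U2 composite required for a U12 call (default 15 bits, roughly half
#'   the composite advantage of a genuine U12 site; large enough that
#'   canonical terminal dinucleotides alone cannot force a U12 call — see
#'   the methods vignette for the calibration).
#' @param branch_search End-offset range scanned for the branch point.
#' @param intron_id Optional id carried into the output.
#' @return A one-row tibble: `intron_id`, per-site scores
#'   (`score_donor_u12_atac`, `score_branch_u12_atac`, `score_donor_u12_gtag`,
#'   `score_branch_u12_gtag`, `score_donor_u2`, `score_acceptor_u2`),
#'   `branch_pos` (end offset of the winning subtype's branch placement),
#'   `margin` (best U12 composite minus U2 composite), `assigned_class`.
#' @export
classify_intron <- function(sequence, pwms, margin_threshold = 15,
                            branch_search = c(-40L, -8L),
                            intron_id = NA_character_) {
  stopifnot(length(sequence) == 1)
  seq_up <- toupper(sequence)
  len <- nchar(seq_up)

  n_frac <- stringr::str_count(seq_up, "N") / max(len, 1)
  if (n_frac > 0.5) {
    warn(paste0(
      "intron ", intron_id %|na|% "<unnamed>",
      " has >50% N; classified U2"
    ))
    return(classification_row(intron_id,
      scores = rep(NA_real_, 6), branch_pos = NA_integer_,
      margin = NA_real_, assigned_class = "U2"
    ))
  }

  dw <- pwms$donor_u2$width
  aw <- pwms$acceptor_u2$width
  too_short <- len < max(dw, aw) + 4

  donor_win <- if (len >= dw) substr(seq_up, 1, dw) else NA_character_
  accept_win <- if (len >= aw) substr(seq_up, len - aw + 1, len) else NA_character_

  sc_donor <- function(pwm) {
    if (is.na(donor_win)) -Inf else score_window(pwm, donor_win)
  }
  s_d_atac <- sc_donor(pwms$donor_u12_atac)
  s_d_gtag <- sc_donor(pwms$donor_u12_gtag)
  s_d_u2 <- sc_donor(pwms$donor_u2)
  s_a_u2 <- if (is.na(accept_win)) -Inf else score_window(pwms$acceptor_u2, accept_win)

  bp_atac <- locate_branch_point(pwms$branch_u12_atac, seq_up, branch_search)
  bp_gtag <- locate_branch_point(pwms$branch_u12_gtag, seq_up, branch_search)

  comp_atac <- s_d_atac + bp_atac$score
  comp_gtag <- s_d_gtag + bp_gtag$score
  comp_u2 <- s_d_u2 + s_a_u2

  din <- c(substr(seq_up, 1, 2), substr(seq_up, len - 1, len))
  atac_ok <- din[1] == "AT" && din[2] == "AC"
  gtag_ok <- din[1] == "GT" && din[2] == "AG"

  if (comp_atac > comp_gtag) {
    best <- "U12-ATAC"
  } else if (comp_gtag > comp_atac) {
    best <- "U12-GTAG"
  } else if (atac_ok && !gtag_ok) {
    best <- "U12-ATAC"
  } else {
    best <- "U12-GTAG"
  }
  best_comp <- max(comp_atac, comp_gtag)
  margin <- best_comp - comp_u2
  if (!is.finite(best_comp) && !is.finite(comp_u2)) margin <- -Inf

  termini_ok <- if (best == "U12-ATAC") atac_ok else gtag_ok
  assigned <- if (is.finite(margin) && margin > margin_threshold &&
    termini_ok && !too_short) best else "U2"
  branch_pos <- if (best == "U12-ATAC") bp_atac$offset else bp_gtag$offset

  classification_row(intron_id,
    scores = c(s_d_atac, bp_atac$score, s_d_gtag, bp_gtag$score, s_d_u2, s_a_u2),
    branch_pos = branch_pos, margin = margin, assigned_class = assigned
  )
}

classification_row <- function(intron_id, scores, branch_pos, margin,
                               assigned_class) {
  tibble(
    intron_id = intron_id,
    score_donor_u12_atac = scores[1], score_branch_u12_atac = scores[2],
    score_donor_u12_gtag = scores[3], score_branch_u12_gtag = scores[4],
    score_donor_u2 = scores[5], score_acceptor_u2 = scores[6],
    branch_pos = as.integer(branch_pos), margin = margin,
    assigned_class = assigned_class
  )
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' Classify every intron of a catalog
#'
#' Applies [classify_intron()] to the gene-level deduplicated introns of a
#' catalog and tallies the classes.
#'
#' @param catalog Intron catalog tibble ([extract_introns()] output; it is
#'   deduplicated per gene with [dedup_introns()] before classification).
#' @inheritParams classify_intron
#' @return A list with `classifications` (one row per deduplicated intron,
#'   classification columns joined to `intron_id`, `gene_id`, `rank`) and
#'   `summary` (tibble of counts per `assigned_class`).
#' @export
classify_catalog <- function(catalog, pwms, margin_threshold = 15,
                             branch_search = c(-40L, -8L)) {
  dedup <- dedup_introns(catalog)
  if (nrow(dedup) == 0) {
    empty <- classification_row("x", rep(NA_real_, 6), NA_integer_,
      NA_real_, "U2")[0, ]
    empty <- dplyr::bind_cols(
      empty["intron_id"],
      tibble(gene_id = character(0), rank = integer(0)),
      empty[setdiff(names(empty), "intron_id")]
    )
    return(list(
      classifications = empty,
      summary = tibble(assigned_class = character(0), n = integer(0))
    ))
  }
  rows <- purrr::pmap(
    list(dedup$sequence, dedup$intron_id),
    function(s, id) classify_intron(s, pwms, margin_threshold, branch_search, id)
  )
  cls <- dplyr::bind_rows(rows) %>%
    left_join(
      dedup %>% select("intron_id", "gene_id", "rank"),
      by = "intron_id"
    ) %>%
    select("intron_id", "gene_id", "rank", dplyr::everything())
  summ <- cls %>% count(.data$assigned_class)
  list(classifications = cls, summary = summ)
}

#' Write / read PWMs in a MEME-motif-style text format
#'
#' One motif block per PWM: a header with kind/subtype/width/n_training, a
#' background line, and the probability matrix (rows = positions, columns =
#' A C G T). The pseudocount is recorded so re-read matrices rebuild the
#' same log-odds.
#'
#' @param pwms Named list of `splice_pwm` objects.
#' @param path Output/input file path.
#' @export
write_pwm_meme <- function(pwms, path) {
  lines <- c("MEME-like splice PWM set version 1", "")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    lines <- c(
      lines,
      sprintf("MOTIF %s %s %s", nm, p$site_kind, p$subtype),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %d pseudocount= %.17g",
        p$width, p$n_training, p$pseudocount
      ),
      sprintf("background: %s", paste(sprintf("%.17g", p$background), collapse = " ")),
      apply(p$probs, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_meme
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF ", lines)
  pwms <- list()
  for (i in motif_at) {
    hdr <- strsplit(lines[i], " +")[[1]]
    nm <- hdr[2]; kind <- hdr[3]; subtype <- hdr[4]
    meta <- lines[i + 1]
    width <- as.integer(sub(".* w= (\\d+).*", "\\1", meta))
    nsites <- as.integer(sub(".* nsites= (\\d+).*", "\\1", meta))
    pc <- as.numeric(sub(".* pseudocount= ([0-9.eE+-]+).*", "\\1", meta))
    bg <- as.numeric(strsplit(sub("^background: ", "", lines[i + 2]), " +")[[1]])
    probs <- do.call(rbind, lapply(
      lines[(i + 3):(i + 2 + width)],
      function(l) as.numeric(strsplit(trimws(l), " +")[[1]])
    ))
    colnames(probs) <- DNA_BASES
    bg <- setNames(bg, DNA_BASES)
    pwms[[nm]] <- structure(
      list(
        site_kind = kind, subtype = subtype, width = width,
        logodds = log2(sweep(probs, 2, bg, `/`)), probs = probs,
        background = bg, pseudocount = pc, n_training = nsites
      ),
      class = "splice_pwm"
    )
  }
  pwms
}

#' Write classification results to TSV
#' @param classifications Classification tibble from [classify_catalog()].
#' @param path Output path.
#' @export
write_classification_tsv <- function(classifications, path) {
  readr::write_tsv(classifications, path)
  invisible(path)
}
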