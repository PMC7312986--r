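# Shared fixtures: one PWM set for the whole suite (construction is cheap
# but repeated everywhere), plus an independent reverse-complement oracle
# used to check strand handling without going through Biostrings.

PWMS <- default_pwm_set()

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
    collapse = ""
  )
}

# A 30-nt toy chromosome with distinguishable ends, used across the
# intron-extraction tests.
TOY_REF <- "ACGTTGCAAGCTTGCAACGGATCCGGTTAA"

toy_annotation <- function(strand) {
  tibble::tibble(
    chrom = "chrT",
    start = c(1L, 21L), end = c(10L, 30L),
    strand = strand, gene_id = "g1", transcript_id = "t1"
  )
}

# Deterministic random event-count table for the splicing tests: PSI values
# are exact (counts chosen by hand), not sampled.
events_from_psi <- function(psi_wt, psi_mu, depth = 100, event_id = "e1",
                            event_class = "IR", gene_id = "g1",
                            intron_id = NA_character_) {
  stopifnot(length(psi_wt) >= 1, length(psi_mu) >= 1)
  tibble::tibble(
    event_id = event_id, event_class = event_class, gene_id = gene_id,
    intron_id = intron_id,
    sample = c(
      paste0("WT_", seq_along(psi_wt)),
      paste0("MU_", seq_along(psi_mu))
    ),
    group = rep(c("WT", "MU"), c(length(psi_wt), length(psi_mu))),
    inclusion_reads = as.integer(round(depth * c(psi_wt, psi_mu) / 100)),
    exclusion_reads = as.integer(depth -
      round(depth * c(psi_wt, psi_mu) / 100))
  )
}
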