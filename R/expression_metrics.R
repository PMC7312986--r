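#' Comparative-CT (2^-ddCT) fold changes
#'
#' Relative qPCR quantification. Technical replicates (rows sharing
#' `sample_id` and `gene_id`) are averaged at the CT level. Then
#' `dCT_s = CT_target,s - CT_ref,s`, the calibrator is the sample with the
#' HIGHEST dCT (lowest target expression), `ddCT_s = dCT_s - max(dCT)` and
#' `fold_s = 2^-ddCT_s`, so the calibrator sample has fold exactly 1 and a
#' one-cycle dCT advantage doubles the fold.
#'
#' @param table Tibble with columns `sample_id`, `gene_id`, `ct` (and
#'   optionally `group`, carried through).
#' @param target_gene Gene of interest.
#' @param reference_gene Endogenous control gene (e.g. `"H2afz"`).
#' @return Tibble with one row per sample: `sample_id` (and `group` if
#'   present), `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' tab <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   gene_id = rep(c("Pole2", "H2afz"), 2),
#'   ct = c(25, 20, 24, 20)
#' )
#' delta_delta_ct(tab, "Pole2", "H2afz") # folds 1 and 2
#' @export
delta_delta_ct <- function(table, target_gene, reference_gene) {
  if (any(table$ct <= 0)) {
    abort("CT values must be positive")
  }
  avg <- table %>%
    group_by(across(dplyr::any_of(c("sample_id", "group", "gene_id")))) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")

  samples <- unique(avg$sample_id)
  get_ct <- function(gene) {
    sub <- avg %>% filter(.data$gene_id == gene)
    missing <- setdiff(samples, sub$sample_id)
    if (length(missing) > 0) {
      abort(paste0(
        "missing CT for gene ", gene, " in sample(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    sub
  }
  tgt <- get_ct(target_gene)
  ref <- get_ct(reference_gene)

  out <- tgt %>%
    select(-"gene_id") %>%
    rename(ct_target = "ct") %>%
    left_join(
      ref %>% select("sample_id", ct_ref = "ct"),
      by = "sample_id"
    ) %>%
    mutate(
      delta_ct = .data$ct_target - .data$ct_ref,
      delta_delta_ct = .data$delta_ct - max(.data$delta_ct),
      fold = 2^(-.data$delta_delta_ct)
    ) %>%
    select(-"ct_target", -"ct_ref")
  out
}

#' Fraction of a gene subset expressed per stage
#'
#' For each column (stage) of an expression matrix, the fraction of the
#' subset genes whose value exceeds `threshold`.
#'
#' @param expression_matrix Numeric matrix, rows = genes (rownames
#'   required), columns = stages.
#' @param gene_subset Character vector of genes (must be a subset of the
#'   matrix rownames; non-empty).
#' @param threshold Expression value a gene must exceed to count as
#'   expressed (default 0).
#' @return Tibble `stage`, `fraction` (in `[0, 1]`).
#' @export
expressed_fraction <- function(expression_matrix, gene_subset, threshold = 0) {
  if (length(gene_subset) == 0) {
    abort("gene_subset must be non-empty")
  }
  missing <- setdiff(gene_subset, rownames(expression_matrix))
  if (length(missing) > 0) {
    abort(paste0(
      "genes absent from the matrix: ", paste(missing, collapse = ", ")
    ))
  }
  sub <- expression_matrix[gene_subset, , drop = FALSE]
  tibble(
    stage = colnames(sub) %||% as.character(seq_len(ncol(sub))),
    fraction = unname(colMeans(sub > threshold))
  )
}
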