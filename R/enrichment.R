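#' Exact binomial enrichment of a count against an expected proportion
#'
#' Upper-tail exact binomial test of `observed` successes in `total` trials
#' against the null proportion `expected_fraction`, with fold enrichment
#' `observed_fraction / expected_fraction`.
#'
#' @param observed,total Non-negative integers, `observed <= total`.
#' @param expected_fraction Null proportion in `(0, 1)`.
#' @return An `enrichment_result` object (see [tidy.enrichment_result()]).
#' @export
enrichment_binomial <- function(observed, total, expected_fraction) {
  stopifnot(observed >= 0, total >= observed)
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    abort("expected_fraction must be strictly between 0 and 1")
  }
  observed_fraction <- observed / total
  res <- structure(
    list(
      observed = as.integer(observed), total = as.integer(total),
      observed_fraction = observed_fraction,
      expected_fraction = expected_fraction,
      fold = observed_fraction / expected_fraction,
      p_value = pbinom(observed - 1, total, expected_fraction,
        lower.tail = FALSE)
    ),
    class = "enrichment_result"
  )
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "U12 enrichment: %d/%d (%.2f%%) vs %.4f%% expected; fold %.1f, p = %.3g\n",
    x$observed, x$total, 100 * x$observed_fraction,
    100 * x$expected_fraction, x$fold, x$p_value
  ))
  invisible(x)
}

#' Tidy an enrichment result
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with the observed/total counts, fractions, fold
#'   and exact binomial upper-tail p-value.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    observed = x$observed, total = x$total,
    observed_fraction = x$observed_fraction,
    expected_fraction = x$expected_fraction,
    fold = x$fold, p_value = x$p_value
  )
}

#' @export
glance.enrichment_result <- function(x, ...) tidy(x)

#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(
    what = factor(c("observed", "expected"), c("observed", "expected")),
    fraction = 100 * c(object$observed_fraction, object$expected_fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(
      y = "% U12 among events", x = NULL,
      title = sprintf(
        "%d/%d U12, fold %.1f, p = %.2g",
        object$observed, object$total, object$fold, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' U12 enrichment among upregulated intron-retention events
#'
#' Counts how many of the IR events called up in the mutant fall in
#' U12-classified introns and tests that count against the expected U12
#' proportion with an exact binomial upper-tail test. With the counts of
#' the motivating study (53 U12 among 710 upregulated IR events against an
#' expected genome-wide fraction of 0.04%) this reports an observed
#' fraction of ~7.5% and a vanishing p-value.
#'
#' @param calls Output of [call_differential()]; only rows with
#'   `event_class == "IR"` and `call == "up_in_MU"` are used.
#' @param classifications Classification tibble (from
#'   [classify_catalog()]`$classifications`) with `intron_id` and
#'   `assigned_class`.
#' @param expected_fraction Null U12 proportion (default `4e-4`, the
#'   genome-wide proportion of U12 introns; for synthetic catalogs pass the
#'   realized catalog fraction instead).
#' @return An `enrichment_result`.
#' @export
u12_ir_enrichment <- function(calls, classifications, expected_fraction = 4e-4) {
  ir_up <- calls %>%
    filter(.data$event_class == "IR", .data$call == "up_in_MU")
  unmapped <- setdiff(ir_up$intron_id, classifications$intron_id)
  if (length(unmapped) > 0) {
    abort(paste0(
      "IR events with unclassified introns: ",
      paste(ir_up$event_id[ir_up$intron_id %in% unmapped], collapse = ", ")
    ))
  }
  joined <- ir_up %>%
    left_join(
      classifications %>% select("intron_id", "assigned_class"),
      by = "intron_id"
    )
  enrichment_binomial(
    observed = sum(startsWith(joined$assigned_class, "U12")),
    total = nrow(joined),
    expected_fraction = expected_fraction
  )
}

#' Rank adjacency of affected U2 introns to U12 introns in the same gene
#'
#' For each affected U2 intron (an upregulated IR event on a U2-classified
#' intron inside a U12-containing gene), computes the rank distance to the
#' nearest U12 intron of the gene. Distance 1 means the U2 intron lies
#' immediately upstream or downstream of a U12 intron.
#'
#' @param u2_intron_ids Character vector of affected U2 `intron_id`s.
#' @param catalog Gene-level intron catalog (ranks as in
#'   [dedup_introns()]).
#' @param classifications Classification tibble with `intron_id`,
#'   `assigned_class`.
#' @return A list with `distances` (tibble `intron_id`, `distance`),
#'   `histogram` (tibble `distance`, `n`), `fraction_at_distance_1`, and
#'   `n_excluded` (events in genes without any U12 intron, dropped with a
#'   warning).
#' @export
adjacency_to_u12 <- function(u2_intron_ids, catalog, classifications) {
  u12_ids <- classifications$intron_id[
    startsWith(classifications$assigned_class, "U12")
  ]
  dist <- vapply(
    u2_intron_ids,
    function(id) intron_rank_distance(catalog, id, u12_ids),
    integer(1), USE.NAMES = FALSE
  )
  excluded <- sum(is.na(dist))
  if (excluded > 0) {
    warn(paste0(
      excluded, " event(s) lie in genes with no U12 intron; excluded"
    ))
  }
  dtab <- tibble(intron_id = u2_intron_ids, distance = dist) %>%
    filter(!is.na(.data$distance))
  hist <- dtab %>% count(.data$distance)
  list(
    distances = dtab,
    histogram = hist,
    fraction_at_distance_1 =
      if (nrow(dtab) > 0) mean(dtab$distance == 1) else NA_real_,
    n_excluded = excluded
  )
}

#' Plot the adjacency distance histogram
#' @param adjacency Output of [adjacency_to_u12()].
#' @return A ggplot object.
#' @export
plot_adjacency <- function(adjacency) {
  ggplot2::ggplot(
    adjacency$histogram,
    ggplot2::aes(x = factor(.data$distance), y = .data$n)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "rank distance to nearest U12 intron", y = "affected U2 introns",
      title = sprintf(
        "%.0f%% at distance 1", 100 * adjacency$fraction_at_distance_1
      )
    ) +
    ggplot2::theme_minimal()
}

#' Two-proportion z-test (pooled)
#'
#' Pooled-proportion z statistic for `k1/n1` vs `k2/n2` with a two-sided
#' normal p-value. When the pooled proportion is 0 or 1 the statistic is
#' undefined; `z = NA`, `p = 1` and `degenerate = TRUE` are returned.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return A `prop_ztest` object with elements `k1 n1 k2 n2 p1 p2 z p_value
#'   degenerate`.
#' @examples
#' two_proportion_ztest(121, 197, 5, 129) # the mRNA-rescue comparison
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    z <- NA_real_
    p <- 1
    degenerate <- TRUE
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    z <- (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
    degenerate <- FALSE
  }
  structure(
    list(
      k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
      z = z, p_value = p, degenerate = degenerate
    ),
    class = "prop_ztest"
  )
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat(sprintf(
    "two-proportion z-test: %d/%d (%.1f%%) vs %d/%d (%.1f%%), z = %.3f, p = %.3g\n",
    x$k1, x$n1, 100 * x$p1, x$k2, x$n2, 100 * x$p2, x$z, x$p_value
  ))
  invisible(x)
}

#' Tidy a two-proportion z-test
#' @param x A `prop_ztest`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.prop_ztest <- function(x, ...) {
  tibble(
    k1 = x$k1, n1 = x$n1, k2 = x$k2, n2 = x$n2,
    estimate1 = x$p1, estimate2 = x$p2,
    statistic = x$z, p_value = x$p_value, degenerate = x$degenerate
  )
}

#' @export
glance.prop_ztest <- function(x, ...) tidy(x)

#' Overlap summary of two identifier sets
#'
#' Counts the intersection and the mutual coverage percentages of two sets
#' (e.g. differentially expressed genes vs genes with differential isoform
#' usage). Comparing a coverage percentage between two contexts is done
#' with [two_proportion_ztest()] on the underlying counts.
#'
#' @param set_a,set_b Character vectors of identifiers (duplicates are
#'   dropped).
#' @return Tibble with `n_a`, `n_b`, `n_both`, `pct_a_in_b`, `pct_b_in_a`.
#' @export
set_overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  both <- length(intersect(a, b))
  tibble(
    n_a = length(a), n_b = length(b), n_both = both,
    pct_a_in_b = if (length(a) > 0) 100 * both / length(a) else NA_real_,
    pct_b_in_a = if (length(b) > 0) 100 * both / length(b) else NA_real_
  )
}

#' Consensus differential-expression intersection of two result tables
#'
#' A gene is accepted only when BOTH analyses call it significant
#' (adjusted p below `alpha`) AND agree on the direction of change — the
#' conservative consensus rule for combining two DE programs. Genes present
#' in only one table are treated as not significant in the other.
#'
#' @param results_a,results_b Tibbles with columns `gene_id`, `log_fc`,
#'   `adjusted_p`.
#' @param alpha Significance cutoff on the adjusted p-value (default 0.01).
#' @return Character vector of consensus gene ids (sorted).
#' @export
consensus_de_intersection <- function(results_a, results_b, alpha = 0.01) {
  joined <- inner_join(
    results_a %>% select("gene_id", "log_fc", "adjusted_p"),
    results_b %>% select("gene_id", "log_fc", "adjusted_p"),
    by = "gene_id", suffix = c("_a", "_b")
  )
  hits <- joined %>%
    filter(
      .data$adjusted_p_a < alpha,
      .data$adjusted_p_b < alpha,
      sign(.data$log_fc_a) == sign(.data$log_fc_b),
      sign(.data$log_fc_a) != 0
    )
  sort(hits$gene_id)
}

#' Per-class U12-gene enrichment with BH correction
#'
#' For each event class, tests whether events called in that class fall in
#' U12-intron-containing genes more often than expected, then adjusts the
#' binomial p-values across classes with Benjamini-Hochberg.
#'
#' @param calls Output of [call_differential()] (called events only are
#'   used).
#' @param u12_gene_ids Character vector of genes containing a U12 intron.
#' @param expected_fraction Null proportion of events expected to fall in
#'   U12-containing genes.
#' @return Tibble per event class: `event_class`, `observed`, `total`,
#'   `observed_fraction`, `fold`, `p_value`, `p_adjusted`.
#' @export
per_class_u12_enrichment <- function(calls, u12_gene_ids, expected_fraction) {
  called <- calls %>% filter(.data$call %in% c("up_in_MU", "down_in_MU"))
  res <- called %>%
    group_by(.data$event_class) %>%
    summarise(
      observed = sum(.data$gene_id %in% u12_gene_ids),
      total = n(), .groups = "drop"
    ) %>%
    mutate(
      observed_fraction = .data$observed / .data$total,
      fold = .data$observed_fraction / expected_fraction,
      p_value = pbinom(.data$observed - 1, .data$total, expected_fraction,
        lower.tail = FALSE)
    )
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}
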