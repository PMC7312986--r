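#' Percent spliced-in from inclusion/exclusion read counts
#'
#' `PSI = 100 * inclusion / (inclusion + exclusion)`. A sample with zero
#' reads of either kind has undefined PSI (`NA`); the event is handled as
#' low-coverage downstream, no error is raised.
#'
#' @param inclusion,exclusion Non-negative integer vectors (recycled to a
#'   common length).
#' @return Numeric vector of PSI values in `[0, 100]` (`NA` where both
#'   counts are zero).
#' @examples
#' compute_psi(8, 2) # 80
#' @export
compute_psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0 | exclusion < 0)) {
    abort("read counts must be non-negative")
  }
  total <- inclusion + exclusion
  ifelse(total > 0, 100 * inclusion / total, NA_real_)
}

#' Per-event read-coverage filter
#'
#' An event passes when `inclusion + exclusion >= min_reads` in EVERY
#' sample.
#'
#' @param events Long-format event-count tibble (columns `event_id`,
#'   `sample`, `inclusion_reads`, `exclusion_reads`).
#' @param min_reads Minimum total reads per sample (default 10).
#' @return Tibble `event_id`, `passed_coverage`.
#' @export
coverage_filter <- function(events, min_reads = 10) {
  events %>%
    group_by(.data$event_id) %>%
    summarise(
      passed_coverage =
        all(.data$inclusion_reads + .data$exclusion_reads >= min_reads),
      .groups = "drop"
    )
}

#' Call differential splicing events by delta-PSI
#'
#' Computes per-sample PSI, unweighted group mean PSI for the wild-type
#' (`WT`) and mutant (`MU`) groups, and `delta_psi = mean(MU) - mean(WT)`.
#' Events passing the coverage filter are called `up_in_MU` when
#' `delta_psi > threshold_percent` and `down_in_MU` when
#' `delta_psi < -threshold_percent` (strict inequalities: an event at
#' exactly the threshold is `unchanged`). Low-coverage events are never
#' called.
#'
#' @param events Long-format tibble with columns `event_id`, `event_class`,
#'   `gene_id`, `intron_id`, `sample`, `group` (`"WT"`/`"MU"`),
#'   `inclusion_reads`, `exclusion_reads`.
#' @param threshold_percent Absolute delta-PSI that must be exceeded
#'   (default 10).
#' @param min_reads Coverage filter threshold, see [coverage_filter()].
#' @return Tibble with one row per event: `event_id`, `event_class`,
#'   `gene_id`, `intron_id`, `mean_psi_wt`, `mean_psi_mu`, `delta_psi`,
#'   `passed_coverage`, `call` in
#'   `{up_in_MU, down_in_MU, unchanged, low_coverage}`.
#' @export
call_differential <- function(events, threshold_percent = 10, min_reads = 10) {
  req <- c(
    "event_id", "event_class", "gene_id", "intron_id", "sample", "group",
    "inclusion_reads", "exclusion_reads"
  )
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("WT", "MU") %in% events$group)) {
    absent <- setdiff(c("WT", "MU"), events$group)
    abort(paste0("no samples in group ", paste(absent, collapse = ", ")))
  }

  psi <- events %>%
    mutate(psi = compute_psi(.data$inclusion_reads, .data$exclusion_reads))

  calls <- psi %>%
    group_by(.data$event_id, .data$event_class, .data$gene_id, .data$intron_id) %>%
    summarise(
      mean_psi_wt = mean(.data$psi[.data$group == "WT"]),
      mean_psi_mu = mean(.data$psi[.data$group == "MU"]),
      passed_coverage =
        all(.data$inclusion_reads + .data$exclusion_reads >= min_reads) &&
          !anyNA(.data$psi),
      .groups = "drop"
    ) %>%
    mutate(
      delta_psi = .data$mean_psi_mu - .data$mean_psi_wt,
      call = dplyr::case_when(
        !passed_coverage ~ "low_coverage",
        delta_psi > threshold_percent ~ "up_in_MU",
        delta_psi < -threshold_percent ~ "down_in_MU",
        TRUE ~ "unchanged"
      )
    ) %>%
    select(
      "event_id", "event_class", "gene_id", "intron_id",
      "mean_psi_wt", "mean_psi_mu", "delta_psi", "passed_coverage", "call"
    )
  calls
}

#' Tally called events per class and direction
#'
#' The analogue of the event-category breakdown figure: for each direction
#' (`up_in_MU`, `down_in_MU`) the count and within-direction percentage of
#' each event class.
#'
#' @param calls Output of [call_differential()].
#' @return Tibble `call`, `event_class`, `n`, `percent` (percentages sum to
#'   100 within each direction).
#' @export
summarize_by_class <- function(calls) {
  called <- calls %>% filter(.data$call %in% c("up_in_MU", "down_in_MU"))
  if (nrow(called) == 0) {
    return(tibble(
      call = character(0), event_class = character(0),
      n = integer(0), percent = numeric(0)
    ))
  }
  called %>%
    count(.data$call, .data$event_class) %>%
    group_by(.data$call) %>%
    mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Read an event-counts table
#'
#' Long-format TSV with columns `event_id`, `event_class`, `gene_id`,
#' `intron_id`, `sample`, `group`, `inclusion_reads`, `exclusion_reads`.
#'
#' @param path TSV file path.
#' @return Tibble in the [call_differential()] input format.
#' @export
read_event_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    event_id = readr::col_character(),
    event_class = readr::col_character(),
    gene_id = readr::col_character(),
    intron_id = readr::col_character(),
    sample = readr::col_character(),
    group = readr::col_character(),
    inclusion_reads = readr::col_integer(),
    exclusion_reads = readr::col_integer()
  ))
}

#' Plot the class-by-direction breakdown of differential events
#' @param class_summary Output of [summarize_by_class()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(class_summary) {
  ggplot2::ggplot(
    class_summary,
    ggplot2::aes(x = .data$event_class, y = .data$percent, fill = .data$call)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "event class", y = "% of called events",
      fill = NULL, title = "Differential splicing events by class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot delta-PSI per event colored by call
#' @param calls Output of [call_differential()].
#' @param threshold_percent Threshold used for the calls (drawn as guides).
#' @return A ggplot object.
#' @export
plot_delta_psi <- function(calls, threshold_percent = 10) {
  ggplot2::ggplot(
    calls %>% filter(.data$passed_coverage),
    ggplot2::aes(x = .data$delta_psi, fill = .data$call)
  ) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(
      xintercept = c(-threshold_percent, threshold_percent),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = expression(Delta * "PSI (MU - WT)"), y = "events") +
    ggplot2::theme_minimal()
}
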