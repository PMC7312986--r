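#' Parental genotype at Zrsr1 (autosomal, imprinted) and Zrsr2 (X-linked)
#'
#' Zrsr1 is autosomal and maternally imprinted: embryos express only the
#' paternal allele. Zrsr2 is X-linked; because X inactivation is imprinted
#' in early preimplantation development (the paternal X is silenced), early
#' embryos express only the maternal Zrsr2 allele. Males carry a single
#' (maternal) Zrsr2 allele.
#'
#' @param sex `"female"` or `"male"`.
#' @param zrsr1 Character vector of 2 alleles in `{WT, mu}`.
#' @param zrsr2 Character vector of 2 alleles for females, 1 for males.
#' @return A `parent_genotype` object.
#' @examples
#' parent_genotype("female", c("WT", "mu"), c("mu", "mu"))
#' @export
parent_genotype <- function(sex, zrsr1, zrsr2) {
  sex <- match.arg(sex, c("female", "male"))
  ok_allele <- function(a) all(a %in% c("WT", "mu"))
  if (length(zrsr1) != 2 || !ok_allele(zrsr1)) {
    abort("zrsr1 must be two alleles in {WT, mu}")
  }
  n2 <- if (sex == "female") 2L else 1L
  if (length(zrsr2) != n2 || !ok_allele(zrsr2)) {
    abort(paste0(
      "zrsr2 must be ", n2, " allele(s) in {WT, mu} for a ", sex
    ))
  }
  structure(
    list(sex = sex, zrsr1 = zrsr1, zrsr2 = zrsr2),
    class = "parent_genotype"
  )
}

#' @export
print.parent_genotype <- function(x, ...) {
  z2 <- if (x$sex == "male") paste0(x$zrsr2, "/y") else paste(x$zrsr2, collapse = "/")
  cat(sprintf(
    "<parent_genotype> %s Zrsr1:%s Zrsr2:%s\n",
    x$sex, paste(x$zrsr1, collapse = "/"), z2
  ))
  invisible(x)
}

#' Parse a genotype string like "Zrsr1:WT/mu Zrsr2:mu/mu sex:F"
#'
#' Males are written with a `y` second allele (`Zrsr2:WT/y sex:M`).
#'
#' @param spec Genotype specification string.
#' @return A `parent_genotype`.
#' @export
parse_genotype <- function(spec) {
  fields <- strsplit(trimws(spec), "\\s+")[[1]]
  kv <- strsplit(fields, ":")
  names(kv) <- tolower(vapply(kv, `[`, "", 1))
  get <- function(key) {
    if (!key %in% names(kv)) abort(paste0("missing field `", key, "` in genotype spec"))
    kv[[key]][2]
  }
  sex <- switch(toupper(get("sex")),
    "F" = "female", "FEMALE" = "female",
    "M" = "male", "MALE" = "male",
    abort("sex must be F or M")
  )
  z1 <- strsplit(get("zrsr1"), "/")[[1]]
  z2 <- strsplit(get("zrsr2"), "/")[[1]]
  if (sex == "male") {
    if (length(z2) == 2 && tolower(z2[2]) == "y") z2 <- z2[1]
  }
  parent_genotype(sex, z1, z2)
}

#' Enumerate offspring of a Zrsr1 x Zrsr2 cross with expression rules
#'
#' Mendelian enumeration: the autosomal Zrsr1 allele segregates
#' independently in each parent; Zrsr2 rides the X, and offspring sex is
#' set by the paternal X/Y gamete (1:1). Expression rules of the early
#' embryo are then applied: `expressed_zrsr1` is always the paternal Zrsr1
#' allele (maternal imprinting) and `expressed_zrsr2_early` is always the
#' maternal Zrsr2 allele (imprinted X inactivation silences the paternal
#' X; a male's single X is maternal anyway). An outcome is viable when at
#' least one expressed allele is wild type.
#'
#' @param mother,father `parent_genotype` objects (mother female, father
#'   male).
#' @return A `cross_result`: list with `outcomes` (tibble of distinct
#'   outcomes with `probability`, expression fields and `viable`) and
#'   `viable_fraction`.
#' @examples
#' m <- parent_genotype("female", c("mu", "mu"), c("mu", "mu"))
#' f <- parent_genotype("male", c("mu", "mu"), "WT")
#' enumerate_offspring(m, f)$viable_fraction # 0: lethal cross
#' @export
enumerate_offspring <- function(mother, father) {
  if (!inherits(mother, "parent_genotype") || mother$sex != "female") {
    abort("`mother` must be a female parent_genotype")
  }
  if (!inherits(father, "parent_genotype") || father$sex != "male") {
    abort("`father` must be a male parent_genotype")
  }

  # maternal gametes: zrsr1 allele x X(zrsr2 allele), each 1/2 x 1/2
  mg <- tidyr::expand_grid(
    zrsr1_maternal = mother$zrsr1,
    zrsr2_maternal = mother$zrsr2
  ) %>% mutate(p_m = 1 / 4)
  # paternal gametes: zrsr1 allele x {X(zrsr2), Y}
  pg <- tidyr::expand_grid(
    zrsr1_paternal = father$zrsr1,
    sex_chrom = c("X", "Y")
  ) %>%
    mutate(
      zrsr2_paternal = if_else(.data$sex_chrom == "X", father$zrsr2, "none"),
      p_p = 1 / 4
    )

  outcomes <- tidyr::expand_grid(mg, pg) %>%
    mutate(
      probability = .data$p_m * .data$p_p,
      sex = if_else(.data$sex_chrom == "X", "female", "male"),
      expressed_zrsr1 = .data$zrsr1_paternal,
      expressed_zrsr2_early = .data$zrsr2_maternal,
      viable = .data$expressed_zrsr1 == "WT" |
        .data$expressed_zrsr2_early == "WT"
    ) %>%
    group_by(
      .data$sex, .data$zrsr1_maternal, .data$zrsr1_paternal,
      .data$zrsr2_maternal, .data$zrsr2_paternal,
      .data$expressed_zrsr1, .data$expressed_zrsr2_early, .data$viable
    ) %>%
    summarise(probability = sum(.data$probability), .groups = "drop") %>%
    arrange(dplyr::desc(.data$probability), .data$sex)

  structure(
    list(
      mother = mother, father = father,
      outcomes = outcomes,
      viable_fraction = sum(outcomes$probability[outcomes$viable])
    ),
    class = "cross_result"
  )
}

#' @export
print.cross_result <- function(x, ...) {
  cat(sprintf(
    "<cross_result> %d distinct outcomes, viable fraction %.3f\n",
    nrow(x$outcomes), x$viable_fraction
  ))
  print(x$outcomes, n = 10)
  invisible(x)
}

#' Tidy a cross result (one row per distinct offspring outcome)
#' @param x A `cross_result`.
#' @param ... Unused.
#' @export
tidy.cross_result <- function(x, ...) x$outcomes

#' One-row summary of a cross
#' @param x A `cross_result`.
#' @param ... Unused.
#' @return Tibble with `n_outcomes`, `viable_fraction`.
#' @export
glance.cross_result <- function(x, ...) {
  tibble(n_outcomes = nrow(x$outcomes), viable_fraction = x$viable_fraction)
}

#' Viability of one offspring outcome
#'
#' An early embryo survives iff it expresses at least one wild-type allele:
#' paternal Zrsr1 WT or maternal Zrsr2 WT.
#'
#' @param expressed_zrsr1 Paternal Zrsr1 allele (`"WT"`/`"mu"`).
#' @param expressed_zrsr2_early Maternal Zrsr2 allele (`"WT"`/`"mu"`).
#' @return Logical vector.
#' @export
is_viable <- function(expressed_zrsr1, expressed_zrsr2_early) {
  expressed_zrsr1 == "WT" | expressed_zrsr2_early == "WT"
}

#' Genotype spectrum of surviving offspring
#'
#' Conditions the enumerated outcome distribution on viability and
#' renormalizes. A fully lethal cross returns an empty spectrum.
#'
#' @param cross A `cross_result` from [enumerate_offspring()].
#' @return Tibble of viable outcomes with renormalized `probability`
#'   (sums to 1), or a zero-row tibble when no outcome is viable.
#' @export
surviving_genotype_spectrum <- function(cross) {
  viable <- cross$outcomes %>% filter(.data$viable)
  if (nrow(viable) == 0) {
    return(viable)
  }
  viable %>% mutate(probability = .data$probability / sum(.data$probability))
}

#' Exact consistency test of observed litter counts against a predicted
#' spectrum
#'
#' Exact multinomial (binomial for two categories) goodness-of-fit test:
#' the p-value is the total probability of outcomes no more probable than
#' the observed one under the predicted category probabilities. Observing
#' any category with predicted probability 0 gives p = 0. For two
#' categories this reduces to the standard two-sided exact binomial test.
#' Category enumeration is exact up to ~1e6 compositions; beyond that a
#' chi-square approximation is used with a warning.
#'
#' @param predicted Named numeric vector of category probabilities (sums
#'   to 1).
#' @param observed Named integer vector of category counts (names must be
#'   a subset of `names(predicted)`, modulo zero-probability violations).
#' @return A `litter_test` object with `p_value`, `n`, `method`.
#' @examples
#' litter_consistency_test(c(A = 0.5, B = 0.5), c(A = 10, B = 0))
#' @export
litter_consistency_test <- function(predicted, observed) {
  stopifnot(abs(sum(predicted) - 1) < 1e-9, all(observed >= 0))
  obs <- setNames(rep(0L, length(predicted)), names(predicted))
  extra <- setdiff(names(observed), names(predicted))
  shared <- intersect(names(observed), names(predicted))
  if (any(observed[extra] > 0) ||
    any(observed[shared] > 0 & predicted[shared] == 0)) {
    # an outcome the model says cannot happen
    return(structure(
      list(p_value = 0, n = sum(observed), method = "structural zero"),
      class = "litter_test"
    ))
  }
  obs[names(observed)] <- as.integer(observed)
  keep <- predicted > 0 | obs > 0
  p <- predicted[keep] / sum(predicted[keep])
  x <- obs[keep]
  n <- sum(x)
  k <- length(p)

  if (n == 0 || k == 1) {
    return(structure(
      list(p_value = 1, n = n, method = "degenerate"),
      class = "litter_test"
    ))
  }

  if (k == 2) {
    p_obs <- dbinom(x[1], n, p[1])
    probs <- dbinom(0:n, n, p[1])
    pval <- sum(probs[probs <= p_obs + 1e-12])
    return(structure(
      list(p_value = min(pval, 1), n = n, method = "exact binomial"),
      class = "litter_test"
    ))
  }

  n_comp <- choose(n + k - 1, k - 1)
  if (n_comp <= 1e6) {
    comps <- compositions(n, k)
    probs <- apply(comps, 1, function(cc) stats::dmultinom(cc, prob = p))
    p_obs <- stats::dmultinom(x, prob = p)
    pval <- sum(probs[probs <= p_obs * (1 + 1e-10)])
    method <- "exact multinomial"
  } else {
    warn("too many compositions for an exact test; using chi-square")
    cs <- suppressWarnings(chisq.test(x, p = p))
    pval <- cs$p.value
    method <- "chi-square approximation"
  }
  structure(
    list(p_value = min(pval, 1), n = n, method = method),
    class = "litter_test"
  )
}

# all compositions of n into k non-negative parts (rows)
compositions <- function(n, k) {
  if (k == 1) {
    return(matrix(n, ncol = 1))
  }
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1))
  }))
}

#' @export
print.litter_test <- function(x, ...) {
  cat(sprintf(
    "litter consistency test (%s): n = %d, p = %.4g\n",
    x$method, x$n, x$p_value
  ))
  invisible(x)
}

#' Tidy a litter consistency test
#' @param x A `litter_test`.
#' @param ... Unused.
#' @export
tidy.litter_test <- function(x, ...) {
  tibble(n = x$n, p_value = x$p_value, method = x$method)
}

#' Plot the outcome spectrum of a cross
#' @param object A `cross_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_result <- function(object, ...) {
  df <- object$outcomes %>%
    mutate(label = paste0(
      .data$sex, " Zrsr1:", .data$zrsr1_maternal, "/", .data$zrsr1_paternal,
      " Zrsr2:", .data$zrsr2_maternal, "/", .data$zrsr2_paternal
    ))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$probability),
      y = .data$probability, fill = .data$viable
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "probability", fill = "viable") +
    ggplot2::theme_minimal()
}
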