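test_that("exact binomial upper tail equals direct summation", {
  withr::with_seed(55, {
    cases <- data.frame(
      total = sample(1:1000, 40, replace = TRUE),
      p0 = runif(40, 0.001, 0.5)
    )
  })
  cases$obs <- with(cases, pmin(total, rpois(40, total * p0)))
  for (i in seq_len(nrow(cases))) {
    res <- enrichment_binomial(cases$obs[i], cases$total[i], cases$p0[i])
    tail_sum <- sum(dbinom(cases$obs[i]:cases$total[i], cases$total[i], cases$p0[i]))
    expect_equal(res$p_value, tail_sum, tolerance = 1e-12)
  }

  # the small worked case: 3/10 against 0.1
  res <- enrichment_binomial(3, 10, 0.1)
  expect_equal(res$p_value, sum(dbinom(3:10, 10, 0.1)))
})

test_that("the reported U12 IR counts give ~7% observed vs 0.04% expected", {
  res <- enrichment_binomial(53, 710, 4e-4)
  expect_equal(100 * res$observed_fraction, 7.464789, tolerance = 1e-6)
  expect_gt(res$fold, 100)
  expect_lt(res$p_value, 1e-20)

  none <- enrichment_binomial(0, 100, 4e-4)
  expect_equal(none$fold, 0)
  expect_equal(none$p_value, 1)

  expect_error(enrichment_binomial(5, 10, 0), "between 0 and 1")
})

test_that("fold enrichment is invariant to scaling the counts", {
  a <- enrichment_binomial(5, 100, 0.01)
  b <- enrichment_binomial(5 * 7, 100 * 7, 0.01)
  expect_equal(a$fold, b$fold)
  expect_equal(tidy(a)$fold, a$fold)
})

test_that("u12_ir_enrichment counts U12 introns among up-called IR events", {
  calls <- tibble::tibble(
    event_id = paste0("e", 1:6),
    event_class = c("IR", "IR", "IR", "IR", "ES", "IR"),
    gene_id = "g", intron_id = paste0("i", 1:6),
    delta_psi = c(30, 30, 30, -30, 30, 30),
    passed_coverage = TRUE,
    call = c("up_in_MU", "up_in_MU", "up_in_MU", "down_in_MU", "up_in_MU", "up_in_MU")
  )
  cls <- tibble::tibble(
    intron_id = paste0("i", 1:6),
    assigned_class = c("U12-GTAG", "U2", "U12-ATAC", "U12-GTAG", "U2", "U2")
  )
  res <- u12_ir_enrichment(calls, cls, expected_fraction = 0.1)
  # events 1,2,3,6 are up IR; 1 and 3 are U12
  expect_equal(res$observed, 2L)
  expect_equal(res$total, 4L)

  expect_error(
    u12_ir_enrichment(calls, cls[1:3, ], expected_fraction = 0.1),
    "unclassified"
  )
})

test_that("adjacency distances match a brute-force pairwise rank scan", {
  # toy gene: U12 at rank 3, affected U2 introns at ranks 2, 4, 6
  cat_tab <- tibble::tibble(
    intron_id = paste0("i", 1:6), gene_id = "gA", rank = 1:6
  )
  cls <- tibble::tibble(
    intron_id = paste0("i", 1:6),
    assigned_class = c("U2", "U2", "U12-GTAG", "U2", "U2", "U2")
  )
  adj <- adjacency_to_u12(c("i2", "i4", "i6"), cat_tab, cls)
  expect_equal(sort(adj$distances$distance), c(1L, 1L, 3L))
  expect_equal(adj$fraction_at_distance_1, 2 / 3)

  all_adjacent <- adjacency_to_u12(c("i2", "i4"), cat_tab, cls)
  expect_equal(all_adjacent$fraction_at_distance_1, 1)

  # random catalogs against an independent pairwise scan
  withr::with_seed(77, {
    for (rep in 1:5) {
      n <- 30
      genes <- sample(paste0("g", 1:5), n, replace = TRUE)
      rcat <- tibble::tibble(
        intron_id = paste0("r", 1:n), gene_id = genes
      ) |>
        dplyr::group_by(gene_id) |>
        dplyr::mutate(rank = dplyr::row_number()) |>
        dplyr::ungroup()
      rcls <- tibble::tibble(
        intron_id = rcat$intron_id,
        assigned_class = sample(c("U2", "U12-GTAG"), n, replace = TRUE, prob = c(0.8, 0.2))
      )
      u2_ids <- rcat$intron_id[rcls$assigned_class == "U2"]
      got <- suppressWarnings(adjacency_to_u12(u2_ids, rcat, rcls))
      # oracle: scan all pairs directly
      oracle <- vapply(u2_ids, function(id) {
        g <- rcat$gene_id[rcat$intron_id == id]
        r <- rcat$rank[rcat$intron_id == id]
        u12_same <- rcat[rcat$gene_id == g &
          rcat$intron_id %in% rcls$intron_id[rcls$assigned_class != "U2"], ]
        if (nrow(u12_same) == 0) NA_integer_ else min(abs(r - u12_same$rank))
      }, integer(1), USE.NAMES = FALSE)
      expect_equal(got$distances$distance, oracle[!is.na(oracle)])
      expect_equal(got$n_excluded, sum(is.na(oracle)))
    }
  })
})

test_that("the rescue comparison is significant and the z-test behaves at the edges", {
  rescue <- two_proportion_ztest(121, 197, 5, 129)
  expect_lt(rescue$p_value, 0.01)
  expect_gt(rescue$z, 0)

  same <- two_proportion_ztest(4, 10, 4, 10)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  degen <- two_proportion_ztest(0, 10, 0, 20)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("z-test agrees with Fisher's exact test on rejection decisions", {
  # moderate effect: both should reject or not reject together at alpha 0.05
  cases <- list(c(3, 10, 7, 10), c(30, 100, 70, 100), c(10, 50, 12, 50))
  for (cs in cases) {
    z <- two_proportion_ztest(cs[1], cs[2], cs[3], cs[4])
    f <- fisher.test(matrix(
      c(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3]),
      nrow = 2
    ))
    # document the (bounded) disagreement between normal and exact p
    expect_lt(abs(z$p_value - f$p.value), 0.2)
    if (min(f$p.value, z$p_value) < 0.04 || max(f$p.value, z$p_value) > 0.06) {
      expect_equal(z$p_value < 0.05, f$p.value < 0.05)
    }
  }
})

test_that("set overlap summaries count intersections exactly", {
  expect_equal(set_overlap_summary(c("a", "b"), c("c"))$n_both, 0L)
  ident <- set_overlap_summary(c("a", "b"), c("b", "a"))
  expect_equal(ident$n_both, 2L)
  expect_equal(ident$pct_a_in_b, 100)

  withr::with_seed(88, {
    for (rep in 1:5) {
      a <- sample(letters, sample(5:20, 1))
      b <- sample(letters, sample(5:20, 1))
      s <- set_overlap_summary(a, b)
      expect_equal(s$n_both, length(intersect(unique(a), unique(b))))
      expect_lte(s$n_both, min(s$n_a, s$n_b))
    }
  })
})

test_that("consensus DE intersection needs both programs and concordant signs", {
  a <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    log_fc = c(2, 1, -1, 1),
    adjusted_p = c(0.005, 0.005, 0.005, 0.02)
  )
  b <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g5"),
    log_fc = c(1.5, -1, -2, 1),
    adjusted_p = c(0.005, 0.005, 0.005, 0.001)
  )
  hits <- consensus_de_intersection(a, b)
  expect_equal(hits, c("g1", "g3")) # g2 discordant, g4 fails in a, g5 only in b

  # symmetry and brute-force oracle on random tables
  withr::with_seed(99, {
    for (rep in 1:5) {
      mk <- function() {
        tibble::tibble(
          gene_id = sample(paste0("g", 1:30), 20),
          log_fc = rnorm(20),
          adjusted_p = runif(20, 0, 0.05)
        )
      }
      ra <- mk()
      rb <- mk()
      got <- consensus_de_intersection(ra, rb)
      expect_equal(got, consensus_de_intersection(rb, ra))
      oracle <- character(0)
      for (g in intersect(ra$gene_id, rb$gene_id)) {
        pa <- ra$adjusted_p[ra$gene_id == g]
        pb <- rb$adjusted_p[rb$gene_id == g]
        fa <- ra$log_fc[ra$gene_id == g]
        fb <- rb$log_fc[rb$gene_id == g]
        if (pa < 0.01 && pb < 0.01 && sign(fa) == sign(fb) && sign(fa) != 0) {
          oracle <- c(oracle, g)
        }
      }
      expect_equal(got, sort(oracle))
    }
  })
})

test_that("per-class enrichment counts events in U12 genes and adjusts across classes", {
  calls <- tibble::tibble(
    event_id = paste0("e", 1:8),
    event_class = c("IR", "IR", "IR", "ES", "ES", "MIC", "IR", "ES"),
    gene_id = c("u1", "u2", "g1", "u1", "g2", "g3", "u3", "u2"),
    intron_id = NA_character_,
    call = c(rep("up_in_MU", 7), "down_in_MU")
  )
  res <- per_class_u12_enrichment(calls, c("u1", "u2", "u3"), expected_fraction = 0.1)
  expect_equal(res$observed[res$event_class == "IR"], 3L)
  expect_equal(res$total[res$event_class == "ES"], 3L)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
})
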