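# Independent gamete-product oracle: enumerates the 16 equally likely
# gamete combinations directly, without going through enumerate_offspring's
# tidy machinery.
oracle_cross <- function(mother, father) {
  rows <- list()
  for (m1 in 1:2) {
    for (mx in seq_along(mother$zrsr2)) {
      for (f1 in 1:2) {
        for (fc in c("X", "Y")) {
          z2p <- if (fc == "X") father$zrsr2 else "none"
          e1 <- father$zrsr1[f1]
          e2 <- mother$zrsr2[mx]
          rows[[length(rows) + 1]] <- data.frame(
            sex = if (fc == "X") "female" else "male",
            zrsr1_maternal = mother$zrsr1[m1],
            zrsr1_paternal = father$zrsr1[f1],
            zrsr2_maternal = mother$zrsr2[mx],
            zrsr2_paternal = z2p,
            expressed_zrsr1 = e1,
            expressed_zrsr2_early = e2,
            viable = e1 == "WT" || e2 == "WT",
            probability = 1 / (2 * length(mother$zrsr2) * 2 * 2)
          )
        }
      }
    }
  }
  agg <- do.call(rbind, rows)
  stats::aggregate(
    probability ~ sex + zrsr1_maternal + zrsr1_paternal + zrsr2_maternal +
      zrsr2_paternal + expressed_zrsr1 + expressed_zrsr2_early + viable,
    data = agg, FUN = sum
  )
}

random_parent <- function(sex) {
  alleles <- function(n) sample(c("WT", "mu"), n, replace = TRUE)
  parent_genotype(sex, alleles(2), alleles(if (sex == "female") 2 else 1))
}

test_that("a wild-type cross is fully viable with probabilities summing to 1", {
  cross <- enumerate_offspring(
    parent_genotype("female", c("WT", "WT"), c("WT", "WT")),
    parent_genotype("male", c("WT", "WT"), "WT")
  )
  expect_equal(sum(cross$outcomes$probability), 1, tolerance = 1e-12)
  expect_equal(cross$viable_fraction, 1)
  expect_equal(sum(cross$outcomes$probability[cross$outcomes$sex == "female"]), 0.5)
})

test_that("the double-mutant cross is fully lethal and its reciprocal fully viable", {
  lethal <- enumerate_offspring(
    parent_genotype("female", c("mu", "mu"), c("mu", "mu")), # Zrsr2^mu/mu dam
    parent_genotype("male", c("mu", "mu"), "WT") # Zrsr1^mu/mu sire
  )
  expect_equal(lethal$viable_fraction, 0)
  # every embryo expresses paternal Zrsr1 = mu and maternal Zrsr2 = mu
  expect_true(all(lethal$outcomes$expressed_zrsr1 == "mu"))
  expect_true(all(lethal$outcomes$expressed_zrsr2_early == "mu"))

  reciprocal <- enumerate_offspring(
    parent_genotype("female", c("mu", "mu"), c("WT", "WT")), # Zrsr1^mu/mu dam
    parent_genotype("male", c("WT", "WT"), "mu") # Zrsr2^mu/y sire
  )
  expect_equal(reciprocal$viable_fraction, 1)
})

test_that("enumeration matches the gamete-product oracle on random crosses", {
  withr::with_seed(111, {
    parents <- replicate(20, list(
      mother = random_parent("female"), father = random_parent("male")
    ), simplify = FALSE)
  })
  for (pr in parents) {
    got <- enumerate_offspring(pr$mother, pr$father)
    expect_equal(sum(got$outcomes$probability), 1, tolerance = 1e-12)
    oracle <- oracle_cross(pr$mother, pr$father)
    merged <- merge(
      as.data.frame(got$outcomes), oracle,
      by = c(
        "sex", "zrsr1_maternal", "zrsr1_paternal", "zrsr2_maternal",
        "zrsr2_paternal", "expressed_zrsr1", "expressed_zrsr2_early", "viable"
      ),
      all = TRUE
    )
    expect_false(anyNA(merged$probability.x))
    expect_false(anyNA(merged$probability.y))
    expect_equal(merged$probability.x, merged$probability.y, tolerance = 1e-12)
    expect_equal(
      got$viable_fraction,
      sum(oracle$probability[oracle$viable]),
      tolerance = 1e-12
    )
  }
})

test_that("viability is one WT expressed allele, from either parent", {
  expect_true(is_viable("WT", "mu"))
  expect_true(is_viable("mu", "WT"))
  expect_false(is_viable("mu", "mu"))
})

test_that("converting a mu allele to WT never lowers the viable fraction", {
  withr::with_seed(121, {
    for (rep in 1:10) {
      mother <- random_parent("female")
      father <- random_parent("male")
      base <- enumerate_offspring(mother, father)$viable_fraction
      # flip every mu slot one at a time
      for (slot in 1:2) {
        if (mother$zrsr1[slot] == "mu") {
          m2 <- mother
          m2$zrsr1[slot] <- "WT"
          expect_gte(enumerate_offspring(m2, father)$viable_fraction, base)
        }
        if (mother$zrsr2[slot] == "mu") {
          m2 <- mother
          m2$zrsr2[slot] <- "WT"
          expect_gte(enumerate_offspring(m2, father)$viable_fraction, base)
        }
        if (father$zrsr1[slot] == "mu") {
          f2 <- father
          f2$zrsr1[slot] <- "WT"
          expect_gte(enumerate_offspring(mother, f2)$viable_fraction, base)
        }
      }
      if (father$zrsr2 == "mu") {
        f2 <- father
        f2$zrsr2 <- "WT"
        expect_gte(enumerate_offspring(mother, f2)$viable_fraction, base)
      }
    }
  })
})

test_that("no surviving pup carries the mutant Zrsr2 allele from a het mother", {
  cross <- enumerate_offspring(
    parent_genotype("female", c("WT", "WT"), c("WT", "mu")),
    parent_genotype("male", c("mu", "mu"), "WT")
  )
  spectrum <- surviving_genotype_spectrum(cross)
  expect_equal(sum(spectrum$probability), 1, tolerance = 1e-12)
  expect_true(all(spectrum$zrsr2_maternal == "WT"))

  lethal <- enumerate_offspring(
    parent_genotype("female", c("mu", "mu"), c("mu", "mu")),
    parent_genotype("male", c("mu", "mu"), "WT")
  )
  expect_equal(nrow(surviving_genotype_spectrum(lethal)), 0)
})

test_that("surviving spectra renormalize to 1 across random crosses", {
  withr::with_seed(131, {
    for (rep in 1:20) {
      cross <- enumerate_offspring(random_parent("female"), random_parent("male"))
      spec <- surviving_genotype_spectrum(cross)
      if (nrow(spec) > 0) {
        expect_equal(sum(spec$probability), 1, tolerance = 1e-12)
      } else {
        expect_equal(cross$viable_fraction, 0)
      }
    }
  })
})

test_that("litter consistency test has the exact closed forms", {
  expect_equal(litter_consistency_test(c(A = 1), c(A = 10))$p_value, 1)

  half <- litter_consistency_test(c(A = 0.5, B = 0.5), c(A = 10, B = 0))
  expect_equal(half$p_value, 2 * 0.5^10, tolerance = 1e-12)

  zero <- litter_consistency_test(c(A = 1, B = 0), c(A = 5, B = 1))
  expect_equal(zero$p_value, 0)

  # k = 3 exact multinomial against direct enumeration
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  obs <- c(A = 5, B = 0, C = 0)
  got <- litter_consistency_test(p, obs)
  outcomes <- expand.grid(a = 0:5, b = 0:5, c = 0:5)
  outcomes <- outcomes[rowSums(outcomes) == 5, ]
  probs <- apply(outcomes, 1, function(x) dmultinom(x, prob = p))
  p_obs <- dmultinom(obs, prob = p)
  expect_equal(got$p_value, sum(probs[probs <= p_obs * (1 + 1e-10)]),
    tolerance = 1e-12
  )
})

test_that("genotype strings parse into parent genotypes", {
  m <- parse_genotype("Zrsr1:WT/mu Zrsr2:mu/mu sex:F")
  expect_equal(m$sex, "female")
  expect_equal(m$zrsr1, c("WT", "mu"))
  f <- parse_genotype("Zrsr1:mu/mu Zrsr2:WT/y sex:M")
  expect_equal(f$sex, "male")
  expect_equal(f$zrsr2, "WT")
  expect_error(parse_genotype("Zrsr1:WT/mu sex:F"), "zrsr2")
  expect_error(parent_genotype("male", c("WT", "mu"), c("WT", "mu")), "1 allele")
})

test_that("simulated offspring converge to the enumerated distribution", {
  cross <- enumerate_offspring(
    parent_genotype("female", c("WT", "mu"), c("WT", "mu")),
    parent_genotype("male", c("WT", "mu"), "mu")
  )
  draws <- simulate_cross_offspring(cross, 1e5, seed = 202)
  key <- function(df) {
    paste(df$sex, df$zrsr1_maternal, df$zrsr1_paternal,
      df$zrsr2_maternal, df$zrsr2_paternal,
      sep = "|"
    )
  }
  observed <- table(factor(key(draws), levels = key(cross$outcomes)))
  gof <- suppressWarnings(
    chisq.test(as.vector(observed), p = cross$outcomes$probability)
  )
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(draws$status == "live"), cross$viable_fraction, tolerance = 0.01)

  # structural behavior at the extremes
  lethal <- enumerate_offspring(
    parent_genotype("female", c("mu", "mu"), c("mu", "mu")),
    parent_genotype("male", c("mu", "mu"), "WT")
  )
  arrested <- simulate_cross_offspring(lethal, 258, seed = 203)
  expect_equal(sum(arrested$status == "live"), 0)

  wt <- enumerate_offspring(
    parent_genotype("female", c("WT", "WT"), c("WT", "WT")),
    parent_genotype("male", c("WT", "WT"), "WT")
  )
  expect_equal(
    sum(simulate_cross_offspring(wt, 100, seed = 204)$status == "live"), 100
  )
})
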