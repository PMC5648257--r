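test_that("gamete distributions follow distorted segregation in W/H and are Mendelian elsewhere", {
  p0 <- model_params(e = 0, gamma_m = 0)
  expect_equal(gamete_distribution("W/W", p0),
               c(W = 1, H = 0, R1 = 0, R2 = 0))
  expect_equal(gamete_distribution("W/H", p0),
               c(W = 0.5, H = 0.5, R1 = 0, R2 = 0))

  p <- model_params(e = 0.984, gamma_m = 0.01, xi_m = 0.5)
  g <- gamete_distribution("W/H", p)
  expect_equal(g[["H"]], 0.992)
  expect_equal(g[["W"]], 0.003)
  expect_equal(g[["R1"]], 0.0025)
  expect_equal(g[["R2"]], 0.0025)

  # Mendelian for every non-W/H genotype, and all sum to 1
  set.seed(11)
  for (i in 1:5) {
    pr <- random_params()
    for (geno in gd_genotypes()) {
      g <- gamete_distribution(geno, pr)
      expect_equal(sum(g), 1, tolerance = 1e-12)
      if (geno != "W/H") {
        a <- unique(strsplit(geno, "/", fixed = TRUE)[[1]])
        expect_equal(unname(sum(g[a])), 1)
        if (length(a) == 2) expect_equal(unname(g[a[1]]), 0.5)
      }
    }
  }
  expect_error(gamete_distribution("W/Q", model_params()), "invalid")
})

test_that("probability of an H gamete from W/H is strictly increasing in the homing rate", {
  es <- seq(0, 0.99, by = 0.03)
  ph <- vapply(es, function(e) {
    gamete_distribution("W/H", model_params(e = e, gamma_m = 0.01))[["H"]]
  }, numeric(1))
  expect_true(all(diff(ph) > 0))
})

test_that("embryonic modification converts W alleles only in offspring of drive mothers", {
  p <- model_params(gamma_e = 0.796, xi_e = 1 / 3, beta = 0)
  passthrough <- embryo_modification("W/H", FALSE, p)
  expect_equal(passthrough[["W/H"]], 1)
  expect_equal(sum(passthrough), 1)

  z <- embryo_modification("W/H", TRUE, p)
  expect_equal(z[["W/H"]], 0.204)
  expect_equal(z[["H/R1"]], 0.796 / 3, tolerance = 1e-12)
  expect_equal(z[["H/R2"]], 0.796 * 2 / 3, tolerance = 1e-12)
  expect_equal(sum(z), 1, tolerance = 1e-12)

  forced <- embryo_modification("W/W", TRUE,
                                model_params(gamma_e = 1, xi_e = 1))
  expect_equal(forced[["R1/R1"]], 1)

  # alleles other than W are never modified
  set.seed(12)
  for (i in 1:5) {
    pr <- random_params()
    for (geno in c("H/H", "H/R1", "R1/R2", "R2/R2")) {
      z <- embryo_modification(geno, TRUE, pr)
      expect_equal(z[[canonical_genotype(geno)]], 1)
    }
    for (geno in gd_genotypes()) {
      expect_equal(sum(embryo_modification(geno, TRUE, pr)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("female fecundity encodes sterile classes and the dominant heterozygous cost", {
  p <- model_params(d = 0.907)
  expect_equal(female_fecundity("H/R2", p), 0)
  expect_equal(female_fecundity("H/H", p), 0)
  expect_equal(female_fecundity("R2/R2", p), 0)
  expect_equal(female_fecundity("W/H", p), 0.093)
  expect_equal(female_fecundity("R1/R1", p), 1)
  expect_equal(female_fecundity("H/R1", p), 1)  # restored fertility
  expect_equal(female_fecundity("W/R2", p), 1)
})

test_that("an all wild-type population is a fixed point", {
  st <- population_state(c("W/W" = 1))
  nxt <- next_generation(st, model_params())
  expect_equal(nxt$female[["W/W"]], 1)
  expect_equal(nxt$generation, 1L)
})

test_that("with all rates and costs zero, allele frequencies are constant (Hardy-Weinberg limit)", {
  # the structural sterilities (H/H, H/R2, R2/R2 females) are part of the
  # model, not parameters, so the Mendelian limit applies on the fully
  # fertile drive-free subspace spanned by W and R1
  p0 <- model_params(e = 0, gamma_m = 0, gamma_e = 0, beta = 0, d = 0)
  set.seed(13)
  f <- stats::rgamma(3, 1)
  f <- f / sum(f)
  st <- population_state(c("W/W" = f[1], "W/R1" = f[2], "R1/R1" = f[3]))
  af0 <- (allele_frequencies(st$female) + allele_frequencies(st$male)) / 2
  tr <- simulate_drive(p0, st, n_generations = 10)
  for (s in tr$states) {
    af <- (allele_frequencies(s$female) + allele_frequencies(s$male)) / 2
    expect_equal(af, af0, tolerance = 1e-12)
  }
  # after one round of random mating the distribution is at equilibrium
  s1 <- tr$states[[2]]$female
  s2 <- tr$states[[3]]$female
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("genotype vectors stay normalised and non-negative across random parameter sets", {
  set.seed(14)
  for (i in 1:8) {
    tr <- simulate_drive(random_params(), random_state(), n_generations = 6)
    for (s in tr$states) {
      expect_equal(sum(s$female), 1, tolerance = 1e-12)
      expect_equal(sum(s$male), 1, tolerance = 1e-12)
      expect_true(all(s$female >= 0) && all(s$male >= 0))
    }
  }
})

test_that("equal initial sex frequencies stay identical every generation", {
  set.seed(15)
  for (i in 1:4) {
    f <- stats::rgamma(10, 1)
    st <- population_state(f / sum(f), f / sum(f))
    tr <- simulate_drive(random_params(), st, n_generations = 8)
    for (s in tr$states) expect_identical(s$female, s$male)
  }
})

test_that("a population with only sterile females signals extinction rather than NaN", {
  st <- population_state(c("H/H" = 0.5, "H/R2" = 0.5))
  expect_error(next_generation(st, model_params()),
               class = "gd_extinction")
  tr <- simulate_drive(model_params(), st, n_generations = 5)
  expect_true(tr$extinct)
  expect_length(tr$states, 1)
})

test_that("trajectory summaries are consistent with the genotype vectors", {
  s0 <- summarize_trajectory(simulate_drive(model_params(),
                                            population_state(c("W/W" = 1)),
                                            0))
  expect_equal(s0$drive_carrier_fraction, 0)
  expect_equal(s0$freq_W, 1)

  s1 <- summarize_trajectory(simulate_drive(model_params(),
                                            population_state(c("W/H" = 1)),
                                            0))
  expect_equal(s1$drive_carrier_fraction, 1)
  expect_equal(s1$freq_H, 0.5)

  tr <- simulate_drive(model_params(), n_generations = 6)
  s <- summarize_trajectory(tr)
  expect_equal(nrow(s), 7)
  for (i in seq_along(tr$states)) {
    st <- tr$states[[i]]
    af <- (allele_frequencies(st$female) + allele_frequencies(st$male)) / 2
    expect_equal(s$freq_H[i], af[["H"]])
    nd <- af[c("W", "R1", "R2")]
    expect_equal(s$nondrive_W[i], unname(nd[1] / sum(nd)))
    carriers <- grepl("H", gd_genotypes(), fixed = TRUE)
    expect_equal(s$drive_carrier_fraction[i], sum(st$female[carriers]))
  }
})

test_that("simulate_drive with zero generations returns only the initial state", {
  tr <- simulate_drive(model_params(), n_generations = 0)
  expect_length(tr$states, 1)
  expect_false(tr$extinct)
})

test_that("parameter validation rejects out-of-range and inconsistent rates", {
  expect_error(model_params(e = 1.2), "in \\[0, 1\\]")
  expect_error(model_params(e = 0.9, gamma_m = 0.2), "exceed 1")
  expect_error(model_params(gamma_e = 0.9, beta = 0.2), "exceed 1")
})
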