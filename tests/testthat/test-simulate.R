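test_that("noise-free well means follow the closed-form readout model", {
  truth <- screen_truth(
    pharmacology = tibble::tibble(
      receptor = "R1", peptide = c("full", "inert"), pathway = "Gq_IP",
      ec50 = c(1e-8, 1e-8), emax = c(1, 0), hill = 1),
    receptor_windows = tibble::tibble(receptor = "R1", pathway = "Gq_IP",
                                      basal = 50, window = 10)
  )
  d0 <- screen_design(concentrations = c(1e-7, 1e-5), noise_cv = 0,
                      experiment_cv = 0)
  rec <- simulate_screen(truth, d0, seed = 1)
  buffer <- rec$signal[rec$peptide == "buffer"]
  expect_equal(unique(buffer), 50, tolerance = 1e-12)
  # full agonist, ec50 10 nM, hill 1, window 10: fold at 100 nM = 1 + 9*100/110
  at100 <- rec$signal[rec$peptide == "full" & rec$conc_M == 1e-7]
  expect_equal(unique(at100), 50 * (1 + 9 * (100 / 110)), tolerance = 1e-12)
  # inert pair wells equal the buffer mean exactly
  expect_equal(unique(rec$signal[rec$peptide == "inert"]), 50, tolerance = 1e-12)
})

test_that("forskolin-stimulated cAMP inhibition follows the closed form", {
  truth <- screen_truth(
    pharmacology = tibble::tibble(receptor = "R1", peptide = "ago",
                                  pathway = "Gio_cAMP_fsk",
                                  ec50 = 1e-8, emax = 1, hill = 1),
    receptor_windows = tibble::tibble(receptor = "R1", pathway = "Gio_cAMP_fsk",
                                      basal = 100, window = 10),
    forskolin_fold = 20
  )
  d0 <- screen_design(noise_cv = 0, experiment_cv = 0)
  rec <- simulate_screen(truth, d0, seed = 1)
  fsk <- unique(rec$signal[rec$peptide == "forskolin"])
  expect_equal(fsk, 2000, tolerance = 1e-12)
  at10u <- unique(rec$signal[rec$peptide == "ago" & rec$conc_M == 1e-5])
  # 1 - 10000/10010 of the forskolin signal
  expect_equal(at10u / fsk, 1 - 1e-5 / (1e-5 + 1e-8), tolerance = 1e-12)
  expect_equal(at10u / fsk, 0.000999001, tolerance = 1e-6)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  truth <- grade_fixture_truth()
  d <- screen_design(noise_cv = 0.1)
  a <- simulate_screen(truth, d, seed = 11)
  b <- simulate_screen(truth, d, seed = 11)
  c <- simulate_screen(truth, d, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$signal, c$signal)))
})

test_that("Monte-Carlo well means converge to the model mean", {
  truth <- screen_truth(
    pharmacology = tibble::tibble(receptor = "R1", peptide = "ago",
                                  pathway = "Gq_IP", ec50 = 1e-8,
                                  emax = 1, hill = 1),
    receptor_windows = tibble::tibble(receptor = "R1", pathway = "Gq_IP",
                                      basal = 100, window = 10)
  )
  cv <- 0.10
  d <- screen_design(n_experiments = 200, n_replicates = 3, noise_cv = cv,
                     experiment_cv = 0)
  rec <- simulate_screen(truth, d, seed = 5)
  w <- rec$signal[rec$peptide == "ago" & rec$conc_M == 1e-5]
  mu <- 100 * (1 + 9 * (1e-5 / (1e-5 + 1e-8)))
  expect_lt(abs(mean(w) / mu - 1), 3 * cv / sqrt(length(w)))
})

test_that("invalid designs and pathways are rejected", {
  expect_error(screen_design(concentrations = c(0, 1e-5)), "positive")
  expect_error(
    screen_truth(
      pharmacology = tibble::tibble(receptor = "R", peptide = "p",
                                    pathway = "Gx_IP", ec50 = 1, emax = 1,
                                    hill = 1),
      receptor_windows = tibble::tibble(receptor = "R", pathway = "Gq_IP",
                                        basal = 1, window = 2)),
    "unknown pathway")
})

test_that("avoidance plate simulation respects probabilities and seeds", {
  all_mesa <- behavior_truth(tibble::tibble(genotype = "wt", p_mesa = 1,
                                            n_worms = 80, n_plates = 3))
  plates <- simulate_avoidance_plates(all_mesa, seed = 1)
  expect_true(all(plates$n_eoh == 0))
  expect_true(all(plates$n_mesa == 80))
  ai <- avoidance_index(plates)
  expect_true(all(ai$avoidance_index == 1))

  # p = 0.5 at large n: index within 3 standard errors of zero
  big <- behavior_truth(tibble::tibble(genotype = "wt", p_mesa = 0.5,
                                       n_worms = 10000, n_plates = 1))
  p <- simulate_avoidance_plates(big, seed = 2)
  se <- 2 * sqrt(0.25 / 10000)  # var of (2X/n - 1)
  expect_lt(abs(avoidance_index(p)$avoidance_index), 3 * se)

  expect_identical(simulate_avoidance_plates(all_mesa, seed = 9),
                   simulate_avoidance_plates(all_mesa, seed = 9))
  expect_error(behavior_truth(tibble::tibble(genotype = "wt", p_mesa = -0.1,
                                             n_worms = 10, n_plates = 1)),
               "probability")
  expect_error(
    simulate_avoidance_plates(
      behavior_truth(tibble::tibble(genotype = "wt", p_mesa = 0.5,
                                    n_worms = 10, n_plates = 1))$genotypes |>
        dplyr::mutate(n_worms = 0) |>
        (\(g) structure(list(genotypes = g), class = "behavior_truth"))(),
      seed = 1),
    "n_worms")
})

test_that("bordering plate simulation matches binomial expectations", {
  none <- behavior_truth(tibble::tibble(genotype = "wt", p_border = 0,
                                        n_worms = 120, n_plates = 4))
  expect_true(all(simulate_bordering_plates(none, seed = 1)$n_border == 0))

  strong <- behavior_truth(tibble::tibble(genotype = "npr-1", p_border = 0.8,
                                          n_worms = 120, n_plates = 4))
  p <- simulate_bordering_plates(strong, seed = 3)
  frac <- mean(bordering_fraction(p)$bordering_fraction)
  se <- sqrt(0.8 * 0.2 / (120 * 4))
  expect_lt(abs(frac - 0.8), 4 * se)
})
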