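make_folds <- function(truth = grade_fixture_truth(),
                       design = screen_design(noise_cv = 0.05,
                                              experiment_cv = 0.05),
                       seed = 42) {
  normalize_folds(simulate_screen(truth, design, seed = seed))
}

test_that("fold normalization reproduces hand-computed ratios", {
  rec <- tibble::tibble(
    receptor = "R1", pathway = "Gq_IP",
    peptide = c(rep("buffer", 3), rep("pep", 3)),
    conc_M = c(0, 0, 0, 1e-5, 1e-5, 1e-5),
    experiment = 1L, replicate = rep(1:3, 2),
    signal = c(100, 100, 100, 240, 250, 260)
  )
  f <- normalize_folds(rec)
  expect_equal(mean(f$fold[f$peptide == "pep"]), 2.5)
  s <- fold_summary(f)
  expect_equal(s$fold_mean[s$peptide == "pep"], 2.5)

  # peptide wells equal to buffer give fold 1
  rec$signal[4:6] <- 100
  expect_equal(unique(normalize_folds(rec)$fold), 1)
})

test_that("forskolin normalization expresses inhibition as fold of forskolin", {
  rec <- tibble::tibble(
    receptor = "R1", pathway = "Gio_cAMP_fsk",
    peptide = c(rep("buffer", 2), rep("forskolin", 2), rep("pep", 2)),
    conc_M = c(0, 0, 0, 0, 1e-5, 1e-5),
    experiment = 1L, replicate = rep(1:2, 3),
    signal = c(50, 50, 1000, 1000, 600, 600)
  )
  f <- normalize_folds(rec)
  expect_equal(unique(f$fold[f$peptide == "pep"]), 0.6)  # 40% inhibition
  expect_true(above_threshold(0.6, "Gio_cAMP_fsk"))
})

test_that("missing controls raise an error naming the stratum", {
  rec <- tibble::tibble(receptor = "R9", pathway = "Gq_IP", peptide = "pep",
                        conc_M = 1e-5, experiment = 1L, replicate = 1:3,
                        signal = c(1, 2, 3))
  expect_error(normalize_folds(rec), "R9")
})

test_that("threshold rule is boundary-inclusive in both directions", {
  expect_true(above_threshold(2.0, "Gq_IP"))
  expect_false(above_threshold(1.99, "Gs_cAMP"))
  expect_true(above_threshold(5.0, "G16_IP"))
  expect_true(above_threshold(0.8, "Gio_cAMP_fsk"))
  expect_false(above_threshold(0.85, "Gio_cAMP_fsk"))  # 15% inhibition
})

test_that("activation testing flags large shifts and not relabelled controls", {
  set.seed(1)
  base <- tidyr::expand_grid(receptor = "R1", pathway = "Gq_IP",
                             peptide = c("buffer", "shifted", "null_pep"),
                             experiment = 1:3, replicate = 1:3)
  base$conc_M <- ifelse(base$peptide == "buffer", 0, 1e-5)
  sd_w <- 5
  base$signal <- 100 + stats::rnorm(nrow(base), 0, sd_w) +
    ifelse(base$peptide == "shifted", 10 * sd_w, 0)
  res <- test_activation(normalize_folds(base))
  expect_true(res$significant[res$peptide == "shifted"])
  expect_false(res$significant[res$peptide == "null_pep"])
  # single-well conditions carry no variance estimate
  solo <- base[base$replicate == 1 & base$experiment == 1, ]
  expect_error(test_activation(normalize_folds(solo)), "single well")
})

test_that("receptor window rules differ between nematode and human receptors", {
  s <- tibble::tribble(
    ~receptor, ~pathway, ~peptide, ~conc_M, ~fold_mean, ~fold_sem, ~n,
    "NPR-X", "Gq_IP", "a", 1e-5, 9.2, 0.1, 3,
    "NPR-X", "Gq_IP", "b", 1e-5, 4.0, 0.1, 3,
    "Y2R",   "Gq_IP", "endo", 1e-5, 6.0, 0.1, 3,
    "Y2R",   "Gq_IP", "endo", 1e-7, 3.0, 0.1, 3,
    "Y2R",   "Gq_IP", "surrogate", 1e-5, 7.5, 0.1, 3
  )
  spec <- tibble::tibble(receptor = c("NPR-X", "Y2R"),
                         species = c("C. elegans", "human"),
                         pathway = "Gq_IP",
                         endogenous_agonist = c(NA, "endo"))
  rm <- receptor_max(s, spec)
  expect_equal(rm$fold_max[rm$receptor == "NPR-X"], 9.2)  # any peptide
  expect_equal(rm$fold_max[rm$receptor == "Y2R"], 6.0)    # endogenous only
  expect_error(
    receptor_max(s, dplyr::mutate(spec, endogenous_agonist = NA)),
    "endogenous agonist")
  # silent receptor: window undefined
  none <- receptor_max(s[0, ], spec[1, ])
  expect_true(is.na(none$fold_max))
})

test_that("grading matches closed-form two-concentration profiles", {
  window <- 10
  fold_max <- 1 + (window - 1) * (1e-5 / (1e-5 + 1e-8))  # strongest agonist
  cases <- list(
    list(ec50 = 1e-8, emax = 1, grade = "v"),
    list(ec50 = 5e-7, emax = 1, grade = "iv"),
    list(ec50 = 5e-5, emax = 1, grade = "i"),
    list(ec50 = 1e-8, emax = 0.5, grade = "iii", asterisk = TRUE)
  )
  for (cs in cases) {
    pr <- closed_form_profile(cs$ec50, cs$emax, window, fold_max)
    g <- grade_pair(pr$active_low, pr$active_high, pr$frac_low, pr$frac_high)
    expect_equal(as.character(g$grade), cs$grade,
                 info = sprintf("ec50=%g emax=%g", cs$ec50, cs$emax))
    if (!is.null(cs$asterisk)) expect_true(g$asterisk)
  }
  # spec of the partial-agonist flag: near-equal submaximal responses
  pr <- closed_form_profile(1e-8, 0.5, window, fold_max)
  expect_lt(abs(pr$frac_high - pr$frac_low), 0.1)
})

test_that("grade_pair equals the brute-force oracle over a parameter sweep", {
  set.seed(33)
  n <- 4000
  active_low <- sample(c(TRUE, FALSE), n, replace = TRUE)
  active_high <- sample(c(TRUE, FALSE), n, replace = TRUE)
  frac_low <- stats::runif(n, -0.1, 1.2)
  frac_high <- stats::runif(n, -0.1, 1.2)
  got <- grade_pair(active_low, active_high, frac_low, frac_high)
  for (i in seq_len(n)) {
    want <- oracle_grade(active_low[i], active_high[i], frac_low[i],
                         frac_high[i])
    expect_identical(as.character(got$grade[i]), want$grade)
    expect_identical(got$asterisk[i], want$asterisk)
  }
})

test_that("grade is monotone in potency for noise-free full agonists", {
  window <- 10
  ec50s <- 10^seq(-4, -10, length.out = 60)
  fold_max <- 1 + (window - 1) * (1e-5 / (1e-5 + min(ec50s)))
  grades <- vapply(ec50s, function(e) {
    pr <- closed_form_profile(e, 1, window, fold_max)
    as.integer(grade_pair(pr$active_low, pr$active_high,
                          pr$frac_low, pr$frac_high)$grade)
  }, integer(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("out-of-range window fractions are a normalization fault", {
  expect_error(grade_pair(TRUE, TRUE, 1.6, 0.9), "normalization fault")
  expect_error(grade_pair(TRUE, TRUE, 0.5, -0.3), "normalization fault")
})

test_that("matrix construction is complete, ordered and order-invariant", {
  folds <- make_folds()
  spec <- fixture_panel_spec()
  calls <- call_activation(folds, spec)
  m <- build_interaction_matrix(calls)
  expect_s3_class(m, "interaction_matrix")
  expect_equal(nrow(m), dplyr::n_distinct(calls$peptide))

  shuffled <- folds[sample.int(nrow(folds)), ]
  m2 <- build_interaction_matrix(call_activation(shuffled, spec),
                                 peptides = levels(m$peptide))
  expect_equal(as.character(m$grade), as.character(m2$grade))
  expect_equal(m$asterisk, m2$asterisk)

  expect_error(build_interaction_matrix(calls, receptors = c("R1", "ghost")),
               "ghost")
})

test_that("noise-free calls equal pure threshold calls", {
  truth <- grade_fixture_truth()
  folds <- make_folds(truth, screen_design(noise_cv = 0, experiment_cv = 0))
  calls <- call_activation(folds, fixture_panel_spec())
  s <- fold_summary(folds) |>
    dplyr::filter(!.data$peptide %in% c("buffer", "forskolin"))
  thr <- s |>
    dplyr::mutate(pass = above_threshold(.data$fold_mean, .data$pathway)) |>
    dplyr::select("peptide", "conc_M", "pass") |>
    tidyr::pivot_wider(names_from = "conc_M", values_from = "pass")
  merged <- dplyr::left_join(calls, thr, by = "peptide")
  expect_equal(merged$active_low, merged[["1e-07"]])
  expect_equal(merged$active_high, merged[["1e-05"]])
})

test_that("known-truth grades are recovered from a noisy screen", {
  folds <- make_folds(seed = 202)
  calls <- call_activation(folds, fixture_panel_spec())
  want <- grade_fixture_expected()
  got <- dplyr::left_join(want, calls, by = "peptide",
                          suffix = c("_want", "_got"))
  expect_equal(as.character(got$grade_got), got$grade_want)
  expect_equal(got$asterisk_got, got$asterisk_want)
})

test_that("coupling preference ranks activated pathways by signal strength", {
  # Gq strongly elevated, Gs slightly but significantly elevated:
  # Gq primary, Gs secondary
  truth <- screen_truth(
    pharmacology = tibble::tibble(
      receptor = "NPR-5b", peptide = "FLP-21",
      pathway = c("Gq_IP", "Gs_cAMP"),
      ec50 = 1e-8, emax = c(1, 1), hill = 1),
    receptor_windows = tibble::tibble(receptor = "NPR-5b",
                                      pathway = c("Gq_IP", "Gs_cAMP"),
                                      basal = 100, window = c(10, 2.5))
  )
  folds <- normalize_folds(simulate_screen(truth,
                                           screen_design(noise_cv = 0.05,
                                                         experiment_cv = 0),
                                           seed = 9))
  prof <- coupling_profile(folds)
  expect_equal(prof$status[prof$pathway == "Gq_IP"], "primary")
  expect_equal(prof$status[prof$pathway == "Gs_cAMP"], "secondary")

  # only Gi/o inhibition responds: Gi/o primary, the rest inactive
  truth2 <- screen_truth(
    pharmacology = tibble::tibble(
      receptor = "NPR-1", peptide = "FLP-21",
      pathway = c("Gio_cAMP_fsk", "Gs_cAMP"),
      ec50 = 1e-8, emax = c(1, 0), hill = 1),
    receptor_windows = tibble::tibble(receptor = "NPR-1",
                                      pathway = c("Gio_cAMP_fsk", "Gs_cAMP"),
                                      basal = 100, window = c(10, 10))
  )
  folds2 <- normalize_folds(simulate_screen(truth2,
                                            screen_design(noise_cv = 0.05,
                                                          experiment_cv = 0),
                                            seed = 10))
  prof2 <- coupling_profile(folds2)
  expect_equal(prof2$status[prof2$pathway == "Gio_cAMP_fsk"], "primary")
  expect_equal(prof2$status[prof2$pathway == "Gs_cAMP"], "inactive")

  # nothing responds anywhere: all inactive
  truth3 <- screen_truth(
    pharmacology = tibble::tibble(receptor = "R", peptide = "p",
                                  pathway = "Gq_IP", ec50 = 1e-8,
                                  emax = 0, hill = 1),
    receptor_windows = tibble::tibble(receptor = "R", pathway = "Gq_IP",
                                      basal = 100, window = 10))
  folds3 <- normalize_folds(simulate_screen(truth3,
                                            screen_design(noise_cv = 0.05,
                                                          experiment_cv = 0),
                                            seed = 11))
  expect_true(all(coupling_profile(folds3)$status == "inactive"))
  expect_error(coupling_profile(folds3[0, ]), "no pathway")
})
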