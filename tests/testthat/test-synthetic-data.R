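test_that("band mapping is the deterministic cut table", {
  # HpaII blocked by any methylation; MspI blocked only by external (CHG)
  expect_identical(band_from_state(1:4, "HpaII"), c(1L, 0L, 0L, 0L))
  expect_identical(band_from_state(1:4, "MspI"), c(1L, 1L, 0L, 0L))
  expect_identical(band_from_state("CG_INTERNAL", "MspI"), 1L)
  expect_error(band_from_state(5, "HpaII"), "unknown")
})

test_that("population spec validation rejects bad probabilities and counts", {
  expect_error(population_spec(state_frequencies = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(population_spec(p_demeth = 1.5), "\\[0, 1\\]")
  expect_error(population_spec(n_loci = 0), "positive")
  expect_error(population_spec(n_effective_treated = 99), "between 0")
})

test_that("paired matrices share one latent state vector per sample", {
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 2, n_treated_lines = 2,
                    n_samples_per_line = 3, n_loci = 60, rng_seed = 5))
  check_paired_msap(pop$hpaii, pop$mspi)
  # HpaII band 1 forces MspI band 1 (both cut only when unmethylated)
  expect_true(all(pop$mspi$values[pop$hpaii$values == 1L] == 1L))
})

test_that("with no treatment effect treated and control lines are exchangeable", {
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 3, n_treated_lines = 3,
                    n_samples_per_line = 4, n_loci = 400,
                    p_demeth = 0, p_epi_noise = 0,
                    p_line_effective = 1, rng_seed = 9))
  disc <- rowMeans(pop$hpaii$values != pop$mspi$values)
  treated <- pop$hpaii$samples$line_id %in%
    pop$lines$line_id[pop$lines$treated]
  # both groups' expected discordance is the CG_INTERNAL frequency (0.3);
  # samples share their line founder, so the effective number of
  # independent state draws is lines x loci (3 x 400 per group)
  se3 <- 3 * sqrt(0.3 * 0.7 / 1200)
  expect_lt(abs(mean(disc[treated]) - 0.3), se3)
  expect_lt(abs(mean(disc[!treated]) - 0.3), se3)
})

test_that("all-CG loci with complete demethylation force the band patterns", {
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 2, n_treated_lines = 2,
                    n_samples_per_line = 3, n_loci = 40,
                    state_frequencies = c(0, 1, 0, 0),
                    p_demeth = 1, p_epi_noise = 0,
                    n_effective_treated = 2, rng_seed = 1))
  ctrl <- pop$hpaii$samples$line_id %in%
    pop$lines$line_id[!pop$lines$treated]
  expect_true(all(pop$hpaii$values[ctrl, ] == 0L))
  expect_true(all(pop$mspi$values[ctrl, ] == 1L))
  expect_true(all(pop$hpaii$values[!ctrl, ] == 1L))
  expect_true(all(pop$mspi$values[!ctrl, ] == 1L))
})

test_that("per-locus enzyme discordance matches its closed-form expectation", {
  # discordant bands occur exactly at CG_INTERNAL loci, so the Monte-Carlo
  # discordance frequency must match the state frequency
  freqs <- c(0.45, 0.25, 0.2, 0.1)
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 4, n_treated_lines = 1,
                    n_samples_per_line = 5, n_loci = 500,
                    state_frequencies = freqs, p_demeth = 0,
                    p_epi_noise = 0, rng_seed = 21))
  ctrl <- pop$hpaii$samples$line_id %in%
    pop$lines$line_id[!pop$lines$treated]
  disc <- mean(pop$hpaii$values[ctrl, ] != pop$mspi$values[ctrl, ])
  # founders are shared within a line: effective draws = 4 lines x 500 loci
  se <- sqrt(0.25 * 0.75 / (4 * 500))
  expect_lt(abs(disc - 0.25), 4 * se)
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  spec <- population_spec(n_control_lines = 2, n_treated_lines = 3,
                          n_samples_per_line = 3, n_loci = 80, rng_seed = 33)
  a <- simulate_msap_population(spec)
  b <- simulate_msap_population(spec)
  expect_identical(a$hpaii$values, b$hpaii$values)
  expect_identical(a$mspi$values, b$mspi$values)
  expect_identical(a$lines, b$lines)
  d1 <- simulate_dose_response(dose_response_spec(rng_seed = 4))
  d2 <- simulate_dose_response(dose_response_spec(rng_seed = 4))
  expect_identical(d1, d2)
  lines <- a$lines
  t1 <- simulate_traits(trait_spec(rng_seed = 6), lines)
  t2 <- simulate_traits(trait_spec(rng_seed = 6), lines)
  expect_identical(t1, t2)
})

test_that("stronger demethylation weakly reduces treated-line discordance", {
  disc_at <- function(p) {
    pop <- simulate_msap_population(
      population_spec(n_control_lines = 1, n_treated_lines = 6,
                      n_samples_per_line = 4, n_loci = 300,
                      p_demeth = p, p_line_effective = 1,
                      p_epi_noise = 0.02, rng_seed = 100))
    tr <- pop$hpaii$samples$line_id %in% pop$lines$line_id[pop$lines$treated]
    mean(pop$hpaii$values[tr, ] != pop$mspi$values[tr, ])
  }
  d <- vapply(c(0, 0.25, 0.5, 0.75, 1), disc_at, numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("dose-response counts are exact at dose 0 and match the curve mean", {
  spec <- dose_response_spec(doses = c(0, 0.32, 0.64),
                             reps_per_dose = 2500, n_per_rep = 4,
                             true_params = list(A = 40, b = 2, m = 0.32),
                             rng_seed = 17)
  tab <- simulate_dose_response(spec)
  # the curve starts at exactly 100%, so every control seedling responds
  expect_true(all(tab$responders[tab$dose == 0] == tab$total[tab$dose == 0]))
  # binomial oracle at the midpoint: mean response = (100 + A)/2 = 70%
  at_m <- tab$responders[tab$dose == 0.32]
  n_draws <- sum(tab$total[tab$dose == 0.32])
  p_hat <- sum(at_m) / n_draws
  se <- sqrt(0.7 * 0.3 / n_draws)
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("trait generator honours degenerate and null settings", {
  lines <- data.frame(line_id = sprintf("L%02d", 1:8),
                      treated = rep(c(FALSE, TRUE), each = 4))
  spec0 <- trait_spec(
    seed_area = list(
      control = list(mean = 2.75, var_between = 0, var_within = 0),
      treated = list(mean = 2.61, var_between = 0, var_within = 0)),
    oil = list(control = list(mean = 48.9, var_between = 0),
               treated = list(mean = 43.1, var_between = 0)),
    protein = list(control = list(mean = 23.4, var_between = 0),
                   treated = list(mean = 27.2, var_between = 0)),
    fatty_acids = list(control = c(palmitic = 3.15, linoleic = 18.82,
                                   erucic = 57.56),
                       treated = c(palmitic = 3.24, linoleic = 19.45,
                                   erucic = 54.19),
                       sd = c(palmitic = 0, linoleic = 0, erucic = 0)),
    latent_desaturation_effect = 0, reading_sd = 0, rng_seed = 2)
  tt <- simulate_traits(spec0, lines)
  # every observation equals its group mean
  sa <- tt[tt$trait == "seed_area", ]
  expect_true(all(sa$value[sa$treatment == "control"] == 2.75))
  expect_true(all(sa$value[sa$treatment == "treated"] == 2.61))
  expect_true(all(tt$value[tt$trait == "erucic" &
                             tt$treatment == "treated"] == 54.19))
})

test_that("zero latent desaturation effect decouples the fatty acids", {
  lines <- data.frame(line_id = sprintf("L%03d", 1:300),
                      treated = TRUE)
  tt <- simulate_traits(trait_spec(latent_desaturation_effect = 0,
                                   rng_seed = 8), lines)
  r <- trait_correlations(tt, c("erucic", "linoleic"))$r["erucic", "linoleic"]
  expect_lt(abs(r), 3 / sqrt(300))
})

test_that("calibrated fatty-acid model reproduces the erucic-linoleic trade-off", {
  # single-factor loadings solve the three pairwise correlation targets;
  # check the n=100 sample correlation lands in its own Fisher-z band
  # around -0.88 in nearly all replicates
  lines <- data.frame(line_id = sprintf("L%03d", 1:100), treated = TRUE)
  n_sim <- 200
  covered <- logical(n_sim)
  sign_neg <- logical(n_sim)
  for (k in seq_len(n_sim)) {
    tt <- simulate_traits(trait_spec(rng_seed = 5000 + k), lines)
    tc <- trait_correlations(tt, c("erucic", "linoleic", "palmitic"))
    covered[k] <- tc$conf_low["erucic", "linoleic"] <= -0.88 &&
      tc$conf_high["erucic", "linoleic"] >= -0.88
    sign_neg[k] <- tc$r["erucic", "linoleic"] < 0
  }
  expect_true(all(sign_neg))
  expect_gte(mean(covered), 0.9)
})

test_that("infeasible trait means are rejected", {
  expect_error(trait_spec(
    oil = list(control = list(mean = 60, var_between = 1),
               treated = list(mean = 60, var_between = 1)),
    protein = list(control = list(mean = 50, var_between = 1),
                   treated = list(mean = 50, var_between = 1))),
    "oil \\+ protein")
})

test_that("pedigree ledger reproduces the population bookkeeping", {
  ped <- build_population_pedigree(n_e1 = 473, siliques_per_plant = 3,
                                   pooled_per_plant = 1)
  e2_seed <- ped[ped$generation == "E2_seed", ]
  expect_identical(nrow(e2_seed), 473L * 4L)
  expect_identical(unname(table(e2_seed$source_type)["silique"]), 473L * 3L)
  # four accessions per E1 plant
  expect_true(all(table(e2_seed$parent) == 4))

  ped2 <- build_population_pedigree(n_e1 = 100, siliques_per_plant = 3,
                                    pooled_per_plant = 1,
                                    n_selected_lines = 100,
                                    seeds_sown_per_selected_line = 10)
  expect_identical(sum(ped2$generation == "E2_plant"), 1000L)
  expect_false(anyDuplicated(ped2$accession_id) > 0)

  expect_identical(nrow(build_population_pedigree(0)), 0L)
  expect_error(build_population_pedigree(-1), "non-negative")
})
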