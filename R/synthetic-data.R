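#' Methylation states of a CCGG site and their MSAP band mapping
#'
#' MSAP scores each CCGG restriction site through the isoschizomer pair
#' HpaII/MspI. HpaII is blocked by methylation of either cytosine; MspI
#' cuts when only the internal cytosine is methylated (CG context) but is
#' blocked by methylation of the external cytosine (CHG context). Four
#' full-methylation classes are modelled (hemimethylation is not, because
#' bands are scored only present/absent):
#'
#' | state          | meaning           | HpaII band | MspI band |
#' |----------------|-------------------|-----------|-----------|
#' | `UNMETHYLATED` | no methylation    | 1         | 1         |
#' | `CG_INTERNAL`  | C^mCGG            | 0         | 1         |
#' | `CHG_EXTERNAL` | ^mCCGG            | 0         | 0         |
#' | `FULL`         | both cytosines    | 0         | 0         |
#'
#' Only the `CG_INTERNAL` state produces discordant bands between the two
#' digests, which is what the hypomethylation screen exploits.
#'
#' @format `METHYLATION_STATES` is the character vector of the four state
#'   names, in the integer coding used throughout the generator.
#' @export
METHYLATION_STATES <- c("UNMETHYLATED", "CG_INTERNAL", "CHG_EXTERNAL", "FULL")

#' Band call implied by a methylation state
#'
#' Pure lookup of the cut/no-cut table above.
#'
#' @param state integer codes 1-4 (order of [METHYLATION_STATES]) or state
#'   names.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @return Integer vector of 0/1 band calls.
#' @export
band_from_state <- function(state, enzyme = c("HpaII", "MspI")) {
  enzyme <- match.arg(enzyme)
  if (is.character(state)) state <- match(state, METHYLATION_STATES)
  if (anyNA(state) || any(state < 1 | state > 4))
    stop("unknown methylation state")
  map <- if (enzyme == "HpaII") c(1L, 0L, 0L, 0L) else c(1L, 1L, 0L, 0L)
  map[state]
}

#' Specification of a simulated epimutagenised MSAP population
#'
#' Describes the control and treated sib-line cohort whose paired HpaII and
#' MspI profiles [simulate_msap_population()] generates. Each line has one
#' founder methylation-state vector over the loci; treatment acts on
#' founders of *effectively* treated lines by reverting each methylated
#' locus to `UNMETHYLATED` with probability `p_demeth`; individual samples
#' then deviate from their founder by per-locus state resampling with
#' probability `p_epi_noise` (within-line epigenetic variability).
#'
#' Treatment effectiveness is a line-level Bernoulli event
#' (`p_line_effective`), reflecting that chemically induced hypomethylation
#' takes hold in some treated lines and not others; `n_effective_treated`
#' instead fixes the exact number of effective lines (chosen at random
#' among the treated lines).
#'
#' @param n_control_lines,n_treated_lines numbers of sib-lines.
#' @param n_samples_per_line seedlings sampled per line (default 10).
#' @param n_loci scored MSAP loci (default 500).
#' @param state_frequencies probability vector over the four states, in
#'   [METHYLATION_STATES] order; must sum to 1. Default places half the
#'   loci in methylated classes.
#' @param p_demeth probability that a methylated locus of an effective
#'   treated line's founder reverts to `UNMETHYLATED` (default 1: complete
#'   erasure at assayed sites).
#' @param p_epi_noise per-sample per-locus probability of resampling the
#'   state from `state_frequencies` (default 0.02).
#' @param p_line_effective probability a treated line responds to treatment
#'   (default 0.4).
#' @param n_effective_treated optional exact count of effective treated
#'   lines, overriding `p_line_effective`.
#' @param control_generations,treated_generations generation labels
#'   recycled over the control / treated lines (defaults "S2" / "E2").
#' @param rng_seed integer seed consumed by the generator.
#' @return A validated list of class `population_spec`.
#' @export
population_spec <- function(n_control_lines = 4,
                            n_treated_lines = 10,
                            n_samples_per_line = 10,
                            n_loci = 500,
                            state_frequencies = c(0.5, 0.3, 0.1, 0.1),
                            p_demeth = 1,
                            p_epi_noise = 0.02,
                            p_line_effective = 0.4,
                            n_effective_treated = NULL,
                            control_generations = "S2",
                            treated_generations = "E2",
                            rng_seed = 1L) {
  spec <- list(n_control_lines = as.integer(n_control_lines),
               n_treated_lines = as.integer(n_treated_lines),
               n_samples_per_line = as.integer(n_samples_per_line),
               n_loci = as.integer(n_loci),
               state_frequencies = as.numeric(state_frequencies),
               p_demeth = p_demeth,
               p_epi_noise = p_epi_noise,
               p_line_effective = p_line_effective,
               n_effective_treated = n_effective_treated,
               control_generations = control_generations,
               treated_generations = treated_generations,
               rng_seed = as.integer(rng_seed))
  with(spec, {
    if (any(c(n_control_lines, n_treated_lines, n_samples_per_line,
              n_loci) < 1))
      stop("counts must be positive")
    if (length(state_frequencies) != 4 || any(state_frequencies < 0) ||
        abs(sum(state_frequencies) - 1) > 1e-8)
      stop("state_frequencies must be 4 non-negative probabilities summing to 1")
    probs <- c(p_demeth, p_epi_noise, p_line_effective)
    if (any(probs < 0 | probs > 1))
      stop("probabilities must lie in [0, 1]")
    if (!is.null(n_effective_treated) &&
        (n_effective_treated < 0 || n_effective_treated > n_treated_lines))
      stop("n_effective_treated must be between 0 and n_treated_lines")
  })
  structure(spec, class = "population_spec")
}

#' Simulate a paired HpaII/MspI MSAP population
#'
#' Draws founder methylation states for every line, applies stochastic
#' demethylation to the founders of effective treated lines, adds
#' per-sample state noise, and maps every sample's states to the two
#' enzyme band profiles through the deterministic cut table
#' ([band_from_state()]). The two returned matrices share one latent state
#' array, so every sample's HpaII and MspI profiles are consistent.
#'
#' @param spec a [population_spec()].
#' @return A list of class `msap_population`: `hpaii` and `mspi`
#'   (`msap_matrix` objects with identical samples/loci), `lines` (a
#'   data.frame with `line_id`, `generation`, `treated`, and the true
#'   hypomethylation label `effective`), and `spec`.
#' @export
simulate_msap_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$rng_seed)
  n_lines <- spec$n_control_lines + spec$n_treated_lines
  treated <- rep(c(FALSE, TRUE),
                 c(spec$n_control_lines, spec$n_treated_lines))
  line_id <- sprintf("%s%02d", ifelse(treated, "T", "C"),
                     c(seq_len(spec$n_control_lines),
                       seq_len(spec$n_treated_lines)))
  generation <- character(n_lines)
  generation[!treated] <- rep_len(spec$control_generations,
                                  spec$n_control_lines)
  generation[treated] <- rep_len(spec$treated_generations,
                                 spec$n_treated_lines)

  effective <- rep(FALSE, n_lines)
  if (!is.null(spec$n_effective_treated)) {
    pick <- which(treated)[sample.int(sum(treated),
                                      spec$n_effective_treated)]
    effective[pick] <- TRUE
  } else {
    effective[treated] <- stats::runif(spec$n_treated_lines) <
      spec$p_line_effective
  }

  per_line <- spec$n_samples_per_line
  n_samples <- n_lines * per_line
  states <- matrix(0L, n_samples, spec$n_loci)
  row <- 0L
  for (l in seq_len(n_lines)) {
    founder <- sample.int(4L, spec$n_loci, replace = TRUE,
                          prob = spec$state_frequencies)
    if (effective[l]) {
      meth <- founder > 1L
      revert <- meth & (stats::runif(spec$n_loci) < spec$p_demeth)
      founder[revert] <- 1L
    }
    for (s in seq_len(per_line)) {
      row <- row + 1L
      st <- founder
      if (spec$p_epi_noise > 0) {
        flip <- stats::runif(spec$n_loci) < spec$p_epi_noise
        if (any(flip))
          st[flip] <- sample.int(4L, sum(flip), replace = TRUE,
                                 prob = spec$state_frequencies)
      }
      states[row, ] <- st
    }
  }

  sample_ids <- sprintf("%s_s%02d", rep(line_id, each = per_line),
                        rep(seq_len(per_line), n_lines))
  mk <- function(enzyme) {
    vals <- matrix(band_from_state(states, enzyme),
                   n_samples, spec$n_loci)
    msap_matrix(vals, sample_ids = sample_ids,
                line_ids = rep(line_id, each = per_line),
                generations = rep(generation, each = per_line),
                enzyme = enzyme)
  }
  structure(
    list(hpaii = mk("HpaII"), mspi = mk("MspI"),
         lines = data.frame(line_id = line_id, generation = generation,
                            treated = treated, effective = effective,
                            stringsAsFactors = FALSE),
         spec = spec),
    class = "msap_population")
}

#' The 14-line MSAP screening cohort
#'
#' Convenience wrapper reproducing the sampling design of the motivating
#' screen: ten seedlings from each of two S2 and two S3 untreated control
#' lines and five E2 and five E3 treated lines (14 lines, 140 samples per
#' enzyme), with a fixed number of treated lines in which the treatment was
#' actually effective (default 4, as observed in that screen).
#'
#' @param n_effective_treated effective treated lines (default 4).
#' @param rng_seed integer seed.
#' @param ... further arguments passed to [population_spec()].
#' @return A [population_spec()].
#' @export
cohort_spec <- function(n_effective_treated = 4, rng_seed = 1L, ...) {
  population_spec(n_control_lines = 4, n_treated_lines = 10,
                  n_samples_per_line = 10,
                  control_generations = c("S2", "S2", "S3", "S3"),
                  treated_generations = rep(c("E2", "E3"), each = 5),
                  n_effective_treated = n_effective_treated,
                  rng_seed = rng_seed, ...)
}

# ---- dose-response generator ---------------------------------------------

#' Specification of a simulated seed-treatment dose-response experiment
#'
#' @param doses concentrations in mM; must be non-negative and include 0
#'   (the water control). Default is the six-treatment design 0, 0.01,
#'   0.1, 0.5, 1.0, 1.5 mM.
#' @param reps_per_dose replicates per concentration (default 4).
#' @param n_per_rep seedlings per replicate (default 100).
#' @param true_params list with `A` (lower asymptote, %), `b` (rate),
#'   `m` (midpoint dose, mM) of the constrained logistic response
#'   [logistic100()]. Defaults A = 40, b = 2, m = 0.32.
#' @param rng_seed integer seed.
#' @return A validated list of class `dose_response_spec`.
#' @export
dose_response_spec <- function(doses = c(0, 0.01, 0.1, 0.5, 1.0, 1.5),
                               reps_per_dose = 4,
                               n_per_rep = 100,
                               true_params = list(A = 40, b = 2, m = 0.32),
                               rng_seed = 1L) {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (!any(doses == 0)) stop("doses must include the 0 control")
  if (reps_per_dose < 1 || n_per_rep < 1) stop("counts must be positive")
  if (true_params$A < 0 || true_params$A > 100)
    stop("lower asymptote A must lie in [0, 100]")
  if (true_params$b <= 0 || true_params$m <= 0)
    stop("rate b and midpoint m must be positive")
  structure(list(doses = sort(as.numeric(doses)),
                 reps_per_dose = as.integer(reps_per_dose),
                 n_per_rep = as.integer(n_per_rep),
                 true_params = true_params,
                 rng_seed = as.integer(rng_seed)),
            class = "dose_response_spec")
}

#' Simulate binomial dose-response counts on the constrained logistic
#'
#' For each dose and replicate, the number of responding (surviving /
#' phenotypically normal) seedlings is drawn as
#' Binomial(`n_per_rep`, y(dose)/100) with y the constrained logistic
#' [logistic100()] at the spec's true parameters.
#'
#' @param spec a [dose_response_spec()].
#' @return data.frame with columns `dose`, `rep`, `responders`, `total`.
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_response_spec"))
  set.seed(spec$rng_seed)
  y <- logistic100(spec$doses, A = spec$true_params$A,
                   b = spec$true_params$b, m = spec$true_params$m)
  if (any(y < 0 | y > 100)) stop("response curve leaves [0, 100]")
  out <- expand.grid(rep = seq_len(spec$reps_per_dose), dose = spec$doses,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("dose", "rep")]
  out <- out[order(out$dose, out$rep), , drop = FALSE]
  p <- y[match(out$dose, spec$doses)] / 100
  out$responders <- stats::rbinom(nrow(out), spec$n_per_rep, p)
  out$total <- spec$n_per_rep
  rownames(out) <- NULL
  out
}

# ---- trait generator ------------------------------------------------------

#' Specification of simulated sib-line seed traits
#'
#' Defines per-treatment-group means and between/within-line variances for
#' seed area, oil and protein content, and the fatty-acid composition
#' factor model. Fatty-acid line means load on one latent "desaturation"
#' variable per line (the biological picture: lines in which desaturase
#' activity, e.g. FAD2, is up-regulated convert more C18:1 onward, raising
#' linoleic and palmitic fractions at the expense of erucic elongation
#' products). With unit loadings calibrated below the model reproduces the
#' observed line-mean correlation structure (erucic:linoleic r = -0.88,
#' palmitic:linoleic r = 0.75, palmitic:erucic r = -0.74);
#' `latent_desaturation_effect` scales the loadings (0 switches the
#' trade-off off entirely).
#'
#' Default group means and variance components follow the motivating
#' screen: seed area smaller by 0.14 mm^2 in treated lines with between- /
#' within-line variances 0.125 / 0.122 (treated) vs 0.009 / 0.083
#' (control); oil 43.1% vs 48.9%; protein 27.2% vs 23.4%; palmitic
#' 3.24% vs 3.15%, linoleic 19.45% vs 18.82%, erucic 54.19% vs 57.56% of
#' total oil.
#'
#' @param seed_area list of per-group `mean`, `var_between`, `var_within`
#'   (mm^2), elements `control` and `treated`.
#' @param oil,protein lists of per-group `mean`, `var_between` (percent,
#'   dry-matter basis); measured per line with `n_readings` replicate
#'   readings of standard deviation `reading_sd`.
#' @param fatty_acids list with per-group means for `palmitic`,
#'   `linoleic`, `erucic` (% of total oil) and line-mean standard
#'   deviations `sd` (named vector).
#' @param latent_desaturation_effect scalar in [0, 1] scaling the shared
#'   latent desaturation loadings (default 1).
#' @param n_seeds_per_line seeds measured per line for seed area
#'   (default 20).
#' @param n_readings replicate composition readings per line (default 2).
#' @param reading_sd standard deviation of one composition reading about
#'   the line value (default 0.2 percentage points).
#' @param rng_seed integer seed.
#' @return A validated list of class `trait_spec`.
#' @export
trait_spec <- function(
    seed_area = list(
      control = list(mean = 2.75, var_between = 0.009, var_within = 0.083),
      treated = list(mean = 2.61, var_between = 0.125, var_within = 0.122)),
    oil = list(control = list(mean = 48.9, var_between = 1.0),
               treated = list(mean = 43.1, var_between = 4.0)),
    protein = list(control = list(mean = 23.4, var_between = 0.5),
                   treated = list(mean = 27.2, var_between = 2.0)),
    fatty_acids = list(
      control = c(palmitic = 3.15, linoleic = 18.82, erucic = 57.56),
      treated = c(palmitic = 3.24, linoleic = 19.45, erucic = 54.19),
      sd = c(palmitic = 0.30, linoleic = 1.20, erucic = 2.50)),
    latent_desaturation_effect = 1,
    n_seeds_per_line = 20,
    n_readings = 2,
    reading_sd = 0.2,
    rng_seed = 1L) {
  for (g in c("control", "treated")) {
    if (oil[[g]]$mean + protein[[g]]$mean > 100)
      stop("infeasible means: oil + protein exceeds 100% for ", g)
    if (any(fatty_acids[[g]] < 0))
      stop("fatty-acid fractions must be non-negative")
  }
  vars <- c(unlist(lapply(seed_area, function(x)
    c(x$var_between, x$var_within))),
    oil$control$var_between, oil$treated$var_between,
    protein$control$var_between, protein$treated$var_between)
  if (any(vars < 0)) stop("variances must be non-negative")
  if (latent_desaturation_effect < 0)
    stop("latent_desaturation_effect must be non-negative")
  if (reading_sd < 0) stop("reading_sd must be non-negative")
  structure(list(seed_area = seed_area, oil = oil, protein = protein,
                 fatty_acids = fatty_acids,
                 latent_desaturation_effect = latent_desaturation_effect,
                 n_seeds_per_line = as.integer(n_seeds_per_line),
                 n_readings = as.integer(n_readings),
                 reading_sd = reading_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "trait_spec")
}

# Loadings of the single-factor fatty-acid model solving
#   rho_e * rho_l = 0.88, rho_p * rho_l = 0.75, rho_p * rho_e = 0.74
# so that with effect = 1 the implied line-mean correlations are
# r(erucic, linoleic) = -0.88, r(palmitic, linoleic) = +0.75,
# r(palmitic, erucic) = -0.74.
fatty_acid_loadings <- function() {
  rho_l <- sqrt(0.88 * 0.75 / 0.74)
  c(palmitic = 0.75 / rho_l, linoleic = rho_l, erucic = -0.88 / rho_l)
}

#' Simulate a long-format sib-line trait table
#'
#' Seed area is generated seed-by-seed as line effect (between-line
#' variance) plus seed deviation (within-line variance). Oil and protein
#' are line-level values with replicate reading noise. Fatty-acid line
#' means come from the single-latent-factor model described in
#' [trait_spec()].
#'
#' @param spec a [trait_spec()].
#' @param lines data.frame with columns `line_id` and logical `treated`
#'   (e.g. the `lines` element of [simulate_msap_population()], or any
#'   ledger of line ids and treatment flags).
#' @return A long data.frame of class `trait_table` with columns
#'   `line_id`, `treatment` ("control"/"treated"), `sample_id`, `trait`,
#'   `value`, `unit`.
#' @export
simulate_traits <- function(spec, lines) {
  stopifnot(inherits(spec, "trait_spec"))
  if (!all(c("line_id", "treated") %in% names(lines)))
    stop("lines must have columns line_id and treated")
  set.seed(spec$rng_seed)
  grp <- ifelse(lines$treated, "treated", "control")
  n_lines <- nrow(lines)
  rows <- list()

  # seed area: per-seed observations
  sa <- spec$seed_area
  line_eff <- stats::rnorm(n_lines) *
    sqrt(vapply(grp, function(g) sa[[g]]$var_between, numeric(1)))
  for (l in seq_len(n_lines)) {
    g <- grp[l]
    vals <- sa[[g]]$mean + line_eff[l] +
      stats::rnorm(spec$n_seeds_per_line) * sqrt(sa[[g]]$var_within)
    rows[[length(rows) + 1]] <- data.frame(
      line_id = lines$line_id[l], treatment = g,
      sample_id = sprintf("%s_seed%02d", lines$line_id[l],
                          seq_len(spec$n_seeds_per_line)),
      trait = "seed_area", value = vals, unit = "mm2",
      stringsAsFactors = FALSE)
  }

  # oil & protein: line value + replicate reading noise
  for (tr in c("oil", "protein")) {
    ts <- spec[[tr]]
    lv <- vapply(grp, function(g) ts[[g]]$mean, numeric(1)) +
      stats::rnorm(n_lines) *
      sqrt(vapply(grp, function(g) ts[[g]]$var_between, numeric(1)))
    for (l in seq_len(n_lines)) {
      vals <- lv[l] + stats::rnorm(spec$n_readings) * spec$reading_sd
      rows[[length(rows) + 1]] <- data.frame(
        line_id = lines$line_id[l], treatment = grp[l],
        sample_id = sprintf("%s_read%d", lines$line_id[l],
                            seq_len(spec$n_readings)),
        trait = tr, value = vals, unit = "percent_dm",
        stringsAsFactors = FALSE)
    }
  }

  # fatty acids: line means from the latent desaturation factor
  fa <- spec$fatty_acids
  load <- fatty_acid_loadings() * spec$latent_desaturation_effect
  latent <- stats::rnorm(n_lines)
  for (acid in c("palmitic", "linoleic", "erucic")) {
    sd_a <- fa$sd[[acid]]
    rho <- min(abs(load[[acid]]), 1)
    resid_sd <- sd_a * sqrt(max(0, 1 - rho^2))
    vals <- vapply(grp, function(g) fa[[g]][[acid]], numeric(1)) +
      sign(load[[acid]]) * rho * sd_a * latent +
      stats::rnorm(n_lines) * resid_sd
    vals <- pmax(vals, 0)
    rows[[length(rows) + 1]] <- data.frame(
      line_id = lines$line_id, treatment = grp,
      sample_id = paste0(lines$line_id, "_fa"),
      trait = acid, value = vals, unit = "percent_oil",
      stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

# ---- pedigree -------------------------------------------------------------

#' Build the accession ledger of an epimutagenesis population
#'
#' Book-keeping of the population design: each E1 plant contributes
#' `siliques_per_plant` independently harvested silique accessions plus
#' `pooled_per_plant` pooled-seed accessions (so E2 accessions per plant =
#' siliques + pools); a subset of `n_selected_lines` E1 plants is then
#' advanced by sowing `seeds_sown_per_selected_line` seeds each, giving the
#' E2 plants.
#'
#' @param n_e1 number of E1 plants harvested.
#' @param siliques_per_plant independently harvested siliques per plant.
#' @param pooled_per_plant pooled accessions per plant (usually 1).
#' @param n_selected_lines E1 plants selected for advancement (capped at
#'   `n_e1`).
#' @param seeds_sown_per_selected_line seeds sown per selected line.
#' @return data.frame ledger with columns `accession_id`, `generation`
#'   ("E1", "E2_seed", "E2_plant"), `parent`, `source_type` ("plant",
#'   "silique", "pool", "seed"); all ids unique.
#' @export
build_population_pedigree <- function(n_e1,
                                      siliques_per_plant = 3,
                                      pooled_per_plant = 1,
                                      n_selected_lines = 0,
                                      seeds_sown_per_selected_line = 0) {
  args <- c(n_e1, siliques_per_plant, pooled_per_plant, n_selected_lines,
            seeds_sown_per_selected_line)
  if (any(args < 0)) stop("counts must be non-negative")
  empty <- data.frame(accession_id = character(), generation = character(),
                      parent = character(), source_type = character(),
                      stringsAsFactors = FALSE)
  if (n_e1 == 0) return(empty)
  e1_ids <- sprintf("E1_%04d", seq_len(n_e1))
  ledger <- list(data.frame(accession_id = e1_ids, generation = "E1",
                            parent = NA_character_, source_type = "plant",
                            stringsAsFactors = FALSE))
  per_plant <- siliques_per_plant + pooled_per_plant
  if (per_plant > 0) {
    src <- c(rep("silique", siliques_per_plant),
             rep("pool", pooled_per_plant))
    ledger[[2]] <- data.frame(
      accession_id = sprintf("%s_a%d", rep(e1_ids, each = per_plant),
                             rep(seq_len(per_plant), n_e1)),
      generation = "E2_seed",
      parent = rep(e1_ids, each = per_plant),
      source_type = rep(src, n_e1),
      stringsAsFactors = FALSE)
  }
  n_sel <- min(n_selected_lines, n_e1)
  if (n_sel > 0 && seeds_sown_per_selected_line > 0) {
    sel <- e1_ids[seq_len(n_sel)]
    ledger[[length(ledger) + 1]] <- data.frame(
      accession_id = sprintf("%s_p%02d",
                             rep(sel, each = seeds_sown_per_selected_line),
                             rep(seq_len(seeds_sown_per_selected_line),
                                 n_sel)),
      generation = "E2_plant",
      parent = rep(sel, each = seeds_sown_per_selected_line),
      source_type = "seed",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ledger)
  stopifnot(!anyDuplicated(out$accession_id))
  rownames(out) <- NULL
  out
}
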