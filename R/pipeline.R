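#' Run the full simulate -> screen -> dose-response -> traits pipeline
#'
#' Orchestrates every stage of the hypomethylated-population analysis on
#' synthetic data under one configuration and one global seed, writing all
#' stage outputs plus a checksum manifest into a run directory. Stages run
#' in a fixed order and draw per-stage seeds derived from the global seed,
#' so a rerun with the same configuration reproduces every file
#' bit-for-bit. A stage failure is recorded in the manifest and does not
#' destroy the outputs of earlier stages.
#'
#' @param config either a list or a path to a JSON file. Recognised
#'   top-level fields (all optional except `seed`):
#'   \describe{
#'     \item{seed}{integer, the global seed (required).}
#'     \item{population}{arguments for [population_spec()] (without
#'       `rng_seed`).}
#'     \item{dose}{arguments for [dose_response_spec()] (without
#'       `rng_seed`).}
#'     \item{traits}{arguments for [trait_spec()] (without `rng_seed`).}
#'     \item{screen}{list with `alpha` (default 0.05) and
#'       `n_permutations` (default 9999).}
#'     \item{pedigree}{arguments for [build_population_pedigree()];
#'       omitted unless given.}
#'   }
#' @param out_dir run directory (created if missing).
#' @param verbose print stage progress (default TRUE).
#' @return Invisibly, a list with `manifest` (data.frame: file, stage,
#'   status, md5), `screen`, `dose_fit`, `dose_report`, `trait_summary`
#'   and the resolved `config`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed))
    stop("config validation: missing required field 'seed'")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  # per-stage seeds derived once from the global seed, in documented order:
  # 1 population, 2 dose, 3 traits, 4 screen permutations
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max %/% 2L, 4)

  manifest <- data.frame(file = character(), stage = character(),
                         status = character(), md5 = character(),
                         stringsAsFactors = FALSE)
  record <- function(files, stage, status = "ok") {
    sums <- if (status == "ok") unname(tools::md5sum(files))
            else rep(NA_character_, length(files))
    manifest <<- rbind(manifest,
                       data.frame(file = basename(files), stage = stage,
                                  status = status, md5 = sums,
                                  stringsAsFactors = FALSE))
  }
  results <- list(config = config)
  failed <- character()
  run_stage <- function(stage, fn) {
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      say(sprintf("stage %s FAILED: %s", stage, conditionMessage(out)))
      record(file.path(out_dir, paste0(stage, ".failed")), stage, "failed")
      failed <<- c(failed, stage)
      NULL
    } else out
  }

  ## stage: simulate ---------------------------------------------------
  say("stage simulate: generating MSAP population, dose-response and traits")
  sim <- run_stage("simulate", function() {
    pop_spec <- do.call(population_spec,
                        c(config$population, list(rng_seed = stage_seeds[1])))
    pop <- simulate_msap_population(pop_spec)
    write_msap(pop$hpaii, file.path(out_dir, "msap_hpaii.tsv"))
    write_msap(pop$mspi, file.path(out_dir, "msap_mspi.tsv"))
    utils::write.csv(pop$lines, file.path(out_dir, "lines.csv"),
                     row.names = FALSE)
    dspec <- do.call(dose_response_spec,
                     c(config$dose, list(rng_seed = stage_seeds[2])))
    dose_tab <- simulate_dose_response(dspec)
    utils::write.csv(dose_tab, file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE)
    tspec <- do.call(trait_spec,
                     c(config$traits, list(rng_seed = stage_seeds[3])))
    traits <- simulate_traits(tspec, pop$lines)
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    files <- file.path(out_dir, c("msap_hpaii.tsv", "msap_mspi.tsv",
                                  "lines.csv", "dose_response.csv",
                                  "traits.csv"))
    if (!is.null(config$pedigree)) {
      ped <- do.call(build_population_pedigree, config$pedigree)
      utils::write.csv(ped, file.path(out_dir, "pedigree.csv"),
                       row.names = FALSE)
      files <- c(files, file.path(out_dir, "pedigree.csv"))
    }
    record(files, "simulate")
    list(pop = pop, dose = dose_tab, traits = traits)
  })

  ## stage: pcoa --------------------------------------------------------
  if (!is.null(sim)) {
    say("stage pcoa: ordination of combined enzyme profiles")
    run_stage("pcoa", function() {
      both <- rbind(sim$pop$hpaii$values, sim$pop$mspi$values)
      rownames(both) <- c(paste0(rownames(sim$pop$hpaii$values), "_H"),
                          paste0(rownames(sim$pop$mspi$values), "_M"))
      d <- msap_dist(both, metric = "euclidean")
      p <- pcoa(d, n_axes = 4)
      coords <- data.frame(sample = rownames(p$coordinates),
                           enzyme = rep(c("HpaII", "MspI"),
                                        each = nrow(sim$pop$hpaii$values)),
                           line = rep(sim$pop$hpaii$samples$line_id, 2),
                           p$coordinates)
      utils::write.csv(coords, file.path(out_dir, "pcoa_coordinates.csv"),
                       row.names = FALSE)
      eig <- data.frame(axis = seq_along(p$eigenvalues),
                        eigenvalue = p$eigenvalues)
      utils::write.csv(eig, file.path(out_dir, "pcoa_eigenvalues.csv"),
                       row.names = FALSE)
      cent <- group_centroids(p, paste(coords$line, coords$enzyme))
      utils::write.csv(data.frame(group = rownames(cent), cent),
                       file.path(out_dir, "pcoa_centroids.csv"),
                       row.names = FALSE)
      record(file.path(out_dir, c("pcoa_coordinates.csv",
                                  "pcoa_eigenvalues.csv",
                                  "pcoa_centroids.csv")), "pcoa")
      NULL
    })

    ## stage: screen ----------------------------------------------------
    say("stage screen: per-line isoschizomer-divergence AMOVA")
    results$screen <- run_stage("screen", function() {
      sc <- config$screen
      scr <- screen_lines(sim$pop$hpaii, sim$pop$mspi,
                          alpha = if (is.null(sc$alpha)) 0.05 else sc$alpha,
                          n_permutations = if (is.null(sc$n_permutations))
                            9999 else sc$n_permutations,
                          seed = stage_seeds[4])
      utils::write.csv(as.data.frame(scr),
                       file.path(out_dir, "screen.csv"), row.names = FALSE)
      record(file.path(out_dir, "screen.csv"), "screen")
      scr
    })

    ## stage: doseresponse ------------------------------------------------
    say("stage doseresponse: constrained logistic fit and F-tests")
    dr <- run_stage("doseresponse", function() {
      fit1 <- fit_dose_response(sim$dose, estimate_lower_asymptote = TRUE)
      fit0 <- fit_dose_response(sim$dose, estimate_lower_asymptote = FALSE)
      at <- asymptote_test(fit1, fit0)
      lof <- lack_of_fit_test(fit1)
      rep_d <- report_doses(fit1)
      params <- data.frame(
        quantity = c("A", "b", "m", "residual_ss",
                     "asymptote_F", "asymptote_p",
                     "lack_of_fit_F", "lack_of_fit_p", "n_obs",
                     "dose_at_absolute_50", "half_reduction_dose",
                     "survival_at_half_reduction"),
        value = c(fit1$A, fit1$b, fit1$m, fit1$residual_ss,
                  at$F, at$p_value, lof$F, lof$p_value, lof$n_obs,
                  rep_d$dose_at_absolute_50, rep_d$half_reduction_dose,
                  rep_d$survival_at_half_reduction))
      utils::write.csv(params, file.path(out_dir, "dose_fit.csv"),
                       row.names = FALSE)
      grid <- seq(0, max(sim$dose$dose), length.out = 200)
      curve_tab <- data.frame(
        dose = grid,
        fitted_percent = logistic100(grid, fit1$A, fit1$b, fit1$m))
      utils::write.csv(curve_tab, file.path(out_dir, "dose_curve.csv"),
                       row.names = FALSE)
      record(file.path(out_dir, c("dose_fit.csv", "dose_curve.csv")),
             "doseresponse")
      list(fit = fit1, asymptote = at, lack_of_fit = lof, report = rep_d)
    })
    results$dose_fit <- dr$fit
    results$dose_report <- dr$report

    ## stage: traits ------------------------------------------------------
    say("stage traits: variance decomposition, contrasts, correlations")
    results$trait_summary <- run_stage("traits", function() {
      tt <- sim$traits
      vc_rows <- do.call(rbind, lapply(c("control", "treated"), function(g) {
        vc <- variance_components(tt, "seed_area",
                                  subset = tt$treatment == g)
        data.frame(group = g, trait = "seed_area",
                   between = vc$between, within = vc$within)
      }))
      utils::write.csv(vc_rows,
                       file.path(out_dir, "trait_variance_components.csv"),
                       row.names = FALSE)
      ctr <- do.call(rbind, lapply(c("seed_area", "oil", "protein"),
                                   function(tr) {
        gc <- group_contrast(tt, tr)
        data.frame(trait = tr, estimate = gc$estimate, se = gc$se,
                   wald = gc$wald, p_value = gc$p_value)
      }))
      utils::write.csv(ctr, file.path(out_dir, "trait_contrasts.csv"),
                       row.names = FALSE)
      fa <- trait_correlations(tt, c("palmitic", "linoleic", "erucic"))
      utils::write.csv(data.frame(trait = rownames(fa$r), round(fa$r, 4)),
                       file.path(out_dir, "fatty_acid_correlations.csv"),
                       row.names = FALSE)
      bx <- do.call(rbind, lapply(c("seed_area", "oil", "protein"),
                                  function(tr)
        cbind(trait = tr, boxplot_summary(tt, tr))))
      utils::write.csv(bx, file.path(out_dir, "trait_boxplots.csv"),
                       row.names = FALSE)
      record(file.path(out_dir,
                       c("trait_variance_components.csv",
                         "trait_contrasts.csv",
                         "fatty_acid_correlations.csv",
                         "trait_boxplots.csv")), "traits")
      list(variance_components = vc_rows, contrasts = ctr,
           correlations = fa$r)
    })
  }

  run_info <- c(sprintf("seed: %d", seed),
                sprintf("timestamp: %s",
                        format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                sprintf("stages_failed: %s",
                        if (length(failed)) paste(failed, collapse = ",")
                        else "none"))
  writeLines(run_info, file.path(out_dir, "run_log.txt"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  results$manifest <- manifest
  results$failed <- failed
  invisible(results)
}
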