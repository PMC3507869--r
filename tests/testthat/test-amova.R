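test_that("identical groups give PhiPT 0 and fixed groups give PhiPT 1", {
  # two groups that are the same multiset of profiles: Va <= 0, clamped
  prof <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1, 0, 0))
  x <- rbind(prof, prof)
  rownames(x) <- paste0("s", 1:6)
  d <- msap_dist(x, "squared_euclidean")
  a <- amova(d, rep(c("A", "B"), each = 3))
  expect_lte(a$Va, 0)
  expect_identical(a$phi_pt, 0)

  # internally identical groups differing between: Vw = 0, PhiPT = 1
  y <- rbind(matrix(rep(c(1, 0, 1, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0, 1), 3), 3, byrow = TRUE))
  rownames(y) <- paste0("s", 1:6)
  a2 <- amova(msap_dist(y, "squared_euclidean"), rep(c("A", "B"), each = 3))
  expect_identical(a2$Vw, 0)
  expect_identical(a2$phi_pt, 1)
})

test_that("AMOVA matches an independent brute-force oracle", {
  set.seed(40)
  for (k in 1:10) {
    g <- sample(2:3, 1)
    sizes <- sample(2:5, g, replace = TRUE)
    x <- random_binary(sum(sizes), 8, seed = 40 + k)
    grp <- rep(seq_len(g), sizes)
    a <- amova(msap_dist(x, "squared_euclidean"), grp)
    o <- brute_amova(x, grp)
    expect_equal(a$ss_total, o$ss_total, tolerance = 1e-12)
    expect_equal(a$ss_within, o$ss_within, tolerance = 1e-12)
    expect_equal(a$ss_among, o$ss_among, tolerance = 1e-12)
    expect_equal(a$Va, o$Va, tolerance = 1e-12)
    expect_equal(a$Vw, o$Vw, tolerance = 1e-12)
    expect_equal(a$phi_pt, o$phi_pt, tolerance = 1e-12)
    # decomposition conservation
    expect_lt(abs(a$ss_among + a$ss_within - a$ss_total), 1e-9)
  }
})

test_that("AMOVA sums of squares agree with vegan's partition", {
  x <- random_binary(12, 15, seed = 77)
  grp <- rep(c("A", "B", "C"), each = 4)
  a <- amova(msap_dist(x, "squared_euclidean"), grp)
  perm <- vegan::adonis2(stats::dist(x) ~ g,
                         data = data.frame(g = grp), permutations = 2)
  expect_equal(a$ss_among, perm$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(a$ss_within, perm$SumOfSqs[2], tolerance = 1e-9)
})

test_that("AMOVA validates its grouping", {
  x <- random_binary(5, 6, seed = 1)
  d <- msap_dist(x, "squared_euclidean")
  expect_error(amova(d, c("A", "A", "A", "A", "B")), "size 1")
  expect_error(amova(d, rep("A", 5)), "at least 2 groups")
})

test_that("PhiPT is invariant to relabelling within groups and to locus order", {
  x <- random_binary(10, 30, seed = 9)
  grp <- rep(c("A", "B"), each = 5)
  a <- amova(msap_dist(x, "squared_euclidean"), grp)
  # permute sample order within groups
  ord <- c(sample(1:5), sample(6:10))
  a2 <- amova(msap_dist(x[ord, ], "squared_euclidean"), grp)
  expect_equal(a$phi_pt, a2$phi_pt, tolerance = 1e-12)
  # permute loci
  a3 <- amova(msap_dist(x[, sample(1:30)], "squared_euclidean"), grp)
  expect_equal(a$phi_pt, a3$phi_pt, tolerance = 1e-12)
})

test_that("SSWP matches its closed form and brute force", {
  # two samples at squared distance 4 -> 4/2 = 2
  x <- rbind(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 0))
  rownames(x) <- c("a", "b")
  d <- msap_dist(x, "squared_euclidean")
  expect_equal(sswp(d, c("a", "b")), 2)
  # internally identical group -> 0
  y <- rbind(c(1, 0), c(1, 0), c(1, 0))
  rownames(y) <- paste0("s", 1:3)
  expect_equal(sswp(msap_dist(y, "squared_euclidean"), 1:3), 0)
  expect_error(sswp(d, "a"), "at least 2")
  # brute-force double sum on a random group
  z <- random_binary(6, 12, seed = 55)
  dz <- msap_dist(z, "squared_euclidean")
  acc <- 0
  for (i in 1:5) for (j in (i + 1):6) acc <- acc + sum((z[i, ] - z[j, ])^2)
  expect_equal(sswp(dz, 1:6), acc / 6)
})

test_that("permutation p is exact for degenerate data and reproducible", {
  # all samples identical: every permuted statistic equals the observed
  x <- matrix(1L, 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  d <- msap_dist(x, "squared_euclidean")
  a <- amova_permutation(d, rep(c("A", "B"), each = 3),
                         n_permutations = 99, seed = 1)
  expect_identical(a$p_value, 1)
  expect_error(amova_permutation(d, rep(c("A", "B"), each = 3),
                                 n_permutations = 0), "at least 1")
  # seeded reproducibility
  y <- random_binary(8, 10, seed = 3)
  dy <- msap_dist(y, "squared_euclidean")
  p1 <- amova_permutation(dy, rep(1:2, each = 4), 199, seed = 5)
  p2 <- amova_permutation(dy, rep(1:2, each = 4), 199, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$perm_phi_pt, p2$perm_phi_pt)
})

test_that("Monte-Carlo permutation p tracks the exhaustive enumeration", {
  # 4 samples split 2+2: only choose(4,2) = 6 label assignments exist
  x <- rbind(c(1, 1, 1, 0, 0), c(1, 1, 0, 0, 1),
             c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0))
  rownames(x) <- paste0("s", 1:4)
  d <- msap_dist(x, "squared_euclidean")
  obs <- amova(d, c("A", "A", "B", "B"))$phi_pt
  combos <- utils::combn(4, 2)
  phis <- apply(combos, 2, function(g1) {
    grp <- ifelse(seq_len(4) %in% g1, "A", "B")
    amova(d, grp)$phi_pt
  })
  p_exact <- mean(phis >= obs - 1e-12)
  n_perm <- 4999
  p_mc <- amova_permutation(d, c("A", "A", "B", "B"), n_perm,
                            seed = 8)$p_value
  # binomial 99% bound around the exact p (plus add-one offset)
  bound <- 2.58 * sqrt(p_exact * (1 - p_exact) / n_perm) + 2 / (n_perm + 1)
  expect_lt(abs(p_mc - p_exact), bound)
})

test_that("a fully demethylated line is flagged and a methylated one is not", {
  # all-CG loci erased by treatment: enzyme profiles coincide, PhiPT = 0
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 1, n_treated_lines = 1,
                    n_samples_per_line = 6, n_loci = 120,
                    state_frequencies = c(0.4, 0.6, 0, 0),
                    p_demeth = 1, p_epi_noise = 0.02,
                    n_effective_treated = 1, rng_seed = 14))
  scr <- screen_lines(pop$hpaii, pop$mspi, n_permutations = 499, seed = 2)
  flagged <- scr$line_id[scr$classified_hypomethylated]
  treated_line <- pop$lines$line_id[pop$lines$treated]
  control_line <- pop$lines$line_id[!pop$lines$treated]
  expect_identical(flagged, treated_line)
  expect_lt(scr$phi_pt[scr$line_id == treated_line], 0.1)
  # the methylated control line is highly significantly divergent
  expect_gt(scr$phi_pt[scr$line_id == control_line], 0.5)
  expect_lte(scr$p_value[scr$line_id == control_line], 0.05)
  # results sorted by phi_pt ascending, SSWP reported per enzyme
  expect_true(!is.unsorted(scr$phi_pt))
  expect_true(all(c("sswp_hpaii", "sswp_mspi") %in% names(scr)))
})

test_that("screening rejects unpaired matrices", {
  pop <- simulate_msap_population(
    population_spec(n_control_lines = 1, n_treated_lines = 1,
                    n_samples_per_line = 3, n_loci = 20, rng_seed = 2))
  broken <- pop$mspi
  broken$samples$sample_id[1] <- "other"
  expect_error(screen_lines(pop$hpaii, broken), "identical sample ids")
  expect_error(check_paired_msap(pop$hpaii, pop$hpaii), "isoschizomers")
})
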