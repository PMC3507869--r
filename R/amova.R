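#' Analysis of molecular variance (AMOVA) for one grouping level
#'
#' Partitions the squared pairwise distances among samples into among-group
#' and within-group sums of squares and converts the mean squares into
#' variance components, following the standard binary-marker AMOVA used by
#' GenAlEx:
#'
#' \deqn{SS_{tot} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
#'       SS_{wp} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}}
#'
#' with \eqn{SS_{ap} = SS_{tot} - SS_{wp}}, \eqn{df_{ap} = G-1},
#' \eqn{df_{wp} = N-G}, \eqn{V_w = MS_{wp}}, \eqn{V_a = (MS_{ap}-V_w)/n_0}
#' where \eqn{n_0 = (N - \sum_g n_g^2/N)/(G-1)} is the average-group-size
#' coefficient, and
#' \eqn{\Phi_{PT} = \max(0,V_a) / (\max(0,V_a) + V_w)} — the fixation-index
#' analogue for binary epigenetic/marker data.
#'
#' @param d an `msap_dist` (either metric; squared distances are used) or a
#'   symmetric matrix of squared distances.
#' @param grouping vector of group labels, one per sample.
#' @return A list of class `amova_result` with elements `ss_among`,
#'   `ss_within`, `ss_total`, `df_among`, `df_within`, `ms_among`,
#'   `ms_within`, `Va`, `Vw`, `n0`, `phi_pt`, `sswp_per_group`,
#'   `group_sizes`. `p_value` and `n_permutations` are `NA` until
#'   [amova_permutation()] fills them.
#' @seealso [amova_permutation()], [sswp()], [screen_lines()]
#' @export
amova <- function(d, grouping) {
  d2 <- if (inherits(d, "msap_dist")) squared_dist(d) else unclass(d)
  check_distance(structure(sqrt(pmax(d2, 0)), class = "matrix"))
  f <- factor(grouping)
  if (length(f) != nrow(d2)) stop("grouping must label every sample")
  sizes <- as.integer(table(f))
  if (nlevels(f) < 2) stop("AMOVA needs at least 2 groups")
  if (any(sizes < 2))
    stop("group of size 1 (zero within-group degrees of freedom): ",
         paste(levels(f)[sizes < 2], collapse = ", "))
  n <- length(f)
  g <- nlevels(f)
  idx <- split(seq_len(n), f)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  sswp_g <- vapply(idx, function(i) {
    sub <- d2[i, i, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(i)
  }, numeric(1))
  ss_within <- sum(sswp_g)
  ss_among <- ss_total - ss_within
  df_among <- g - 1L
  df_within <- n - g
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / df_among
  vw <- ms_within
  va <- (ms_among - vw) / n0
  phi <- if (max(0, va) + vw <= 0) 0 else max(0, va) / (max(0, va) + vw)
  structure(
    list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
         df_among = df_among, df_within = df_within,
         ms_among = ms_among, ms_within = ms_within,
         Va = va, Vw = vw, n0 = n0,
         phi_pt = phi,
         sswp_per_group = sswp_g, group_sizes = stats::setNames(sizes, levels(f)),
         p_value = NA_real_, n_permutations = NA_integer_),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(
    df = c(x$df_among, x$df_within),
    SS = c(x$ss_among, x$ss_within),
    MS = c(x$ms_among, x$ms_within),
    `Est. var.` = c(max(0, x$Va), x$Vw),
    row.names = c("Among groups", "Within groups"), check.names = FALSE)
  print(tab, digits = 4)
  cat(sprintf("PhiPT = %.4f", x$phi_pt))
  if (!is.na(x$p_value))
    cat(sprintf("  (P = %.4g, %d permutations)", x$p_value,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

# PhiPT alone from a squared-distance matrix and a 0-based membership split;
# used in the permutation loop where the full bookkeeping is not needed.
phi_pt_stat <- function(d2, idx_list, n, g, n0_df) {
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (i in idx_list) {
    sub <- d2[i, i, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(i)
  }
  ms_among <- (ss_total - ss_within) / (g - 1L)
  ms_within <- ss_within / (n - g)
  va <- (ms_among - ms_within) / n0_df
  denom <- max(0, va) + ms_within
  if (denom <= 0) 0 else max(0, va) / denom
}

#' Permutation test of PhiPT
#'
#' Sample labels are shuffled across groups (group sizes preserved), PhiPT
#' recomputed for each shuffle, and significance taken as the probability
#' of a permuted statistic at least as large as the observed one, with the
#' add-one convention \eqn{p = (b + 1)/(n_{perm} + 1)} where \eqn{b} counts
#' permutations with \eqn{\Phi_{PT}^{perm} \ge \Phi_{PT}^{obs}}. With 9,999
#' permutations the smallest attainable p is therefore 0.0001.
#'
#' @inheritParams amova
#' @param n_permutations number of label shuffles (default 9999).
#' @param seed integer seed for the shuffles.
#' @return The `amova_result` for the observed grouping with `p_value` and
#'   `n_permutations` filled in, plus `perm_phi_pt` (the permuted values).
#' @export
amova_permutation <- function(d, grouping, n_permutations = 9999,
                              seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  obs <- amova(d, grouping)
  d2 <- if (inherits(d, "msap_dist")) squared_dist(d) else unclass(d)
  f <- factor(grouping)
  n <- length(f)
  g <- nlevels(f)
  sizes <- as.integer(table(f))
  n0 <- (n - sum(sizes^2) / n) / (g - 1L)
  if (!is.null(seed)) set.seed(seed)
  breaks <- rep.int(seq_len(g), sizes)
  perm_phi <- vapply(seq_len(n_permutations), function(k) {
    shuffled <- sample.int(n)
    phi_pt_stat(d2, split(shuffled, breaks), n, g, n0)
  }, numeric(1))
  b <- sum(perm_phi >= obs$phi_pt - 1e-12)
  obs$p_value <- (b + 1) / (n_permutations + 1)
  obs$n_permutations <- as.integer(n_permutations)
  obs$perm_phi_pt <- perm_phi
  obs
}

#' Sum of squares within one group (SSWP)
#'
#' \eqn{SSWP_g = \frac{1}{n_g} \sum_{i<j \in g} d^2_{ij}} — the AMOVA
#' within-population sum of squares for a single group, used as a measure
#' of intra-line epigenetic variability.
#'
#' @inheritParams amova
#' @param group indices or sample ids of the group's members (at least 2).
#' @return Numeric scalar.
#' @export
sswp <- function(d, group) {
  d2 <- if (inherits(d, "msap_dist")) squared_dist(d) else unclass(d)
  if (is.character(group)) group <- match(group, rownames(d2))
  if (anyNA(group)) stop("unknown sample id in group")
  if (length(group) < 2) stop("SSWP needs a group of at least 2 samples")
  sub <- d2[group, group, drop = FALSE]
  sum(sub[upper.tri(sub)]) / length(group)
}

#' Screen lines for effective hypomethylation by isoschizomer divergence
#'
#' For each sib-line, the line's HpaII samples and its MspI samples form
#' the two groups of a two-group AMOVA on squared Euclidean band distances.
#' In a methylated (untreated or ineffectively treated) line the two
#' digests differ systematically at CG-methylated CCGG sites, so PhiPT is
#' large and the permutation test significant; in an effectively
#' hypomethylated line the two profiles converge, PhiPT falls towards 0 and
#' the test loses significance. A line is flagged hypomethylated when its
#' permutation p-value exceeds `alpha` (failure to detect enzyme
#' divergence).
#'
#' @param hpaii,mspi paired `msap_matrix` objects (same samples, same loci).
#' @param alpha significance level for the divergence call (default 0.05).
#' @param n_permutations permutations per line (default 9999).
#' @param seed integer seed; per-line streams are derived from it.
#' @return A data.frame of class `line_screen` with one row per line,
#'   sorted by `phi_pt` ascending: `line_id`, `generation`, `n_samples`,
#'   `phi_pt`, `p_value`, `classified_hypomethylated`, `sswp_hpaii`,
#'   `sswp_mspi`. Attributes record `alpha`, `n_permutations`, `seed`.
#' @export
screen_lines <- function(hpaii, mspi, alpha = 0.05, n_permutations = 9999,
                         seed = NULL) {
  check_paired_msap(hpaii, mspi)
  lines <- unique(hpaii$samples$line_id)
  if (!is.null(seed)) set.seed(seed)
  line_seeds <- sample.int(.Machine$integer.max, length(lines))
  res <- lapply(seq_along(lines), function(li) {
    ln <- lines[li]
    keep <- hpaii$samples$line_id == ln
    if (sum(keep) < 2)
      stop("line ", ln, " has fewer than 2 samples per enzyme")
    vals <- rbind(hpaii$values[keep, , drop = FALSE],
                  mspi$values[keep, , drop = FALSE])
    rownames(vals) <- c(paste0(hpaii$samples$sample_id[keep], "_H"),
                        paste0(mspi$samples$sample_id[keep], "_M"))
    d <- msap_dist(vals, metric = "squared_euclidean")
    grp <- rep(c("HpaII", "MspI"), each = sum(keep))
    am <- amova_permutation(d, grp, n_permutations = n_permutations,
                            seed = line_seeds[li])
    data.frame(line_id = ln,
               generation = hpaii$samples$generation[keep][1],
               n_samples = sum(keep),
               phi_pt = am$phi_pt,
               p_value = am$p_value,
               classified_hypomethylated = am$p_value > alpha,
               sswp_hpaii = am$sswp_per_group[["HpaII"]],
               sswp_mspi = am$sswp_per_group[["MspI"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$phi_pt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("line_screen", "data.frame")
  out
}

#' @export
print.line_screen <- function(x, ...) {
  cat(sprintf(
    "Isoschizomer-divergence screen: %d lines, %d permutations, alpha = %g\n",
    nrow(x), attr(x, "n_permutations"), attr(x, "alpha")))
  cat(sprintf("Flagged hypomethylated: %d\n",
              sum(x$classified_hypomethylated)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
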