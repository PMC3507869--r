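#' One-way between/within-line variance decomposition
#'
#' Method-of-moments (one-way random effects) decomposition of a trait
#' into between-line and within-line variance components, the forward
#' screen's summary of how much a treatment has inflated line-to-line
#' variation relative to seed-to-seed variation:
#' within = pooled within-line mean square; between =
#' \eqn{(MS_{between} - MS_{within}) / \tilde n} with
#' \eqn{\tilde n = (N - \sum_g n_g^2/N)/(G-1)} the average-group-size
#' coefficient for unbalanced data, clamped at 0 (flagged) when the moment
#' estimate is negative.
#'
#' @param table a long trait table (columns `line_id`, `trait`, `value`;
#'   see [simulate_traits()]), or any data.frame with those columns.
#' @param trait trait name to decompose.
#' @param grouping column defining the lines (default `"line_id"`).
#' @param subset optional logical vector on the rows of `table` (e.g. one
#'   treatment group).
#' @return List of class `variance_decomposition`: `between`, `within`,
#'   `clamped`, `ms_between`, `ms_within`, `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `n_tilde`, `group_means`, `grand_mean`,
#'   `n_lines`, `n_obs`.
#' @export
variance_components <- function(table, trait, grouping = "line_id",
                                subset = NULL) {
  df <- as.data.frame(table)
  if (!is.null(subset)) df <- df[subset, , drop = FALSE]
  if ("trait" %in% names(df)) df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no observations for trait ", trait)
  y <- df$value
  g <- factor(df[[grouping]])
  sizes <- as.integer(base::table(g))
  if (nlevels(g) < 2)
    stop("variance decomposition needs at least 2 lines")
  if (all(sizes < 2))
    stop("at least one line needs 2 or more observations")
  n <- length(y)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_between <- k - 1L
  df_within <- n - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  n_tilde <- (n - sum(sizes^2) / n) / df_between
  between_raw <- (ms_between - ms_within) / n_tilde
  structure(
    list(between = max(0, between_raw), within = ms_within,
         clamped = between_raw < 0,
         ms_between = ms_between, ms_within = ms_within,
         ss_between = ss_between, ss_within = ss_within,
         df_between = df_between, df_within = df_within,
         n_tilde = n_tilde,
         group_means = means, grand_mean = grand,
         n_lines = k, n_obs = n),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("One-way variance decomposition\n")
  cat(sprintf("  between-line variance: %.4g%s\n", x$between,
              if (x$clamped) " (clamped from negative estimate)" else ""))
  cat(sprintf("  within-line variance:  %.4g\n", x$within))
  cat(sprintf("  %d lines, %d observations\n", x$n_lines, x$n_obs))
  invisible(x)
}

#' Treatment contrast with line-clustered standard error
#'
#' Difference of group means for one trait (second factor level minus
#' first), with a cluster-robust standard error that treats sib-lines as
#' the independent units (seeds within a line are correlated), and the
#' Wald statistic \eqn{(\hat\delta/\widehat{se})^2} referred to
#' \eqn{\chi^2_1}.
#'
#' @inheritParams variance_components
#' @param factor column splitting the samples into the two groups
#'   (default `"treatment"`).
#' @param cluster column defining the independent clusters (default
#'   `"line_id"`).
#' @return List of class `group_contrast`: `estimate`, `se`, `wald`,
#'   `p_value`, `levels` (contrast direction), `group_means`,
#'   `degenerate` (TRUE when the robust variance vanishes).
#' @export
group_contrast <- function(table, trait, factor = "treatment",
                           cluster = "line_id") {
  df <- as.data.frame(table)
  if ("trait" %in% names(df)) df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no observations for trait ", trait)
  f <- factor(df[[factor]])
  if (nlevels(f) != 2) stop("contrast requires exactly two groups, found ",
                            nlevels(f))
  if (any(base::table(f) == 0)) stop("empty group")
  fit <- stats::lm(value ~ f, data = data.frame(value = df$value, f = f))
  est <- unname(stats::coef(fit)[2])
  # zero-residual fits trip a harmless "perfect fit" warning inside the
  # meat computation; degeneracy is flagged explicitly below instead
  vc <- suppressWarnings(sandwich::vcovCL(fit, cluster = df[[cluster]]))
  se <- sqrt(vc[2, 2])
  degenerate <- !is.finite(se) || se < .Machine$double.eps^0.5 * max(1, abs(est))
  wald <- if (degenerate && est != 0) Inf else (est / se)^2
  list(estimate = est, se = se, wald = wald,
       p_value = if (is.finite(wald))
         stats::pchisq(wald, 1, lower.tail = FALSE) else 0,
       levels = paste(levels(f)[2], "-", levels(f)[1]),
       group_means = tapply(df$value, f, mean),
       degenerate = degenerate)
}

#' Pairwise trait correlations on line means
#'
#' Pearson correlations between traits computed on per-line means (the
#' line, not the seed, is the replicate for composition traits), with
#' Fisher-z 95% confidence intervals. Used to read off metabolic
#' trade-offs such as the erucic:linoleic anticorrelation.
#'
#' @inheritParams variance_components
#' @param traits character vector of trait names (>= 2).
#' @return List of class `trait_correlations`: `r` (correlation matrix),
#'   `n` (lines per pair), `conf_low`, `conf_high` (Fisher-z 95% bounds),
#'   `line_means` (lines x traits matrix), `undefined` (logical matrix
#'   flagging zero-variance pairs).
#' @export
trait_correlations <- function(table, traits, grouping = "line_id") {
  df <- as.data.frame(table)
  df <- df[df$trait %in% traits, , drop = FALSE]
  lm_mat <- tapply(df$value, list(df[[grouping]], df$trait), mean)
  lm_mat <- lm_mat[, traits, drop = FALSE]
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  nmat <- lo <- hi <- r
  undef <- matrix(FALSE, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(lm_mat[, c(i, j)])
      n <- sum(ok)
      if (n < 3) stop("need at least 3 complete line means per pair")
      xi <- lm_mat[ok, i]; xj <- lm_mat[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        undef[i, j] <- undef[j, i] <- TRUE
        next
      }
      rv <- stats::cor(xi, xj)
      z <- atanh(min(max(rv, -1 + 1e-15), 1 - 1e-15))
      half <- stats::qnorm(0.975) / sqrt(n - 3)
      r[i, j] <- r[j, i] <- rv
      nmat[i, j] <- nmat[j, i] <- n
      lo[i, j] <- lo[j, i] <- tanh(z - half)
      hi[i, j] <- hi[j, i] <- tanh(z + half)
    }
  }
  structure(list(r = r, n = nmat, conf_low = lo, conf_high = hi,
                 line_means = lm_mat, undefined = undef),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Pearson correlations of line means\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Box-plot summary statistics per group
#'
#' Quartiles, whisker bounds (Tukey, 1.5 IQR) and outlier counts for one
#' trait split by a grouping column — the numeric content of a box-plot
#' panel.
#'
#' @inheritParams group_contrast
#' @param by column to split by (default `"treatment"`).
#' @return data.frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
boxplot_summary <- function(table, trait, by = "treatment") {
  df <- as.data.frame(table)
  if ("trait" %in% names(df)) df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no observations for trait ", trait)
  groups <- split(df$value, df[[by]])
  out <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    wl <- min(v[v >= q[1] - 1.5 * iqr])
    wh <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(group = g, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v),
               whisker_low = wl, whisker_high = wh,
               n_outliers = sum(v < wl | v > wh),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
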