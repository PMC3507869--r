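#' Constrained logistic dose-response curve
#'
#' Declining log-logistic with the upper asymptote fixed at 100% so that
#' the curve passes exactly through 100 at dose 0:
#'
#' \deqn{y(x) = A + \frac{100 - A}{1 + (x/m)^b}}
#'
#' `A` is the lower asymptote (% responding as dose grows without bound),
#' `b > 0` the rate, and `m` the half-reduction dose: at `x = m`,
#' `y = (100 + A)/2`, i.e. the dose at which the response has fallen by
#' half of the total possible reduction from 100 down to `A`.
#'
#' @param x dose (non-negative, same units as `m`, typically mM).
#' @param A lower asymptote in `[0, 100)`.
#' @param b rate (positive).
#' @param m midpoint / half-reduction dose (positive).
#' @return Response percentage(s) in `[A, 100]`.
#' @export
logistic100 <- function(x, A, b, m) {
  if (any(x < 0)) stop("dose must be non-negative")
  A + (100 - A) / (1 + (x / m)^b)
}

norm_dose_table <- function(table) {
  if (all(c("responders", "total") %in% names(table))) {
    table$percent <- 100 * table$responders / table$total
  } else if (!("percent" %in% names(table))) {
    stop("dose-response table needs (responders, total) or percent")
  }
  if (!("dose" %in% names(table))) stop("dose-response table needs a dose column")
  table
}

#' Fit the constrained logistic to dose-response data
#'
#' Nonlinear least squares on the response percentages,
#' \eqn{\min \sum_i (y_i - y(x_i))^2}, with the upper asymptote fixed at
#' 100. Fitting is multi-start: the rate is started over \{0.5, 1, 2, 4\},
#' the midpoint over the quartiles of the positive doses, and the lower
#' asymptote at the smallest observed response (or fixed at 0 when
#' `estimate_lower_asymptote = FALSE`); the best converged start by
#' residual sum of squares wins. Each start runs Levenberg-Marquardt
#' least squares with box bounds keeping `A` in [0, 99], `b` and `m`
#' positive.
#'
#' @param table data.frame with `dose` plus either `responders`/`total`
#'   or `percent`; a `rep` column is carried along if present.
#' @param estimate_lower_asymptote if `FALSE`, fixes `A = 0` (the nested
#'   model used by [asymptote_test()]).
#' @param weights `"none"` (unweighted, the default, treating the
#'   percentages as the regression response) or `"binomial"` (weights
#'   total/(y(1-y)) recomputed from the fitted values once).
#' @return List of class `logistic_fit`: `A`, `b`, `m`, `residual_ss`,
#'   `df_residual`, `n_params`, `fitted`, `data`, `identifiable`,
#'   `convergence` (per-start diagnostics), `vcov` (of the estimated
#'   parameters, when available).
#' @export
fit_dose_response <- function(table,
                              estimate_lower_asymptote = TRUE,
                              weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  table <- norm_dose_table(table)
  x <- table$dose
  y <- table$percent
  if (length(unique(x[x > 0])) < 2 || !any(x == 0))
    stop("need at least 2 distinct positive doses plus the 0 control")
  if (stats::sd(y) == 0) {
    # flat response: the curve parameters are not identifiable
    return(structure(list(A = NA_real_, b = NA_real_, m = NA_real_,
                          residual_ss = 0,
                          df_residual = length(y) -
                            (2L + estimate_lower_asymptote),
                          n_params = 2L + estimate_lower_asymptote,
                          fitted = y, data = table,
                          identifiable = FALSE, convergence = NULL,
                          vcov = NULL),
                     class = "logistic_fit"))
  }
  pos <- x[x > 0]
  m_starts <- unique(stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE))
  b_starts <- c(0.5, 1, 2, 4)
  a_start <- if (estimate_lower_asymptote) max(min(y), 0) else 0
  starts <- expand.grid(b = b_starts, m = m_starts)

  w <- rep(1, length(y))
  fit_one <- function(b0, m0) {
    if (estimate_lower_asymptote) {
      minpack.lm::nlsLM(
        percent ~ A + (100 - A) / (1 + (dose / m)^b),
        data = table, weights = w,
        start = list(A = a_start, b = b0, m = m0),
        lower = c(A = 0, b = 1e-3, m = 1e-6),
        upper = c(A = 99, b = 50, m = max(pos) * 100),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-10))
    } else {
      minpack.lm::nlsLM(
        percent ~ 100 / (1 + (dose / m)^b),
        data = table, weights = w,
        start = list(b = b0, m = m0),
        lower = c(b = 1e-3, m = 1e-6),
        upper = c(b = 50, m = max(pos) * 100),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-10))
    }
  }
  run_starts <- function() {
    best <- NULL
    log <- vector("list", nrow(starts))
    for (i in seq_len(nrow(starts))) {
      f <- tryCatch(fit_one(starts$b[i], starts$m[i]),
                    error = function(e) e)
      if (inherits(f, "error")) {
        log[[i]] <- list(start = starts[i, ], converged = FALSE,
                         message = conditionMessage(f))
      } else {
        rss <- sum((y - stats::fitted(f))^2)
        log[[i]] <- list(start = starts[i, ], converged = TRUE, rss = rss)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
    list(best = best, log = log)
  }
  res <- run_starts()
  if (weights == "binomial" && !is.null(res$best) &&
      "total" %in% names(table)) {
    mu <- pmin(pmax(stats::fitted(res$best$fit) / 100, 1e-6), 1 - 1e-6)
    w <- table$total / (mu * (1 - mu))
    w <- w / mean(w)
    res <- run_starts()
  }
  if (is.null(res$best)) {
    msgs <- vapply(res$log, function(l)
      if (is.null(l$message)) "" else l$message, character(1))
    stop("dose-response fit failed to converge from every start:\n",
         paste(unique(msgs[nzchar(msgs)]), collapse = "\n"))
  }
  f <- res$best$fit
  cf <- stats::coef(f)
  n_params <- length(cf) # A,b,m or b,m
  rss <- sum((y - stats::fitted(f))^2)
  vc <- tryCatch(stats::vcov(f), error = function(e) NULL)
  structure(
    list(A = if (estimate_lower_asymptote) unname(cf["A"]) else 0,
         b = unname(cf["b"]), m = unname(cf["m"]),
         residual_ss = rss,
         df_residual = length(y) - n_params,
         n_params = n_params,
         fitted = as.numeric(stats::fitted(f)),
         data = table,
         identifiable = TRUE,
         convergence = res$log,
         vcov = vc),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Constrained logistic dose-response fit (upper asymptote = 100)\n")
  if (!x$identifiable) {
    cat("Non-identifiable: response is flat\n")
    return(invisible(x))
  }
  cat(sprintf("  A (lower asymptote) = %.3f %%\n", x$A))
  cat(sprintf("  b (rate)            = %.3f\n", x$b))
  cat(sprintf("  m (half-reduction dose) = %.4f\n", x$m))
  cat(sprintf("  residual SS = %.3f on %d df\n", x$residual_ss,
              x$df_residual))
  invisible(x)
}

#' Extra-sum-of-squares F-test for the lower asymptote
#'
#' Compares the 3-parameter fit (A estimated) with the nested 2-parameter
#' fit (A fixed at 0) on the same data:
#' \eqn{F = ((RSS_0 - RSS_1)/1) / (RSS_1/df_1)} on (1, df_1) degrees of
#' freedom.
#'
#' @param fit_with_A fit from `fit_dose_response(..., estimate_lower_asymptote = TRUE)`.
#' @param fit_without_A the nested fit with `A` fixed at 0.
#' @return List with `F`, `df`, `p_value`, `rss_full`, `rss_reduced`,
#'   `degenerate` (TRUE when the full model fits exactly).
#' @export
asymptote_test <- function(fit_with_A, fit_without_A) {
  stopifnot(inherits(fit_with_A, "logistic_fit"),
            inherits(fit_without_A, "logistic_fit"))
  if (!isTRUE(all.equal(fit_with_A$data$percent,
                        fit_without_A$data$percent)))
    stop("asymptote test requires nested fits on identical data")
  rss1 <- fit_with_A$residual_ss
  rss0 <- fit_without_A$residual_ss
  df1 <- fit_with_A$df_residual
  if (rss1 <= 0) {
    return(list(F = Inf, df = c(1, df1), p_value = 0,
                rss_full = rss1, rss_reduced = rss0, degenerate = TRUE))
  }
  fstat <- max(0, (rss0 - rss1) / 1) / (rss1 / df1)
  list(F = fstat, df = c(1, df1),
       p_value = stats::pf(fstat, 1, df1, lower.tail = FALSE),
       rss_full = rss1, rss_reduced = rss0, degenerate = FALSE)
}

#' Lack-of-fit F-test against pure replicate error
#'
#' Splits the residual sum of squares of the fitted curve into pure error
#' (deviation of replicates about their dose means, on N - n_doses df) and
#' lack of fit (dose means about the curve, on n_doses - n_params df):
#' \eqn{F = (SS_{lof}/df_{lof}) / (SS_{pe}/df_{pe})}.
#'
#' @param fit a `logistic_fit`.
#' @param table the data it was fitted to (defaults to `fit$data`).
#' @return List with `F`, `df_lof`, `df_pure_error`, `p_value`,
#'   `ss_lack_of_fit`, `ss_pure_error`, `n_obs`.
#' @export
lack_of_fit_test <- function(fit, table = fit$data) {
  stopifnot(inherits(fit, "logistic_fit"))
  table <- norm_dose_table(table)
  doses <- unique(table$dose)
  n <- nrow(table)
  if (n == length(doses))
    stop("lack-of-fit test requires replicated doses")
  dose_means <- tapply(table$percent, table$dose, mean)
  ss_pe <- sum((table$percent - dose_means[as.character(table$dose)])^2)
  df_pe <- n - length(doses)
  ss_lof <- max(0, fit$residual_ss - ss_pe)
  df_lof <- length(doses) - fit$n_params
  if (df_lof <= 0) stop("no degrees of freedom for lack of fit")
  fstat <- if (ss_pe <= 0) Inf else (ss_lof / df_lof) / (ss_pe / df_pe)
  list(F = fstat, df_lof = df_lof, df_pure_error = df_pe,
       p_value = if (is.finite(fstat))
         stats::pf(fstat, df_lof, df_pe, lower.tail = FALSE) else 0,
       ss_lack_of_fit = ss_lof, ss_pure_error = ss_pe, n_obs = n)
}

#' Doses of interest from a fitted dose-response curve
#'
#' Reports the two doses used to choose treatment concentrations:
#' the dose at which the absolute response falls to 50%
#' (solving \eqn{y(x) = 50}, only defined when `A < 50`), and the
#' half-reduction dose `m` — the dose removing 50% of the total possible
#' reduction — together with the response there, \eqn{(100 + A)/2}.
#'
#' @param fit a `logistic_fit`.
#' @return List with `dose_at_absolute_50` (mM; `NA` with reason when
#'   `A >= 50`), `half_reduction_dose` (mM), `survival_at_half_reduction`
#'   (%).
#' @export
report_doses <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$identifiable) stop("cannot report doses from a non-identifiable fit")
  a <- fit$A; b <- fit$b; m <- fit$m
  d50 <- if (a >= 50) NA_real_ else m * (50 / (50 - a))^(1 / b)
  list(dose_at_absolute_50 = d50,
       half_reduction_dose = m,
       survival_at_half_reduction = (100 + a) / 2,
       note = if (a >= 50)
         "absolute 50% response unreachable: lower asymptote >= 50" else NULL)
}
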