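#' Pairwise epigenetic distances between MSAP profiles
#'
#' For binary band vectors the squared Euclidean distance is the count of
#' loci at which two profiles disagree, which is the quantity AMOVA sums of
#' squares are built from; the Euclidean distance is its square root and is
#' the metric used for ordination. Cells missing in either member of a pair
#' are excluded for that pair (pairwise-complete loci) with a warning.
#'
#' @param x an `msap_matrix`, or a plain 0/1 matrix with sample row names.
#' @param metric `"euclidean"` or `"squared_euclidean"`.
#' @return A symmetric matrix of class `msap_dist` with zero diagonal,
#'   sample ids as dimnames and attributes `metric` and `samples` (the
#'   metadata data.frame when available).
#' @export
msap_dist <- function(x, metric = c("euclidean", "squared_euclidean")) {
  metric <- match.arg(metric)
  samples <- NULL
  if (inherits(x, "msap_matrix")) {
    samples <- x$samples
    x <- x$values
  }
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0))
    stop("sample with all-missing profile: ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0], collapse = ", "))
  if (anyNA(x)) {
    warning("missing band calls present; using pairwise-complete loci")
    n <- nrow(x)
    d2 <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(x[i, ]) & !is.na(x[j, ])
        if (!any(ok)) stop("no common scored loci for a sample pair")
        d2[i, j] <- d2[j, i] <- sum((x[i, ok] - x[j, ok])^2)
      }
    }
  } else {
    # |u - v|^2 = |u|^2 + |v|^2 - 2 u.v, exact for 0/1 integers
    g <- tcrossprod(x)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    d2[d2 < 0] <- 0
    diag(d2) <- 0
  }
  out <- if (metric == "euclidean") sqrt(d2) else d2
  structure(out, metric = metric, samples = samples, class = "msap_dist")
}

#' @export
print.msap_dist <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d samples\n",
              attr(x, "metric"), nrow(x)))
  invisible(x)
}

# squared distances regardless of the stored metric
squared_dist <- function(d) {
  m <- attr(d, "metric")
  dm <- unclass(d)
  if (identical(m, "euclidean")) dm^2 else dm
}

check_distance <- function(d) {
  dm <- unclass(d)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance input must be a square matrix")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(dm < -1e-12)) stop("distance matrix has negative entries")
  if (max(abs(diag(dm))) > 1e-12) stop("distance matrix diagonal is not zero")
  invisible(TRUE)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centred
#' (Gower), the centred matrix eigendecomposed, and coordinates formed as
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Axes with negative eigenvalues are reported in the eigenvalue table but
#' carry no coordinates. Axis orientation is made deterministic by forcing
#' the largest-magnitude loading of each axis positive.
#'
#' @param d an `msap_dist` (either metric) or symmetric distance matrix in
#'   ordinary Euclidean units.
#' @param n_axes maximum number of positive axes to return.
#' @return A list of class `pcoa_result`: `coordinates` (samples x axes,
#'   column-centred), `eigenvalues` (all, descending), `prop_variance`
#'   (share of the positive-eigenvalue total per returned axis) and
#'   `samples` metadata if available.
#' @export
pcoa <- function(d, n_axes = NULL) {
  check_distance(d)
  d2 <- if (inherits(d, "msap_dist")) squared_dist(d) else unclass(d)^2
  n <- nrow(d2)
  if (n < 2) stop("PCoA needs at least 2 samples")
  a <- -0.5 * d2
  g <- sweep(a, 1, rowMeans(a))
  g <- sweep(g, 2, colMeans(g))
  g <- g + mean(a)
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  pos <- which(vals > max(vals[1], 0) * 1e-10 & vals > 0)
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  coords <- matrix(0, n, k,
                   dimnames = list(rownames(d2), paste0("Axis", seq_len(k))))
  for (j in seq_len(k)) {
    v <- vecs[, pos[j]]
    if (v[which.max(abs(v))] < 0) v <- -v
    coords[, j] <- v * sqrt(vals[pos[j]])
  }
  pos_total <- sum(vals[vals > 0])
  structure(
    list(coordinates = coords,
         eigenvalues = vals,
         prop_variance = if (k > 0) vals[pos[seq_len(k)]] / pos_total
                         else numeric(0),
         samples = attr(d, "samples")),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d samples, %d positive axes returned\n",
              nrow(x$coordinates), k))
  if (k > 0) {
    pv <- round(100 * x$prop_variance[seq_len(min(k, 3))], 1)
    cat("Variance explained (%):", paste(pv, collapse = ", "),
        if (k > 3) "..." else "", "\n")
  }
  invisible(x)
}

#' Group centroids in principal-coordinate space
#'
#' Arithmetic mean of the member samples' coordinates, one row per group —
#' the "mean epigenetic distance" representation used to summarise an
#' ordination by line and enzyme.
#'
#' @param p a `pcoa_result`.
#' @param grouping vector assigning every sample to one group (same order
#'   as the coordinate rows).
#' @return Matrix of group means (groups x axes).
#' @export
group_centroids <- function(p, grouping) {
  stopifnot(inherits(p, "pcoa_result"))
  if (length(grouping) != nrow(p$coordinates))
    stop("grouping must assign every sample to one group")
  if (anyNA(grouping)) stop("grouping contains NA (empty group assignment)")
  f <- factor(grouping)
  if (any(table(f) == 0)) stop("empty group in grouping")
  rowsum(p$coordinates, f) / as.vector(table(f))
}
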