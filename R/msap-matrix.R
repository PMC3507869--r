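#' MSAP band matrix
#'
#' Container for a binary methylation-sensitive amplified polymorphism
#' (MSAP) profile: samples in rows, scored loci (fragment bins) in columns,
#' with per-sample line and generation metadata and the restriction enzyme
#' used for the digest. A band value of 1 means the fragment was amplified
#' (the CCGG site was cut), 0 means it was absent; `NA` marks an unscored
#' cell.
#'
#' All epigenetic statistics in the package (distances, PCoA, AMOVA/PhiPT,
#' the hypomethylation screen) start from one or two of these matrices. The
#' two digests of one DNA sample (HpaII and MspI) are kept as two paired
#' `msap_matrix` objects sharing `sample_ids` and `locus_ids`.
#'
#' @param values numeric/integer matrix of 0/1 band calls (`NA` allowed).
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `values`.
#' @param line_ids character vector, the sib-line each sample belongs to.
#' @param generations character vector of generation labels (e.g. "S2",
#'   "S3", "E2", "E3"); recycled if length 1.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param locus_ids optional character vector of locus names; defaults to
#'   `L001`, `L002`, ...
#' @return An object of class `msap_matrix`: a list with elements `values`
#'   (integer matrix with dimnames), `samples` (data.frame of sample_id,
#'   line_id, generation) and `enzyme`.
#' @export
msap_matrix <- function(values, sample_ids, line_ids, generations,
                        enzyme = c("HpaII", "MspI"), locus_ids = NULL) {
  enzyme <- match.arg(enzyme)
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L) | is.na(values)))
    stop("MSAP band values must be 0, 1 or NA")
  storage.mode(values) <- "integer"
  n <- nrow(values)
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(line_ids) == 1L) line_ids <- rep(line_ids, n)
  if (length(generations) == 1L) generations <- rep(generations, n)
  if (length(line_ids) != n || length(generations) != n)
    stop("line_ids and generations must have one entry per sample")
  if (is.null(locus_ids))
    locus_ids <- sprintf("L%03d", seq_len(ncol(values)))
  if (length(locus_ids) != ncol(values))
    stop("length(locus_ids) must equal ncol(values)")
  dimnames(values) <- list(sample_ids, locus_ids)
  structure(
    list(values = values,
         samples = data.frame(sample_id = as.character(sample_ids),
                              line_id = as.character(line_ids),
                              generation = as.character(generations),
                              stringsAsFactors = FALSE),
         enzyme = enzyme),
    class = "msap_matrix")
}

#' @export
print.msap_matrix <- function(x, ...) {
  cat(sprintf("MSAP matrix: %d samples x %d loci, enzyme %s\n",
              nrow(x$values), ncol(x$values), x$enzyme))
  cat(sprintf("Lines: %s\n",
              paste(unique(x$samples$line_id), collapse = ", ")))
  miss <- sum(is.na(x$values))
  if (miss > 0) cat(sprintf("Missing cells: %d\n", miss))
  invisible(x)
}

#' @export
dim.msap_matrix <- function(x) dim(x$values)

#' Check that two MSAP matrices are a valid HpaII/MspI pair
#'
#' Paired digests must cover the same samples (same ids, same order) and the
#' same loci, with distinct enzymes.
#'
#' @param hpaii,mspi `msap_matrix` objects.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
check_paired_msap <- function(hpaii, mspi) {
  stopifnot(inherits(hpaii, "msap_matrix"), inherits(mspi, "msap_matrix"))
  if (!identical(hpaii$samples$sample_id, mspi$samples$sample_id))
    stop("paired MSAP matrices must have identical sample ids in the same order")
  if (!identical(colnames(hpaii$values), colnames(mspi$values)))
    stop("paired MSAP matrices must have identical locus ids")
  if (identical(hpaii$enzyme, mspi$enzyme))
    stop("paired MSAP matrices must come from the two different isoschizomers")
  invisible(TRUE)
}

# ---- I/O ------------------------------------------------------------------

#' Read / write MSAP matrices as TSV
#'
#' The file dialect is UTF-8 tab-separated text: one header row, metadata
#' columns `sample`, `line`, `generation`, `enzyme`, then one column per
#' locus holding 0/1 (missing = empty cell). `write_msap` followed by
#' `read_msap` is the identity.
#'
#' @param path file path.
#' @return `read_msap` returns an `msap_matrix`; `write_msap` returns
#'   `path` invisibly.
#' @export
read_msap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  meta_cols <- c("sample", "line", "generation", "enzyme")
  if (!all(meta_cols %in% names(df)))
    stop("MSAP TSV must contain columns: ", paste(meta_cols, collapse = ", "))
  locus_cols <- setdiff(names(df), meta_cols)
  if (length(locus_cols) == 0L) stop("MSAP TSV contains no locus columns")
  vals <- as.matrix(df[, locus_cols, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1") | is.na(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary MSAP value '%s' at sample '%s', locus '%s'",
      vals[bad[1, 1], bad[1, 2]], df$sample[bad[1, 1]],
      locus_cols[bad[1, 2]]))
  }
  storage.mode(vals) <- "integer"
  enzymes <- unique(df$enzyme)
  if (length(enzymes) != 1L)
    stop("one MSAP file must hold exactly one enzyme; found: ",
         paste(enzymes, collapse = ", "))
  msap_matrix(vals, sample_ids = df$sample, line_ids = df$line,
              generations = df$generation, enzyme = enzymes,
              locus_ids = locus_cols)
}

#' @rdname read_msap
#' @param x an `msap_matrix`.
#' @export
write_msap <- function(x, path) {
  stopifnot(inherits(x, "msap_matrix"))
  df <- data.frame(sample = x$samples$sample_id,
                   line = x$samples$line_id,
                   generation = x$samples$generation,
                   enzyme = x$enzyme,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Export an MSAP matrix in a GenAlEx-style layout
#'
#' Writes the two-extra-header-row CSV layout used by GenAlEx for binary
#' marker data: row 1 holds the counts (n loci, n samples, n groups and the
#' group sizes), row 2 a title followed by the group names, row 3 the column
#' header (`sample`, `pop`, locus ids), then one row per sample with the
#' grouping variable in column 2.
#'
#' @param x an `msap_matrix`.
#' @param path output file.
#' @param group grouping used as the GenAlEx "population": one of
#'   `"line"` or `"generation"`.
#' @param title dataset title placed in the second header row.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path, group = c("line", "generation"),
                          title = "MSAP binary matrix") {
  stopifnot(inherits(x, "msap_matrix"))
  group <- match.arg(group)
  pop <- switch(group, line = x$samples$line_id,
                generation = x$samples$generation)
  pop_levels <- unique(pop)
  sizes <- as.integer(table(factor(pop, levels = pop_levels)))
  n_loci <- ncol(x$values)
  n_samp <- nrow(x$values)
  row1 <- c(n_loci, n_samp, length(pop_levels), sizes)
  row2 <- c(title, "", "", pop_levels)
  header <- c("sample", "pop", colnames(x$values))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(row1, collapse = ","), con)
  writeLines(paste(row2, collapse = ","), con)
  writeLines(paste(header, collapse = ","), con)
  body <- cbind(x$samples$sample_id, pop,
                apply(x$values, 2, function(v) ifelse(is.na(v), "", v)))
  utils::write.table(body, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
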