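#' Convert an RPKM table to fold changes centered around 1
#'
#' Divides each condition column elementwise by the mean of the standard
#' control replicate columns, yielding dimensionless fold changes that equal 1
#' at control-like expression. Genes with a zero control mean produce
#' non-finite values, resolved downstream by the fusion policy of
#' [flux_foldchange()]/[build_multiomic()].
#'
#' @param rpkm numeric matrix, genes x columns (rownames = gene ids).
#' @param control_columns indices (or names) of the control replicate columns.
#' @param condition_columns indices (or names) of the condition columns.
#' @return genes x conditions fold-change matrix.
#' @export
rpkm_to_foldchange <- function(rpkm, control_columns, condition_columns) {
  rpkm <- as.matrix(rpkm)
  if (length(control_columns) < 1) stop("need at least one control column")
  if (any(rpkm < 0, na.rm = TRUE)) stop("RPKM values must be >= 0")
  ctrl_mean <- rowMeans(rpkm[, control_columns, drop = FALSE])
  fc <- rpkm[, condition_columns, drop = FALSE] / ctrl_mean
  if (any(!is.finite(fc)))
    message("rpkm_to_foldchange: ", sum(rowSums(!is.finite(fc)) > 0),
            " gene(s) with zero control mean produced non-finite fold changes")
  fc
}

#' Read an RPKM table from CSV or XLSX
#'
#' Expects a gene-id column, optional category metadata columns, and named
#' condition columns. XLSX input requires the `readxl` package.
#'
#' @param path file path (`.csv`/`.tsv` or `.xlsx`).
#' @param gene_id_col name of the gene id column (default first column).
#' @return data.frame with the gene id column first.
#' @export
read_rpkm_table <- function(path, gene_id_col = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package; convert to CSV instead")
    as.data.frame(readxl::read_excel(path))
  } else if (ext == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.null(gene_id_col)) gene_id_col <- names(df)[1]
  df[c(gene_id_col, setdiff(names(df), gene_id_col))]
}

#' Flux fold changes relative to the standard control
#'
#' Divides per-condition flux rows by the control row and applies the fusion
#' policy in this order: (a) record the largest finite fold change treating
#' Inf as 0 and ignoring NaN; (b) recompute the ratios; (c) zero values at or
#' below `threshold`; (d) NaN (0/0, a reaction inactive everywhere) becomes 1;
#' (e) Inf (active flux over an inactive control) takes the value from (a).
#'
#' @param flux conditions x reactions matrix including the control row,
#'   post-processed (non-negative, thresholded).
#' @param control_row index of the standard-control row.
#' @param threshold fold-change zeroing cutoff (default 1e-4, inclusive).
#' @return (conditions - 1) x reactions fold-change matrix.
#' @export
flux_foldchange <- function(flux, control_row = nrow(flux), threshold = 1e-4) {
  flux <- as.matrix(flux)
  if (control_row < 1 || control_row > nrow(flux))
    stop("control_row out of range")
  ctrl <- flux[control_row, ]
  fc0 <- sweep(flux[-control_row, , drop = FALSE], 2, ctrl, "/")
  noinf <- fc0
  noinf[is.infinite(noinf)] <- 0
  max_fc <- suppressWarnings(max(noinf, na.rm = TRUE))
  if (!is.finite(max_fc)) max_fc <- 0
  fc <- sweep(flux[-control_row, , drop = FALSE], 2, ctrl, "/")
  fc[!is.nan(fc) & fc <= threshold] <- 0
  fc[is.nan(fc)] <- 1
  fc[is.infinite(fc)] <- max_fc
  fc
}

#' Fuse transcript and flux fold changes into one multi-omic matrix
#'
#' Column-binds the transcript and flux fold-change matrices (conditions must
#' match row-for-row) and appends a final all-ones row representing the
#' standard control, whose fold change against itself is 1 everywhere.
#'
#' @param transcript_fc conditions x genes fold-change matrix.
#' @param flux_fc conditions x reactions fold-change matrix.
#' @param control_name label for the appended control row.
#' @return An `omics_matrix`: the fused (conditions + 1) x (genes + reactions)
#'   matrix with a `feature_kind` attribute tagging each column as
#'   `"transcript"` or `"flux"`.
#' @export
build_multiomic <- function(transcript_fc, flux_fc, control_name = "Standard control") {
  transcript_fc <- as.matrix(transcript_fc)
  flux_fc <- as.matrix(flux_fc)
  if (nrow(transcript_fc) != nrow(flux_fc))
    stop("row counts differ: ", nrow(transcript_fc), " vs ", nrow(flux_fc))
  rt <- rownames(transcript_fc); rf <- rownames(flux_fc)
  if (!is.null(rt) && !is.null(rf) && !identical(rt, rf))
    stop("condition labels differ between transcript and flux matrices")
  fused <- cbind(transcript_fc, flux_fc)
  fused <- rbind(fused, rep(1, ncol(fused)))
  if (!is.null(rt)) rownames(fused) <- c(rt, control_name)
  if (any(!is.finite(fused)))
    stop("fused matrix contains non-finite entries; apply flux_foldchange() first")
  if (any(fused < 0))
    stop("fused fold-change matrix contains negative entries")
  structure(fused, feature_kind = c(rep("transcript", ncol(transcript_fc)),
                                    rep("flux", ncol(flux_fc))))
}

#' Subset conditions with measured growth rates
#'
#' Of the 23 experimental growth conditions, only those with (i) reported
#' growth rates, (ii) doubling times, or (iii) growth curves enter the
#' regression analyses -- plus the standard control. Retained rows are the
#' control first (all ones for transcript-only data) followed by the flagged
#' conditions in matrix order, with the growth-rate response aligned
#' row-for-row.
#'
#' @param matrix conditions x features matrix with condition rownames
#'   (control row included for flux/multi-omic data; for transcript-only data
#'   lacking a control row an all-ones control row is synthesized).
#' @param available character vector of condition names with growth rates.
#' @param growth_rates named numeric response vector (control first), names
#'   matching `c(control, available)`.
#' @param control control row/condition name.
#' @return list with `x` (subset matrix) and `y` (aligned response).
#' @export
subset_growth_conditions <- function(matrix, available, growth_rates,
                                     control = "Standard control") {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop("matrix must have condition rownames")
  missing_rows <- setdiff(available, rownames(matrix))
  if (length(missing_rows))
    stop("condition(s) not in matrix: ", paste(missing_rows, collapse = ", "))
  ctrl_row <- if (control %in% rownames(matrix)) matrix[control, , drop = FALSE]
  else matrix(1, 1, ncol(matrix), dimnames = list(control, colnames(matrix)))
  keep <- available[order(match(available, rownames(matrix)))]
  x <- rbind(ctrl_row, matrix[keep, , drop = FALSE])
  rownames(x) <- c(control, keep)
  if (length(growth_rates) != nrow(x))
    stop("response length ", length(growth_rates), " != retained row count ", nrow(x))
  if (!is.null(names(growth_rates))) {
    ix <- match(rownames(x), names(growth_rates))
    if (anyNA(ix)) stop("growth_rates names do not cover the retained conditions")
    growth_rates <- growth_rates[ix]
  }
  list(x = x, y = as.numeric(growth_rates))
}
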