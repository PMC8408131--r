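#' Convert raw counts to transcripts per million (TPM)
#'
#' Divides each gene's counts by its effective length, then scales every
#' column so that the length-normalized abundances sum to one million.
#'
#' @param counts Numeric matrix of nonnegative counts, genes in rows
#'   (rownames = gene ids), samples in columns.
#' @param lengths Numeric vector of positive effective lengths (bases), one
#'   per gene, in row order (or named by gene id).
#' @return Numeric matrix of TPM values with the same dimnames as `counts`.
#'   Each column sums to 1e6, except all-zero columns which stay zero (with
#'   a warning).
#' @examples
#' tpm <- counts_to_tpm(matrix(c(10, 10), 2, 1,
#'   dimnames = list(c("g1", "g2"), "s1")), lengths = c(1000, 2000))
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all effective lengths must be positive")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero column(s): ", paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  tot[tot == 0] <- 1  # keep zero columns at zero
  sweep(rate, 2, tot, "/") * 1e6
}

#' Average replicate columns into per-tissue means
#'
#' @param expr Expression matrix (genes x samples).
#' @param design Data frame with columns `sample_id`, `tissue` (and
#'   optionally `replicate`). Every column of `expr` must appear in
#'   `design$sample_id`.
#' @return Genes x tissues matrix of arithmetic means of the replicate
#'   columns; tissue order follows first appearance in `design`.
#' @export
tissue_means <- function(expr, design) {
  expr <- as.matrix(expr)
  design <- validate_design(design)
  missing <- setdiff(design$sample_id, colnames(expr))
  if (length(missing) > 0) {
    stop("design references samples absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(expr), design$sample_id)
  if (length(extra) > 0) {
    stop("matrix columns missing from the design: ", paste(extra, collapse = ", "))
  }
  tissues <- unique(design$tissue)
  out <- matrix(0, nrow(expr), length(tissues),
                dimnames = list(rownames(expr), tissues))
  for (tt in tissues) {
    cols <- design$sample_id[design$tissue == tt]
    out[, tt] <- rowMeans(expr[, cols, drop = FALSE])
  }
  out
}

validate_design <- function(design) {
  design <- as.data.frame(design)
  stopifnot(all(c("sample_id", "tissue") %in% names(design)))
  design$sample_id <- as.character(design$sample_id)
  design$tissue <- as.character(design$tissue)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids in design")
  design
}

#' Keep genes expressed above a TPM floor
#'
#' Default reproduces the usual expression filter: a gene is retained when
#' its abundance exceeds `min_tpm` in at least one tissue. The comparison
#' is strict (`>`) by default; set `ge = TRUE` for `>=`.
#'
#' @param profile Genes x tissues matrix (per-tissue mean TPM).
#' @param min_tpm Expression floor, default 1.
#' @param mode `"any_tissue"` (default) keeps genes passing in at least one
#'   tissue; `"all_tissues"` requires every tissue to pass.
#' @param ge Use `>=` instead of `>`.
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expressed <- function(profile, min_tpm = 1,
                             mode = c("any_tissue", "all_tissues"),
                             ge = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_tpm >= 0)
  profile <- as.matrix(profile)
  pass <- if (ge) profile >= min_tpm else profile > min_tpm
  keep <- if (mode == "any_tissue") rowSums(pass) >= 1 else rowSums(pass) == ncol(profile)
  rownames(profile)[keep]
}

#' Filter genes for network construction
#'
#' Retains genes with a maximal tissue mean at or above `min_mean_tpm` and
#' an across-tissue variance strictly greater than `min_variance` -- the
#' low-expression/low-variance filter applied before building the
#' co-expression network.
#'
#' @param profile Genes x tissues matrix of mean TPM.
#' @param min_mean_tpm Minimal mean TPM required in at least one tissue.
#' @param min_variance Minimal across-tissue variance (sample variance).
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_for_network <- function(profile, min_mean_tpm = 1, min_variance = 1) {
  profile <- as.matrix(profile)
  stopifnot(ncol(profile) >= 2)
  vmax <- apply(profile, 1, max)
  v <- apply(profile, 1, stats::var)
  rownames(profile)[vmax >= min_mean_tpm & v > min_variance]
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every column to share the same value distribution: each value is
#' replaced by the mean, across columns, of the values at its rank. Ties
#' within a column receive the average of the reference values spanned by
#' the tied ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix with at least two columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Assign 0-10 BIN expression levels per tissue
#'
#' Discretizes each tissue column to eleven levels. Zero expression maps
#' to level 0 and the tissue's maximally expressed gene to level 10. The
#' default grid is equal-width on `log2(v + 1)` anchored at zero
#' (`round(10 * log2(v + 1) / log2(max + 1))`), which keeps the grid
#' identical across tissues that share a value distribution (e.g. after
#' quantile normalization). `method = "logwidth"` spans the grid between
#' the smallest and largest nonzero values instead; `method = "decile"`
#' uses rank deciles of the nonzero values.
#'
#' @param qn_profile Genes x tissues matrix of nonnegative (typically
#'   quantile-normalized) expression values.
#' @param method `"logmax"` (default), `"logwidth"` or `"decile"`.
#' @return Integer matrix of the same shape with values in 0..10.
#' @export
assign_bins <- function(qn_profile, method = c("logmax", "logwidth", "decile")) {
  method <- match.arg(method)
  x <- as.matrix(qn_profile)
  if (any(x < 0)) stop("expression values must be nonnegative")
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    nz <- v > 0
    if (!any(nz)) next
    if (method == "logmax") {
      M <- log2(max(v) + 1)
      out[nz, j] <- as.integer(round(10 * log2(v[nz] + 1) / M))
    } else if (method == "logwidth") {
      y <- log2(v[nz] + 1)
      m <- min(y); M <- max(y)
      out[nz, j] <- if (M == m) 10L else as.integer(round(10 * (y - m) / (M - m)))
    } else {
      r <- rank(v[nz], ties.method = "average")
      out[nz, j] <- as.integer(ceiling(10 * r / sum(nz)))
    }
  }
  out
}

#' Quantile-normalize a tissue profile, keeping absent genes absent
#'
#' Applies [quantile_normalize()] and then restores exact zeros: a gene
#' not expressed in a tissue stays at zero rather than inheriting the
#' tie-averaged reference value of the zero block, so downstream
#' specificity statistics treat absence as absence.
#'
#' @param profile Genes x tissues matrix of nonnegative expression.
#' @return Quantile-normalized matrix with the input's zeros preserved.
#' @export
normalize_profile <- function(profile) {
  profile <- as.matrix(profile)
  qn <- quantile_normalize(profile)
  qn[profile == 0] <- 0
  qn
}

#' Row-wise z-score standardization
#'
#' Centers and scales each row to mean 0 and sample standard deviation 1
#' (the heatmap normalization `z = (value - mean(row)) / sd(row)`).
#' Constant rows become all zeros, with a warning.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape.
#' @export
row_zscore <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  flat <- sd == 0 | is.na(sd)
  if (any(flat)) {
    warning(sum(flat), " constant row(s) set to zero")
    sd[flat] <- 1
  }
  out <- (x - mu) / sd
  out[flat, ] <- 0
  out
}
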