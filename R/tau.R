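#' Tau tissue-specificity index
#'
#' For a per-tissue expression profile `v` over `N >= 2` tissues,
#' `tau = sum(1 - v/max(v)) / (N - 1)`. The index is 0 for a perfectly
#' uniform profile and 1 for expression confined to a single tissue, and is
#' invariant to positive rescaling of the profile.
#'
#' @param profile Nonnegative numeric vector (one gene across tissues), or
#'   a genes x tissues matrix to evaluate row-wise.
#' @return A numeric value in `[0, 1]` (or a vector for matrix input).
#'   All-zero profiles are undefined and return `NA` with a warning.
#' @examples
#' tau(c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0)) # 1
#' tau(rep(3, 10))                      # 0
#' @export
tau <- function(profile) {
  if (is.matrix(profile)) {
    return(apply(profile, 1, tau_one, warn = FALSE))
  }
  tau_one(profile, warn = TRUE)
}

tau_one <- function(v, warn = TRUE) {
  v <- as.numeric(v)
  if (length(v) < 2) stop("tau needs at least two tissues")
  if (any(v < 0)) stop("expression values must be nonnegative")
  m <- max(v)
  if (m == 0) {
    if (warn) warning("all-zero profile: tau undefined")
    return(NA_real_)
  }
  sum(1 - v / m) / (length(v) - 1)
}

#' Per-tissue tau expression fractions
#'
#' Distributes a gene's tau over tissues: `tau_ef[t] = tau * qn[t] /
#' max(qn)`, so the maximally expressed tissue carries the full tau and the
#' others a proportional share.
#'
#' @param tau_value Scalar tau for the gene.
#' @param qn_profile Nonnegative per-tissue expression vector (typically
#'   quantile-normalized).
#' @return Numeric vector of the same length as `qn_profile`.
#' @export
tau_expression_fraction <- function(tau_value, qn_profile) {
  qn_profile <- as.numeric(qn_profile)
  m <- max(qn_profile)
  if (m == 0) stop("all-zero profile: tau expression fraction undefined")
  tau_value * qn_profile / m
}

#' Classify genes by specificity from tau
#'
#' `tau = 1` is absolutely specific (ASG); `hsg_cut <= tau < 1` is highly
#' specific (HSG); `tau < const_cut` is constitutive; anything else is
#' intermediate. For set reports ASG are conventionally counted inside HSG
#' (`tau >= hsg_cut`); this function returns the exclusive four-way class.
#'
#' @param tau_values Numeric vector of tau values in `[0, 1]` (NA allowed).
#' @param hsg_cut Highly-specific threshold, default 0.85.
#' @param const_cut Constitutive threshold, default 0.2.
#' @return Factor with levels `ASG`, `HSG`, `intermediate`, `constitutive`.
#' @export
classify_specificity <- function(tau_values, hsg_cut = 0.85, const_cut = 0.2) {
  stopifnot(hsg_cut > const_cut)
  k <- ifelse(is.na(tau_values), NA_character_,
       ifelse(tau_values == 1, "ASG",
       ifelse(tau_values >= hsg_cut, "HSG",
       ifelse(tau_values < const_cut, "constitutive", "intermediate"))))
  factor(k, levels = c("ASG", "HSG", "intermediate", "constitutive"))
}

#' Composite per-tissue marker score
#'
#' Scores each gene in each tissue as the sum of its tau expression
#' fraction and its 0-1 min-max-scaled expression within the tissue
#' (scaling across genes), yielding values in `[0, 2]`: high only for genes
#' that are both specific to and strongly expressed in the tissue.
#'
#' @param tau_ef Genes x tissues matrix of tau expression fractions.
#' @param qn_profile Genes x tissues expression matrix aligned with
#'   `tau_ef`.
#' @return Genes x tissues numeric matrix of scores.
#' @export
gene_score <- function(tau_ef, qn_profile) {
  tau_ef <- as.matrix(tau_ef)
  qn <- as.matrix(qn_profile)
  stopifnot(identical(dim(tau_ef), dim(qn)))
  norm <- apply(qn, 2, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("constant tissue column: normalized expression set to 0")
      return(rep(0, length(v)))
    }
    (v - rng[1]) / (rng[2] - rng[1])
  })
  out <- tau_ef + norm
  dimnames(out) <- dimnames(qn)
  out
}

#' Rank the top marker ("optimum") genes per tissue
#'
#' @param scores Genes x tissues score matrix (see [gene_score()]).
#' @param tau_values Per-gene tau used to break score ties (descending),
#'   then by gene id.
#' @param k Number of genes to return per tissue, default 10.
#' @return Named list (one element per tissue) of data frames with columns
#'   `gene`, `score`, `tau`, sorted by descending score.
#' @export
rank_optimum_genes <- function(scores, tau_values = NULL, k = 10) {
  scores <- as.matrix(scores)
  genes <- rownames(scores)
  if (is.null(tau_values)) tau_values <- rep(0, nrow(scores))
  if (!is.null(names(tau_values))) tau_values <- tau_values[genes]
  if (k > nrow(scores)) {
    warning("fewer genes than k; returning all")
    k <- nrow(scores)
  }
  out <- lapply(colnames(scores), function(tt) {
    s <- scores[, tt]
    ord <- order(-s, -tau_values, genes)
    head_i <- ord[seq_len(k)]
    data.frame(gene = genes[head_i], score = s[head_i],
               tau = as.numeric(tau_values[head_i]), row.names = NULL)
  })
  names(out) <- colnames(scores)
  out
}

#' Call housekeeping (constitutive reference) genes
#'
#' Retains genes whose tau is at most `tau_max` (default exactly 0, i.e. a
#' zero tau expression fraction in every tissue) and whose TPM exceeds
#' `min_tpm` in every tissue; the list is sorted by ascending standard
#' deviation of TPM across tissues, most stable first.
#'
#' @param tau_values Named numeric vector of per-gene tau values.
#' @param tpm_profile Genes x tissues matrix of mean TPM.
#' @param tau_max Maximal tau allowed, default 0.
#' @param min_tpm TPM floor required in all tissues, default 100.
#' @return Data frame with columns `gene`, `tau`, `mean_tpm`, `sd_tpm`.
#' @export
housekeeping_genes <- function(tau_values, tpm_profile, tau_max = 0, min_tpm = 100) {
  tpm <- as.matrix(tpm_profile)
  genes <- intersect(names(tau_values), rownames(tpm))
  tv <- tau_values[genes]
  tpm <- tpm[genes, , drop = FALSE]
  keep <- !is.na(tv) & tv <= tau_max & apply(tpm, 1, min) > min_tpm
  tpm <- tpm[keep, , drop = FALSE]
  out <- data.frame(gene = genes[keep], tau = as.numeric(tv[keep]),
                    mean_tpm = rowMeans(tpm), sd_tpm = apply(tpm, 1, stats::sd),
                    row.names = NULL)
  out[order(out$sd_tpm, out$gene), , drop = FALSE]
}

#' Full tau specificity table
#'
#' Runs the whole specificity stage on a quantile-normalized tissue
#' profile: BIN discretization, tau (on the BIN profile by default,
#' following the pipeline order quantile normalization -> BIN -> tau; set
#' `tau_on = "qn"` to use the continuous values), per-tissue tau expression
#' fractions on the continuous values, specificity classes, and composite
#' scores. Genes whose profile is entirely zero (or whose BIN profile is,
#' under the default mode) are excluded with a message.
#'
#' @param qn_profile Genes x tissues matrix of quantile-normalized mean
#'   expression.
#' @param tau_on Compute tau on `"bins"` (default) or `"qn"`.
#' @param bins Optional precomputed BIN matrix (see [assign_bins()]).
#' @param hsg_cut,const_cut Class thresholds, see [classify_specificity()].
#' @return Object of class `tau_table`: a list with elements `table` (data
#'   frame: gene, tau, klass, tissue = argmax tau_ef), `tau_ef`, `bins`,
#'   `scores` (genes x tissues matrices), `qn`, and `excluded` (gene ids).
#' @export
tau_table <- function(qn_profile, tau_on = c("bins", "qn"), bins = NULL,
                      hsg_cut = 0.85, const_cut = 0.2) {
  tau_on <- match.arg(tau_on)
  qn <- as.matrix(qn_profile)
  if (is.null(bins)) bins <- assign_bins(qn)
  basis <- if (tau_on == "bins") bins else qn
  ok <- apply(basis, 1, max) > 0 & apply(qn, 1, max) > 0
  if (any(!ok)) {
    message(sum(!ok), " gene(s) with an all-zero profile excluded from the tau table")
  }
  qn <- qn[ok, , drop = FALSE]
  bins <- bins[ok, , drop = FALSE]
  basis <- basis[ok, , drop = FALSE]
  tv <- apply(basis, 1, tau_one, warn = FALSE)
  tau_ef <- tv * qn / apply(qn, 1, max)
  scores <- gene_score(tau_ef, qn)
  best <- colnames(qn)[max.col(qn, ties.method = "first")]
  tab <- data.frame(gene = rownames(qn), tau = as.numeric(tv),
                    klass = classify_specificity(tv, hsg_cut, const_cut),
                    tissue = best, row.names = NULL)
  structure(list(table = tab, tau_ef = tau_ef, bins = bins, scores = scores,
                 qn = qn, excluded = rownames(as.matrix(qn_profile))[!ok],
                 tau_on = tau_on),
            class = "tau_table")
}

#' @export
print.tau_table <- function(x, ...) {
  cat("tau specificity table:", nrow(x$table), "genes x", ncol(x$qn), "tissues",
      sprintf("(tau on %s)\n", x$tau_on))
  print(table(x$table$klass))
  invisible(x)
}

#' Per-tissue highly specific gene sets
#'
#' Splits the HSG calls (tau >= `hsg_cut`, ASG included) by the tissue of
#' maximal expression.
#'
#' @param tt A [tau_table()] result.
#' @param hsg_cut Threshold, default 0.85.
#' @return Named list of gene-id vectors, one per tissue.
#' @export
hsg_by_tissue <- function(tt, hsg_cut = 0.85) {
  stopifnot(inherits(tt, "tau_table"))
  tab <- tt$table[!is.na(tt$table$tau) & tt$table$tau >= hsg_cut, ]
  out <- split(tab$gene, factor(tab$tissue, levels = colnames(tt$qn)))
  lapply(out, as.character)
}
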