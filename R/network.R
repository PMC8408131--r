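# Signed weighted co-expression network: soft-threshold selection by
# scale-free fit, topological overlap, average-linkage module detection with
# a minimum size, eigengenes, eigengene-based merging, module membership
# (kME), gene significance and module-trait association.

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`: anticorrelated genes get adjacency
#' near 0, perfectly correlated genes 1.
#'
#' @param cor_matrix Symmetric correlation matrix with values in `[-1, 1]`.
#' @param beta Soft-thresholding power (>= 1).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(cor_matrix, beta) {
  if (beta <= 0) stop("beta must be positive")
  cor_matrix <- as.matrix(cor_matrix)
  if (any(abs(cor_matrix) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  a <- ((1 + pmin(pmax(cor_matrix, -1), 1)) / 2)^beta
  diag(a) <- 1
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  # Signed scale-free topology fit: R^2 of log10 p(k) on log10 mean k per
  # degree bin, multiplied by minus the sign of the slope (so a decaying
  # power law scores +1).
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 2) return(list(fit = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  mk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- is.finite(mk) & mk > 0 & pk > 0
  if (sum(ok) < 3) return(list(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-thresholding power by approximate scale-free topology
#'
#' For each candidate power, builds the signed adjacency, computes each
#' gene's connectivity `k_i = sum_j a_ij (j != i)`, bins genes by
#' connectivity and regresses `log10 p(k)` on `log10 k`. The signed fit
#' index is `-sign(slope) * R^2`. Returns the smallest power whose fit
#' reaches `r2_cut`; if none does, the power with the maximal fit, flagged
#' with a warning.
#'
#' @param x Genes x columns expression matrix (rows are correlated).
#' @param powers Ascending candidate powers, default 1:30 (signed networks
#'   often need powers well above the unsigned range).
#' @param r2_cut Required signed fit, default 0.9.
#' @param n_bins Connectivity bins for the regression, default 10.
#' @return List with `beta` (selected power), `reached_cut` (logical) and
#'   `fit_table` (data frame: power, fit, slope, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(x, powers = 1:30, r2_cut = 0.9, n_bins = 10) {
  stopifnot(length(powers) > 0, !is.unsorted(powers))
  cm <- stats::cor(t(as.matrix(x)))
  cm[is.na(cm)] <- 0
  rows <- lapply(powers, function(b) {
    a <- signed_adjacency(cm, b)
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k, n_bins)
    if (is.na(sf$fit)) warning("degenerate connectivity at power ", b, "; fit undefined")
    data.frame(power = b, fit = sf$fit, slope = sf$slope, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  hit <- which(!is.na(tab$fit) & tab$fit >= r2_cut)
  if (length(hit) > 0) {
    beta <- tab$power[hit[1]]
    reached <- TRUE
  } else {
    warning("no candidate power reached the scale-free fit cut; using the best fit")
    beta <- tab$power[which.max(tab$fit)]
    reached <- FALSE
  }
  list(beta = beta, reached_cut = reached, fit_table = tab)
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity;
#' the returned dissimilarity is `1 - TOM` with a zero diagonal. Genes
#' sharing many strong neighbors get a small dissimilarity even if their
#' direct adjacency is moderate.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return Dissimilarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a  # L_ij = sum_u a_iu a_uj, u != i,j since diag(a) = 0
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Detect co-expression modules by adaptive average-linkage clustering
#'
#' Clusters the TOM dissimilarity with average linkage and cuts the tree
#' at a fraction `cut_height` of its maximal merge height. By default the
#' cut is applied recursively: every retained cluster is re-clustered and
#' re-cut at the same relative height within its own subtree, and accepted
#' the descent continues until clusters stop yielding viable (`min_size`)
#' children. This peels apart co-expression groups that a single global
#' cut leaves chained together through shared weak neighbors; genes
#' stripped from cohesive clusters in the process are recovered by the
#' membership-based rescue in [coexpression_network()], and over-splitting
#' is repaired by the eigengene-based [merge_modules()]. Candidate
#' clusters smaller than `min_size` are
#' assigned the unassigned label 0 ("grey"); retained modules are labelled
#' 1..M by decreasing size.
#'
#' @param diss Square symmetric dissimilarity matrix (gene ids as
#'   dimnames).
#' @param min_size Minimal module size, default 30.
#' @param cut_height Cut as a fraction of the (sub)tree height (`cut_mode
#'   = "fraction"`, default 0.99) or an absolute height.
#' @param cut_mode `"fraction"` or `"absolute"`.
#' @param recursive Re-cut retained clusters within their own subtrees
#'   (default TRUE); `FALSE` gives the single global static cut.
#' @return List with `labels` (named integer vector, 0 = grey) and `tree`
#'   (the full `hclust` object).
#' @export
detect_modules <- function(diss, min_size = 30, cut_height = 0.99,
                           cut_mode = c("fraction", "absolute"),
                           recursive = TRUE) {
  cut_mode <- match.arg(cut_mode)
  diss <- as.matrix(diss)
  n <- nrow(diss)
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  # guard against tiny floating-point inversions in the merge heights
  tree$height <- cummax(tree$height)
  if (n < min_size) {
    warning("fewer genes than min_size: all genes unassigned")
    labels <- stats::setNames(rep(0L, n), rownames(diss))
    return(list(labels = labels, tree = tree))
  }

  cut_groups <- function(tr, h_max) {
    h <- if (cut_mode == "fraction") cut_height * h_max else cut_height
    stats::cutree(tr, h = h)
  }
  split_rec <- function(idx, tr) {
    gr <- cut_groups(tr, max(tr$height))
    sizes <- table(gr)
    big <- as.integer(names(sizes)[sizes >= min_size])
    if (length(big) == 0) return(list())
    recurse_child <- function(sub) {
      if (!recursive || length(sub) < 2 * min_size) return(list(sub))
      str <- stats::hclust(stats::as.dist(diss[sub, sub]), method = "average")
      str$height <- cummax(str$height)
      child <- split_rec(sub, str)
      if (length(child) > 0) child else list(sub)
    }
    if (length(big) == 1 && sizes[as.character(big)] == length(idx)) {
      return(list(idx))  # cut did not separate anything (absolute mode)
    }
    out <- list()
    for (b in big) out <- c(out, recurse_child(idx[gr == b]))
    out
  }

  clusters <- split_rec(seq_len(n), tree)
  labels <- rep(0L, n)
  if (length(clusters) > 0) {
    ord <- order(-lengths(clusters))
    for (i in seq_along(ord)) labels[clusters[[ord[i]]]] <- i
  }
  names(labels) <- rownames(diss)
  list(labels = labels, tree = tree)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression: gene rows are centered and scaled, and the
#' leading right singular vector (scores across columns, unit norm) is
#' taken, with its sign fixed so that it correlates nonnegatively with the
#' module's mean standardized profile.
#'
#' @param x Genes x columns expression matrix.
#' @param labels Named module assignment (0 = unassigned, skipped).
#' @return Modules x columns matrix of eigengenes (rownames `ME<label>`).
#' @export
module_eigengenes <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 3)
  labels <- labels[rownames(x)]
  mods <- sort(unique(labels[labels > 0]))
  out <- matrix(NA_real_, length(mods), ncol(x),
                dimnames = list(paste0("ME", mods), colnames(x)))
  drop <- logical(length(mods))
  for (i in seq_along(mods)) {
    rows <- which(labels == mods[i])
    sub <- x[rows, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) {
      warning("module ", mods[i], " contains only constant genes; dropped")
      drop[i] <- TRUE
      next
    }
    sub <- sub[sds > 0, , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    out[i, ] <- e
  }
  out[!drop, , drop = FALSE]
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively computes eigengenes, clusters them (average linkage on
#' `1 - cor`), merges every group joining below `merge_height`, and
#' repeats until all retained eigengene pairs have dissimilarity at least
#' `merge_height`. Labels are renumbered 1..M by decreasing size.
#'
#' @param x Genes x columns expression matrix.
#' @param labels Named module assignment (0 = unassigned).
#' @param merge_height Eigengene dissimilarity below which modules merge,
#'   default 0.25.
#' @param max_iter Safety bound on merge rounds.
#' @return List with `labels` (merged assignment) and `eigengenes` (final
#'   eigengene matrix).
#' @export
merge_modules <- function(x, labels, merge_height = 0.25, max_iter = 20) {
  x <- as.matrix(x)
  for (it in seq_len(max_iter)) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) <= 1) break
    me <- module_eigengenes(x, labels)
    present <- as.integer(sub("^ME", "", rownames(me)))
    d <- 1 - stats::cor(t(me))
    tr <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(tr, h = merge_height)
    if (max(grp) == length(present)) break  # nothing joins below the height
    new <- labels
    for (g in unique(grp)) {
      members <- present[grp == g]
      new[labels %in% members] <- min(members)
    }
    labels <- new
  }
  labels <- relabel_by_size(labels)
  me <- if (any(labels > 0)) module_eigengenes(x, labels) else
    matrix(numeric(0), 0, ncol(x), dimnames = list(NULL, colnames(x)))
  list(labels = labels, eigengenes = me)
}

relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

cor_pvalue <- function(r, n) {
  # two-sided Student t for a Pearson correlation, df = n - 2
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Module membership (kME) with p-values
#'
#' `kME[g, m]` is the Pearson correlation of gene `g`'s profile with
#' eigengene `m` across columns; p-values come from the two-sided Student
#' test `t = r sqrt(n-2) / sqrt(1-r^2)`. Constant genes get kME 0, p 1.
#'
#' @param x Genes x columns expression matrix.
#' @param eigengenes Modules x columns eigengene matrix.
#' @return List of genes x modules matrices `kme` and `p`.
#' @export
module_membership <- function(x, eigengenes) {
  x <- as.matrix(x)
  me <- as.matrix(eigengenes)
  stopifnot(ncol(x) == ncol(me))
  n <- ncol(x)
  flat <- apply(x, 1, stats::sd) == 0
  kme <- suppressWarnings(stats::cor(t(x), t(me)))
  kme[flat, ] <- 0
  p <- cor_pvalue(kme, n)
  p[flat, ] <- 1
  dimnames(kme) <- dimnames(p) <- list(rownames(x), rownames(me))
  list(kme = kme, p = p)
}

#' Gene significance for a tissue trait
#'
#' Correlates each gene with a binary tissue indicator over the matrix
#' columns. Returns the absolute correlation (`signed = FALSE`, default)
#' plus `-log10(p)` from the Student test. Constant genes get GS 0.
#'
#' @param x Genes x columns expression matrix.
#' @param trait Binary (0/1) vector over columns, at least one of each.
#' @param signed Keep the correlation sign.
#' @return Data frame with columns `gene`, `gs`, `neg_log10_p`.
#' @export
gene_significance <- function(x, trait, signed = FALSE) {
  x <- as.matrix(x)
  trait <- as.numeric(trait)
  stopifnot(length(trait) == ncol(x))
  if (all(trait == trait[1])) stop("trait indicator has zero variance")
  if (!all(trait %in% c(0, 1))) stop("trait must be binary")
  flat <- apply(x, 1, stats::sd) == 0
  r <- suppressWarnings(as.numeric(stats::cor(t(x), trait)))
  r[flat] <- 0
  p <- cor_pvalue(r, ncol(x))
  p[flat] <- 1
  gs <- if (signed) r else abs(r)
  data.frame(gene = rownames(x), gs = gs, neg_log10_p = -log10(p),
             row.names = NULL)
}

#' Module-trait correlation table
#'
#' Pearson correlation of every module eigengene with every binary tissue
#' indicator, with Student-t p-values, plus the best (max r) module per
#' trait.
#'
#' @param eigengenes Modules x columns eigengene matrix.
#' @param traits Columns x traits 0/1 indicator matrix (colnames = tissue
#'   labels).
#' @return List with matrices `r` and `p` (modules x traits) and
#'   `best_module` (named character: trait -> module row name).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  me <- as.matrix(eigengenes)
  tr <- as.matrix(traits)
  stopifnot(ncol(me) == nrow(tr), ncol(me) >= 3)
  r <- stats::cor(t(me), tr)
  p <- cor_pvalue(r, ncol(me))
  dimnames(r) <- dimnames(p) <- list(rownames(me), colnames(tr))
  best <- rownames(r)[apply(r, 2, which.max)]
  names(best) <- colnames(tr)
  list(r = r, p = p, best_module = best)
}

#' Tissue indicator matrix
#'
#' @param columns Column labels of the network matrix (tissue names, or
#'   sample names with a design).
#' @param design Optional design mapping samples to tissues.
#' @return Columns x tissues 0/1 matrix.
#' @export
tissue_traits <- function(columns, design = NULL) {
  tissue <- if (is.null(design)) columns else {
    design <- validate_design(design)
    design$tissue[match(columns, design$sample_id)]
  }
  lev <- unique(tissue)
  out <- vapply(lev, function(tt) as.numeric(tissue == tt), numeric(length(columns)))
  dimnames(out) <- list(columns, lev)
  out
}

#' Hub genes per module
#'
#' Genes assigned to a module whose membership (kME) for that module
#' exceeds `mm_cut`, sorted by descending kME.
#'
#' @param kme Genes x modules kME matrix (colnames `ME<label>`).
#' @param labels Named module assignment.
#' @param mm_cut Membership threshold, default 0.9.
#' @return Named list (one per module) of gene-id vectors.
#' @export
hub_genes <- function(kme, labels, mm_cut = 0.9) {
  kme <- as.matrix(kme)
  labels <- labels[rownames(kme)]
  mods <- sort(unique(labels[labels > 0]))
  out <- lapply(mods, function(m) {
    col <- paste0("ME", m)
    if (!col %in% colnames(kme)) return(character(0))
    own <- rownames(kme)[labels == m & kme[, col] > mm_cut]
    own[order(-kme[own, col])]
  })
  names(out) <- paste0("ME", mods)
  out
}

#' Build the full signed co-expression network and detect modules
#'
#' End-to-end network stage: optional log2(x+1) transform, soft-threshold
#' selection (unless `beta` is fixed), signed adjacency, TOM dissimilarity,
#' average-linkage module detection with a minimum size, eigengene-based
#' merging, kME, per-tissue gene significance and module-trait correlation.
#' Columns are expected to be tissue-level means by default; pass a
#' per-sample matrix together with `design` to work at sample level.
#'
#' @param x Genes x tissues (or genes x samples) expression matrix, TPM
#'   scale.
#' @param design Optional design (sample-level columns).
#' @param beta Soft power; `NULL` (default) selects it by scale-free fit.
#' @param powers Candidate powers for the selection.
#' @param r2_cut Scale-free fit cut, default 0.9.
#' @param min_size Minimal module size, default 30.
#' @param merge_height Eigengene merge height, default 0.25.
#' @param mm_cut Hub membership threshold, default 0.9.
#' @param cut_height Tree cut fraction, default 0.99.
#' @param log2_transform Correlate `log2(x + 1)` (default) or raw values.
#' @param rescue_kme Unassigned genes with module membership above this
#'   value are assigned to the corresponding module after detection (the
#'   assignment stage of a hybrid tree cut); set to 1 to disable.
#' @return Object of class `coexpr_net`: list with `labels`, `eigengenes`,
#'   `kme`, `kme_p`, `gs`, `trait` (module-trait tables), `hubs`,
#'   `beta`, `fit_table`, `tree`, `input` (the transformed matrix) and
#'   `tissues`.
#' @export
coexpression_network <- function(x, design = NULL, beta = NULL, powers = 1:30,
                                 r2_cut = 0.9, min_size = 30,
                                 merge_height = 0.25, mm_cut = 0.9,
                                 cut_height = 0.99, log2_transform = TRUE,
                                 rescue_kme = 0.9) {
  x <- as.matrix(x)
  inp <- if (log2_transform) log2(x + 1) else x
  fit_table <- NULL
  reached <- NA
  if (is.null(beta)) {
    sel <- pick_soft_threshold(inp, powers = powers, r2_cut = r2_cut)
    beta <- sel$beta
    fit_table <- sel$fit_table
    reached <- sel$reached_cut
  }
  cm <- stats::cor(t(inp))
  cm[is.na(cm)] <- 0
  adj <- signed_adjacency(cm, beta)
  diss <- topological_overlap(adj)
  det <- detect_modules(diss, min_size = min_size, cut_height = cut_height)
  mrg <- merge_modules(inp, det$labels, merge_height = merge_height)
  if (rescue_kme < 1 && nrow(mrg$eigengenes) > 0 && any(mrg$labels == 0)) {
    # membership-based rescue (the assignment stage of a hybrid tree cut):
    # unassigned genes whose correlation with a module eigengene exceeds
    # rescue_kme join that module, then merging is rechecked
    mm0 <- module_membership(inp, mrg$eigengenes)
    grey <- which(mrg$labels == 0)
    best <- max.col(mm0$kme[grey, , drop = FALSE], ties.method = "first")
    top <- mm0$kme[cbind(grey, best)]
    take <- top > rescue_kme
    if (any(take)) {
      lab2 <- mrg$labels
      lab2[grey[take]] <- as.integer(sub("^ME", "",
        colnames(mm0$kme)[best[take]]))
      mrg <- merge_modules(inp, lab2, merge_height = merge_height)
    }
  }
  labels <- mrg$labels
  me <- mrg$eigengenes
  traits <- tissue_traits(colnames(inp), design)
  if (nrow(me) > 0) {
    mm <- module_membership(inp, me)
    tt <- module_trait_correlation(me, traits)
    hubs <- hub_genes(mm$kme, labels, mm_cut = mm_cut)
  } else {
    mm <- list(kme = matrix(numeric(0), nrow(inp), 0,
                            dimnames = list(rownames(inp), NULL)),
               p = matrix(numeric(0), nrow(inp), 0))
    tt <- list(r = NULL, p = NULL, best_module = NULL)
    hubs <- list()
  }
  gs <- lapply(colnames(traits), function(lab) {
    gene_significance(inp, traits[, lab])
  })
  names(gs) <- colnames(traits)
  structure(list(labels = labels, eigengenes = me, kme = mm$kme, kme_p = mm$p,
                 gs = gs, trait = tt, hubs = hubs, beta = beta,
                 reached_cut = reached, fit_table = fit_table,
                 tree = det$tree, input = inp, tissues = colnames(traits)),
            class = "coexpr_net")
}

#' @export
print.coexpr_net <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  cat("signed co-expression network:", length(x$labels), "genes,",
      length(sizes), "modules (beta =", x$beta, ")\n")
  if (length(sizes) > 0) {
    cat("module sizes:", paste(sizes, collapse = ", "),
        "| unassigned:", sum(x$labels == 0), "\n")
  }
  invisible(x)
}

#' Export a module dendrogram as Newick text
#'
#' @param net A [coexpression_network()] result.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(net, file = NULL) {
  stopifnot(inherits(net, "coexpr_net"))
  phy <- ape::as.phylo(net$tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
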