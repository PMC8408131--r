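# Integration of the specificity and network results: key hub genes,
# three-set Venn regions, transcription-factor screening, hypergeometric
# gene-set enrichment and external atlas cross-referencing.

#' Key hub genes: specificity calls intersected with module hubs
#'
#' For each tissue, intersects its highly specific gene set with the hub
#' genes of the module mapped to that tissue (by default the module whose
#' eigengene correlates best with the tissue indicator), and reports the
#' overlap as a percentage of the module's hub set.
#'
#' @param hsg_by_tissue Named list: tissue -> HSG gene ids.
#' @param hub_by_module Named list: module -> hub gene ids.
#' @param module_tissue_map Named character: tissue -> module name (e.g.
#'   the `best_module` element of [module_trait_correlation()]).
#' @return Named list per tissue with elements `genes` (the intersection),
#'   `module`, and `pct_of_hubs`.
#' @export
key_hub_genes <- function(hsg_by_tissue, hub_by_module, module_tissue_map) {
  out <- lapply(names(hsg_by_tissue), function(tt) {
    mod <- module_tissue_map[tt]
    if (is.na(mod) || is.null(mod) || !mod %in% names(hub_by_module)) {
      warning("tissue ", tt, " has no mapped module")
      return(list(genes = character(0), module = NA_character_,
                  pct_of_hubs = NA_real_))
    }
    hubs <- hub_by_module[[mod]]
    inter <- intersect(hsg_by_tissue[[tt]], hubs)
    list(genes = inter, module = unname(mod),
         pct_of_hubs = if (length(hubs) > 0) 100 * length(inter) / length(hubs)
                       else NA_real_)
  })
  names(out) <- names(hsg_by_tissue)
  out
}

#' Three-set Venn region counts
#'
#' @param a,b,c Character vectors of ids.
#' @param names Labels for the three sets.
#' @return Named integer vector of the 7 region counts
#'   (`A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`); the counts
#'   sum to `|A union B union C|`.
#' @export
venn_overlap <- function(a, b, c, names = c("A", "B", "C")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  out <- c(sum(ina & !inb & !inc), sum(!ina & inb & !inc), sum(!ina & !inb & inc),
           sum(ina & inb & !inc), sum(ina & !inb & inc), sum(!ina & inb & inc),
           sum(ina & inb & inc))
  names(out) <- c(paste0(names[1], "_only"), paste0(names[2], "_only"),
                  paste0(names[3], "_only"),
                  paste0(names[1], names[2]), paste0(names[1], names[3]),
                  paste0(names[2], names[3]), paste0(names, collapse = ""))
  out
}

#' Screen genes against a transcription-factor annotation table
#'
#' @param genes Character vector of gene ids (deduplicated before the
#'   join).
#' @param tf_table Data frame with columns `gene_id`, `family`.
#' @return List with `annotated` (data frame gene_id, family) and
#'   `family_counts` (descending table as a data frame).
#' @export
screen_tf <- function(genes, tf_table) {
  if (is.null(tf_table) || nrow(tf_table) == 0) {
    warning("empty transcription-factor table")
    return(list(annotated = data.frame(gene_id = character(0),
                                       family = character(0)),
                family_counts = data.frame(family = character(0),
                                           n = integer(0))))
  }
  stopifnot(all(c("gene_id", "family") %in% names(tf_table)))
  genes <- unique(genes)
  hit <- tf_table[tf_table$gene_id %in% genes, c("gene_id", "family")]
  hit <- hit[!duplicated(hit$gene_id), , drop = FALSE]
  cnt <- sort(table(hit$family), decreasing = TRUE)
  list(annotated = hit,
       family_counts = data.frame(family = names(cnt), n = as.integer(cnt),
                                  row.names = NULL))
}

#' Hypergeometric over-representation test over a gene-set collection
#'
#' For each set, `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where
#' `N` is the universe size, `K` the set size, `n` the query size and `k`
#' the overlap; fold enrichment is `(k/n) / (K/N)`. P-values are adjusted
#' across sets with Benjamini-Hochberg by default.
#'
#' @param query Character vector of gene ids; ids outside the universe are
#'   dropped with a warning.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]);
#'   members outside the universe are dropped.
#' @param universe Character vector of all assayed gene ids.
#' @param fdr_method Method for [stats::p.adjust()], default `"BH"`.
#' @return Data frame sorted by p with columns `set`, `k`, `n`, `K`, `N`,
#'   `fold`, `p`, `fdr`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe,
                                      fdr_method = "BH") {
  universe <- unique(universe)
  query <- unique(query)
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0) {
    warning(length(out_q), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K > 0) (k / n) / (K / N) else 0
    data.frame(set = nm, k = k, n = n, K = K, N = N, fold = fold, p = p)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = fdr_method)
  tab[order(tab$p, tab$set), , drop = FALSE]
}

#' Cross key genes with external atlas flags
#'
#' Keeps, per tissue, the genes flagged as flower-specific in an external
#' expression atlas. Genes absent from the flag table count as unflagged
#' and are tallied in `n_unmapped`.
#'
#' @param genes_by_tissue Named list: tissue -> gene ids.
#' @param atlas_flags Data frame with columns `gene_id`, `flag` (logical or
#'   0/1).
#' @return List with `by_tissue` (named list of flagged gene ids),
#'   `summary` (data frame tissue, n_genes, n_flagged, n_unmapped).
#' @export
atlas_cross <- function(genes_by_tissue, atlas_flags) {
  stopifnot(all(c("gene_id", "flag") %in% names(atlas_flags)))
  flag <- stats::setNames(as.logical(atlas_flags$flag), atlas_flags$gene_id)
  by_tissue <- lapply(genes_by_tissue, function(g) {
    f <- flag[g]
    g[!is.na(f) & f]
  })
  summ <- data.frame(
    tissue = names(genes_by_tissue),
    n_genes = vapply(genes_by_tissue, length, integer(1)),
    n_flagged = vapply(by_tissue, length, integer(1)),
    n_unmapped = vapply(genes_by_tissue, function(g) sum(!g %in% names(flag)),
                        integer(1)),
    row.names = NULL)
  list(by_tissue = by_tissue, summary = summ)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member ids.
#'
#' @param path File path.
#' @return Named list of gene-id vectors; descriptions kept as the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Optional descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
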