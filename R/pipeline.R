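# End-to-end marker discovery: one fitting function (`floramark`) tying the
# preparation, network, specificity and integration stages together, plus a
# config-driven runner that writes a run directory with TSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the marker-discovery pipeline with
#' its default. Defaults follow the reference analysis: expression floor
#' TPM > 1 in at least one tissue; network filter mean TPM >= 1 and
#' variance > 1; signed network with automatic soft-threshold selection at
#' scale-free fit 0.9 (candidates 1..30); minimum module size 30; eigengene
#' merge height 0.25; hub membership > 0.9; HSG tau >= 0.85, constitutive
#' tau < 0.2; housekeeping tau = 0 with TPM > 100 in all tissues; top 10
#' marker genes per tissue; motif width 8, 10 motifs, 50 iterations.
#'
#' @param min_tpm,expressed_mode,expressed_ge Expression filter.
#' @param min_mean_tpm,min_variance Network filter.
#' @param beta Soft power (`NULL` = select automatically).
#' @param powers,r2_cut Soft-threshold selection.
#' @param min_module_size,merge_height,mm_cut,cut_height Network stage.
#' @param hsg_cut,const_cut,hk_tau_max,hk_min_tpm,top_k Specificity stage.
#' @param tau_on Compute tau on `"bins"` (default) or `"qn"`.
#' @param motif_k,n_motifs,n_iter Motif stage.
#' @param log2_transform,sample_level_network Network input handling.
#' @param seed Seed recorded with the run.
#' @return A list of class `floramark_config`.
#' @export
pipeline_config <- function(min_tpm = 1, expressed_mode = "any_tissue",
                            expressed_ge = FALSE,
                            min_mean_tpm = 1, min_variance = 1,
                            beta = NULL, powers = 1:30, r2_cut = 0.9,
                            min_module_size = 30, merge_height = 0.25,
                            mm_cut = 0.9, cut_height = 0.99,
                            hsg_cut = 0.85, const_cut = 0.2,
                            hk_tau_max = 0, hk_min_tpm = 100, top_k = 10,
                            tau_on = "bins",
                            motif_k = 8, n_motifs = 10, n_iter = 50,
                            log2_transform = TRUE,
                            sample_level_network = FALSE, seed = 1) {
  cfg <- as.list(environment())
  ok <- with(cfg, min_tpm >= 0 && min_mean_tpm >= 0 &&
               min_variance >= 0 && (is.null(beta) || beta >= 1) &&
               r2_cut > 0 && r2_cut <= 1 && min_module_size >= 1 &&
               merge_height >= 0 && merge_height <= 1 &&
               mm_cut >= 0 && mm_cut <= 1 &&
               hsg_cut > const_cut && hsg_cut <= 1 && const_cut >= 0 &&
               hk_tau_max >= 0 && hk_min_tpm >= 0 && top_k >= 1 &&
               motif_k >= 4 && n_motifs >= 1 && n_iter >= 1 &&
               tau_on %in% c("bins", "qn") &&
               expressed_mode %in% c("any_tissue", "all_tissues"))
  if (!ok) stop("invalid pipeline configuration", call. = FALSE)
  structure(cfg, class = "floramark_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `floramark_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Discover tissue-specific marker genes from expression data
#'
#' The main entry point: from raw counts (plus gene lengths) or a TPM
#' matrix and a sample design, runs expression preparation (TPM, tissue
#' means, expression filter, quantile normalization, BIN profiles), the
#' tau specificity stage, the signed weighted co-expression network, and
#' their integration into per-tissue key hub genes and a housekeeping
#' list. Optional annotation tables add gene-set enrichment, transcription
#' factor screening and external atlas cross-referencing.
#'
#' @param counts Genes x samples count matrix (with `lengths`), or `NULL`
#'   if `tpm` is given.
#' @param design Data frame with `sample_id`, `tissue` columns.
#' @param lengths Effective gene lengths (required with `counts`).
#' @param tpm Genes x samples TPM matrix (alternative to `counts`).
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param tf_table Optional data frame (`gene_id`, `family`).
#' @param atlas_flags Optional data frame (`gene_id`, `flag`).
#' @param config A [pipeline_config()].
#' @return Object of class `floramark`; see [summary.floramark()]. Main
#'   elements: `tpm_tissue` (tissue-mean TPM), `qn`, `tau` (a
#'   [tau_table()]), `network` (a [coexpression_network()] result),
#'   `key_hubs`, `optimum` (top-k markers per tissue), `housekeeping`,
#'   `enrichment`, `tf`, `atlas`, `counts_summary`.
#' @export
floramark <- function(counts = NULL, design, lengths = NULL, tpm = NULL,
                      gene_sets = NULL, tf_table = NULL, atlas_flags = NULL,
                      config = pipeline_config()) {
  stopifnot(inherits(config, "floramark_config"))
  design <- validate_design(design)
  if (is.null(tpm)) {
    if (is.null(counts) || is.null(lengths)) {
      stop("provide either a tpm matrix or counts plus lengths")
    }
    tpm <- counts_to_tpm(counts, lengths)
  }
  tpm <- as.matrix(tpm)

  # --- preparation -------------------------------------------------------
  tiss <- tissue_means(tpm, design)
  expressed <- filter_expressed(tiss, min_tpm = config$min_tpm,
                                mode = config$expressed_mode,
                                ge = config$expressed_ge)
  prof <- tiss[expressed, , drop = FALSE]
  qn <- normalize_profile(prof)

  # --- tau specificity ---------------------------------------------------
  tt <- tau_table(qn, tau_on = config$tau_on, hsg_cut = config$hsg_cut,
                  const_cut = config$const_cut)
  tau_values <- stats::setNames(tt$table$tau, tt$table$gene)
  optimum <- rank_optimum_genes(tt$scores, tau_values, k = config$top_k)
  hk <- housekeeping_genes(tau_values, prof, tau_max = config$hk_tau_max,
                           min_tpm = config$hk_min_tpm)

  # --- network -----------------------------------------------------------
  net_genes <- filter_for_network(tiss, min_mean_tpm = config$min_mean_tpm,
                                  min_variance = config$min_variance)
  if (config$sample_level_network) {
    net_in <- tpm[net_genes, design$sample_id, drop = FALSE]
    net <- coexpression_network(net_in, design = design, beta = config$beta,
                                powers = config$powers, r2_cut = config$r2_cut,
                                min_size = config$min_module_size,
                                merge_height = config$merge_height,
                                mm_cut = config$mm_cut,
                                cut_height = config$cut_height,
                                log2_transform = config$log2_transform)
  } else {
    net <- coexpression_network(tiss[net_genes, , drop = FALSE],
                                beta = config$beta,
                                powers = config$powers, r2_cut = config$r2_cut,
                                min_size = config$min_module_size,
                                merge_height = config$merge_height,
                                mm_cut = config$mm_cut,
                                cut_height = config$cut_height,
                                log2_transform = config$log2_transform)
  }

  # --- integration -------------------------------------------------------
  hsg <- hsg_by_tissue(tt, hsg_cut = config$hsg_cut)
  key <- key_hub_genes(hsg, net$hubs, net$trait$best_module)
  key_union <- unique(unlist(lapply(key, `[[`, "genes")))

  enrichment <- NULL
  if (!is.null(gene_sets) && length(key_union) > 0) {
    enrichment <- hypergeometric_enrichment(key_union, gene_sets, expressed)
  }
  tf <- if (!is.null(tf_table)) screen_tf(key_union, tf_table) else NULL
  atlas <- if (!is.null(atlas_flags)) {
    atlas_cross(lapply(key, `[[`, "genes"), atlas_flags)
  } else NULL

  counts_summary <- c(n_genes_input = nrow(tpm),
                      n_expressed = length(expressed),
                      n_network = length(net_genes),
                      n_tau = nrow(tt$table),
                      n_asg = sum(tt$table$klass == "ASG", na.rm = TRUE),
                      n_hsg_total = sum(tt$table$tau >= config$hsg_cut, na.rm = TRUE),
                      n_constitutive = sum(tt$table$klass == "constitutive",
                                           na.rm = TRUE),
                      n_housekeeping = nrow(hk),
                      n_modules = length(unique(net$labels[net$labels > 0])),
                      n_key_hubs = length(key_union))

  structure(list(tpm_tissue = prof, qn = qn, tau = tt, network = net,
                 hsg = hsg, key_hubs = key, optimum = optimum,
                 housekeeping = hk, enrichment = enrichment, tf = tf,
                 atlas = atlas, counts_summary = counts_summary,
                 design = design, config = config),
            class = "floramark")
}

#' @export
print.floramark <- function(x, ...) {
  cs <- x$counts_summary
  cat("floramark marker discovery\n")
  cat(sprintf("  %d genes in, %d expressed, %d in network, %d in tau table\n",
              cs["n_genes_input"], cs["n_expressed"], cs["n_network"], cs["n_tau"]))
  cat(sprintf("  %d modules (beta = %s); %d HSG (%d ASG); %d housekeeping; %d key hub genes\n",
              cs["n_modules"], x$network$beta, cs["n_hsg_total"], cs["n_asg"],
              cs["n_housekeeping"], cs["n_key_hubs"]))
  invisible(x)
}

#' Summarize a floramark fit
#'
#' @param object A [floramark()] result.
#' @param ... Unused.
#' @return Invisibly, a list with the per-stage gene counts, module sizes,
#'   per-tissue key hub counts and top marker genes.
#' @export
summary.floramark <- function(object, ...) {
  print(object)
  sizes <- table(object$network$labels[object$network$labels > 0])
  cat("  module sizes:", if (length(sizes)) paste(sizes, collapse = ", ") else "none", "\n")
  cat("  key hub genes per tissue:\n")
  for (tt in names(object$key_hubs)) {
    k <- object$key_hubs[[tt]]
    cat(sprintf("    %-12s %4d genes (%s, %.1f%% of hubs)\n", tt,
                length(k$genes), k$module,
                if (is.na(k$pct_of_hubs)) 0 else k$pct_of_hubs))
  }
  invisible(list(counts = object$counts_summary, module_sizes = sizes,
                 key_hubs = lapply(object$key_hubs, `[[`, "genes"),
                 optimum = object$optimum))
}

#' Diagnostic plots for a floramark fit
#'
#' `type = "tau"` draws the tau distribution; `"fit"` the scale-free fit
#' against candidate powers; `"modules"` module sizes; `"trait"` the
#' module-trait correlation heatmap.
#'
#' @param x A [floramark()] result.
#' @param type One of `"tau"`, `"fit"`, `"modules"`, `"trait"`.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.floramark <- function(x, type = c("tau", "fit", "modules", "trait"), ...) {
  type <- match.arg(type)
  if (type == "tau") {
    graphics::hist(x$tau$table$tau, breaks = 30, main = "tau distribution",
                   xlab = "tau", col = "grey80", ...)
  } else if (type == "fit") {
    ft <- x$network$fit_table
    if (is.null(ft)) stop("network was built with a fixed beta; no fit table")
    graphics::plot(ft$power, ft$fit, type = "b", xlab = "soft power",
                   ylab = "signed scale-free fit", ylim = c(min(0, ft$fit), 1), ...)
    graphics::abline(h = 0.9, lty = 2)
  } else if (type == "modules") {
    sizes <- table(x$network$labels[x$network$labels > 0])
    graphics::barplot(sizes, xlab = "module", ylab = "genes", ...)
  } else {
    r <- x$network$trait$r
    if (is.null(r)) stop("no modules detected")
    graphics::image(t(r), axes = FALSE, zlim = c(-1, 1),
                    col = grDevices::hcl.colors(51, "Blue-Red 2"),
                    main = "module-trait correlation", ...)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(r)), labels = colnames(r),
                   las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(r)), labels = rownames(r),
                   las = 1, cex.axis = 0.7)
  }
  invisible(x)
}

#' Write a gene x column table as TSV with a provenance header
#'
#' @param x Matrix or data frame; matrices are written with the row names
#'   as a leading `gene` column.
#' @param path Output path.
#' @param params Named list recorded in the `#` header line.
#' @export
write_tsv_prov <- function(x, path, params = list()) {
  hdr <- sprintf("# floramark %s%s",
                 as.character(utils::packageVersion("floramark")),
                 if (length(params) > 0) {
                   paste0(" | ", paste(names(params), unlist(params),
                                       sep = "=", collapse = " "))
                 } else "")
  if (is.matrix(x)) {
    x <- data.frame(gene = rownames(x), x, check.names = FALSE, row.names = NULL)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_prov()] (or any headered TSV)
#'
#' @param path File path.
#' @param rownames_from Optional column name turned into row names (the
#'   result is then returned as a matrix).
#' @return Data frame, or numeric matrix when `rownames_from` is given.
#' @export
read_tsv_prov <- function(path, rownames_from = NULL) {
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(rownames_from)) {
    rn <- x[[rownames_from]]
    x <- as.matrix(x[, setdiff(names(x), rownames_from), drop = FALSE])
    rownames(x) <- rn
  }
  x
}

#' Run the full pipeline into an output directory
#'
#' Executes prep -> tau -> network -> integration (and optionally the
#' motif stage) on files or in-memory inputs, writing TSV outputs, a
#' machine-readable `summary.json` and a `MANIFEST` recording stage
#' completion. Reruns with the same inputs, config and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param counts,lengths,tpm,design In-memory inputs (see [floramark()]),
#'   or paths to TSV files (first column = gene id / design columns).
#' @param gene_sets Optional gene sets (list or GMT path).
#' @param tf_table,atlas_flags Optional tables (data frame or TSV path).
#' @param promoters_fg,promoters_bg Optional promoter FASTA paths or
#'   `DNAStringSet`s; when both are given the motif stage runs.
#' @return Invisibly, the summary list (also serialized as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         counts = NULL, lengths = NULL, tpm = NULL, design,
                         gene_sets = NULL, tf_table = NULL, atlas_flags = NULL,
                         promoters_fg = NULL, promoters_bg = NULL) {
  stopifnot(inherits(config, "floramark_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(outdir, "MANIFEST")
  status <- c(prep_tau_network_integration = "pending", motifs = "skipped")
  write_manifest <- function() {
    writeLines(paste(names(status), status, sep = "\t"), manifest)
  }
  write_manifest()

  read_maybe <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else x
  counts <- read_maybe(counts, function(p) read_tsv_prov(p, rownames_from = "gene"))
  tpm <- read_maybe(tpm, function(p) read_tsv_prov(p, rownames_from = "gene"))
  design <- read_maybe(design, read_tsv_prov)
  gene_sets <- read_maybe(gene_sets, read_gmt)
  tf_table <- read_maybe(tf_table, read_tsv_prov)
  atlas_flags <- read_maybe(atlas_flags, read_tsv_prov)
  if (is.character(lengths) && length(lengths) == 1) {
    lt <- read_tsv_prov(lengths)
    lengths <- stats::setNames(lt[[2]], lt[[1]])
  }

  fit <- tryCatch(
    floramark(counts = counts, design = design, lengths = lengths, tpm = tpm,
              gene_sets = gene_sets, tf_table = tf_table,
              atlas_flags = atlas_flags, config = config),
    error = function(e) {
      status["prep_tau_network_integration"] <<- "failed"
      write_manifest()
      stop("pipeline stage failed (prep/tau/network/integration): ",
           conditionMessage(e), call. = FALSE)
    })
  status["prep_tau_network_integration"] <- "done"
  write_manifest()

  p <- function(f) file.path(outdir, f)
  cfg_chr <- lapply(unclass(config), function(v) if (is.null(v)) "auto" else v)
  write_tsv_prov(fit$qn, p("qn_profile.tsv"), list(seed = config$seed))
  tau_out <- cbind(fit$tau$table,
                   as.data.frame(fit$tau$tau_ef)[fit$tau$table$gene, , drop = FALSE])
  write_tsv_prov(tau_out, p("tau.tsv"), list(tau_on = config$tau_on))
  write_tsv_prov(data.frame(gene = names(fit$network$labels),
                            module = fit$network$labels, row.names = NULL),
                 p("modules.tsv"), list(beta = fit$network$beta))
  if (nrow(fit$network$eigengenes) > 0) {
    me <- fit$network$eigengenes
    write_tsv_prov(data.frame(module = rownames(me), me, check.names = FALSE,
                              row.names = NULL), p("eigengenes.tsv"))
    tr <- fit$network$trait$r
    write_tsv_prov(data.frame(module = rownames(tr), tr, check.names = FALSE,
                              row.names = NULL), p("module_trait_r.tsv"))
    dendrogram_newick(fit$network, p("dendrogram.nwk"))
  }
  write_tsv_prov(fit$housekeeping, p("housekeeping.tsv"),
                 list(tau_max = config$hk_tau_max, min_tpm = config$hk_min_tpm))
  key_df <- do.call(rbind, lapply(names(fit$key_hubs), function(tt) {
    k <- fit$key_hubs[[tt]]
    if (length(k$genes) == 0) return(NULL)
    data.frame(tissue = tt, gene = k$genes, module = k$module)
  }))
  if (is.null(key_df)) key_df <- data.frame(tissue = character(0),
                                            gene = character(0),
                                            module = character(0))
  write_tsv_prov(key_df, p("key_hub_genes.tsv"))
  if (!is.null(fit$enrichment)) write_tsv_prov(fit$enrichment, p("enrichment.tsv"))

  summary <- list(
    config = cfg_chr,
    counts = as.list(fit$counts_summary),
    module_sizes = as.list(table(fit$network$labels[fit$network$labels > 0])),
    beta = fit$network$beta,
    key_hubs = lapply(fit$key_hubs, `[[`, "genes"),
    optimum = lapply(fit$optimum, function(d) d$gene),
    housekeeping = fit$housekeeping$gene)

  if (!is.null(promoters_fg) && !is.null(promoters_bg)) {
    mot <- tryCatch({
      fg <- read_maybe(promoters_fg, Biostrings::readDNAStringSet)
      bg <- read_maybe(promoters_bg, Biostrings::readDNAStringSet)
      discover_motifs(fg, bg, k = config$motif_k, n_motifs = config$n_motifs,
                      n_iter = config$n_iter)
    }, error = function(e) {
      status["motifs"] <<- "failed"
      write_manifest()
      stop("pipeline stage failed (motifs): ", conditionMessage(e), call. = FALSE)
    })
    write_meme(mot, p("motifs.meme"))
    sites <- do.call(rbind, lapply(seq_along(mot), function(i) {
      s <- mot[[i]]$sites
      if (nrow(s) == 0) return(NULL)
      cbind(motif = mot[[i]]$consensus, s)
    }))
    if (!is.null(sites)) write_tsv_prov(sites, p("motif_sites.tsv"))
    summary$motifs <- lapply(mot, function(m) {
      list(consensus = m$consensus, enrichment = m$enrichment, p = m$p,
           low_confidence = m$low_confidence)
    })
    status["motifs"] <- "done"
    write_manifest()
  }

  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest()
  invisible(summary)
}
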