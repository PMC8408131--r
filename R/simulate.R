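# Synthetic data with planted ground truth: expression matrices (specific /
# module / housekeeping / background gene classes), promoter sets with planted
# k-mers, and gene-set collections with one enriched set.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  force(code)
}

default_tissues <- function(n) {
  std <- c("CalyptraBA", "CalyxBA", "AntherBA", "FilamentBA", "StigmaBA",
           "OvaryBA", "CalyxAA", "StigmaAA", "OvaryAA", "EmbryoAA")
  if (n <= length(std)) std[seq_len(n)] else paste0("T", seq_len(n))
}

#' Gene plan for the expression simulator
#'
#' Describes how many genes of each truth class to plant. Defaults give a
#' 5,000-gene matrix over 10 tissues: 35 tissue-specific genes per tissue
#' (fold 50 over baseline; half of them leak a tenth of their baseline into
#' `leak_tissues` related tissues, the rest are exclusive), 3 co-expression
#' modules of 50 genes anchored to distinct tissues, 300 housekeeping
#' genes, and background genes making up the remainder of `n_total`.
#'
#' @param n_specific Specific genes per tissue.
#' @param specific_fold Target-tissue fold enrichment over baseline.
#' @param leak_fraction Fraction of specific genes with off-target leakage.
#' @param leak_tissues Number of off-target tissues receiving leakage
#'   (baseline/10) for leaky specific genes.
#' @param spec_base_range Baseline (off-scale) mean TPM range of specific
#'   genes, drawn log-uniformly.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module.
#' @param module_fold Anchor-tissue fold enrichment of module profiles.
#' @param module_base_range Baseline mean TPM range of module genes.
#' @param module_gene_sd Upper bound of the per-gene profile deviation SD
#'   (log scale, drawn uniformly per gene): graded module membership, so
#'   within-module connectivity decays smoothly as in real networks.
#' @param module_anchors Optional tissue indices anchoring each module
#'   (recycled); default modules 1..n_modules anchor tissues 1..n_modules.
#' @param n_housekeeping Housekeeping genes (uniform, high expression).
#' @param hk_range Mean TPM range of housekeeping genes (log-uniform).
#' @param n_background Background genes; if `NA`, filled so the matrix has
#'   `n_total` genes.
#' @param bg_meanlog,bg_sdlog Lognormal parameters of the background mean
#'   TPM distribution.
#' @param n_total Total gene count used when `n_background = NA`.
#' @return A list of class `gene_plan`.
#' @export
gene_plan <- function(n_specific = 35, specific_fold = 50, leak_fraction = 0.5,
                      leak_tissues = 1, spec_base_range = c(100, 600),
                      n_modules = 3, module_size = 50,
                      module_fold = 12, module_base_range = c(2, 8),
                      module_gene_sd = 0.7, module_anchors = NULL,
                      n_housekeeping = 300, hk_range = c(300, 3000),
                      n_background = NA, bg_meanlog = log(30), bg_sdlog = 1.1,
                      n_total = 5000) {
  plan <- list(n_specific = n_specific, specific_fold = specific_fold,
               leak_fraction = leak_fraction, leak_tissues = leak_tissues,
               spec_base_range = spec_base_range,
               n_modules = n_modules, module_size = module_size,
               module_fold = module_fold, module_base_range = module_base_range,
               module_gene_sd = module_gene_sd, module_anchors = module_anchors,
               n_housekeeping = n_housekeeping, hk_range = hk_range,
               n_background = n_background, bg_meanlog = bg_meanlog,
               bg_sdlog = bg_sdlog, n_total = n_total)
  num <- unlist(plan[c("n_specific", "n_modules", "module_size",
                       "n_housekeeping", "n_background")])
  if (any(num < 0, na.rm = TRUE)) stop("plan counts must be nonnegative")
  if (any(c(specific_fold, module_fold) < 1)) stop("fold must be >= 1")
  structure(plan, class = "gene_plan")
}

#' Simulate a multi-tissue RNA-seq count matrix with planted truth
#'
#' Draws negative-binomial counts for four gene classes. Background genes
#' have a constant (lognormal, heavy-tailed) baseline mean across tissues.
#' Specific genes have `baseline * fold` in their target tissue and either
#' zero mean or `baseline / 10` (in a few related tissues) elsewhere.
#' Module genes share a tissue-anchored latent profile plus a per-sample
#' shared lognormal factor, inducing strong within-module correlation.
#' Housekeeping genes have identical means (TPM well above 100) in every
#' tissue and shot noise only (`hk_dispersion = 0`, i.e. Poisson), the
#' idealization of a stable reference gene.
#'
#' The default expression bands are tiered so that each planted class is
#' recoverable by its own detection rule: specific on-target means
#' (5,000-30,000 TPM) sit above the housekeeping band (300-3,000), while
#' specific leakage and module anchors stay below it. Every tissue carries
#' the same number of high specific genes, so the transcriptome
#' composition -- and hence each housekeeping gene's rank under quantile
#' normalization -- is balanced across tissues. Per-sample library sizes
#' are drawn from the interior of `lib_size_range` (padded by sampling
#' noise) so realized column sums stay inside the range.
#'
#' @param n_tissues Number of tissues (default 10).
#' @param replicates Integer scalar or per-tissue vector of replicate
#'   counts. The default (3) emulates a design in which two of ten tissues
#'   lost one replicate (2 instead of 3).
#' @param plan A [gene_plan()].
#' @param dispersion NB dispersion for specific/module/background genes.
#' @param hk_dispersion Dispersion for housekeeping genes (0 = Poisson).
#' @param lib_size_range Range of per-sample library sizes (total counts).
#' @param profile_sd Lognormal SD of the module latent profile smoothing.
#' @param factor_sd SD of the shared per-sample module factor (log scale).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `sim_expression`: `counts` (genes x samples),
#'   `lengths`, `design` (sample_id, tissue, replicate), `truth` (gene_id,
#'   klass, target_tissue, module_id, fold), `lib_sizes`.
#' @export
simulate_expression <- function(n_tissues = 10, replicates = 3,
                                plan = gene_plan(), dispersion = 0.1,
                                hk_dispersion = 0,
                                lib_size_range = c(2e7, 3e7),
                                profile_sd = 0.2, factor_sd = 0.25,
                                seed = 1) {
  stopifnot(n_tissues >= 2, inherits(plan, "gene_plan"))
  tissues <- default_tissues(n_tissues)
  if (length(replicates) == 1) {
    replicates <- rep(replicates, n_tissues)
    if (n_tissues == 10 && replicates[1] == 3) {
      replicates[c(4, 5)] <- 2  # filament / stigma pre-anthesis lost one replicate
    }
  }
  stopifnot(length(replicates) == n_tissues, all(replicates >= 1))
  if (any(replicates < 2)) {
    warning("tissue(s) with a single replicate: correlation stages degrade")
  }

  n_spec <- plan$n_specific * n_tissues
  n_mod <- plan$n_modules * plan$module_size
  n_bg <- plan$n_background
  if (is.na(n_bg)) n_bg <- max(plan$n_total - n_spec - n_mod - plan$n_housekeeping, 0)
  n_genes <- n_spec + n_mod + plan$n_housekeeping + n_bg
  if (n_genes < 1) stop("empty gene plan")

  with_seed(seed, {
    truth <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      klass = rep(c("specific", "module", "housekeeping", "background"),
                  c(n_spec, n_mod, plan$n_housekeeping, n_bg)),
      target_tissue = NA_character_, module_id = NA_integer_,
      fold = 1, stringsAsFactors = FALSE)

    mu <- matrix(0, n_genes, n_tissues,
                 dimnames = list(truth$gene_id, tissues))  # mean TPM per tissue
    disp <- rep(dispersion, n_genes)

    if (n_spec > 0) {
      idx <- which(truth$klass == "specific")
      tt <- rep(seq_len(n_tissues), each = plan$n_specific)
      truth$target_tissue[idx] <- tissues[tt]
      truth$fold[idx] <- plan$specific_fold
      # one magnitude ladder shared by all tissues: every tissue carries the
      # same specific-gene load, keeping the transcriptome composition (and
      # hence TPM ranks of uniform genes) balanced across tissues
      ladder <- exp(stats::runif(plan$n_specific, log(plan$spec_base_range[1]),
                                 log(plan$spec_base_range[2])))
      base <- rep(ladder, n_tissues)
      leaky <- stats::runif(n_spec) < plan$leak_fraction
      for (i in seq_along(idx)) {
        mu[idx[i], tt[i]] <- base[i] * plan$specific_fold
        if (leaky[i] && plan$leak_tissues > 0) {
          others <- setdiff(seq_len(n_tissues), tt[i])
          leak <- sample(others, min(plan$leak_tissues, length(others)))
          mu[idx[i], leak] <- base[i] / 10
        }
      }
    }

    module_of <- rep(NA_integer_, n_genes)
    if (n_mod > 0) {
      idx <- which(truth$klass == "module")
      mid <- rep(seq_len(plan$n_modules), each = plan$module_size)
      module_of[idx] <- mid
      truth$module_id[idx] <- mid
      anchors <- plan$module_anchors
      if (is.null(anchors)) anchors <- seq_len(plan$n_modules)
      anchors <- rep_len(anchors, plan$n_modules)
      truth$target_tissue[idx] <- tissues[anchors[mid]]
      truth$fold[idx] <- plan$module_fold
      base <- exp(stats::runif(n_mod, log(plan$module_base_range[1]),
                               log(plan$module_base_range[2])))
      # graded membership: cube-root transform puts more genes at weak
      # membership, giving a smoothly decaying connectivity distribution
      gsd <- plan$module_gene_sd * stats::runif(n_mod)^(1 / 3)
      for (m in seq_len(plan$n_modules)) {
        latent <- ifelse(seq_len(n_tissues) == anchors[m], log(plan$module_fold), 0) +
          stats::rnorm(n_tissues, 0, profile_sd)
        rows <- idx[mid == m]
        sub <- which(mid == m)
        dev <- matrix(stats::rnorm(length(sub) * n_tissues, 0,
                                   rep(gsd[sub], n_tissues)),
                      length(sub), n_tissues)
        mu[rows, ] <- outer(base[sub], exp(latent)) * exp(dev)
      }
    }

    if (plan$n_housekeeping > 0) {
      idx <- which(truth$klass == "housekeeping")
      lev <- exp(stats::runif(plan$n_housekeeping, log(plan$hk_range[1]),
                              log(plan$hk_range[2])))
      mu[idx, ] <- matrix(lev, length(idx), n_tissues)
      disp[idx] <- hk_dispersion
    }

    if (n_bg > 0) {
      idx <- which(truth$klass == "background")
      lev <- stats::rlnorm(n_bg, plan$bg_meanlog, plan$bg_sdlog)
      mu[idx, ] <- matrix(lev, length(idx), n_tissues)
    }

    lengths <- pmax(round(stats::rlnorm(n_genes, log(1500), 0.4)), 200)
    names(lengths) <- truth$gene_id

    design <- data.frame(
      sample_id = unlist(lapply(seq_len(n_tissues), function(t) {
        paste0(tissues[t], "_r", seq_len(replicates[t]))
      })),
      tissue = rep(tissues, replicates),
      replicate = unlist(lapply(replicates, seq_len)),
      stringsAsFactors = FALSE)
    n_samp <- nrow(design)

    # pad the library-size draw by the column-sum sampling noise so that
    # realized totals stay inside the requested range
    L0 <- mean(lib_size_range)
    f2 <- max(apply(mu, 2, function(m) {
      a <- m * lengths
      if (sum(a) == 0) 0 else sum((a / sum(a))^2)
    }))
    pad <- 0.02 * diff(lib_size_range) + 6 * sqrt(L0 + dispersion * L0^2 * f2)
    pad <- min(pad, 0.45 * diff(lib_size_range))
    lib <- stats::runif(n_samp, lib_size_range[1] + pad, lib_size_range[2] - pad)

    counts <- matrix(0L, n_genes, n_samp,
                     dimnames = list(truth$gene_id, design$sample_id))
    mods <- unique(stats::na.omit(module_of))
    for (s in seq_len(n_samp)) {
      t <- match(design$tissue[s], tissues)
      m_s <- mu[, t]
      if (length(mods) > 0) {
        fac <- stats::rnorm(length(mods), 0, factor_sd)
        for (k in seq_along(mods)) {
          rows <- which(module_of == mods[k])
          m_s[rows] <- m_s[rows] * exp(fac[k] - factor_sd^2 / 2)
        }
      }
      a <- m_s * lengths
      cmu <- if (sum(a) > 0) a / sum(a) * lib[s] else a
      pois <- disp == 0
      x <- numeric(n_genes)
      x[pois] <- stats::rpois(sum(pois), cmu[pois])
      if (any(!pois)) {
        x[!pois] <- stats::rnbinom(sum(!pois), mu = cmu[!pois], size = 1 / disp[!pois])
      }
      counts[, s] <- x
    }

    structure(list(counts = counts, lengths = lengths, design = design,
                   truth = truth, lib_sizes = lib, plan = plan, seed = seed),
              class = "sim_expression")
  })
}

#' @export
print.sim_expression <- function(x, ...) {
  cat("simulated expression:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", length(unique(x$design$tissue)), "tissues )\n")
  print(table(x$truth$klass))
  invisible(x)
}

DNA <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate foreground/background promoter sets with a planted motif
#'
#' Background promoters are i.i.d. uniform DNA. Foreground promoters are
#' drawn from the same distribution, then the motif (or its reverse
#' complement, strand chosen at random) is written at a uniform random
#' offset into `ceiling(insertion_rate * n_fg)` of them.
#'
#' @param n_fg,n_bg Numbers of foreground / background sequences.
#' @param length Sequence length (default 2000, a 2 kb promoter).
#' @param motif Planted consensus (ACGT only), default an 8-mer.
#' @param insertion_rate Fraction of foreground sequences receiving the
#'   motif, in (0, 1].
#' @param seed Integer seed.
#' @return List of class `sim_promoters`: `fg`, `bg`
#'   ([Biostrings::DNAStringSet]) and `truth` (data frame: seq_id, start
#'   (1-based), strand) recording the insertions.
#' @export
simulate_promoters <- function(n_fg = 100, n_bg = 1000, length = 2000,
                               motif = "AAACGTGC", insertion_rate = 1,
                               seed = 1) {
  k <- nchar(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  stopifnot(length >= k, insertion_rate >= 0, insertion_rate <= 1)
  with_seed(seed, {
    fg <- random_dna(n_fg, length)
    bg <- random_dna(n_bg, length)
    names(fg) <- sprintf("fg%04d", seq_len(n_fg))
    names(bg) <- sprintf("bg%04d", seq_len(n_bg))
    n_ins <- ceiling(insertion_rate * n_fg)
    truth <- data.frame(seq_id = character(0), start = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    if (n_ins > 0) {
      who <- sample(n_fg, n_ins)
      for (i in who) {
        pos <- sample(length - k + 1, 1)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") motif else revcomp(motif)
        substr(fg[i], pos, pos + k - 1) <- ins
        truth <- rbind(truth, data.frame(seq_id = names(fg)[i], start = pos,
                                         strand = strand))
      }
    }
    structure(list(fg = Biostrings::DNAStringSet(fg),
                   bg = Biostrings::DNAStringSet(bg),
                   motif = motif, truth = truth, seed = seed),
              class = "sim_promoters")
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' All sets are uniform draws from the universe except the first, which --
#' when `enriched_target` is given -- takes `target_overlap` of its members
#' from the target list, creating a known over-represented set.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of sets.
#' @param set_sizes Integer vector of set sizes (recycled to `n_sets`),
#'   each in 1..length(universe).
#' @param enriched_target Optional gene ids the first set should overlap.
#' @param target_overlap Fraction of the first set drawn from the target.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors (GMT-style); the planted set is
#'   named `"planted_set"`.
#' @export
simulate_gene_sets <- function(universe, n_sets = 10, set_sizes = 50,
                               enriched_target = NULL, target_overlap = 0.8,
                               seed = 1) {
  if (length(universe) == 0) stop("empty universe")
  set_sizes <- rep_len(set_sizes, n_sets)
  if (any(set_sizes < 1)) stop("set sizes must be positive")
  if (any(set_sizes > length(universe))) stop("set size exceeds universe")
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_sizes[i]))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    if (!is.null(enriched_target)) {
      target <- intersect(enriched_target, universe)
      n_in <- min(round(target_overlap * set_sizes[1]), length(target))
      rest <- sample(setdiff(universe, target), set_sizes[1] - n_in)
      sets[[1]] <- c(sample(target, n_in), rest)
      names(sets)[1] <- "planted_set"
    }
    sets
  })
}
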