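# Discriminative k-mer motif discovery: promoter extraction, greedy
# foreground-vs-background k-mer search with masking, PWM construction, and
# column-correlation matching of PWMs against a motif library.

.kmer_cache <- new.env(parent = emptyenv())

kmer_universe <- function(k) {
  key <- paste0("k", k)
  if (!is.null(.kmer_cache[[key]])) return(.kmer_cache[[key]])
  kmers <- Biostrings::mkAllStrings(DNA, k)
  rc <- revcomp(kmers)
  .kmer_cache[[key]] <- list(kmers = kmers, rc_index = match(rc, kmers))
  .kmer_cache[[key]]
}

as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

kmer_counts_both <- function(dss, k) {
  # total occurrences of every k-mer counting both strands; windows
  # containing non-ACGT letters (e.g. the N mask) never match
  uni <- kmer_universe(k)
  cnt <- Biostrings::oligonucleotideFrequency(dss, width = k,
                                              simplify.as = "collapse")
  cnt <- cnt[uni$kmers]
  cnt + cnt[uni$rc_index]
}

count_containing <- function(kmer, dss) {
  # number of sequences containing the k-mer on either strand
  hits <- Biostrings::vcountPattern(kmer, dss)
  rc <- revcomp(kmer)
  if (rc != kmer) hits <- hits + Biostrings::vcountPattern(rc, dss)
  sum(hits > 0)
}

pwm_from_sites <- function(sites, k, pseudocount = 1) {
  if (length(sites) == 0) stop("no sites")
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))
  pwm <- matrix(0, 4, k, dimnames = list(DNA, NULL))
  pwm[rownames(m)[rownames(m) %in% DNA], ] <- m[rownames(m) %in% DNA, ]
  pwm <- pwm + pseudocount
  sweep(pwm, 2, colSums(pwm), "/")
}

collect_sites <- function(consensus, dss, max_mismatch = 1) {
  # fg sites within the given Hamming distance on either strand, oriented
  # to the consensus strand
  k <- nchar(consensus)
  out <- data.frame(seq_id = character(0), start = integer(0),
                    strand = character(0), site = character(0),
                    stringsAsFactors = FALSE)
  scan <- function(pat, strand) {
    mm <- Biostrings::vmatchPattern(pat, dss, max.mismatch = max_mismatch)
    for (i in seq_along(mm)) {
      r <- mm[[i]]
      r <- r[IRanges::start(r) >= 1 & IRanges::end(r) <= Biostrings::width(dss)[i]]
      if (length(r) == 0) next
      s <- as.character(Biostrings::extractAt(dss[[i]], r))
      if (strand == "-") s <- revcomp(s)
      keep <- !grepl("[^ACGT]", s)
      if (!any(keep)) next
      out <<- rbind(out, data.frame(seq_id = names(dss)[i],
                                    start = IRanges::start(r)[keep],
                                    strand = strand, site = s[keep],
                                    stringsAsFactors = FALSE))
    }
  }
  scan(consensus, "+")
  rc <- revcomp(consensus)
  if (rc != consensus) scan(rc, "-")
  out
}

#' De novo discriminative k-mer motif discovery
#'
#' Greedy search for k-mers over-represented in a foreground promoter set
#' relative to a background set, counting both strands. Each round: (1)
#' total k-mer occurrences in the (masked) foreground and background are
#' tallied and scored by pseudocounted log2 odds of the occurrence rates;
#' (2) the top-scoring unseen k-mer becomes the next motif consensus, its
#' sequence-level presence is tested with a hypergeometric tail (motifs
#' failing `candidate_p` are flagged `low_confidence` but still reported,
#' so exactly `n_motifs` motifs are always returned); (3) foreground sites
#' within Hamming distance 1 of the consensus are collected, a
#' position-weight matrix is built from them with a pseudocount, and the
#' sites are masked with N before the next round. A k-mer and its reverse
#' complement are treated as the same motif (the lexicographically smaller
#' one is reported).
#'
#' @param fg,bg Foreground / background sequences
#'   ([Biostrings::DNAStringSet] or character); all at least `k` long and
#'   at least 5 foreground sequences.
#' @param k Motif width, default 8.
#' @param n_motifs Number of motifs to report, default 10.
#' @param n_iter Iteration budget for the greedy refinement, default 50.
#' @param pseudocount Added to occurrence counts and PWM columns.
#' @param candidate_p Family-wise sequence-level cut below which a motif is
#'   considered confident (the hypergeometric p is Bonferroni-corrected
#'   over all canonical k-mers, since the consensus is the best of them),
#'   default 0.05.
#' @param both_strands Count reverse-complement occurrences, default TRUE.
#' @return List of class `motif_list`; each element has `consensus`, `pwm`
#'   (4 x k, columns sum to 1), `enrichment` (log2 odds), `p`, `p_adj`,
#'   `low_confidence`, `n_fg_seqs`, `n_bg_seqs` and `sites` (data frame:
#'   seq_id, start, strand, site).
#' @export
discover_motifs <- function(fg, bg, k = 8, n_motifs = 10, n_iter = 50,
                            pseudocount = 1, candidate_p = 0.05,
                            both_strands = TRUE) {
  fg <- as_dss(fg); bg <- as_dss(bg)
  if (is.null(names(fg))) names(fg) <- paste0("fg", seq_along(fg))
  if (any(Biostrings::width(fg) < k) || any(Biostrings::width(bg) < k)) {
    stop("all sequences must be at least k bases long")
  }
  if (length(fg) < 5) stop("need at least 5 foreground sequences")
  if (length(bg) < length(fg)) stop("background must be at least as large as foreground")

  uni <- kmer_universe(k)
  canonical <- uni$kmers <= uni$kmers[uni$rc_index]
  cnt_bg <- if (both_strands) kmer_counts_both(bg, k) else {
    Biostrings::oligonucleotideFrequency(bg, k, simplify.as = "collapse")[uni$kmers]
  }
  tot_bg <- sum(pmax(Biostrings::width(bg) - k + 1, 0)) * (1 + both_strands)
  tot_fg <- sum(pmax(Biostrings::width(fg) - k + 1, 0)) * (1 + both_strands)

  motifs <- list()
  seen <- character(0)
  masked <- fg
  iter <- 0
  while (length(motifs) < n_motifs && iter < n_iter) {
    iter <- iter + 1
    cnt_fg <- if (both_strands) kmer_counts_both(masked, k) else {
      Biostrings::oligonucleotideFrequency(masked, k, simplify.as = "collapse")[uni$kmers]
    }
    score <- log2(((cnt_fg + pseudocount) / (tot_fg + pseudocount)) /
                  ((cnt_bg + pseudocount) / (tot_bg + pseudocount)))
    avail <- canonical & !(uni$kmers %in% seen)
    if (!any(avail)) break
    idx <- which(avail)[which.max(score[avail])]
    cons <- uni$kmers[idx]
    seen <- c(seen, cons)

    k_fg <- count_containing(cons, masked)
    k_bg <- count_containing(cons, bg)
    n_seq <- length(fg) + length(bg)
    p <- if (k_fg == 0) 1 else
      stats::phyper(k_fg - 1, k_fg + k_bg, n_seq - k_fg - k_bg, length(fg),
                    lower.tail = FALSE)
    sites <- collect_sites(cons, masked, max_mismatch = 1)
    pwm <- if (nrow(sites) > 0) {
      pwm_from_sites(sites$site, k, pseudocount)
    } else {
      pwm_from_sites(cons, k, pseudocount)
    }
    # the consensus is the best of all canonical k-mers, so the presence
    # p-value is Bonferroni-corrected over that selection universe
    p_adj <- min(p * sum(canonical), 1)
    motifs[[length(motifs) + 1]] <- structure(
      list(consensus = cons, pwm = pwm, enrichment = unname(score[idx]),
           p = p, p_adj = p_adj,
           low_confidence = (p_adj >= candidate_p || score[idx] <= 0),
           n_fg_seqs = k_fg, n_bg_seqs = k_bg, sites = sites),
      class = "motif_model")

    if (nrow(sites) > 0) {  # mask discovered sites before the next round
      chars <- as.character(masked)
      for (r in seq_len(nrow(sites))) {
        st <- sites$start[r]
        substr(chars[sites$seq_id[r]], st, st + k - 1) <- strrep("N", k)
      }
      masked <- Biostrings::DNAStringSet(chars)
    }
  }

  if (length(motifs) < n_motifs) {
    # iteration budget exhausted: pad with the best remaining candidates
    cnt_fg <- if (both_strands) kmer_counts_both(masked, k) else {
      Biostrings::oligonucleotideFrequency(masked, k, simplify.as = "collapse")[uni$kmers]
    }
    score <- log2(((cnt_fg + pseudocount) / (tot_fg + pseudocount)) /
                  ((cnt_bg + pseudocount) / (tot_bg + pseudocount)))
    avail <- which(canonical & !(uni$kmers %in% seen))
    avail <- avail[order(-score[avail])]
    for (idx in avail) {
      if (length(motifs) >= n_motifs) break
      cons <- uni$kmers[idx]
      motifs[[length(motifs) + 1]] <- structure(
        list(consensus = cons, pwm = pwm_from_sites(cons, k, pseudocount),
             enrichment = unname(score[idx]), p = 1, p_adj = 1,
             low_confidence = TRUE,
             n_fg_seqs = count_containing(cons, masked),
             n_bg_seqs = count_containing(cons, bg),
             sites = data.frame()),
        class = "motif_model")
    }
  }
  structure(motifs, class = "motif_list")
}

#' @export
print.motif_list <- function(x, ...) {
  cat("discovered motifs (", length(x), "):\n", sep = "")
  for (i in seq_along(x)) {
    m <- x[[i]]
    cat(sprintf("%2d %s  log2-odds %5.2f  p %.3g  fg %d%s\n", i, m$consensus,
                m$enrichment, m$p, m$n_fg_seqs,
                if (m$low_confidence) "  [low confidence]" else ""))
  }
  invisible(x)
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif", x$consensus, "log2-odds", round(x$enrichment, 2),
      "p", signif(x$p, 3), "\n")
  print(round(x$pwm, 3))
  invisible(x)
}

reverse_complement_pwm <- function(pwm) {
  pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
}

#' Ungapped similarity of two position weight matrices
#'
#' Slides one PWM along the other over every offset with at least
#' `min_overlap` overlapping columns, on both strands (the second PWM is
#' also tried as its reverse complement), and scores each alignment by the
#' mean Pearson correlation of aligned probability columns; columns with
#' zero variance contribute 0.
#'
#' @param pwm_a,pwm_b 4 x width column-stochastic matrices with rows
#'   A, C, G, T.
#' @param min_overlap Minimal number of aligned columns, default 4.
#' @return List with `score` (in `[-1, 1]`), `offset` (position of
#'   `pwm_b`'s first column relative to `pwm_a`'s first) and `strand`.
#' @export
pwm_similarity <- function(pwm_a, pwm_b, min_overlap = 4) {
  check_pwm <- function(p) {
    stopifnot(nrow(p) == 4, all(abs(colSums(p) - 1) < 1e-6))
    if (is.null(rownames(p))) rownames(p) <- DNA
    p[DNA, , drop = FALSE]
  }
  pwm_a <- check_pwm(pwm_a)
  pwm_b <- check_pwm(pwm_b)
  ka <- ncol(pwm_a); kb <- ncol(pwm_b)
  if (min(ka, kb) < min_overlap) stop("PWMs too short for the required overlap")
  col_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    stats::cor(u, v)
  }
  best <- list(score = -Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    b <- if (strand == "+") pwm_b else reverse_complement_pwm(pwm_b)
    for (d in seq(-(kb - min_overlap), ka - min_overlap)) {
      ia <- max(1, 1 + d):min(ka, kb + d)
      if (length(ia) < min_overlap) next
      ib <- ia - d
      cs <- vapply(seq_along(ia),
                   function(j) col_cor(pwm_a[, ia[j]], b[, ib[j]]),
                   numeric(1))
      sc <- mean(cs)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, offset = as.integer(d), strand = strand)
      }
    }
  }
  best
}

#' Match a motif against a PWM library
#'
#' @param motif A `motif_model` (from [discover_motifs()]) or a 4 x k PWM.
#' @param library Named list of 4 x width PWMs (e.g. from [read_meme()]).
#' @param top_n Number of matches to return, default 5.
#' @param min_overlap Passed to [pwm_similarity()].
#' @return Data frame sorted by descending score with columns `name`,
#'   `score`, `offset`, `strand`.
#' @export
match_motif_library <- function(motif, library, top_n = 5, min_overlap = 4) {
  if (length(library) == 0) stop("empty motif library")
  pwm <- if (inherits(motif, "motif_model")) motif$pwm else motif
  rows <- lapply(names(library), function(nm) {
    s <- pwm_similarity(pwm, library[[nm]], min_overlap = min_overlap)
    data.frame(name = nm, score = s$score, offset = s$offset,
               strand = s$strand, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, tab$name), , drop = FALSE]
  utils::head(tab, top_n)
}

#' Extract promoter sequences upstream of genes
#'
#' For a gene on the + strand with 0-based half-open coordinates
#' `[start, end)`, the promoter is `[start - length, start)`; on the -
#' strand it is `(end, end + length]`, reverse-complemented. Promoters
#' running off a contig are truncated with a warning; genes on missing
#' contigs are skipped and recorded.
#'
#' @param genome [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param coords Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open, BED convention), or a path to a 6-column
#'   BED file (read with rtracklayer when available).
#' @param length Promoter length in bases, default 2000.
#' @return Named [Biostrings::DNAStringSet] of uppercase promoters; skipped
#'   genes are listed in the `errors` attribute.
#' @export
extract_promoters <- function(genome, coords, length = 2000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  coords <- read_bed_like(coords)
  seqs <- character(0)
  errors <- character(0)
  for (i in seq_len(nrow(coords))) {
    g <- coords[i, ]
    if (!g$chrom %in% names(genome)) {
      errors <- c(errors, sprintf("%s: contig %s not in genome", g$name, g$chrom))
      next
    }
    clen <- Biostrings::width(genome[match(g$chrom, names(genome))])
    if (g$strand == "-") {
      s1 <- g$end + 1          # 1-based
      s2 <- g$end + length
    } else {
      s1 <- g$start - length + 1
      s2 <- g$start
    }
    t1 <- max(s1, 1); t2 <- min(s2, clen)
    if (t1 > t2) {
      errors <- c(errors, sprintf("%s: promoter entirely outside contig", g$name))
      next
    }
    if (t1 != s1 || t2 != s2) {
      warning("promoter of ", g$name, " truncated to ", t2 - t1 + 1, " bases")
    }
    s <- toupper(as.character(Biostrings::subseq(genome[[g$chrom]], t1, t2)))
    if (g$strand == "-") s <- revcomp(s)
    seqs[g$name] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "errors") <- errors
  out
}

read_bed_like <- function(coords) {
  if (is.character(coords) && length(coords) == 1) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      df <- as.data.frame(rtracklayer::import(coords, format = "BED"))
      coords <- data.frame(chrom = as.character(df$seqnames),
                           start = df$start - 1L,  # back to 0-based
                           end = df$end,
                           name = if (!is.null(df$name)) df$name else
                             paste0("feature", seq_len(nrow(df))),
                           strand = as.character(df$strand),
                           stringsAsFactors = FALSE)
    } else {
      tab <- utils::read.table(coords, sep = "\t", comment.char = "#",
                               stringsAsFactors = FALSE)
      if (ncol(tab) < 6) stop("BED file must have 6 columns (strand needed)")
      coords <- stats::setNames(tab[, 1:6],
                                c("chrom", "start", "end", "name", "score", "strand"))
    }
  }
  coords <- as.data.frame(coords)
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(coords)))
  coords$strand[!coords$strand %in% c("+", "-")] <- "+"
  coords
}

#' Write motifs in minimal MEME-like text
#'
#' @param motifs A `motif_list`, a single `motif_model`, or a named list of
#'   4 x k PWMs.
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    pwm <- if (inherits(m, "motif_model")) m$pwm else m
    nm <- if (inherits(m, "motif_model")) m$consensus else names(motifs)[i]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", ncol(pwm)), con)
    for (j in seq_len(ncol(pwm))) {
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a minimal MEME-like motif file
#'
#' @param path File path.
#' @return Named list of 4 x width PWMs (rows A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- sub("^MOTIF\\s+", "", lines[i])
      nm <- strsplit(nm, "\\s+")[[1]][1]
      j <- i + 1
      while (j <= length(lines) && !grepl("letter-probability", lines[j])) j <- j + 1
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1):(j + w)]
      pwm <- t(vapply(rows, function(r) {
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      }, numeric(4)))
      pwm <- t(pwm)  # 4 x w
      rownames(pwm) <- DNA
      out[[nm]] <- pwm
      i <- j + w
    }
    i <- i + 1
  }
  out
}
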