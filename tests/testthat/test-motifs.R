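test_that("promoter extraction obeys BED coordinates, strand and truncation", {
  genome <- toy_genome()
  # chr2 is ACGTACGTAC repeated; a + gene starting at 0-based 500 has the
  # 8 bases before it as its length-8 promoter
  coords <- data.frame(chrom = "chr2", start = 500, end = 520,
                       name = "gplus", strand = "+")
  pr <- extract_promoters(genome, coords, length = 8)
  expect_equal(as.character(pr[["gplus"]]), "GTACGTAC")

  # - strand gene: promoter is downstream, reverse-complemented
  cminus <- data.frame(chrom = "chr2", start = 480, end = 500,
                       name = "gminus", strand = "-")
  prm <- extract_promoters(genome, cminus, length = 8)
  expect_equal(as.character(prm[["gminus"]]), rc_chr("ACGTACGT"))

  # truncation at the contig start
  cshort <- data.frame(chrom = "chr1", start = 5, end = 10,
                       name = "edge", strand = "+")
  expect_warning(pre <- extract_promoters(genome, cshort, length = 2000),
                 "truncated")
  expect_equal(unname(Biostrings::width(pre)), 5L)

  # missing contig is skipped with an error record
  cbad <- data.frame(chrom = "chrX", start = 10, end = 20,
                     name = "lost", strand = "+")
  prb <- extract_promoters(genome, cbad, length = 5)
  expect_length(prb, 0)
  expect_match(attr(prb, "errors"), "chrX")
})

test_that("discovery recovers a planted 8-mer as the top motif", {
  pr <- simulate_promoters(n_fg = 30, n_bg = 150, length = 300,
                           motif = "AAACGTGC", insertion_rate = 1, seed = 17)
  mot <- discover_motifs(pr$fg, pr$bg, n_motifs = 3)
  expect_length(mot, 3)
  expect_true(mot[[1]]$consensus %in% c("AAACGTGC", rc_chr("AAACGTGC")))
  expect_false(mot[[1]]$low_confidence)
  expect_gt(mot[[1]]$n_fg_seqs, 25)
  # PWM columns are probability distributions; sites carry the consensus
  expect_equal(colSums(mot[[1]]$pwm), rep(1, 8), tolerance = 1e-12)
  expect_gt(nrow(mot[[1]]$sites), 20)
  # masking keeps consensi pairwise distinct
  cons <- vapply(mot, `[[`, character(1), "consensus")
  expect_equal(anyDuplicated(cons), 0L)
})

test_that("null foreground yields only low-confidence motifs", {
  pr <- simulate_promoters(n_fg = 20, n_bg = 100, length = 250,
                           motif = "AAACGTGC", insertion_rate = 0, seed = 18)
  mot <- discover_motifs(pr$fg, pr$bg, n_motifs = 5)
  expect_length(mot, 5)
  expect_true(all(vapply(mot, `[[`, logical(1), "low_confidence")))
})

test_that("discovery is invariant to reverse-complementing the foreground", {
  pr <- simulate_promoters(n_fg = 25, n_bg = 120, length = 250,
                           motif = "TTGACCGA", insertion_rate = 1, seed = 19)
  m1 <- discover_motifs(pr$fg, pr$bg, n_motifs = 2)
  m2 <- discover_motifs(Biostrings::reverseComplement(pr$fg), pr$bg,
                        n_motifs = 2)
  canon <- function(x) pmin(x, rc_chr(x))
  expect_equal(canon(m1[[1]]$consensus), canon(m2[[1]]$consensus))
})

test_that("discovery input contracts are enforced", {
  pr <- simulate_promoters(n_fg = 10, n_bg = 10, length = 50, seed = 20)
  expect_error(discover_motifs(pr$fg[1:3], pr$bg), "at least 5")
  expect_error(discover_motifs(pr$fg, pr$bg[1:2]), "at least as large")
  expect_error(discover_motifs(c(pr$fg, Biostrings::DNAStringSet("ACG")),
                               pr$bg), "at least k")
})

test_that("PWM similarity scores alignment, strand and uninformative columns", {
  p <- consensus_pwm("AAACGTGC")
  self <- pwm_similarity(p, p)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$offset, 0L)
  expect_equal(self$strand, "+")

  rc <- unname(p[c(4, 3, 2, 1), rev(seq_len(ncol(p)))])
  s <- pwm_similarity(p, rc)
  expect_equal(s$score, 1, tolerance = 1e-12)
  expect_equal(s$strand, "-")

  uni <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_similarity(p, uni)$score, 0)
  expect_error(pwm_similarity(p[, 1:3], p), "overlap")

  # offset alignment: the same motif embedded with a 2-column shift
  shifted <- cbind(consensus_pwm("GG"), p)[, 1:8]
  sh <- pwm_similarity(p, shifted)
  expect_equal(sh$offset, -2L)
  expect_gt(sh$score, 0.7)
})

test_that("library matching ranks the query itself first", {
  p <- consensus_pwm("AAACGTGC")
  lib <- list(self = p, other = consensus_pwm("GGGGCCCC"),
              third = consensus_pwm("TTTTAAAA"))
  m <- match_motif_library(p, lib, top_n = 2)
  expect_equal(m$name[1], "self")
  expect_equal(m$score[1], 1, tolerance = 1e-12)
  expect_equal(nrow(m), 2)
  full <- match_motif_library(p, lib, top_n = 10)
  expect_equal(nrow(full), 3)
  expect_error(match_motif_library(p, list()), "empty")
})

test_that("random PWM libraries rarely score as strong matches", {
  set.seed(23)
  p <- consensus_pwm("AAACGTGC")
  lib <- lapply(1:20, function(i) {
    m <- matrix(rexp(32), 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    sweep(m, 2, colSums(m), "/")
  })
  names(lib) <- paste0("r", 1:20)
  m <- match_motif_library(p, lib, top_n = 20)
  expect_lt(max(m$score), 0.8)
})

test_that("MEME-like motif text round-trips", {
  mots <- list(m1 = consensus_pwm("AAACGTGC"), m2 = consensus_pwm("TTGACC"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(mots, path)
  back <- read_meme(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(back$m1, mots$m1, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(ncol(back$m2), 6)
})
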