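# Small deterministic fixtures shared across tests.

# Genes x tissues matrix with three orthogonal planted blocks plus noise
# genes, built directly in log-expression space (fast; no count sampling).
planted_block_matrix <- function(n_per_block = 50, n_noise = 50, n_tissues = 10,
                                 amplitude = 5, noise_sd = 0.3, seed = 101) {
  set.seed(seed)
  rows <- list()
  truth <- integer(0)
  for (m in seq_len(3)) {
    anchor <- as.numeric(seq_len(n_tissues) == m) * amplitude
    for (g in seq_len(n_per_block)) {
      rows[[length(rows) + 1]] <- anchor + rnorm(n_tissues, 0, noise_sd)
      truth <- c(truth, m)
    }
  }
  for (g in seq_len(n_noise)) {
    rows[[length(rows) + 1]] <- rnorm(n_tissues, 0, noise_sd)
    truth <- c(truth, 0L)
  }
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                      paste0("T", seq_len(n_tissues)))
  list(x = x, truth = truth)
}

# Tiny two-contig genome for promoter extraction tests.
toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    chr1 = paste(rep(c("A", "C", "G", "T"), 5), collapse = ""),  # 20 bp
    chr2 = strrep("ACGTACGTAC", 100)                              # 1000 bp
  ))
}

# Point-mass PWM for a consensus string.
consensus_pwm <- function(consensus, pseudo = 0.01) {
  k <- nchar(consensus)
  pwm <- matrix(pseudo, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(k)) pwm[substr(consensus, j, j), j] <- 1
  sweep(pwm, 2, colSums(pwm), "/")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
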