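test_that("identical seeds reproduce the simulation bitwise", {
  plan <- gene_plan(n_specific = 3, n_modules = 1, module_size = 5,
                    n_housekeeping = 5, n_background = 30, n_total = NA)
  a <- simulate_expression(n_tissues = 4, replicates = 2, plan = plan, seed = 9)
  b <- simulate_expression(n_tissues = 4, replicates = 2, plan = plan, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_expression(n_tissues = 4, replicates = 2, plan = plan, seed = 10)
  expect_false(identical(a$counts, c$counts))
})

test_that("degenerate plans and invalid plans are handled", {
  plan <- gene_plan(n_specific = 0, n_modules = 0, n_housekeeping = 0,
                    n_background = 100, n_total = NA)
  sim <- suppressWarnings(simulate_expression(n_tissues = 3, replicates = 2,
                                              plan = plan, seed = 1))
  expect_equal(nrow(sim$truth), 100)
  expect_true(all(sim$truth$klass == "background"))
  expect_error(gene_plan(n_background = -5), "nonnegative")
  expect_error(gene_plan(specific_fold = 0.5), "fold")
  expect_warning(
    simulate_expression(n_tissues = 3, replicates = 1, plan = plan, seed = 1),
    "single replicate")
})

test_that("planted specific genes dominate their target tissue in the realized matrix", {
  plan <- gene_plan(n_specific = 50, specific_fold = 50, n_modules = 0,
                    n_housekeeping = 0, n_background = 200, n_total = NA)
  sim <- simulate_expression(n_tissues = 4, replicates = 3, plan = plan, seed = 5)
  tiss <- tissue_means(counts_to_tpm(sim$counts, sim$lengths), sim$design)
  spec <- sim$truth[sim$truth$klass == "specific", ]
  on_target <- tiss[cbind(spec$gene_id, spec$target_tissue)]
  off_max <- vapply(seq_len(nrow(spec)), function(i) {
    max(tiss[spec$gene_id[i], setdiff(colnames(tiss), spec$target_tissue[i])])
  }, numeric(1))
  expect_true(all(on_target > off_max))
})

test_that("realized library sizes stay inside the requested range", {
  sim <- simulate_expression(plan = gene_plan(n_total = 1000), seed = 2,
                             lib_size_range = c(2e7, 3e7))
  cs <- colSums(sim$counts)
  expect_true(all(cs >= 2e7 & cs <= 3e7))
})

test_that("promoter simulation plants the motif as recorded", {
  pr <- simulate_promoters(n_fg = 10, n_bg = 5, length = 60,
                           motif = "AAACGTGC", insertion_rate = 1, seed = 3)
  expect_length(pr$fg, 10)
  rc <- rc_chr("AAACGTGC")
  hits <- Biostrings::vcountPattern("AAACGTGC", pr$fg) +
    Biostrings::vcountPattern(rc, pr$fg)
  expect_true(all(hits >= 1))
  # recorded positions contain the motif on the recorded strand
  for (i in seq_len(nrow(pr$truth))) {
    s <- as.character(Biostrings::subseq(pr$fg[[pr$truth$seq_id[i]]],
                                         pr$truth$start[i],
                                         pr$truth$start[i] + 7))
    expect_equal(s, if (pr$truth$strand[i] == "+") "AAACGTGC" else rc)
  }
  # no insertion leaves foreground and background alike
  pr0 <- simulate_promoters(n_fg = 5, n_bg = 5, length = 30,
                            motif = "AAACGTGC", insertion_rate = 0, seed = 4)
  expect_equal(nrow(pr0$truth), 0)
  # boundary: sequence length equal to the motif length
  pr8 <- simulate_promoters(n_fg = 4, n_bg = 2, length = 8,
                            motif = "AAACGTGC", insertion_rate = 1, seed = 5)
  expect_true(all(as.character(pr8$fg) %in% c("AAACGTGC", rc)))
  expect_error(simulate_promoters(motif = "AAANGTGC"), "A, C, G, T")
})

test_that("gene-set simulation plants one enriched set and writes valid GMT", {
  universe <- sprintf("g%03d", 1:200)
  target <- universe[1:40]
  sets <- simulate_gene_sets(universe, n_sets = 5, set_sizes = 30,
                             enriched_target = target, target_overlap = 1,
                             seed = 6)
  expect_named(sets)
  expect_equal(names(sets)[1], "planted_set")
  expect_true(all(sets$planted_set %in% target))
  expect_error(simulate_gene_sets(character(0), 2, 5), "empty universe")
  expect_error(simulate_gene_sets(universe, 2, 0), "positive")
  expect_error(simulate_gene_sets(universe, 2, 500), "exceeds")

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, sort), lapply(sets, sort))
})

test_that("uniform random sets show no systematic enrichment", {
  set.seed(7)
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:50]
  folds <- replicate(100, {
    sets <- simulate_gene_sets(universe, n_sets = 1, set_sizes = 40,
                               seed = sample.int(1e6, 1))
    hypergeometric_enrichment(query, sets, universe)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.15)
})
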