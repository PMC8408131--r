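test_that("signed adjacency transforms correlations as specified", {
  cm <- matrix(c(1, 1, -1, 0, 1, 1, -1, 0,
                 -1, -1, 1, 0, 0, 0, 0, 1), 4, 4)
  a <- signed_adjacency(cm, 12)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^12)
  expect_true(all(diag(a) == 1))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(signed_adjacency(cm, 0), "positive")
  expect_error(signed_adjacency(matrix(2, 2, 2), 2), "\\[-1, 1\\]")
  # raising beta never increases an off-diagonal entry
  set.seed(21)
  r <- cor(matrix(rnorm(80), 10, 8))
  a6 <- signed_adjacency(r, 6); a12 <- signed_adjacency(r, 12)
  off <- row(r) != col(r)
  expect_true(all(a12[off] <= a6[off] + 1e-15))
})

test_that("scale-free fit is exact on a constructed power-law degree sequence", {
  # isolated degree values 10,20,40,80 with counts proportional to 1/k:
  # p(k) is exactly a power law over the equal-width bins
  k <- rep(c(10, 20, 40, 80), times = c(8, 4, 2, 1))
  sf <- suppressWarnings(floramark:::scale_free_fit(k))  # lm on an exact fit
  expect_equal(sf$fit, 1, tolerance = 1e-10)
  expect_lt(sf$slope, 0)
})

test_that("soft-threshold selection returns the first power crossing the cut", {
  mats <- planted_block_matrix(n_per_block = 30, n_noise = 60, seed = 31)
  sel <- suppressWarnings(pick_soft_threshold(mats$x, powers = 1:30))
  tab <- sel$fit_table
  crossing <- tab$power[!is.na(tab$fit) & tab$fit >= 0.9]
  if (length(crossing) > 0) {
    expect_equal(sel$beta, crossing[1])
    expect_true(sel$reached_cut)
    expect_gte(tab$fit[tab$power == sel$beta], 0.9)
  } else {
    expect_equal(sel$beta, tab$power[which.max(tab$fit)])
    expect_false(sel$reached_cut)
  }
  # mean connectivity decreases with the power
  expect_true(all(diff(tab$mean_k) < 0))
})

test_that("topological overlap matches closed forms and a brute-force oracle", {
  tri <- matrix(1, 3, 3)
  expect_equal(unname(topological_overlap(tri)), matrix(0, 3, 3))

  # two genes with no connection and no shared neighbor are maximally distant
  a <- diag(2)
  expect_equal(topological_overlap(a)[1, 2], 1)

  set.seed(41)
  n <- 6
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
  d <- topological_overlap(m)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + m[i, u] * m[u, j]
    ki <- sum(m[i, -i]); kj <- sum(m[j, -j])
    oracle[i, j] <- 1 - (l + m[i, j]) / (min(ki, kj) + 1 - m[i, j])
  }
  expect_equal(unname(d), oracle, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("module detection recovers planted blocks and greys small ones", {
  mats <- planted_block_matrix(seed = 51)
  cm <- cor(t(mats$x))
  diss <- topological_overlap(signed_adjacency(cm, 12))
  det <- detect_modules(diss)
  found <- det$labels[mats$truth > 0]
  expect_gte(mclust::adjustedRandIndex(mats$truth[mats$truth > 0], found), 0.9)
  expect_equal(length(unique(found[found > 0])), 3)

  # a 10-gene block cannot survive min_size = 30
  small <- planted_block_matrix(n_per_block = 10, n_noise = 80, seed = 52)
  d2 <- topological_overlap(signed_adjacency(cor(t(small$x)), 12))
  det2 <- detect_modules(d2)
  expect_true(all(det2$labels[small$truth == 1] == 0))

  # identical genes collapse into one module
  d3 <- matrix(0, 40, 40, dimnames = list(paste0("g", 1:40), NULL))
  det3 <- detect_modules(d3)
  expect_equal(unname(det3$labels), rep(1L, 40))

  expect_warning(detect_modules(matrix(0, 5, 5), min_size = 30), "fewer genes")
})

test_that("eigengenes are the leading principal direction", {
  set.seed(61)
  v <- rnorm(10)
  x <- matrix(rep(v, each = 20), 20, 10) * runif(20, 0.5, 2)
  rownames(x) <- paste0("g", 1:20); colnames(x) <- paste0("T", 1:10)
  labels <- setNames(rep(1L, 20), rownames(x))
  me <- module_eigengenes(x, labels)
  expect_equal(abs(cor(me[1, ], v)), 1, tolerance = 1e-10)
  expect_equal(sum(me[1, ]^2), 1, tolerance = 1e-12)
  expect_gte(cor(me[1, ], colMeans(t(scale(t(x))))), 0)

  # maximal variance: the eigengene explains at least as much as any of
  # 1000 random unit directions
  y <- matrix(rnorm(300), 30, 10)
  dimnames(y) <- list(paste0("h", 1:30), paste0("T", 1:10))
  mey <- module_eigengenes(y, setNames(rep(1L, 30), rownames(y)))
  z <- t(scale(t(y)))
  var_e <- sum((z %*% mey[1, ])^2)
  rand <- replicate(1000, {
    u <- rnorm(10); u <- u / sqrt(sum(u^2))
    sum((z %*% u)^2)
  })
  expect_true(all(var_e >= rand - 1e-9))

  # mirrored halves: sign convention follows the mean profile
  g <- rnorm(10)
  xm <- rbind(matrix(rep(g, each = 10), 10, 10),
              matrix(rep(-g, each = 5), 5, 10))
  dimnames(xm) <- list(paste0("m", 1:15), paste0("T", 1:10))
  mem <- module_eigengenes(xm, setNames(rep(1L, 15), rownames(xm)))
  expect_equal(abs(cor(mem[1, ], g)), 1, tolerance = 1e-10)
  expect_warning(
    module_eigengenes(matrix(1, 3, 10, dimnames = list(letters[1:3], NULL)),
                      setNames(rep(1L, 3), letters[1:3])),
    "constant")
})

test_that("eigengene merging joins only close modules", {
  set.seed(71)
  base <- rnorm(10)
  near <- base + rnorm(10, 0, 0.25)   # cor ~ 0.95-0.98
  far <- rnorm(10)
  mk <- function(v, n) matrix(rep(v, each = n), n, 10) + rnorm(n * 10, 0, 0.05)
  x <- rbind(mk(base, 10), mk(near, 10), mk(far, 10))
  dimnames(x) <- list(paste0("g", 1:30), paste0("T", 1:10))
  labels <- setNames(rep(1:3, each = 10), rownames(x))
  me0 <- module_eigengenes(x, labels)
  stopifnot(1 - cor(me0[1, ], me0[2, ]) < 0.25, 1 - cor(me0[1, ], me0[3, ]) > 0.25)
  mrg <- merge_modules(x, labels)
  expect_equal(length(unique(mrg$labels)), 2)
  expect_equal(unname(mrg$labels[1]), unname(mrg$labels[11]))
  # post-merge, no retained pair is closer than the merge height
  d <- 1 - cor(t(mrg$eigengenes))
  expect_gte(min(d[upper.tri(d)]), 0.25)
  # single module is left untouched
  one <- merge_modules(x[1:10, ], setNames(rep(1L, 10), rownames(x)[1:10]))
  expect_equal(unique(one$labels), 1L)
})

test_that("module membership reproduces the Student-t correlation test", {
  set.seed(81)
  e <- matrix(rnorm(10), 1, 10, dimnames = list("ME1", paste0("T", 1:10)))
  x <- rbind(same = e[1, ], flat = rep(2, 10),
             noise = rnorm(10))
  colnames(x) <- colnames(e)
  mm <- module_membership(x, e)
  expect_equal(mm$kme["same", "ME1"], 1)
  expect_equal(mm$kme["flat", "ME1"], 0)
  expect_equal(mm$p["flat", "ME1"], 1)
  # frozen oracle: r = 0.97, n = 10 -> p = 3.4178e-6 (two-sided t, df 8)
  expect_equal(floramark:::cor_pvalue(0.97, 10), 3.41776285e-06,
               tolerance = 1e-6)
})

test_that("gene significance scores tissue association", {
  trait <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  x <- rbind(hit = trait * 10, flat = rep(3, 10), anti = -trait)
  colnames(x) <- paste0("T", 1:10)
  gs <- gene_significance(x, trait)
  expect_equal(gs$gs[gs$gene == "hit"], 1)
  expect_equal(gs$gs[gs$gene == "flat"], 0)
  expect_equal(gs$gs[gs$gene == "anti"], 1)  # absolute by default
  expect_equal(gene_significance(x, trait, signed = TRUE)$gs[3], -1)
  expect_error(gene_significance(x, rep(1, 10)), "zero variance")
  expect_error(gene_significance(x, c(2, rep(0, 9))), "binary")
})

test_that("module-trait correlation finds each trait's best module", {
  traits <- tissue_traits(paste0("T", 1:10))
  expect_equal(dim(traits), c(10L, 10L))
  me <- rbind(ME1 = as.numeric(scale(traits[, 1])),
              ME2 = as.numeric(scale(traits[, 2])))
  colnames(me) <- paste0("T", 1:10)
  mt <- module_trait_correlation(me, traits)
  expect_equal(mt$r["ME1", "T1"], 1, tolerance = 1e-12)
  expect_equal(unname(mt$best_module["T1"]), "ME1")
  expect_equal(unname(mt$best_module["T2"]), "ME2")
  expect_equal(mt$p["ME1", "T1"], floramark:::cor_pvalue(1, 10))
})

test_that("hub genes require membership above the cut in their own module", {
  kme <- rbind(a = c(ME1 = 0.95, ME2 = 0.1),
               b = c(ME1 = 0.85, ME2 = 0.2),
               c = c(ME1 = 0.2, ME2 = 0.99))
  labels <- c(a = 1L, b = 1L, c = 2L)
  hubs <- hub_genes(kme, labels)
  expect_equal(hubs$ME1, "a")
  expect_equal(hubs$ME2, "c")
  labels2 <- c(a = 1L, b = 1L, c = 1L)
  expect_equal(hub_genes(kme, labels2)$ME1, "a")
})

test_that("the full network stage recovers planted structure end to end", {
  mats <- planted_block_matrix(seed = 91)
  net <- suppressWarnings(coexpression_network(2^mats$x, log2_transform = TRUE))
  found <- net$labels[mats$truth > 0]
  expect_gte(mclust::adjustedRandIndex(mats$truth[mats$truth > 0], found), 0.9)
  # each planted block's module is best-correlated with its anchor tissue
  for (m in 1:3) {
    lab <- as.integer(names(which.max(table(found[mats$truth == m]))))
    expect_equal(unname(net$trait$best_module[paste0("T", m)]),
                 paste0("ME", lab))
  }
  nwk <- dendrogram_newick(net)
  expect_match(nwk, "^\\(.*;$")
})
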