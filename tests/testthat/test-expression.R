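# FPKM, DEG calling, profile clustering, GO enrichment and ortholog
# expression correlation.

test_that("FPKM follows the closed form and its normalization property", {
  counts <- matrix(c(100, 999900), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(counts, c(g1 = 1000, g2 = 500))
  expect_equal(f["g1", "s1"], 100)   # 100 * 1e9 / (1e6 * 1000)
  # zero counts stay zero; doubling a library leaves FPKM unchanged
  expect_equal(fpkm(counts * 2, c(g1 = 1000, g2 = 500)), f)
  counts0 <- matrix(c(0, 10), nrow = 2,
                    dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(fpkm(counts0, c(g1 = 1000, g2 = 500))["g1", "s1"], 0)
  expect_error(fpkm(counts * 0, c(g1 = 1000, g2 = 500)), "library")
  expect_error(fpkm(counts, c(g1 = 1000)), "length")
})

test_that("the DEG rule needs both thresholds and preserves p order", {
  set.seed(41)
  n <- 200
  counts <- matrix(rnbinom(n * 6, mu = 100, size = 10), nrow = n,
                   dimnames = list(paste0("g", 1:n),
                                   c(paste0("c", 1:3), paste0("t", 1:3))))
  # one gene with a clear but small (< 1 log2) shift
  counts["g1", 4:6] <- round(counts["g1", 4:6] * 1.7)
  design <- data.frame(sample = colnames(counts),
                       condition = rep(c("control", "cold"), each = 3))
  lens <- setNames(rep(1000, n), rownames(counts))
  d <- call_degs(counts, lens, design, "cold")
  expect_true(all(d$call[abs(d$log2fc) <= 1] == "none"))
  expect_true(all(d$call[d$padj >= 0.05] == "none"))
  # BH adjustment is monotone in the raw p
  o <- order(d$p)
  expect_true(all(diff(d$padj[o]) >= -1e-12))
  # row permutation invariance
  perm <- sample(n)
  d2 <- call_degs(counts[perm, ], lens, design, "cold")
  expect_equal(d2[match(d$gene, d2$gene), "log2fc"], d$log2fc)
  expect_error(call_degs(counts, lens, design, "cold", control = "mock"),
               "control")
})

test_that("fuzzy c-means recovers planted shapes; k = 1 is total variance", {
  set.seed(2)
  shapes <- list(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2),
                 c(-2, 2, 0, -1, -2), c(1, -2, 1, 2, -1))
  prof <- do.call(rbind, lapply(shapes, function(s)
    t(vapply(1:20, function(i) s + rnorm(5, 0, 0.15), numeric(5)))))
  rownames(prof) <- paste0("g", seq_len(nrow(prof)))
  cl <- cluster_profiles(prof, k = 4, seed = 3)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl$cluster, rep(1:4, each = 20))
  expect_equal(ari, 1)
  # k = 1: single cluster, objective = total variance of the z-scores
  c1 <- cluster_profiles(prof, k = 1, seed = 3)
  z <- t(scale(t(prof)))
  expect_equal(c1$objective, sum(sweep(z, 2, colMeans(z))^2))
  expect_true(all(c1$cluster == 1))
  # constant profiles are excluded with a warning
  prof2 <- rbind(prof, flatg = rep(1, 5))
  expect_warning(cl2 <- cluster_profiles(prof2, k = 4, seed = 3),
                 "constant")
  expect_false("flatg" %in% names(cl2$cluster))
})

test_that("the c-means objective never increases with more iterations", {
  set.seed(7)
  z <- t(scale(t(matrix(rnorm(40 * 5), 40, 5))))
  init <- z[1:3, ]
  obj <- vapply(c(1, 3, 10, 50), function(it) {
    e1071::cmeans(z, centers = init, m = 2, iter.max = it)$withinerror
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("Fisher enrichment p equals the hypergeometric-tail oracle", {
  cases <- list(c(8, 2, 10, 80), c(1, 9, 10, 80), c(0, 10, 10, 80),
                c(5, 0, 0, 55), c(3, 3, 3, 3))
  for (cs in cases) {
    p <- erfkit:::fisher_enrichment_p(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, oracle_fisher_tail(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12, label = paste(cs, collapse = ","))
    # and agrees with the standard one-sided Fisher exact test
    m <- matrix(cs, 2, byrow = TRUE)
    expect_equal(p, stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("go_enrichment ranks a planted term first at FDR <= 0.01", {
  set.seed(10)
  bg <- paste0("g", 1:200)
  set <- paste0("g", 1:20)
  ann <- data.frame(gene = set, term = "GO:TARGET")
  for (tm in paste0("GO:BG", 1:10))
    ann <- rbind(ann, data.frame(gene = sample(bg, 30), term = tm))
  out <- go_enrichment(set, bg, ann)
  expect_equal(out$term[1], "GO:TARGET")
  expect_true(out$significant[1])
  # a term annotating every gene is uninformative: p = 1
  ann_all <- data.frame(gene = bg, term = "GO:ALL")
  out2 <- go_enrichment(set, bg, ann_all)
  expect_equal(out2$p, 1)
  expect_equal(nrow(go_enrichment(character(0), bg, ann)), 0)
  expect_error(go_enrichment("zzz", bg, ann), "subset")
})

test_that("ortholog correlation is 1 for mirrored profiles, negative for inverted", {
  genesA <- paste0("a", 1:10)
  genesB <- paste0("b", 1:10)
  times <- c(3, 6, 12, 24, 72)
  designA <- data.frame(sample = paste0("cold_t", times),
                        condition = "cold", time = times)
  designB <- data.frame(sample = "cold_r1", condition = "cold")
  set.seed(11)
  fa <- matrix(rlnorm(50, 3, 1), nrow = 10,
               dimnames = list(genesA, designA$sample))
  fb <- matrix(rowMeans(fa), ncol = 1, dimnames = list(genesB, "cold_r1"))
  pairs <- data.frame(geneA = genesA, geneB = genesB)
  out <- ortholog_expression_correlation(fa, designA, fb, designB, pairs)
  expect_equal(out$r, 1)
  # anti-correlated planted profiles
  fb2 <- matrix(max(fb) - fb + 1, ncol = 1,
                dimnames = list(genesB, "cold_r1"))
  out2 <- ortholog_expression_correlation(fa, designA, fb2, designB, pairs)
  expect_lt(out2$r, 0)
  # fewer than 3 pairs: undefined
  out3 <- ortholog_expression_correlation(fa, designA, fb, designB,
                                          pairs[1:2, ])
  expect_true(is.na(out3$r))
})
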