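# RBH orthologs, collinear-block chaining, specificity and tandem arrays.

test_that("RBH pairs identical proteomes gene-for-gene", {
  set.seed(12)
  seqs <- vapply(1:6, function(i)
    paste(sample(erfkit:::AA20, 80, replace = TRUE), collapse = ""),
    character(1))
  a <- setNames(seqs, paste0("a", 1:6))
  b <- setNames(seqs, paste0("b", 1:6))
  pairs <- rbh_orthologs(a, b)
  expect_equal(nrow(pairs), 6)
  expect_equal(sub("a", "", pairs$geneA), sub("b", "", pairs$geneB))
  expect_equal(nrow(rbh_orthologs(a, character(0))), 0)
  # file order permutation does not change the pair set
  p2 <- rbh_orthologs(a[sample(6)], b[sample(6)])
  expect_setequal(paste(pairs$geneA, pairs$geneB),
                  paste(p2$geneA, p2$geneB))
})

test_that("score ties disqualify a reciprocal pair", {
  a <- setNames(c("AAAAAAAAAA"), "a1")
  b <- setNames(c("AAAAAAAAAA", "AAAAAAAAAA"), c("b1", "b2"))
  expect_equal(nrow(rbh_orthologs(a, b)), 0)
})

mk_loci <- function(genes, chrom = "chr1") {
  data.frame(gene = genes, species = "x", chrom = chrom,
             start = seq_along(genes) * 1000L,
             end = seq_along(genes) * 1000L + 10L, strand = "+",
             rank = seq_along(genes) - 1L, stringsAsFactors = FALSE)
}

test_that("conserved order yields one block; short chains are discarded", {
  ga <- paste0("a", 1:10)
  gb <- paste0("b", 1:10)
  pairs <- data.frame(geneA = ga, geneB = gb)
  bl <- collinear_blocks(pairs, mk_loci(ga), mk_loci(gb))
  expect_equal(length(unique(bl$block)), 1)
  expect_equal(nrow(bl), 10)
  bl4 <- collinear_blocks(pairs[1:4, ], mk_loci(ga), mk_loci(gb),
                          min_block = 5)
  expect_equal(nrow(bl4), 0)
  # inverted order on B is still collinear (monotone either direction)
  blr <- collinear_blocks(pairs, mk_loci(ga), mk_loci(rev(gb)))
  expect_equal(nrow(blr), 10)
})

test_that("chaining equals the brute-force maximum on small instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    ra <- sample(0:(3 * n), n)
    rb <- sample(0:(3 * n), n)
    gap <- sample(c(3, 25), 1)
    ga <- paste0("a", seq_len(n))
    gb <- paste0("b", seq_len(n))
    la <- mk_loci(ga)
    la$rank <- ra
    lb <- mk_loci(gb)
    lb$rank <- rb
    bl <- collinear_blocks(data.frame(geneA = ga, geneB = gb), la, lb,
                           min_block = 2, max_rank_gap = gap)
    got <- if (nrow(bl)) max(table(bl$block)) else 1
    expect_equal(got, max(oracle_max_chain(ra, rb, gap), 1),
                 label = sprintf("instance %d (gap %d)", rep, gap))
  }
})

test_that("block membership, not RBH, defines specificity status", {
  genes <- data.frame(gene = c(paste0("a", 1:6), paste0("b", 1:6),
                               paste0("c", 1:6)),
                      species = rep(c("A", "B", "C"), each = 6),
                      stringsAsFactors = FALSE)
  block_ab <- data.frame(block = 1, chromA = "chr1", chromB = "chr1",
                         geneA = paste0("a", 1:5),
                         geneB = paste0("b", 1:5), position = 1:5)
  none <- block_ab[0, ]
  st <- specificity_status(list("A|B" = block_ab, "A|C" = none,
                                "B|C" = none), genes)
  s <- st$status
  expect_equal(s$status[s$gene == "a1"], "two_species")
  expect_equal(s$status[s$gene == "a6"], "species_specific")
  expect_equal(s$status[s$gene == "c1"], "species_specific")
  # three + two + specific = total per species
  expect_equal(rowSums(st$counts), c(A = 6, B = 6, C = 6))
  block_ac <- data.frame(block = 2, chromA = "chr1", chromB = "chr1",
                         geneA = paste0("a", 1:5),
                         geneB = paste0("c", 1:5), position = 1:5)
  st2 <- specificity_status(list("A|B" = block_ab, "A|C" = block_ac,
                                 "B|C" = none), genes)
  expect_equal(st2$status$status[st2$status$gene == "a1"], "three_species")
  expect_error(specificity_status(list("A|Z" = none), genes), "species")
})

test_that("tandem arrays respect the intervening-gene gap rule", {
  calls <- data.frame(gene = paste0("g", 1:5), subgroup = "B2")
  loci <- mk_loci(paste0("g", 1:5))
  ta <- tandem_arrays(calls, loci)
  expect_equal(length(unique(ta$array)), 1)
  expect_equal(nrow(ta), 5)
  # two same-subgroup genes separated by 11 intervening genes: no array
  loci2 <- mk_loci(paste0("g", 1:2))
  loci2$rank <- c(0L, 12L)
  ta2 <- tandem_arrays(calls[1:2, ], loci2, max_gene_gap = 10)
  expect_equal(nrow(ta2), 0)
  # gap of exactly 10 intervening genes still chains
  loci2$rank <- c(0L, 11L)
  expect_equal(nrow(tandem_arrays(calls[1:2, ], loci2, max_gene_gap = 10)),
               2)
  # different subgroups never chain
  calls3 <- data.frame(gene = paste0("g", 1:2), subgroup = c("B2", "B3"))
  loci3 <- mk_loci(paste0("g", 1:2))
  expect_equal(nrow(tandem_arrays(calls3, loci3)), 0)
})

test_that("planted orthology and arrays are recovered from generated species", {
  tr <- fixture_truth()
  dir <- tempfile()
  gff <- generate_gene_models(tr$config, tr, dir)
  fam <- tr$genes[!is.na(tr$genes$subfamily), ]
  prot <- lapply(tr$proteins, function(p) p[names(p) %in% fam$gene])
  loci <- lapply(tr$species, function(sp)
    read_gene_loci(gff[[sp]], species = sp))
  names(loci) <- tr$species

  blocks <- list()
  combs <- combn(tr$species, 2)
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]
    b <- combs[2, k]
    pairs <- rbh_orthologs(prot[[a]], prot[[b]])
    # recovered RBH pairs equal planted ortholog pairs exactly
    shared <- fam[!is.na(fam$ortholog_group), ]
    truth_pairs <- merge(shared[shared$species == a,
                                c("gene", "ortholog_group")],
                         shared[shared$species == b,
                                c("gene", "ortholog_group")],
                         by = "ortholog_group")
    expect_setequal(paste(pairs$geneA, pairs$geneB),
                    paste(truth_pairs$gene.x, truth_pairs$gene.y))
    blocks[[paste(a, b, sep = "|")]] <-
      collinear_blocks(pairs, rerank_loci(loci[[a]], names(prot[[a]])),
                       rerank_loci(loci[[b]], names(prot[[b]])))
  }
  st <- specificity_status(blocks, fam[, c("gene", "species", "subgroup")])
  m <- merge(st$status, fam[, c("gene", "ortholog_group")], by = "gene")
  expect_equal(mean((m$status == "species_specific") ==
                    is.na(m$ortholog_group)), 1)

  # planted tandem arrays detected exactly, nothing else
  calls_ca <- data.frame(gene = fam$gene[fam$species == "ca"],
                         subgroup = fam$subgroup[fam$species == "ca"])
  ta <- tandem_arrays(calls_ca, loci[["ca"]])
  planted <- fam[!is.na(fam$tandem_array), ]
  expect_setequal(ta$gene, planted$gene)
  expect_equal(length(unique(ta$array)), length(unique(planted$tandem_array)))
  unlink(dir, recursive = TRUE)
})
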