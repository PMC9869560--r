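# Generator contracts: determinism, mix apportionment, planted
# architectures, calibrated CDS pairs, counts and GO annotations.

test_that("invalid configurations are rejected", {
  expect_error(truth_config(subgroup_mix = c(B1 = 0.5, B2 = 0.4)),
               "sum to 1")
  expect_error(truth_config(subgroup_mix = c(B1 = 1.2, B2 = -0.2)),
               "\\[0, 1\\]")
  expect_error(truth_config(genes_per_species = 0), "positive")
  expect_error(truth_config(species_specific_fraction = 1.3), "fractions")
  cfg <- truth_config(ks_targets = c(-0.1))
  expect_error(generate_cds_pairs(cfg), ">= 0")
  cfg2 <- truth_config(ks_targets = numeric(0))
  expect_error(generate_cds_pairs(cfg2), "non-empty")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- truth_config(n_species = 2, genes_per_species = 15,
                      tandem_arrays = list(), seed = 42)
  d1 <- tempfile()
  d2 <- tempfile()
  t1 <- generate_proteomes(cfg, d1)
  t2 <- generate_proteomes(cfg, d2)
  for (code in t1$species) {
    for (part in c("proteins", "cds", "domains")) {
      expect_identical(unname(tools::md5sum(t1$files[[code]][[part]])),
                       unname(tools::md5sum(t2$files[[code]][[part]])),
                       label = paste(code, part))
    }
  }
  g1 <- generate_gene_models(cfg, t1, d1)
  g2 <- generate_gene_models(cfg, t2, d2)
  expect_identical(unname(tools::md5sum(g1)), unname(tools::md5sum(g2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate subfamily mix yields all-ERF truth with diagnostics", {
  cfg <- truth_config(n_species = 1, genes_per_species = 10,
                      subfamily_mix = c(ERF = 1.0),
                      tandem_arrays = list(),
                      species_specific_fraction = 0,
                      domain_noise = 0, seed = 5)
  tr <- generate_proteomes(cfg)
  fam <- tr$genes[!is.na(tr$genes$subfamily), ]
  expect_equal(nrow(fam), 10)
  expect_true(all(fam$subfamily == "ERF"))
  # every planted domain carries Ala/Asp at the diagnostic columns
  prot <- as.character(tr$proteins[[1]])
  for (g in fam$gene) {
    h <- tr$hits[tr$hits$gene == g, ]
    dom <- substr(prot[[g]], h$start[1], h$end[1])
    expect_identical(substr(dom, 14, 14), "A")
    expect_identical(substr(dom, 19, 19), "D")
  }
})

test_that("RAV proportion is apportioned exactly and emits AP2 + B3 hits", {
  cfg <- truth_config(n_species = 1, genes_per_species = 50,
                      subfamily_mix = c(ERF = 0.5, DREB = 0.3, RAV = 0.2),
                      tandem_arrays = list(),
                      species_specific_fraction = 0, seed = 8)
  tr <- generate_proteomes(cfg)
  rows <- tr$domain_rows[[1]]
  with_b3 <- unique(rows$protein[rows$accession == "PF02362"])
  with_ap2 <- unique(rows$protein[rows$accession == "PF00847"])
  expect_length(intersect(with_b3, with_ap2), 10)
  expect_equal(sum(tr$genes$subfamily %in% "RAV"), 10)
})

test_that("species-specific fraction is planted exactly", {
  cfg <- truth_config(n_species = 2, genes_per_species = 100,
                      tandem_arrays = list(),
                      species_specific_fraction = 0.5, seed = 3)
  tr <- generate_proteomes(cfg)
  fam <- tr$genes[!is.na(tr$genes$subfamily), ]
  for (sp in unique(fam$species))
    expect_equal(sum(is.na(fam$ortholog_group[fam$species == sp])), 50)
  # ortholog group ids are consistent across species
  og <- fam[!is.na(fam$ortholog_group), ]
  expect_true(all(table(og$ortholog_group) == 2))
})

test_that("gene ids are unique and tandem arrays occupy consecutive ranks", {
  tr <- fixture_truth()
  expect_false(anyDuplicated(tr$genes$gene) > 0)
  arr <- tr$genes[!is.na(tr$genes$tandem_array), ]
  for (a in unique(arr$tandem_array)) {
    rk <- sort(arr$rank[arr$tandem_array == a])
    expect_equal(rk, seq(min(rk), by = 1, length.out = length(rk)))
    expect_length(unique(arr$chrom[arr$tandem_array == a]), 1)
  }
  # planted arrays sit on their configured chromosomes with stated sizes
  expect_equal(as.integer(table(arr$tandem_array)[c("array1", "array2")]),
               c(6L, 5L))
})

test_that("shared ortholog groups keep conserved order along chromosomes", {
  tr <- fixture_truth()  # collinear_block_fraction = 1
  fam <- tr$genes[!is.na(tr$genes$ortholog_group), ]
  ord <- lapply(split(fam, fam$species), function(g)
    g$ortholog_group[order(g$chrom, g$rank)])
  expect_equal(ord[[1]], ord[[2]])
  expect_equal(ord[[1]], ord[[3]])
})

test_that("CDS pairs hit their planted divergence and edge cases error", {
  cfg <- truth_config(ks_targets = c(0), seed = 2)
  kp <- generate_cds_pairs(cfg, n_codons = 60)
  expect_identical(as.character(kp$cds[[1]]), as.character(kp$cds[[2]]))
  # an unreachable target: more synonymous divergence than the available
  # four-fold sites can carry
  cfg2 <- truth_config(ks_targets = c(5), seed = 2)
  expect_error(generate_cds_pairs(cfg2), "four-fold")
  # moderate target: estimator recovers it on average
  cfg3 <- truth_config(ks_targets = c(0.2), seed = 12)
  kp3 <- generate_cds_pairs(cfg3, n_codons = 300, pairs_per_target = 12)
  est <- vapply(seq_len(nrow(kp3$pairs)), function(i) {
    ca <- codon_align(kp3$cds[[kp3$pairs$gene1[i]]],
                      kp3$cds[[kp3$pairs$gene2[i]]])
    ng86_ks(ca$codons1, ca$codons2)$Ks
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("counts carry planted fold changes and reject bad configs", {
  cfg <- truth_config(n_species = 1, genes_per_species = 12,
                      tandem_arrays = list(), seed = 21)
  tr <- generate_proteomes(cfg)
  fam <- tr$genes$gene[!is.na(tr$genes$subfamily)]
  de <- data.frame(gene = fam[1], condition = "cold", lfc = 3,
                   shape = "flat")
  cfg$de_effects <- de
  cnt <- generate_counts(cfg, tr, background_genes = 50)
  cold <- cnt$design$sample[cnt$design$condition == "cold"]
  ctrl <- cnt$design$sample[cnt$design$condition == "control"]
  ratio <- mean(cnt$counts[fam[1], cold]) / mean(cnt$counts[fam[1], ctrl])
  expect_gt(ratio, 4)      # planted 8x, NB noise allowed for
  expect_lt(ratio, 16)
  cfg_bad <- truth_config(replicates = 1)
  expect_error(generate_counts(cfg_bad, tr), "replicates")
  cfg$de_effects <- data.frame(gene = "nonexistent", condition = "cold",
                               lfc = 2, shape = "flat")
  expect_error(generate_counts(cfg, tr, background_genes = 10),
               "absent")
})

test_that("GO annotations cover the target subgroup and background rate", {
  tr <- fixture_truth()
  ann <- generate_go_annotations(tr, term = "GO:0099999",
                                 target_subgroup = "B2",
                                 background_rate = 0.1)
  b2 <- tr$genes$gene[tr$genes$subgroup %in% "B2"]
  annotated <- ann$gene[ann$term == "GO:0099999"]
  expect_setequal(annotated, b2)
  # background annotation count near binomial expectation
  bg_term <- setdiff(unique(ann$term), "GO:0099999")[1]
  n_hit <- sum(ann$term == bg_term)
  n_genes <- nrow(tr$genes)
  expect_lt(abs(n_hit - 0.1 * n_genes), 4 * sqrt(0.1 * 0.9 * n_genes))
  # determinism
  ann2 <- generate_go_annotations(tr, term = "GO:0099999",
                                  target_subgroup = "B2",
                                  background_rate = 0.1)
  expect_identical(ann, ann2)
})
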