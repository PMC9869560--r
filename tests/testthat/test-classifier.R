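# Model alignment, the subfamily decision ladder, subgroup keys and the
# neighbor-joining coherence check.

test_that("aligning the consensus to the model is the identity", {
  model <- ap2_model()
  al <- align_to_model(model$consensus, model)
  expect_false(al$unalignable)
  expect_equal(paste(al$model_residues, collapse = ""), model$consensus)
  expect_equal(nrow(al$insertions), 0)
  # ungapped self-alignment score equals the closed-form BLOSUM62 sum
  expect_equal(al$score,
               blosum62_ungapped_score(model$consensus, model$consensus))
})

test_that("a 10-residue insertion is located and measured", {
  model <- ap2_model()
  ins <- "GSSNQPTDGH"
  seq <- paste0(substr(model$consensus, 1, 20), ins,
                substr(model$consensus, 21, 57))
  al <- align_to_model(seq, model)
  expect_equal(nrow(al$insertions), 1)
  expect_equal(al$insertions$length, 10)
  expect_equal(al$insertions$after_col, 20)
})

test_that("few-mismatch variants map column-by-column without gaps", {
  model <- ap2_model()
  set.seed(4)
  for (rep in 1:5) {
    chars <- strsplit(model$consensus, "")[[1]]
    pos <- sample(57, 3)
    for (p in pos) chars[p] <- sample(setdiff(erfkit:::AA20, chars[p]), 1)
    mutant <- paste(chars, collapse = "")
    al <- align_to_model(mutant, model)
    expect_equal(nrow(al$insertions), 0)
    expect_equal(sum(al$model_residues !=
                     strsplit(model$consensus, "")[[1]]), 3)
    # ungapped score is the closed-form sum; the DP can do no worse
    expect_gte(al$score,
               blosum62_ungapped_score(mutant, model$consensus))
  }
})

test_that("the subfamily ladder follows architecture and diagnostics", {
  cfg <- classifier_config()
  model <- ap2_model()
  profs <- subgroup_profiles()
  mk_arch <- function(gene, kinds, starts, ends) {
    filter_hits(data.frame(gene = gene, kind = kinds, start = starts,
                           end = ends, evalue = 1e-20, score = NA_real_))
  }
  al <- function(seq) align_to_model(seq, model)

  # one AP2 domain, Ala@14 Asp@19 -> ERF; Val/Glu -> DREB
  erf_dom <- profs$B1$consensus
  a1 <- mk_arch("g", "AP2", 1, 57)
  expect_equal(classify_subfamily(a1, list(al(erf_dom)), cfg)$subfamily,
               "ERF")
  dreb_dom <- profs$A1$consensus
  expect_equal(classify_subfamily(a1, list(al(dreb_dom)), cfg)$subfamily,
               "DREB")

  # two AP2 domains: insertion >= threshold -> AP2, else ANT
  ins_dom <- paste0(substr(profs$AP2$consensus, 1, 20), "GSSNQPTDGH",
                    substr(profs$AP2$consensus, 21, 57))
  a2 <- mk_arch("g", c("AP2", "AP2"), c(1, 80), c(67, 136))
  expect_equal(classify_subfamily(
    a2, list(al(ins_dom), al(profs$AP2$consensus)), cfg)$subfamily, "AP2")
  a3 <- mk_arch("g", c("AP2", "AP2"), c(1, 70), c(57, 126))
  expect_equal(classify_subfamily(
    a3, list(al(profs$ANT$consensus), al(profs$ANT$consensus)),
    cfg)$subfamily, "ANT")

  # AP2 + B3 -> RAV regardless of residues
  a4 <- mk_arch("g", c("AP2", "B3"), c(1, 80), c(57, 129))
  expect_equal(classify_subfamily(a4, list(al(profs$RAV$consensus)),
                                  cfg)$subfamily, "RAV")

  # non-matching diagnostics route to nearest profile -> Soloist
  expect_equal(classify_subfamily(a1, list(al(profs$Soloist$consensus)),
                                  cfg)$subfamily, "Soloist")

  # no retained domains is an error
  empty <- filter_hits(data.frame(gene = "g", kind = "AP2", start = 1,
                                  end = 57, evalue = 1, score = NA_real_))
  expect_error(classify_subfamily(empty, list(), cfg), "not an AP2/ERF")
})

test_that("ERF subgroups follow the residue key at columns 49 and 56", {
  cfg <- classifier_config()
  model <- ap2_model()
  base <- subgroup_profiles()[["B1"]]$consensus
  set_cols <- function(seq, r49, r56) {
    chars <- strsplit(seq, "")[[1]]
    chars[49] <- r49
    chars[56] <- r56
    paste(chars, collapse = "")
  }
  arch <- filter_hits(data.frame(gene = "g", kind = "AP2", start = 1,
                                 end = 57, evalue = 1e-20,
                                 score = NA_real_))
  for (case in list(list("F", "L", "B1"), list("L", "T", "B2"),
                    list("F", "T", "B3"), list("M", "L", "B4"))) {
    dom <- align_to_model(set_cols(base, case[[1]], case[[2]]), model)
    call <- classify_subfamily(arch, list(dom), cfg)
    expect_equal(call$subfamily, "ERF")
    call <- assign_subgroup(call, dom, cfg)
    expect_equal(call$subgroup, case[[3]], label = case[[3]])
  }
  # DREB genes go to the nearest A profile
  for (sg in c("A1", "A2", "A3", "A4")) {
    dom <- align_to_model(subgroup_profiles()[[sg]]$consensus, model)
    call <- classify_subfamily(arch, list(dom), cfg)
    expect_equal(call$subfamily, "DREB")
    expect_equal(assign_subgroup(call, dom, cfg)$subgroup, sg)
  }
})

test_that("classification is exhaustive and deterministic on synthetic data", {
  tr <- fixture_truth()
  archs <- fixture_archs("sl")
  calls <- classify_genes(tr$proteins[["sl"]], archs)
  expect_true(all(calls$subfamily %in%
                  c("ERF", "DREB", "AP2", "ANT", "RAV", "Soloist")))
  expect_true(all(calls$subgroup %in%
                  c(paste0("A", 1:4), paste0("B", 1:4),
                    "AP2", "ANT", "RAV", "Soloist")))
  # subgroup/subfamily consistency
  expect_true(all(calls$subfamily[grepl("^B[1-4]$", calls$subgroup)] == "ERF"))
  expect_true(all(calls$subfamily[grepl("^A[1-4]$", calls$subgroup)] == "DREB"))
  calls2 <- classify_genes(tr$proteins[["sl"]], archs)
  expect_identical(calls, calls2)
})

test_that("one off-diagnostic substitution never flips the subfamily", {
  tr <- fixture_truth()
  archs <- fixture_archs("st")
  truth <- tr$genes[tr$genes$species == "st" & !is.na(tr$genes$subfamily), ]
  prot <- as.character(tr$proteins[["st"]])
  set.seed(77)
  mutated <- vapply(names(prot), function(g) {
    h <- tr$hits[tr$hits$gene == g & tr$hits$kind == "AP2", ]
    if (nrow(h) == 0) return(prot[[g]])
    chars <- strsplit(prot[[g]], "")[[1]]
    # one random substitution inside the domain, off the diagnostic and
    # key columns
    off <- setdiff(seq(h$start[1], h$end[1]),
                   h$start[1] - 1 + c(14, 19, 49, 56))
    p <- off[sample.int(length(off), 1)]
    chars[p] <- sample(setdiff(erfkit:::AA20, chars[p]), 1)
    paste(chars, collapse = "")
  }, character(1))
  calls <- classify_genes(mutated, archs)
  m <- merge(calls, truth, by = "gene")
  expect_equal(mean(m$subfamily.x == m$subfamily.y), 1)
})

test_that("neighbor joining recovers additive quartets and scores coherence", {
  # additive 4-taxon instance with a known topology
  for (seed in 1:5) {
    inst <- random_additive_instance(4, seed)
    res <- nj_tree(labels = rep("x", 4), distances = inst$D)
    skip_if_not_installed("phangorn")
    expect_equal(phangorn::RF.dist(ape::unroot(res$tree),
                                   ape::unroot(inst$tree)), 0)
  }
  # identical sequences: star tree, coherence 1 when labels agree
  seqs <- setNames(rep("AAAA", 4), paste0("t", 1:4))
  res <- nj_tree(seqs, rep("B2", 4))
  expect_equal(res$coherence, 1)
  # two well-separated planted subgroups -> coherence 1
  a <- strrep("A", 30)
  b <- paste0(strrep("A", 15), strrep("W", 15))
  seqs2 <- setNames(c(a, a, a, b, b, b), paste0("t", 1:6))
  set.seed(1)
  seqs2 <- vapply(seqs2, function(s) {
    chars <- strsplit(s, "")[[1]]
    p <- sample(30, 2)
    for (q in p) chars[q] <- sample(setdiff(erfkit:::AA20, chars[q]), 1)
    paste(chars, collapse = "")
  }, character(1))
  res2 <- nj_tree(seqs2, rep(c("g1", "g2"), each = 3))
  expect_equal(res2$coherence, 1)
  # duplicate ids are rejected
  expect_error(nj_tree(setNames(rep("AA", 4), c("a", "a", "b", "c")),
                       rep("x", 4)), "unique")
})
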