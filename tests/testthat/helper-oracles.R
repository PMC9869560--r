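# Independent oracles and shared fixtures for the test suite. Oracles
# deliberately use different algorithms / primitives than the package
# code they check.

.fixture_env <- new.env()

# small noise-free three-species truth, shared by several test files
fixture_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    cfg <- truth_config(n_species = 3, genes_per_species = 40,
                        domain_noise = 0, seed = 101)
    .fixture_env$truth <- generate_proteomes(cfg)
  }
  .fixture_env$truth
}

fixture_archs <- function(code) {
  key <- paste0("archs_", code)
  if (is.null(.fixture_env[[key]])) {
    tr <- fixture_truth()
    rows <- tr$domain_rows[[code]]
    tmp <- tempfile(fileext = ".tsv")
    write.table(rows, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    hits <- parse_interproscan_tsv(tmp)
    .fixture_env[[key]] <- lapply(split(hits, hits$gene), filter_hits)
  }
  .fixture_env[[key]]
}

# brute-force one-sided Fisher (enrichment) p via log-factorial sums,
# independent of stats::phyper
oracle_fisher_tail <- function(a, b, c, d) {
  m <- a + c          # annotated in background
  n <- b + d          # not annotated
  s <- a + b          # set size
  kmax <- min(m, s)
  if (a > kmax) return(0)
  lp <- vapply(a:kmax, function(k) {
    lchoose(m, k) + lchoose(n, s - k) - lchoose(m + n, s)
  }, numeric(1))
  sum(exp(lp))
}

# brute-force synonymous site count of a codon: explicit 9-neighbour
# enumeration written independently of the package implementation
oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  ref <- gc[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (nt in nts) {
      if (substr(codon, pos, pos) == nt) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] == "*") next
      valid <- valid + 1
      if (gc[[mut]] == ref) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# brute-force maximum collinear chain over <= ~15 pairs by bitmask
# enumeration; a subset is a valid chain when, ordered by rank on A,
# ranks are strictly increasing on A, strictly monotone on B (either
# direction), and consecutive gaps are within max_rank_gap on both
oracle_max_chain <- function(ra, rb, max_rank_gap) {
  n <- length(ra)
  best <- 0
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    o <- idx[order(ra[idx])]
    da <- diff(ra[o])
    db <- diff(rb[o])
    ok_a <- all(da > 0) && all(da - 1 <= max_rank_gap)
    ok_b <- (all(db > 0) || all(db < 0)) && all(abs(db) - 1 <= max_rank_gap)
    if (length(idx) == 1 || (ok_a && ok_b)) best <- length(idx)
  }
  best
}

# minimum-evolution topology by exhaustive enumeration: all unrooted
# topologies, OLS branch lengths, pick the perfect-fit / shortest tree
oracle_me_tree <- function(D) {
  skip_if_not_installed("phangorn")
  trees <- phangorn::allTrees(nrow(D), rooted = FALSE,
                              tip.label = rownames(D))
  fits <- lapply(trees, function(tr) phangorn::nnls.tree(D, tr))
  rss <- vapply(fits, function(tr) {
    dt <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    sum((dt - D)^2)
  }, numeric(1))
  fits[[which.min(rss)]]
}

# random additive distance matrix from a random tree with positive
# branch lengths; returns the matrix and its generating topology
random_additive_instance <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.2, 1)
  list(D = ape::cophenetic.phylo(tr), tree = tr)
}

# expected ungapped global-alignment score of two equal-length strings
# under BLOSUM62 (closed form: column sums of the substitution matrix)
blosum62_ungapped_score <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  sum(BLOSUM62[cbind(ac, bc)])
}
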