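# Cross-species comparison: gene loci, reciprocal-best-hit orthologs,
# collinear blocks, species-specificity counting and tandem arrays.
#
# Orthology for specificity counting follows the synteny reading: a gene
# counts as having an ortholog in another species only when it is part of
# a collinear block against that species, not merely an RBH pair.

#' Read gene loci from a GFF3 file
#'
#' Extracts `gene` features (1-based, end-inclusive) and computes each
#' gene's 0-based rank along its chromosome, ordering by start position
#' (ties broken by gene id). Unanchored scaffolds can be excluded by
#' pattern, mirroring the usual practice of restricting chromosomal
#' analyses to anchored sequences.
#'
#' @param path GFF3 file with `gene` features carrying `ID=` attributes.
#' @param species species label stamped on the result.
#' @param anchored_pattern regular expression a seqid must match to be
#'   kept (`NULL` keeps everything). Default keeps `chr*` sequences.
#' @return data.frame: gene, species, chrom, start, end, strand, rank.
#' @export
read_gene_loci <- function(path, species = NA_character_,
                           anchored_pattern = "^chr") {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) stopf("no gene features in %s", path)
  loci <- data.frame(gene = as.character(g$ID),
                     species = species,
                     chrom = as.character(g$seqid),
                     start = as.integer(g$start),
                     end = as.integer(g$end),
                     strand = as.character(g$strand),
                     stringsAsFactors = FALSE)
  if (!is.null(anchored_pattern))
    loci <- loci[grepl(anchored_pattern, loci$chrom), , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$start, loci$gene), , drop = FALSE]
  loci$rank <- NA_integer_
  for (ch in unique(loci$chrom)) {
    ix <- which(loci$chrom == ch)
    loci$rank[ix] <- seq_along(ix) - 1L
  }
  rownames(loci) <- NULL
  loci
}

#' Recompute ranks within a gene subset
#'
#' Subsets a loci table to the given genes and recomputes each gene's
#' 0-based rank along its chromosome within that subset. Collinearity
#' chaining measures rank gaps within the gene set that defines the
#' ortholog pairs (e.g. the family genes), so ranks must be recomputed
#' over that set.
#'
#' @param loci loci table from [read_gene_loci()].
#' @param genes character vector of gene ids to keep.
#' @return reranked loci table.
#' @export
rerank_loci <- function(loci, genes) {
  loci <- loci[loci$gene %in% genes, , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$start, loci$gene), , drop = FALSE]
  for (ch in unique(loci$chrom)) {
    ix <- which(loci$chrom == ch)
    loci$rank[ix] <- seq_along(ix) - 1L
  }
  rownames(loci) <- NULL
  loci
}

#' Global alignment score matrix between two protein sets
#'
#' BLOSUM62 global alignment scores (gap open 10, extend 1), the same
#' scoring used throughout the package. Rows index `setA`, columns
#' `setB`.
#'
#' @param setA,setB named character vectors or `AAStringSet`s.
#' @return numeric matrix of scores.
#' @export
alignment_score_matrix <- function(setA, setB) {
  if (!inherits(setA, "AAStringSet")) setA <- AAStringSet(setA)
  if (!inherits(setB, "AAStringSet")) setB <- AAStringSet(setB)
  S <- matrix(NA_real_, length(setA), length(setB),
              dimnames = list(names(setA), names(setB)))
  for (j in seq_along(setB)) {
    S[, j] <- pairwiseAlignment(setA, setB[[j]], type = "global",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 1,
                                scoreOnly = TRUE)
  }
  S
}

#' @noRd
rbh_from_scores <- function(S, namesA, namesB) {
  bestA <- apply(S, 1, function(r) {
    m <- max(r)
    w <- which(r == m)
    if (length(w) == 1) w else NA_integer_
  })
  bestB <- apply(S, 2, function(cl) {
    m <- max(cl)
    w <- which(cl == m)
    if (length(w) == 1) w else NA_integer_
  })
  pairs <- data.frame(geneA = character(), geneB = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(bestA)) {
    j <- bestA[i]
    if (is.na(j)) next
    if (!is.na(bestB[j]) && bestB[j] == i) {
      pairs <- rbind(pairs, data.frame(geneA = namesA[i], geneB = namesB[j],
                                       score = S[i, j],
                                       stringsAsFactors = FALSE))
    }
  }
  pairs
}

#' Reciprocal-best-hit ortholog pairs between two proteomes
#'
#' All-vs-all global alignment scores; a pair is kept iff each gene is
#' the other's unique best hit (score ties disqualify).
#'
#' @param proteomeA,proteomeB named character vectors / `AAStringSet`s.
#' @return data.frame: geneA, geneB, score.
#' @export
rbh_orthologs <- function(proteomeA, proteomeB) {
  if (length(proteomeA) == 0 || length(proteomeB) == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  S <- alignment_score_matrix(proteomeA, proteomeB)
  out <- rbh_from_scores(S, rownames(S), colnames(S))
  rownames(out) <- NULL
  out
}

#' @noRd
best_chain <- function(ra, rb, max_rank_gap) {
  # longest chain strictly increasing in ra, strictly monotone in rb
  # (either direction), consecutive rank gaps <= max_rank_gap on both
  # genomes; returns indices into ra/rb. Ties broken by earliest start.
  n <- length(ra)
  if (n == 0) return(integer(0))
  run_dir <- function(rbv) {
    ord <- order(ra)
    L <- rep(1L, n)
    pred <- rep(0L, n)
    for (oi in seq_along(ord)) {
      i <- ord[oi]
      for (oj in seq_len(oi - 1L)) {
        j <- ord[oj]
        if (ra[i] > ra[j] && ra[i] - ra[j] - 1L <= max_rank_gap &&
            rbv[i] > rbv[j] && rbv[i] - rbv[j] - 1L <= max_rank_gap) {
          cand <- L[j] + 1L
          if (cand > L[i] || (cand == L[i] && pred[i] != 0L &&
                              ra[j] < ra[pred[i]])) {
            L[i] <- cand
            pred[i] <- j
          }
        }
      }
    }
    ends <- which(L == max(L))
    end <- ends[which.min(ra[ends])]
    chain <- integer(0)
    while (end != 0L) {
      chain <- c(end, chain)
      end <- pred[end]
    }
    chain
  }
  up <- run_dir(rb)
  down <- run_dir(max(rb) - rb)
  if (length(down) > length(up)) down else up
}

#' Chain ortholog pairs into collinear blocks
#'
#' Within each chromosome pair, repeatedly extracts the longest chain of
#' pairs with strictly increasing rank on genome A, strictly monotone
#' rank (either direction) on genome B, and consecutive-pair rank gaps of
#' at most `max_rank_gap` intervening genes on both genomes. Chains
#' shorter than `min_block` are discarded.
#'
#' @param pairs data.frame with columns geneA, geneB (e.g. from
#'   [rbh_orthologs()]).
#' @param lociA,lociB loci tables from [read_gene_loci()] covering the
#'   paired genes.
#' @param min_block minimum pairs per block (default 5, the MCScanX
#'   default).
#' @param max_rank_gap maximum intervening-gene gap (default 25, the
#'   MCScanX default).
#' @return data.frame: block, chromA, chromB, geneA, geneB, position.
#' @export
collinear_blocks <- function(pairs, lociA, lociB, min_block = 5L,
                             max_rank_gap = 25L) {
  empty <- data.frame(block = integer(), chromA = character(),
                      chromB = character(), geneA = character(),
                      geneB = character(), position = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  ia <- match(pairs$geneA, lociA$gene)
  ib <- match(pairs$geneB, lociB$gene)
  if (anyNA(ia) || anyNA(ib))
    stopf("collinear_blocks(): loci missing for some paired genes")
  tab <- data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
                    chromA = lociA$chrom[ia], chromB = lociB$chrom[ib],
                    ra = lociA$rank[ia], rb = lociB$rank[ib],
                    stringsAsFactors = FALSE)
  out <- empty
  bid <- 0L
  for (key in unique(paste(tab$chromA, tab$chromB, sep = "\r"))) {
    sub <- tab[paste(tab$chromA, tab$chromB, sep = "\r") == key, ,
               drop = FALSE]
    repeat {
      chain <- best_chain(sub$ra, sub$rb, max_rank_gap)
      if (length(chain) < max(min_block, 2L)) break
      bid <- bid + 1L
      out <- rbind(out, data.frame(block = bid,
                                   chromA = sub$chromA[chain],
                                   chromB = sub$chromB[chain],
                                   geneA = sub$geneA[chain],
                                   geneB = sub$geneB[chain],
                                   position = seq_along(chain),
                                   stringsAsFactors = FALSE))
      sub <- sub[-chain, , drop = FALSE]
      if (nrow(sub) == 0) break
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-gene species-specificity status over three species
#'
#' A gene has `three_species` status iff it appears in collinear blocks
#' against both other species, `two_species` iff against exactly one,
#' and `species_specific` iff against none. Block membership, not bare
#' RBH, defines orthology here.
#'
#' @param blocks named list of block tables from [collinear_blocks()];
#'   names are `"spA|spB"` species pairs, with `geneA` belonging to the
#'   first species of the pair.
#' @param genes data.frame with columns gene, species (and optionally
#'   subgroup) listing every family gene.
#' @return list with `status` (gene, species, n_partners, status) and
#'   `counts` (species x status table, plus per-subgroup counts when
#'   subgroup labels are supplied).
#' @export
specificity_status <- function(blocks, genes) {
  species <- unique(genes$species)
  partner_sets <- setNames(vector("list", nrow(genes)), genes$gene)
  for (nm in names(blocks)) {
    sp <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(sp) != 2 || !all(sp %in% species))
      stopf("block table name '%s' does not match known species", nm)
    b <- blocks[[nm]]
    if (nrow(b) == 0) next
    for (g in unique(b$geneA))
      partner_sets[[g]] <- union(partner_sets[[g]], sp[2])
    for (g in unique(b$geneB))
      partner_sets[[g]] <- union(partner_sets[[g]], sp[1])
  }
  n_partners <- vapply(genes$gene, function(g)
    length(partner_sets[[g]]), integer(1))
  status <- ifelse(n_partners >= 2, "three_species",
                   ifelse(n_partners == 1, "two_species",
                          "species_specific"))
  st <- data.frame(gene = genes$gene, species = genes$species,
                   n_partners = n_partners, status = status,
                   stringsAsFactors = FALSE)
  counts <- table(st$species,
                  factor(st$status, levels = c("three_species",
                                               "two_species",
                                               "species_specific")))
  out <- list(status = st, counts = counts)
  if (!is.null(genes$subgroup)) {
    st$subgroup <- genes$subgroup
    out$subgroup_counts <- table(st$species, st$subgroup,
                                 factor(st$status,
                                        levels = c("three_species",
                                                   "two_species",
                                                   "species_specific")))
    out$status <- st
  }
  out
}

#' Detect tandem arrays of same-subgroup genes
#'
#' Maximal runs of two or more genes of the same subgroup on one
#' chromosome where consecutive members are separated by at most
#' `max_gene_gap` intervening genes (of any family).
#'
#' @param calls data.frame with columns gene, subgroup.
#' @param loci loci table from [read_gene_loci()] (one species).
#' @param max_gene_gap maximum intervening genes between consecutive
#'   array members (default 10).
#' @return data.frame: array, chrom, subgroup, gene, rank.
#' @export
tandem_arrays <- function(calls, loci, max_gene_gap = 10L) {
  empty <- data.frame(array = integer(), chrom = character(),
                      subgroup = character(), gene = character(),
                      rank = integer(), stringsAsFactors = FALSE)
  fam <- merge(calls[, c("gene", "subgroup")], loci, by = "gene")
  if (nrow(fam) == 0) return(empty)
  out <- empty
  aid <- 0L
  for (key in unique(paste(fam$chrom, fam$subgroup, sep = "\r"))) {
    sub <- fam[paste(fam$chrom, fam$subgroup, sep = "\r") == key, ,
               drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$rank) - 1L > max_gene_gap))
    for (g in unique(grp)) {
      members <- sub[grp == g, , drop = FALSE]
      if (nrow(members) < 2) next
      aid <- aid + 1L
      out <- rbind(out, data.frame(array = aid, chrom = members$chrom,
                                   subgroup = members$subgroup,
                                   gene = members$gene,
                                   rank = members$rank,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
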