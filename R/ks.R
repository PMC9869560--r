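# Synonymous substitution rate estimation (Nei-Gojobori 1986).
#
# Synonymous site counts: at each codon position the synonymous fraction
# is the proportion of synonymous changes among the single-nucleotide
# changes that do not create a stop codon, so S + N = 3 per codon.
# Differences between codons differing at several positions are averaged
# over all minimal mutation paths with equal weights; paths passing
# through a stop codon get zero weight (uniform fallback when every path
# is blocked). pS = sd / S is corrected with the Jukes-Cantor formula
# Ks = -(3/4) ln(1 - (4/3) pS), undefined when pS >= 3/4.

.NT <- c("A", "C", "G", "T")

#' @noRd
codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Synonymous site count of a single codon
#'
#' Enumerates the nine single-nucleotide neighbours of a sense codon.
#' Changes creating stop codons are excluded from both numerator and
#' denominator; per position the synonymous fraction is
#' n_synonymous / n_non_stop, and the codon's synonymous site count is
#' the sum over its three positions (so synonymous + nonsynonymous
#' sites = 3).
#'
#' @param codon a sense codon (3-letter DNA string).
#' @return numeric synonymous site count in [0, 3].
#' @export
ng86_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codon]
  if (is.na(aa) || aa == "*")
    stopf("ng86_codon_sites(): '%s' is not a sense codon", codon)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    n_syn <- 0L
    n_valid <- 0L
    for (nt in setdiff(.NT, chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      maa <- gc[paste(mut, collapse = "")]
      if (maa == "*") next
      n_valid <- n_valid + 1L
      if (maa == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) s <- s + n_syn / n_valid
  }
  s
}

#' @noRd
ng86_pair_diffs <- function(c1, c2) {
  # average synonymous / nonsynonymous difference counts over all minimal
  # mutation paths between two sense codons; paths through stops weighted 0
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    if (k == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  tally <- function(order, strict) {
    cur <- a
    sdiff <- 0
    ndiff <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      if (aa2 == "*" && !identical(paste(nxt, collapse = ""), c2) && strict)
        return(NULL)  # path through a stop codon
      if (aa1 == aa2) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    c(sd = sdiff, nd = ndiff)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, strict = TRUE))
  if (length(res) == 0) res <- lapply(perms, tally, strict = FALSE)
  colMeans(do.call(rbind, res))
}

#' @noRd
ng86_tables <- function() {
  if (!is.null(.erf_cache$ng86)) return(.erf_cache$ng86)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sites <- vapply(sense, ng86_codon_sites, numeric(1))
  n <- length(sense)
  sd_m <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_m <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- ng86_pair_diffs(sense[i], sense[j])
      sd_m[i, j] <- sd_m[j, i] <- d["sd"]
      nd_m[i, j] <- nd_m[j, i] <- d["nd"]
    }
  }
  .erf_cache$ng86 <- list(sense = sense, sites = sites, sd = sd_m, nd = nd_m)
  .erf_cache$ng86
}

#' Thread two CDS through their protein alignment
#'
#' Translates both coding sequences, globally aligns the proteins
#' (BLOSUM62, gap open 10 / extend 1), and threads the codons through
#' that alignment. Columns containing an alignment gap or an ambiguous
#' base are dropped. A trailing stop codon shared by both sequences is
#' trimmed; internal stops are an error, as is a length not divisible by
#' three.
#'
#' @param cds1,cds2 coding sequences (character or `DNAString`).
#' @return list with `codons1`, `codons2` (equal-length codon vectors)
#'   and `dropped` (number of alignment columns removed).
#' @export
codon_align <- function(cds1, cds2) {
  cds1 <- toupper(as.character(cds1))
  cds2 <- toupper(as.character(cds2))
  for (s in list(cds1, cds2))
    if (nchar(s) %% 3 != 0)
      stopf("CDS length (%d) is not a multiple of 3", nchar(s))
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  co1 <- split_codons(cds1)
  co2 <- split_codons(cds2)
  gc <- Biostrings::GENETIC_CODE
  aa_of <- function(co) {
    aa <- gc[co]
    aa[is.na(aa)] <- "X"  # ambiguous bases
    aa
  }
  aa1 <- aa_of(co1)
  aa2 <- aa_of(co2)
  # trailing stop shared by both is trimmed
  if (length(aa1) && length(aa2) &&
      aa1[length(aa1)] == "*" && aa2[length(aa2)] == "*") {
    co1 <- co1[-length(co1)]
    co2 <- co2[-length(co2)]
    aa1 <- aa1[-length(aa1)]
    aa2 <- aa2[-length(aa2)]
  }
  if (any(aa1 == "*") || any(aa2 == "*"))
    stopf("internal stop codon in CDS")
  p1 <- paste(aa1, collapse = "")
  p2 <- paste(aa2, collapse = "")
  aln <- pairwiseAlignment(AAString(p1), AAString(p2), type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 1)
  s1 <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  s2 <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  i1 <- 0L
  i2 <- 0L
  k1 <- character(0)
  k2 <- character(0)
  dropped <- 0L
  ok_codon <- function(co) !grepl("[^ACGT]", co)
  for (k in seq_along(s1)) {
    g1 <- s1[k] == "-"
    g2 <- s2[k] == "-"
    if (!g1) i1 <- i1 + 1L
    if (!g2) i2 <- i2 + 1L
    if (g1 || g2) {
      dropped <- dropped + 1L
      next
    }
    if (ok_codon(co1[i1]) && ok_codon(co2[i2])) {
      k1 <- c(k1, co1[i1])
      k2 <- c(k2, co2[i2])
    } else {
      dropped <- dropped + 1L
    }
  }
  list(codons1 = k1, codons2 = k2, dropped = dropped)
}

#' NG86 synonymous substitution rate for one codon-aligned pair
#'
#' @param codons1,codons2 equal-length vectors of paired sense codons
#'   (e.g. from [codon_align()]).
#' @param gene1,gene2 optional pair labels.
#' @param min_codons minimum paired codons required (default 30).
#' @return data.frame of class `ks_estimate`: gene1, gene2, n_codons, S
#'   (synonymous sites), N (nonsynonymous sites), sd, nd (synonymous /
#'   nonsynonymous differences), pS, pN, Ks, Ka. `Ks` is `NA` when
#'   pS >= 3/4 (Jukes-Cantor correction undefined).
#' @export
ng86_ks <- function(codons1, codons2, gene1 = "gene1", gene2 = "gene2",
                    min_codons = 30L) {
  if (length(codons1) != length(codons2))
    stopf("codon vectors differ in length")
  if (length(codons1) < min_codons)
    stopf("need at least %d paired codons, got %d", min_codons,
          length(codons1))
  tab <- ng86_tables()
  if (!all(codons1 %in% tab$sense) || !all(codons2 %in% tab$sense))
    stopf("non-sense codon in input")
  S <- (sum(tab$sites[codons1]) + sum(tab$sites[codons2])) / 2
  N <- 3 * length(codons1) - S
  sd_tot <- sum(tab$sd[cbind(codons1, codons2)])
  nd_tot <- sum(tab$nd[cbind(codons1, codons2)])
  pS <- sd_tot / S
  pN <- nd_tot / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  out <- data.frame(gene1 = gene1, gene2 = gene2,
                    n_codons = length(codons1),
                    S = S, N = N, sd = sd_tot, nd = nd_tot,
                    pS = pS, pN = pN, Ks = jc(pS), Ka = jc(pN),
                    stringsAsFactors = FALSE)
  class(out) <- c("ks_estimate", class(out))
  out
}

#' Classify duplication recency against speciation thresholds
#'
#' Strict-inequality binning of Ks against the two speciation reference
#' points used for Solanaceae: pepper vs Solanum divergence at Ks = 0.3
#' and tomato vs potato divergence at Ks = 0.1. Pairs with Ks >= 3 are
#' flagged as not retained (saturated).
#'
#' @param ks data.frame with a `Ks` column (e.g. from [ng86_ks()]).
#' @param thresholds numeric c(pepper_split, tomato_potato_split).
#' @param retention_max Ks retention cutoff (default 3).
#' @return input with `recency` in {post_tomato_potato_split,
#'   post_pepper_split, older} (undefined Ks -> `NA`) and `retained`
#'   columns added.
#' @export
classify_recency <- function(ks, thresholds = c(0.3, 0.1),
                             retention_max = 3) {
  cls <- ifelse(is.na(ks$Ks), NA_character_,
                ifelse(ks$Ks < thresholds[2], "post_tomato_potato_split",
                       ifelse(ks$Ks < thresholds[1], "post_pepper_split",
                              "older")))
  ks$recency <- cls
  ks$retained <- !is.na(ks$Ks) & ks$Ks < retention_max
  ks
}

#' Candidate within-species duplicate pairs
#'
#' Reciprocal-best-hit search within one species' family genes (global
#' alignment scores, ties yield no pair), each pair tagged `tandem` when
#' both genes sit on the same chromosome with at most `max_gene_gap`
#' intervening genes, `dispersed` otherwise.
#'
#' @param proteins named character vector / `AAStringSet` of the
#'   species' family proteins.
#' @param loci data.frame from [read_gene_loci()] covering these genes.
#' @param max_gene_gap maximum intervening genes for the tandem tag.
#' @return data.frame: gene1, gene2, score, mode.
#' @export
duplicate_pairs <- function(proteins, loci, max_gene_gap = 10L) {
  if (inherits(proteins, "XStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  n <- length(proteins)
  if (n < 2) return(data.frame(gene1 = character(), gene2 = character(),
                               score = numeric(), mode = character()))
  S <- alignment_score_matrix(proteins, proteins)
  diag(S) <- -Inf
  pairs <- rbh_from_scores(S, rownames(S), colnames(S))
  if (nrow(pairs) == 0)
    return(data.frame(gene1 = character(), gene2 = character(),
                      score = numeric(), mode = character()))
  # mutual best within one set lists each pair twice; keep one orientation
  keep <- pairs$geneA < pairs$geneB
  pairs <- pairs[keep, , drop = FALSE]
  names(pairs) <- c("gene1", "gene2", "score")
  li <- loci[match(pairs$gene1, loci$gene), ]
  lj <- loci[match(pairs$gene2, loci$gene), ]
  same_chr <- !is.na(li$chrom) & !is.na(lj$chrom) & li$chrom == lj$chrom
  gap <- abs(li$rank - lj$rank) - 1L
  pairs$mode <- ifelse(same_chr & gap <= max_gene_gap, "tandem", "dispersed")
  rownames(pairs) <- NULL
  pairs
}
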