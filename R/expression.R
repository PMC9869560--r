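# Expression analysis: FPKM, differential-expression calling, fuzzy
# c-means clustering of stress time courses, GO enrichment and ortholog
# expression correlation.
#
# Differential expression is called with a two-sided Welch test on
# log2(FPKM + 1) across replicates, Benjamini-Hochberg adjusted within
# the contrast, with the standard |log2FC| > 1 and adjusted p < 0.05
# rule. This is a deliberately simple, dependency-light test whose
# type-I and power behaviour is itself exercised by the test suite.

#' Fragments per kilobase per million mapped reads
#'
#' FPKM[g, s] = counts[g, s] * 1e9 / (library_size[s] * length[g]),
#' library size being the column sum of the count matrix.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param lengths named numeric vector of gene lengths in bp (names must
#'   cover the rownames of `counts`).
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("zero library size in sample(s): %s",
                           paste(colnames(counts)[lib == 0], collapse = ", "))
  len <- lengths[rownames(counts)]
  if (anyNA(len)) stopf("missing gene length for: %s",
                        paste(rownames(counts)[is.na(len)][1:5], collapse = ", "))
  if (any(len <= 0)) stopf("gene lengths must be positive")
  sweep(sweep(counts, 2, lib, "/"), 1, len, "/") * 1e9
}

#' Call differentially expressed genes for one contrast
#'
#' log2FC = log2((mean FPKM_condition + 1) / (mean FPKM_control + 1));
#' p-values from a two-sided Welch t-test on log2(FPKM + 1) across
#' replicates; BH adjustment across genes within the contrast; a gene is
#' called `up`/`down` iff |log2FC| > `lfc_min` and adjusted p <
#' `padj_max`.
#'
#' @param counts genes x samples count matrix.
#' @param lengths named gene-length vector (bp).
#' @param design data.frame with columns sample, condition and
#'   optionally time; `sample` must match the columns of `counts`.
#' @param condition,control condition labels to contrast.
#' @param time optional time point; `NULL` pools all samples of the
#'   condition.
#' @param lfc_min,padj_max call thresholds (defaults 1 and 0.05).
#' @return data.frame: gene, condition, log2fc, p, padj, call.
#' @export
call_degs <- function(counts, lengths, design, condition,
                      control = "control", time = NULL,
                      lfc_min = 1, padj_max = 0.05) {
  counts <- as.matrix(counts)
  pick <- function(cond, tm) {
    sel <- design$condition == cond
    if (!is.null(tm) && !is.null(design$time))
      sel <- sel & !is.na(design$time) & design$time == tm
    design$sample[sel]
  }
  cs <- pick(condition, time)
  xs <- pick(control, NULL)
  if (length(xs) == 0) stopf("no control samples labelled '%s'", control)
  if (length(cs) < 2 || length(xs) < 2)
    stopf("need >= 2 replicates per group (got %d vs %d)",
          length(cs), length(xs))
  f <- log2(fpkm(counts, lengths) + 1)
  a <- f[, cs, drop = FALSE]
  b <- f[, xs, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)
  na <- ncol(a)
  nb <- ncol(b)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1  # zero-variance, zero-difference rows
  p[se2 == 0 & ma == mb] <- 1
  # fold change on the FPKM scale with pseudocount 1
  fa <- rowMeans(2^a - 1)
  fb <- rowMeans(2^b - 1)
  log2fc <- log2((fa + 1) / (fb + 1))
  padj <- stats::p.adjust(p, method = "BH")
  call <- ifelse(abs(log2fc) > lfc_min & padj < padj_max,
                 ifelse(log2fc > 0, "up", "down"), "none")
  data.frame(gene = rownames(counts), condition = condition,
             log2fc = log2fc, p = p, padj = padj, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Standardizes each gene's profile to zero mean and unit variance over
#' the time course (constant profiles are excluded with a warning), then
#' runs fuzzy c-means (Bezdek updates, fuzzifier `m`) with `restarts`
#' seeded restarts, keeping the solution with the lowest objective.
#' Hard assignment is the argmax membership.
#'
#' @param profiles genes x timepoints numeric matrix.
#' @param k number of clusters (default 4).
#' @param m fuzzifier (default 2).
#' @param restarts number of random restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @param iter_max,tol convergence controls.
#' @return list: `cluster` (named hard assignments), `membership`,
#'   `centers`, `objective`, `excluded` (constant genes).
#' @export
cluster_profiles <- function(profiles, k = 4L, m = 2, restarts = 20L,
                             seed = 1L, iter_max = 200L, tol = 1e-6) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))
  sds <- apply(profiles, 1, stats::sd)
  excluded <- rownames(profiles)[is.na(sds) | sds == 0]
  if (length(excluded))
    warning(sprintf("%d constant profile(s) excluded from clustering",
                    length(excluded)))
  z <- profiles[!(rownames(profiles) %in% excluded), , drop = FALSE]
  z <- t(scale(t(z)))
  if (nrow(z) < k) stopf("need at least k = %d usable profiles", k)
  if (k == 1) {
    ctr <- matrix(colMeans(z), nrow = 1)
    obj <- sum(sweep(z, 2, ctr[1, ])^2)
    return(list(cluster = setNames(rep(1L, nrow(z)), rownames(z)),
                membership = matrix(1, nrow(z), 1,
                                    dimnames = list(rownames(z), NULL)),
                centers = ctr, objective = obj, excluded = excluded))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, 7000L + r))
    init <- z[sample(nrow(z), k), , drop = FALSE]
    fit <- e1071::cmeans(z, centers = init, m = m, iter.max = iter_max,
                         method = "cmeans",
                         control = list(reltol = tol))
    if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
  }
  list(cluster = setNames(as.integer(best$cluster), rownames(z)),
       membership = best$membership,
       centers = best$centers,
       objective = best$withinerror,
       excluded = excluded)
}

#' @noRd
fisher_enrichment_p <- function(a, b, c, d) {
  # one-sided (enrichment) Fisher exact p: hypergeometric tail
  # a = in-set annotated, b = in-set not, c = out-set annotated, d = out-set not
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' GO term enrichment of a gene set
#'
#' One-sided Fisher exact test (hypergeometric tail) per term against
#' the background, BH-adjusted across terms; a term is significant when
#' its FDR is at most `fdr_max` (default 0.01).
#'
#' @param set character vector of genes (must be a subset of
#'   `background`).
#' @param background character vector of all genes considered.
#' @param annotations data.frame with columns gene, term.
#' @param fdr_max significance cutoff on the BH-adjusted p.
#' @return data.frame sorted by p: term, set_annotated, set_size,
#'   bg_annotated, bg_size, p, fdr, significant, rank.
#' @export
go_enrichment <- function(set, background, annotations, fdr_max = 0.01) {
  empty <- data.frame(term = character(), set_annotated = integer(),
                      set_size = integer(), bg_annotated = integer(),
                      bg_size = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (length(set) == 0) return(empty)
  if (!all(set %in% background))
    stopf("gene set must be a subset of the background")
  if (nrow(annotations) == 0) stopf("empty annotation table")
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  terms <- unique(ann$term)
  n_set <- length(unique(set))
  n_bg <- length(unique(background))
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(ann$gene[ann$term == tm])
    a <- sum(set %in% genes_tm)
    b <- n_set - a
    c_ <- length(genes_tm) - a
    d <- n_bg - n_set - c_
    data.frame(term = tm, set_annotated = a, set_size = n_set,
               bg_annotated = length(genes_tm), bg_size = n_bg,
               p = fisher_enrichment_p(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$significant <- out$fdr <= fdr_max
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Expression correlation between ortholog pairs
#'
#' The time-resolved species' FPKM is averaged over its time points per
#' condition; the Pearson correlation across ortholog pairs is then
#' computed per condition shared by both designs.
#'
#' @param fpkmA genes x samples FPKM matrix of the time-resolved species.
#' @param designA data.frame (sample, condition, time) for `fpkmA`.
#' @param fpkmB genes x samples FPKM matrix of the second species.
#' @param designB data.frame (sample, condition) for `fpkmB`.
#' @param pairs data.frame with columns geneA, geneB (ortholog pairs;
#'   geneA in `fpkmA`).
#' @param min_pairs minimum pairs for a defined correlation (default 3).
#' @return data.frame: condition, n_pairs, r (`NA` when undefined).
#' @export
ortholog_expression_correlation <- function(fpkmA, designA, fpkmB, designB,
                                            pairs, min_pairs = 3L) {
  if (nrow(pairs) == 0) stopf("no ortholog pairs supplied")
  conds <- intersect(unique(designA$condition), unique(designB$condition))
  pairs <- pairs[pairs$geneA %in% rownames(fpkmA) &
                 pairs$geneB %in% rownames(fpkmB), , drop = FALSE]
  rows <- lapply(conds, function(cond) {
    sa <- designA$sample[designA$condition == cond]
    sb <- designB$sample[designB$condition == cond]
    va <- rowMeans(fpkmA[pairs$geneA, sa, drop = FALSE])
    vb <- rowMeans(fpkmB[pairs$geneB, sb, drop = FALSE])
    r <- if (nrow(pairs) < min_pairs ||
             stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else
      stats::cor(va, vb, method = "pearson")
    data.frame(condition = cond, n_pairs = nrow(pairs), r = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
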