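# Domain-hit ingestion and filtering.
#
# Hits come from one of two routes: parsing InterProScan-style Pfam TSV
# output (accessions PF00847 = AP2, PF02362 = B3), or scanning protein
# sequences against the bundled PFMs with a log-odds sliding window.
# filter_hits() then applies the cleaning rules: drop hits with e-value
# above 1e-5 and resolve mutually overlapping hits in favour of the most
# significant one, yielding a per-gene domain architecture.

.PFAM_AP2 <- "PF00847"
.PFAM_B3 <- "PF02362"

#' @noRd
new_hits <- function(gene = character(), kind = character(),
                     start = integer(), end = integer(),
                     evalue = numeric(), score = numeric()) {
  data.frame(gene = gene, kind = kind, start = as.integer(start),
             end = as.integer(end), evalue = evalue, score = score,
             stringsAsFactors = FALSE)
}

#' Parse an InterProScan-style Pfam TSV file
#'
#' Reads the tab-separated layout produced by `interproscan -f tsv -appl
#' Pfam` (protein id, md5, length, analysis, accession, description,
#' start, stop, e-value, ...). Rows whose accession is PF00847 become AP2
#' hits and PF02362 become B3 hits; all other accessions are ignored.
#' Coordinates are taken verbatim (1-based, end-inclusive).
#'
#' @param path path to the TSV file (no header line).
#' @return data.frame of hits: gene, kind, start, end, evalue, score.
#'   e-values reported as "-" are kept as `NA`.
#' @export
parse_interproscan_tsv <- function(path) {
  if (!file.exists(path)) stopf("domain TSV not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- new_hits()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stopf("line %d: expected >= 9 tab-separated columns, found %d",
            i, length(f))
    acc <- f[5]
    if (!acc %in% c(.PFAM_AP2, .PFAM_B3)) next
    start <- suppressWarnings(as.integer(f[7]))
    end <- suppressWarnings(as.integer(f[8]))
    if (is.na(start) || is.na(end))
      stopf("line %d: non-integer domain coordinates '%s'..'%s'",
            i, f[7], f[8])
    if (start > end)
      stopf("line %d: start (%d) greater than end (%d)", i, start, end)
    ev <- if (identical(f[9], "-")) NA_real_ else
      suppressWarnings(as.numeric(f[9]))
    if (!identical(f[9], "-") && is.na(ev))
      stopf("line %d: malformed e-value '%s'", i, f[9])
    out <- rbind(out, new_hits(f[1], if (acc == .PFAM_AP2) "AP2" else "B3",
                               start, end, ev, NA_real_))
  }
  rownames(out) <- NULL
  out
}

#' Scan a protein with a position-frequency model
#'
#' Slides a log-odds window (background = uniform 1/20) of the model's
#' width along the sequence and reports windows scoring at least
#' `threshold` bits, made greedily non-overlapping by descending score.
#' Sequences shorter than the model width yield an empty hit set.
#'
#' @param sequence protein sequence (character scalar).
#' @param model a model as returned by [ap2_model()] or [b3_model()].
#' @param threshold minimum window score in bits (default 15).
#' @param gene gene id to stamp on the hits.
#' @return data.frame of hits; `evalue` is `NA` on this path (bit scores
#'   only), so the downstream e-value filter does not apply to them.
#' @export
scan_pssm <- function(sequence, model = ap2_model(), threshold = 15,
                      gene = "query") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- model$width
  n <- length(chars)
  if (n < w) return(new_hits())
  lod <- log2(model$pfm / (1 / 20))
  idx <- match(chars, AA20)
  scores <- vapply(seq_len(n - w + 1), function(s) {
    ii <- idx[s:(s + w - 1)]
    if (anyNA(ii)) return(-Inf)  # non-standard residues never match
    sum(lod[cbind(ii, seq_len(w))])
  }, numeric(1))
  keep <- which(scores >= threshold)
  if (length(keep) == 0) return(new_hits())
  ord <- keep[order(-scores[keep], keep)]
  taken <- logical(n)
  hits <- new_hits()
  for (s in ord) {
    span <- s:(s + w - 1)
    if (any(taken[span])) next
    taken[span] <- TRUE
    hits <- rbind(hits, new_hits(gene, model$kind, s, s + w - 1,
                                 NA_real_, scores[s]))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter domain hits into a clean architecture
#'
#' Applies the cleaning rules used for AP2/ERF domain identification:
#' hits with e-value above `max_evalue` are dropped (hits lacking an
#' e-value are kept), and among mutually overlapping hits (>= 1 shared
#' residue) the one with the lowest e-value is retained, ties broken by
#' lowest start and then by longest span. Hits without e-values rank
#' below any numeric e-value during overlap resolution.
#'
#' @param hits data.frame of hits for a single gene (as produced by
#'   [parse_interproscan_tsv()] or [scan_pssm()]).
#' @param max_evalue e-value cutoff (default 1e-5; strictly greater is
#'   dropped).
#' @return an object of class `erf_architecture`: list with `gene`,
#'   `hits` (sorted, non-overlapping), `n_AP2` and `has_B3`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(structure(list(gene = NA_character_, hits = new_hits(),
                          n_AP2 = 0L, has_B3 = FALSE),
                     class = "erf_architecture"))
  }
  gene <- unique(hits$gene)
  if (length(gene) > 1)
    stopf("filter_hits() expects hits of a single gene, got: %s",
          paste(gene, collapse = ", "))
  keep <- is.na(hits$evalue) | hits$evalue <= max_evalue
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) > 0) {
    rank_ev <- ifelse(is.na(hits$evalue), Inf, hits$evalue)
    ord <- order(rank_ev, hits$start, -(hits$end - hits$start))
    retained <- integer(0)
    for (i in ord) {
      ov <- FALSE
      for (j in retained) {
        if (hits$start[i] <= hits$end[j] && hits$start[j] <= hits$end[i]) {
          ov <- TRUE
          break
        }
      }
      if (!ov) retained <- c(retained, i)
    }
    hits <- hits[sort(retained), , drop = FALSE]
    hits <- hits[order(hits$start), , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(list(gene = gene, hits = hits,
                 n_AP2 = sum(hits$kind == "AP2"),
                 has_B3 = any(hits$kind == "B3")),
            class = "erf_architecture")
}

#' @export
print.erf_architecture <- function(x, ...) {
  cat(sprintf("<architecture %s: %d AP2 domain(s)%s>\n", x$gene, x$n_AP2,
              if (x$has_B3) " + B3" else ""))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' @noRd
split_hits_by_gene <- function(hits) split(hits, hits$gene)
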