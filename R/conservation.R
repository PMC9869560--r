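# Position-specific conservation of the AP2 domain.
#
# Given a set of sequences aligned to the model width, we compute
# per-column residue frequencies (gaps excluded from the denominator),
# call the consensus residue with the >50% uppercase convention, and
# summarise conservation over the eight divisions derived from the
# domain's secondary structure (three beta-sheets at columns 1-7, 14-20
# and 31-33, one alpha-helix at 48-57, and the intervals between them).

#' Secondary-structure divisions of the AP2 domain
#'
#' The domain's secondary structure (beta1 = columns 1-7, beta2 = 14-20,
#' beta3 = 31-33, alpha = 48-57) partitions the model into eight
#' divisions: the four structured elements and the four intervening /
#' trailing intervals. D8 is empty at the canonical width of 57 and
#' covers any additional columns of wider models.
#'
#' @param width model width (default 57).
#' @return data.frame: division, start, end, structure.
#' @export
ss_divisions <- function(width = 57L) {
  d <- data.frame(
    division = paste0("D", 1:8),
    start = c(1L, 8L, 14L, 21L, 31L, 34L, 48L, 58L),
    end = c(7L, 13L, 20L, 30L, 33L, 47L, 57L, as.integer(width)),
    structure = c("beta1", "loop", "beta2", "loop", "beta3", "loop",
                  "alpha", "tail"),
    stringsAsFactors = FALSE)
  if (width < 58L) d <- d[1:7, ]
  if (width != 57L && width < 58L)
    stopf("ss_divisions() requires width >= 57")
  d
}

#' Per-column residue frequencies of an aligned domain set
#'
#' @param sequences character vector (or `AAStringSet`) of sequences all
#'   aligned to the same width; `-` marks gaps.
#' @return object of class `conservation_profile`: list with `freq`
#'   (20 x width matrix of relative frequencies; columns sum to 1 except
#'   all-gap columns, which are flagged), `all_gap` (logical per column),
#'   `n` and `width`. Gap characters never enter the denominator.
#' @export
column_frequencies <- function(sequences) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0) stopf("column_frequencies(): zero sequences")
  if (length(unique(nchar(sequences))) != 1)
    stopf("sequences must share one aligned width")
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  w <- ncol(m)
  freq <- matrix(0, nrow = 20, ncol = w, dimnames = list(AA20, NULL))
  all_gap <- logical(w)
  for (j in seq_len(w)) {
    col <- m[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) {
      all_gap[j] <- TRUE
    } else {
      tab <- table(factor(col, levels = AA20))
      freq[, j] <- as.numeric(tab) / length(col)
    }
  }
  structure(list(freq = freq, all_gap = all_gap,
                 n = length(sequences), width = w),
            class = "conservation_profile")
}

#' Consensus string with the majority case convention
#'
#' The consensus residue of a column is its most frequent amino acid
#' (ties broken alphabetically). It is written uppercase iff its
#' frequency strictly exceeds 0.5, lowercase otherwise; all-gap columns
#' are written as `-`.
#'
#' @param profile a `conservation_profile`.
#' @return the profile with `consensus` (character vector),
#'   `consensus_fraction` (numeric) and `consensus_string` added.
#' @export
consensus_calling <- function(profile) {
  w <- profile$width
  cons <- character(w)
  frac <- numeric(w)
  for (j in seq_len(w)) {
    if (profile$all_gap[j]) {
      cons[j] <- "-"
      frac[j] <- NA_real_
      next
    }
    f <- profile$freq[, j]
    best <- AA20[which.max(f)]  # which.max takes the first = alphabetical
    frac[j] <- f[best]
    cons[j] <- if (frac[j] > 0.5) best else tolower(best)
  }
  profile$consensus <- cons
  profile$consensus_fraction <- frac
  profile$consensus_string <- paste(cons, collapse = "")
  profile
}

#' Mean consensus fraction per secondary-structure division
#'
#' The "consensus ratio" of a division is the arithmetic mean of the
#' per-column consensus-residue fractions over its columns, with all-gap
#' columns excluded. A fully gapped division is reported as `NA`.
#'
#' @param profile a `conservation_profile` (consensus fractions are
#'   computed on the fly if missing).
#' @param divisions division table from [ss_divisions()].
#' @return data.frame: division, structure, ratio.
#' @export
division_consensus_ratio <- function(profile,
                                     divisions = ss_divisions(profile$width)) {
  if (is.null(profile$consensus_fraction))
    profile <- consensus_calling(profile)
  ratio <- vapply(seq_len(nrow(divisions)), function(i) {
    cols <- divisions$start[i]:divisions$end[i]
    f <- profile$consensus_fraction[cols]
    f <- f[!is.na(f)]
    if (length(f) == 0) NA_real_ else mean(f)
  }, numeric(1))
  data.frame(division = divisions$division,
             structure = divisions$structure,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation profile: %d sequences x %d columns>\n",
              x$n, x$width))
  if (!is.null(x$consensus_string))
    cat(" consensus:", x$consensus_string, "\n")
  invisible(x)
}
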