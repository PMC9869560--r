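# Shared internal helpers: seeded RNG threading, TSV io, small checks.

.erf_cache <- new.env(parent = emptyenv())

#' @noRd
derive_seed <- function(seed, offset) {
  # keep derived seeds well inside 32-bit integer range
  as.integer((as.numeric(seed) %% 1e6L) * 1009 + offset)
}

#' @noRd
write_tsv0 <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

#' @noRd
read_tsv0 <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# The twenty standard amino acids, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' @noRd
substitute_residues <- function(seq, n) {
  chars <- strsplit(seq, "")[[1]]
  if (n <= 0 || length(chars) == 0) return(seq)
  pos <- sample(seq_along(chars), min(n, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}
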