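#' Construct a genome
#'
#' A genome is a named [Biostrings::DNAStringSet] with unique chromosome
#' names and non-empty sequences over the alphabet A, C, G, T, N.
#'
#' @param x Named character vector or `DNAStringSet` of chromosome sequences.
#' @return A validated `DNAStringSet`.
#' @export
genome <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  stopifnot(methods::is(x, "DNAStringSet"))
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort("genome chromosomes must be named")
  }
  if (anyDuplicated(nm)) abort("genome chromosome names must be unique")
  if (any(Biostrings::width(x) == 0)) abort("genome sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(x)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0)) abort("genome sequences restricted to A/C/G/T/N")
  x
}

#' Chromosome lengths of a genome
#' @param g A genome (`DNAStringSet`).
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(g) {
  setNames(Biostrings::width(g), names(g))
}

# Extract sequence chrom:start-end (1-based inclusive) as a character scalar.
# Positions outside the chromosome are an error unless clip = TRUE.
genome_seq <- function(g, chrom, start, end, clip = FALSE) {
  if (!chrom %in% names(g)) abort(sprintf("unknown chromosome '%s'", chrom))
  len <- length(g[[chrom]])
  if (clip) {
    start <- max(1L, start)
    end <- min(len, end)
  }
  if (start < 1L || end > len || end < start) {
    abort(sprintf("region %s:%d-%d outside chromosome (length %d)", chrom, start, end, len))
  }
  as.character(Biostrings::subseq(g[[chrom]], start, end))
}

# In-place base replacement on one chromosome; seq is a character scalar.
genome_replace <- function(g, chrom, start, replacement) {
  end <- start + nchar(replacement) - 1L
  len <- length(g[[chrom]])
  stopifnot(start >= 1L, end <= len)
  s <- g[[chrom]]
  g[[chrom]] <- Biostrings::DNAString(paste0(
    if (start > 1L) as.character(Biostrings::subseq(s, 1L, start - 1L)) else "",
    replacement,
    if (end < len) as.character(Biostrings::subseq(s, end + 1L, len)) else ""
  ))
  g
}
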