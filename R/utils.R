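#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet subseq
NULL

# Coerce any accepted genome representation to a DNAStringSet keyed by the
# first whitespace-delimited token of each header.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome) && !is.null(names(genome))) {
    gs <- Biostrings::DNAStringSet(genome)
  } else {
    abort("`genome` must be a DNAStringSet, a named character vector, or a FASTA path.")
  }
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

# 0-based half-open slice of one contig.
slice_contig <- function(genome, contig, start, end) {
  gs <- as_genome(genome)
  if (!contig %in% names(gs)) {
    abort(sprintf("Contig '%s' not found in genome (contigs: %s).",
                  contig, paste(utils::head(names(gs), 5), collapse = ", ")))
  }
  len <- Biostrings::width(gs[contig])
  if (start < 0 || end > len || end <= start) {
    abort(sprintf("Range [%d, %d) out of bounds for contig '%s' (length %d).",
                  start, end, contig, len))
  }
  as.character(Biostrings::subseq(gs[[contig]], start = start + 1L, end = end))
}

check_dna_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N} at element %d.",
                  what, which(bad)[1]))
  }
  invisible(seq)
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(strsplit(seq, NULL), function(x) paste(rev(x), collapse = ""), ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
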