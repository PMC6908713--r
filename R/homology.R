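#' Read promoter homology hits from BLAST tabular output
#'
#' Parses the standard 12-column BLAST tabular format (`-outfmt 6`: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore) into a tibble of promoter hits. Subject coordinates are
#' converted from BLAST's 1-based inclusive convention to 0-based half-open;
#' a subject start greater than the subject end marks a minus-strand hit and
#' the coordinates are swapped.
#'
#' @param path Path to a BLAST tabular (outfmt 6) file. Extra columns beyond
#'   the canonical 12 are ignored.
#' @param species_id Species the subject genome belongs to; recorded on every
#'   hit so tables from many species can be bound together.
#' @return A tibble with one row per hit: `promoter_id`, `species_id`,
#'   `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `percent_identity`, `alignment_length`, `bitscore`, `evalue`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("p1\tchr1\t85.0\t400\t60\t0\t1\t400\t1001\t1400\t1e-50\t350", tf)
#' read_blast_hits(tf, "sp1")
#' @export
read_blast_hits <- function(path, species_id) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (!file.exists(path)) abort(sprintf("BLAST tabular file not found: '%s'.", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 12L)) {
    abort(sprintf("Malformed BLAST tabular line %d: expected >= 12 tab-separated fields, got %d.",
                  which(n_col < 12L)[1], n_col[which(n_col < 12L)[1]]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) {
      abort(sprintf("Malformed BLAST tabular line %d: non-numeric %s field.",
                    which(is.na(v))[1], name))
    }
    v
  }
  sstart <- num(9, "sstart"); send <- num(10, "send")
  minus <- sstart > send
  lo <- pmin(sstart, send); hi <- pmax(sstart, send)
  tibble(
    promoter_id = get(1),
    species_id = species_id,
    contig = get(2),
    start = as.integer(lo - 1),          # 1-based inclusive -> 0-based half-open
    end = as.integer(hi),
    strand = ifelse(minus, "-", "+"),
    percent_identity = num(3, "pident"),
    alignment_length = as.integer(num(4, "length")),
    bitscore = num(12, "bitscore"),
    evalue = num(11, "evalue")
  )
}

empty_hit_table <- function() {
  tibble(
    promoter_id = character(), species_id = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    percent_identity = double(), alignment_length = integer(),
    bitscore = double(), evalue = double()
  )
}

#' Keep the single best hit per species and promoter
#'
#' Applies the homology filter used to define the clock's feature set: hits at
#' or below the identity threshold are discarded (the threshold is strict,
#' `percent_identity > min_identity`), and among survivors exactly one hit is
#' retained per (species, promoter) pair — the highest bitscore, with ties
#' broken by lowest e-value and then input order. Multiple HSPs are never
#' merged.
#'
#' @param hits Hit tibble as returned by [read_blast_hits()]; tables from
#'   several species may be row-bound first.
#' @param min_identity Identity threshold in percent; hits must exceed it
#'   strictly. Default 70.
#' @return A filtered hit tibble with at most one row per
#'   (species_id, promoter_id).
#' @export
filter_top_hits <- function(hits, min_identity = 70) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0L) return(hits)
  hits |>
    mutate(.ord = dplyr::row_number()) |>
    filter(.data$percent_identity > min_identity) |>
    arrange(.data$species_id, .data$promoter_id,
            dplyr::desc(.data$bitscore), .data$evalue, .data$.ord) |>
    distinct(.data$species_id, .data$promoter_id, .keep_all = TRUE) |>
    select(-".ord")
}

#' Extract the genomic sequence under a hit
#'
#' Returns the forward-strand genomic subsequence covered by a hit's 0-based
#' half-open interval. Minus-strand hits return the same forward-strand slice:
#' the CpG dinucleotide is reverse-complement symmetric, so CpG counts are
#' identical on either strand and no reverse complementation is needed.
#'
#' @param genome A `DNAStringSet`, named character vector of contigs, or FASTA
#'   path. Contigs are keyed by the first whitespace-delimited header token.
#' @param hit A one-row hit tibble (or list) with `contig`, `start`, `end`.
#' @return A character scalar with the subsequence.
#' @export
extract_hit_sequence <- function(genome, hit) {
  slice_contig(genome, hit$contig[[1]], hit$start[[1]], hit$end[[1]])
}

#' Ungapped seed-and-extend alignment of a promoter query
#'
#' A deliberately small homology search used to exercise the pipeline on
#' generated fixtures without an external aligner: exact `word_size`-mers of
#' the query are located in the genome and extended without gaps in both
#' directions for as long as the running identity stays at or above
#' `min_identity`; the extension with the most matching bases wins. This is
#' not a BLAST replacement — no gaps, no e-value model (`evalue` is reported
#' as 0 and `bitscore` as the match count).
#'
#' @param query Query sequence (character scalar), at least `word_size` long.
#' @param genome Genome as in [extract_hit_sequence()].
#' @param species_id Species label recorded on the returned hit.
#' @param word_size Exact seed length. Default 11.
#' @param min_identity Minimum running identity (percent) during extension.
#' @return A one-row hit tibble, or `NULL` when no seed matches.
#' @export
seed_extend_align <- function(query, genome, species_id = "query_species",
                              word_size = 11, min_identity = 70) {
  query <- toupper(query)
  if (nchar(query) < word_size) {
    abort(sprintf("Query (length %d) is shorter than word_size (%d).",
                  nchar(query), word_size))
  }
  gs <- as_genome(genome)
  qlen <- nchar(query)
  qchars <- strsplit(query, NULL)[[1]]
  best <- NULL
  for (contig in names(gs)) {
    subject <- toupper(as.character(gs[[contig]]))
    schars <- strsplit(subject, NULL)[[1]]
    slen <- length(schars)
    seeds <- seed_positions(query, subject, word_size)
    for (k in seq_len(nrow(seeds))) {
      qpos <- seeds$qpos[k]; spos <- seeds$spos[k]
      ext <- extend_ungapped(qchars, schars, qpos, spos, word_size,
                             min_identity / 100)
      if (is.null(best) || ext$matches > best$matches ||
          (ext$matches == best$matches && ext$sstart < best$sstart)) {
        best <- c(ext, list(contig = contig))
      }
    }
  }
  if (is.null(best)) return(NULL)
  tibble(
    promoter_id = "query", species_id = species_id, contig = best$contig,
    start = best$sstart - 1L, end = best$send,
    strand = "+",
    percent_identity = 100 * best$matches / best$len,
    alignment_length = best$len,
    bitscore = as.numeric(best$matches), evalue = 0
  )
}

# All (query, subject) 1-based positions sharing an exact word_size-mer.
seed_positions <- function(query, subject, word_size) {
  qstarts <- seq_len(nchar(query) - word_size + 1L)
  words <- substring(query, qstarts, qstarts + word_size - 1L)
  out_q <- integer(0); out_s <- integer(0)
  for (w in unique(words)) {
    m <- Biostrings::matchPattern(w, Biostrings::DNAString(subject))
    if (length(m) == 0L) next
    sp <- Biostrings::start(m)
    qp <- qstarts[words == w]
    grid <- expand.grid(qpos = qp, spos = sp)
    out_q <- c(out_q, grid$qpos); out_s <- c(out_s, grid$spos)
  }
  data.frame(qpos = out_q, spos = out_s)
}

# Greedy ungapped extension in both directions keeping running identity above
# the threshold; returns the prefix/suffix pair maximising matched bases.
extend_ungapped <- function(qchars, schars, qpos, spos, word_size, min_frac) {
  qlen <- length(qchars); slen <- length(schars)
  # right extension beyond the seed
  matches <- word_size; len <- word_size
  best_r <- c(matches = matches, len = len)
  qi <- qpos + word_size; si <- spos + word_size
  while (qi <= qlen && si <= slen) {
    matches <- matches + (qchars[qi] == schars[si]); len <- len + 1L
    if (matches / len >= min_frac && matches > best_r["matches"]) {
      best_r <- c(matches = matches, len = len)
    }
    if (matches / len < min_frac) break
    qi <- qi + 1L; si <- si + 1L
  }
  # left extension, on top of the chosen right extension
  matches <- best_r[["matches"]]; len <- best_r[["len"]]
  best <- c(matches = matches, len = len, left = 0L)
  qi <- qpos - 1L; si <- spos - 1L; left <- 0L
  while (qi >= 1L && si >= 1L) {
    matches <- matches + (qchars[qi] == schars[si]); len <- len + 1L; left <- left + 1L
    if (matches / len >= min_frac && matches > best["matches"]) {
      best <- c(matches = matches, len = len, left = left)
    }
    if (matches / len < min_frac) break
    qi <- qi - 1L; si <- si - 1L
  }
  sstart <- spos - best[["left"]]
  list(matches = best[["matches"]], len = best[["len"]],
       sstart = sstart, send = sstart + best[["len"]] - 1L)
}

#' Write or read a hit table as TSV
#'
#' Serializes hit tibbles in a fixed column order
#' (species_id, promoter_id, contig, start, end, strand, pident, aln_len,
#' bitscore, evalue) for interchange between pipeline stages.
#'
#' @param hits Hit tibble.
#' @param path Output/input TSV path.
#' @return `write_hit_table()` returns `path` invisibly; `read_hit_table()`
#'   returns the hit tibble.
#' @export
write_hit_table <- function(hits, path) {
  hits |>
    select("species_id", "promoter_id", "contig", "start", "end", "strand",
           pident = "percent_identity", aln_len = "alignment_length",
           "bitscore", "evalue") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    rename(percent_identity = "pident", alignment_length = "aln_len") |>
    select("promoter_id", "species_id", "contig", "start", "end", "strand",
           "percent_identity", "alignment_length", "bitscore", "evalue")
}
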