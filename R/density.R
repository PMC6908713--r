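#' Count CpG dinucleotides in a sequence
#'
#' Counts positions `i` with `seq[i] == "C"` and `seq[i+1] == "G"` on the
#' given strand, case-insensitively. Dinucleotides containing `N` never
#' count. Because the CpG dinucleotide is its own reverse complement, the
#' count is identical on the two strands.
#'
#' @param seq Character vector of sequences over {A,C,G,T,N} (either case).
#' @return Integer vector of CpG counts.
#' @examples
#' count_cpg("ACGCGT") # 2
#' @export
count_cpg <- function(seq) {
  check_dna_alphabet(seq)
  stringr::str_count(toupper(seq), stringr::fixed("CG"))
}

#' CpG density of one promoter hit
#'
#' The clock's per-promoter feature: the number of CpG sites inside the hit's
#' genomic interval divided by the hit's alignment length (the BLAST `length`
#' column, which may exceed the interval width when the alignment is gapped).
#' A promoter with no qualifying hit in a species has density 0 by definition.
#'
#' @param genome Genome as in [extract_hit_sequence()].
#' @param hit One-row hit tibble, or `NULL` for "no hit".
#' @return CpG density (CpG sites per aligned base).
#' @export
promoter_density <- function(genome, hit) {
  if (is.null(hit) || nrow(as.data.frame(hit)) == 0L) return(0)
  len <- hit$alignment_length[[1]]
  if (is.na(len) || len <= 0) abort("Hit alignment_length must be positive.")
  count_cpg(extract_hit_sequence(genome, hit)) / len
}

#' Assemble the species-by-promoter CpG density matrix
#'
#' Builds the clock's feature table: one row per species, one column per
#' promoter in `promoter_ids` (in that order), each entry the CpG density of
#' the species' filtered top hit for that promoter, and exactly 0 where the
#' hit table has no entry.
#'
#' @param genomes Named list (by species_id) of genomes, each as in
#'   [extract_hit_sequence()].
#' @param hits Filtered hit tibble ([filter_top_hits()]); at most one row per
#'   (species, promoter).
#' @param promoter_ids Promoter universe defining the column order.
#' @param species_ids Optional row order; defaults to `names(genomes)`.
#' @return A tibble with column `species_id` followed by one numeric column
#'   per promoter.
#' @export
build_density_matrix <- function(genomes, hits, promoter_ids,
                                 species_ids = names(genomes)) {
  if (anyDuplicated(species_ids)) abort("Duplicate species ids in `species_ids`.")
  if (anyDuplicated(promoter_ids)) abort("Duplicate promoter ids in `promoter_ids`.")
  m <- matrix(0, nrow = length(species_ids), ncol = length(promoter_ids),
              dimnames = list(species_ids, promoter_ids))
  hits <- as_tibble(hits) |>
    filter(.data$species_id %in% species_ids, .data$promoter_id %in% promoter_ids)
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    m[h$species_id, h$promoter_id] <-
      promoter_density(genomes[[h$species_id]], h)
  }
  density_tibble(m)
}

# matrix (species x promoters, dimnames set) -> tidy density tibble
density_tibble <- function(m) {
  bind_cols(tibble(species_id = rownames(m)), as_tibble(m))
}

# density tibble -> plain matrix with species rownames
density_values <- function(densities) {
  densities <- as_tibble(densities)
  m <- as.matrix(densities[setdiff(names(densities), "species_id")])
  rownames(m) <- densities$species_id
  storage.mode(m) <- "double"
  m
}

#' Read or write a density matrix CSV
#'
#' First column `species_id`, remaining columns one per promoter.
#'
#' @param densities Density tibble.
#' @param path CSV path.
#' @export
write_density_matrix <- function(densities, path) {
  readr::write_csv(densities, path)
  invisible(path)
}

#' @rdname write_density_matrix
#' @export
read_density_matrix <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Genome-wide CpG and GC statistics
#'
#' Totals CpG sites (within contigs; never across contig boundaries), genome
#' length, and GC content over all contigs. `N` bases are excluded from both
#' the GC numerator and denominator.
#'
#' @param genome Genome as in [extract_hit_sequence()].
#' @param species_id Optional label recorded in the result.
#' @return One-row tibble: `species_id`, `total_cpg`, `genome_length`,
#'   `gc_content`.
#' @export
genome_stats <- function(genome, species_id = NA_character_) {
  gs <- as_genome(genome)
  if (length(gs) == 0L || sum(Biostrings::width(gs)) == 0L) {
    abort("Empty genome: no contigs or zero total length.")
  }
  freq <- colSums(Biostrings::alphabetFrequency(gs)[, c("A", "C", "G", "T"), drop = FALSE])
  acgt <- sum(freq)
  if (acgt == 0) abort("Genome contains no A/C/G/T bases.")
  tibble(
    species_id = species_id,
    total_cpg = sum(count_cpg(as.character(gs))),
    genome_length = sum(Biostrings::width(gs)),
    gc_content = unname((freq["G"] + freq["C"]) / acgt)
  )
}

#' CpG density profile around transcription start sites
#'
#' For every annotated gene the 5 kb upstream and downstream of its TSS is
#' divided into fixed-width bins (20 bins of 500 bp by default), ordered 5'
#' to 3' relative to the gene — so for minus-strand genes the genomic bin
#' order is mirrored. Per-bin density is CpG count / bin width; bins
#' truncated by a contig edge are dropped for that TSS; the profile is the
#' mean over all usable TSSs.
#'
#' @param genome Genome as in [extract_hit_sequence()].
#' @param annotations GFF3 path, a `GRanges`, or a data frame with columns
#'   `contig`, `start`, `end` (1-based inclusive), `strand`. Feature types
#'   "gene" and "mRNA" are used when a `type` column is present.
#' @param flank Flank size on each side of the TSS, in bases. Default 5000.
#' @param bin Bin width in bases. Default 500.
#' @param species_id Optional label.
#' @return A tibble with one row per bin: `species_id`, `bin` (index, 5'->3'),
#'   `offset_start` (bin start offset from the TSS on the gene's own strand),
#'   `density` (mean CpG density), `n_tss` (TSSs contributing to the bin).
#' @export
tss_flank_profile <- function(genome, annotations, flank = 5000, bin = 500,
                              species_id = NA_character_) {
  stopifnot(flank %% bin == 0)
  gs <- as_genome(genome)
  ann <- as_annotation_table(annotations)
  if (nrow(ann) == 0L) abort("No usable gene/mRNA features with strand in annotations.")
  n_bins <- 2L * flank %/% bin
  acc_sum <- numeric(n_bins); acc_n <- integer(n_bins)
  for (k in seq_len(nrow(ann))) {
    contig <- ann$contig[k]
    if (!contig %in% names(gs)) next
    clen <- Biostrings::width(gs[contig])
    # 0-based TSS position: gene start for "+", gene end for "-"
    tss0 <- if (ann$strand[k] == "+") ann$start[k] - 1L else ann$end[k] - 1L
    for (j in seq_len(n_bins)) {
      if (ann$strand[k] == "+") {
        b0 <- tss0 - flank + (j - 1L) * bin
      } else {
        b0 <- tss0 + flank - j * bin
      }
      b1 <- b0 + bin
      if (b0 < 0 || b1 > clen) next   # truncated bin: drop for this TSS
      acc_sum[j] <- acc_sum[j] + count_cpg(slice_contig(gs, contig, b0, b1)) / bin
      acc_n[j] <- acc_n[j] + 1L
    }
  }
  if (all(acc_n == 0L)) abort("No TSS contributed any complete bin.")
  offsets <- seq(-flank, flank - bin, by = bin)
  tibble(
    species_id = species_id,
    bin = seq_len(n_bins),
    offset_start = offsets,
    density = ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), NA_real_),
    n_tss = acc_n
  )
}

as_annotation_table <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- rtracklayer::import(annotations)
  }
  if (inherits(annotations, "GRanges")) {
    keep <- rep(TRUE, length(annotations))
    if ("type" %in% names(GenomicRanges::mcols(annotations))) {
      keep <- as.character(annotations$type) %in% c("gene", "mRNA")
    }
    g <- annotations[keep]
    ann <- tibble(
      contig = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g))
    )
  } else {
    ann <- as_tibble(annotations)
    if ("type" %in% names(ann)) ann <- filter(ann, .data$type %in% c("gene", "mRNA"))
  }
  filter(ann, .data$strand %in% c("+", "-"))
}

#' Compare two CpG density profiles with a Kolmogorov-Smirnov test
#'
#' Two-sample KS test on the per-bin density values of two TSS-flank profiles
#' (or any two raw density vectors).
#'
#' @param a,b Profile tibbles from [tss_flank_profile()] or numeric vectors.
#' @return One-row tibble: `ks_statistic`, `p_value`.
#' @export
compare_profiles_ks <- function(a, b) {
  va <- if (is.data.frame(a)) a$density else as.numeric(a)
  vb <- if (is.data.frame(b)) b$density else as.numeric(b)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2L || length(vb) < 2L) {
    abort("Each profile needs at least 2 density values for a KS test.")
  }
  kt <- suppressWarnings(stats::ks.test(va, vb))
  tibble(ks_statistic = unname(kt$statistic), p_value = kt$p.value)
}
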