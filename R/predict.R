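#' Evaluate the clock's calibration formula
#'
#' The closed-form second stage: `ln(maximum lifespan) = intercept + slope*x
#' + a*x + b`, with `(a, b)` looked up by vertebrate class (0, 0 for classes
#' without coefficients; an unknown class triggers a warning).
#'
#' @param model A `lifespan_clock`.
#' @param x Raw score(s) from [raw_score()].
#' @param vertebrate_class Class label (scalar).
#' @return Predicted natural-log maximum lifespan(s).
#' @examples
#' clock <- published_clock()
#' predict_ln_lifespan(clock, x = 2, vertebrate_class = "Mammalia")
#' @export
predict_ln_lifespan <- function(model, x, vertebrate_class) {
  stopifnot(inherits(model, "lifespan_clock"))
  known <- names(model$class_coefficients)
  if (!vertebrate_class %in% known && length(known) > 0L &&
      !vertebrate_class %in% c("Amphibia")) {
    warn(sprintf("Class '%s' has no calibration coefficients; using a = b = 0.",
                 vertebrate_class))
  }
  ab <- class_ab(model, vertebrate_class)
  model$global_intercept + model$global_slope * x + ab[["a"]] * x + ab[["b"]]
}

#' Predict maximum lifespan from a promoter density vector
#'
#' Composes [raw_score()] and [predict_ln_lifespan()]; lifespans in years are
#' `exp(ln_lifespan)`.
#'
#' @param model A `lifespan_clock`.
#' @param densities One or more density rows (tibble, named vector or matrix).
#' @param vertebrate_class Class label applied to all rows.
#' @return A tibble with one row per input row: `species_id` (when known),
#'   `vertebrate_class`, `raw_score`, `ln_lifespan`, `lifespan_years`.
#' @export
predict_lifespan <- function(model, densities, vertebrate_class) {
  x <- raw_score(model, densities)
  lnl <- predict_ln_lifespan(model, x, vertebrate_class)
  tibble(
    species_id = if (is.null(names(x))) NA_character_ else names(x),
    vertebrate_class = vertebrate_class,
    raw_score = unname(x),
    ln_lifespan = unname(lnl),
    lifespan_years = exp(unname(lnl))
  )
}

#' Read biallelic SNPs from a VCF
#'
#' Loads a VCF (v4.x) and returns the PASS (or unfiltered) biallelic SNP
#' records; indels and multiallelic records are dropped with a message giving
#' the count.
#'
#' @param path VCF path (plain text).
#' @return Tibble: `contig`, `pos` (1-based), `ref`, `alt`.
#' @export
read_vcf_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(contig = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  filt <- fix$FILTER
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  skipped <- sum(!(pass & snp), na.rm = TRUE)
  if (skipped > 0L) {
    message(sprintf("Skipped %d non-PASS, indel or multiallelic record(s).", skipped))
  }
  keep <- which(pass & snp)
  tibble(
    contig = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = toupper(fix$REF[keep]),
    alt = toupper(fix$ALT[keep])
  )
}

#' Apply SNPs to a reference locus sequence
#'
#' Substitutes ALT bases into a reference locus for every biallelic SNP whose
#' (1-based) position falls inside the locus interval, yielding the
#' consensus-style sequence whose CpG content may differ from the reference
#' (SNPs can create or destroy CpG sites). The REF allele must match the
#' reference sequence at each position; a mismatch aborts, since it almost
#' always means the VCF was called against a different genome build.
#'
#' @param reference_locus_seq Reference sequence of the locus (the slice
#'   `[start, end)` of the contig).
#' @param locus A list/one-row tibble with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param variants SNP tibble from [read_vcf_snps()].
#' @return The edited sequence (same length).
#' @export
apply_snps <- function(reference_locus_seq, locus, variants) {
  seq <- reference_locus_seq
  start <- locus$start[[1]]; end <- locus$end[[1]]; contig <- locus$contig[[1]]
  stopifnot(nchar(seq) == end - start)
  if (nrow(variants) == 0L) return(seq)
  v <- variants |>
    filter(.data$contig == !!contig, .data$pos >= start + 1L, .data$pos <= end)
  if (nrow(v) == 0L) return(seq)
  chars <- strsplit(toupper(seq), NULL)[[1]]
  idx <- v$pos - start           # 1-based index into the locus slice
  ref_here <- chars[idx]
  bad <- ref_here != v$ref
  if (any(bad)) {
    abort(sprintf(
      "REF allele mismatch at %s:%d (VCF says %s, reference has %s); check the genome build.",
      contig, v$pos[which(bad)[1]], v$ref[which(bad)[1]], ref_here[which(bad)[1]]))
  }
  chars[idx] <- v$alt
  paste(chars, collapse = "")
}

#' Read a BED file of lifespan loci
#'
#' Four-column BED (contig, start, end, name) with 0-based half-open
#' intervals; the name column carries the promoter id.
#'
#' @param path BED path.
#' @return Tibble: `promoter_id`, `contig`, `start`, `end`.
#' @export
read_loci_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  tibble(
    promoter_id = if (!is.null(g$name)) g$name else paste0("locus", seq_along(g)),
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g)
  )
}

#' Estimate the lifespan of an extinct species from called variants
#'
#' The ancient-genome path: per lifespan locus, the reference sequence is
#' sliced, the species' SNPs are substituted in, and CpG density is
#' recomputed with the locus interval length as denominator (no alignment
#' exists on this path, so densities stay comparable with reference-interval
#' densities). The edited densities are then scored with the clock. Clock
#' promoters missing from the locus set get density 0, with a warning.
#'
#' @param model A `lifespan_clock`.
#' @param reference_genome Reference genome (as in [extract_hit_sequence()]).
#' @param loci Locus tibble from [read_loci_bed()] (or same columns).
#' @param variants VCF path or SNP tibble from [read_vcf_snps()].
#' @param vertebrate_class Class label of the query species.
#' @param species_id Optional label for the prediction row.
#' @return One-row prediction tibble as in [predict_lifespan()].
#' @export
predict_ancient <- function(model, reference_genome, loci, variants,
                            vertebrate_class, species_id = "ancient") {
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_vcf_snps(variants)
  }
  loci <- as_tibble(loci)
  gs <- as_genome(reference_genome)
  dens <- vapply(seq_len(nrow(loci)), function(k) {
    l <- loci[k, ]
    ref_seq <- slice_contig(gs, l$contig, l$start, l$end)
    edited <- apply_snps(ref_seq, l, variants)
    count_cpg(edited) / (l$end - l$start)
  }, numeric(1))
  names(dens) <- loci$promoter_id
  missing_p <- setdiff(names(model$promoter_weights), loci$promoter_id)
  if (length(missing_p) > 0L) {
    warn(sprintf("%d clock promoter(s) absent from the locus set; density 0 used: %s.",
                 length(missing_p), paste(utils::head(missing_p, 5), collapse = ", ")))
  }
  pred <- predict_lifespan(model, dens, vertebrate_class)
  pred$species_id <- species_id
  pred
}
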