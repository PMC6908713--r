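# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Independent brute-force CpG oracle: explicit position scan.
oracle_count_cpg <- function(seq) {
  chars <- strsplit(toupper(seq), NULL)[[1]]
  n <- length(chars)
  if (n < 2) return(0L)
  sum(chars[-n] == "C" & chars[-1] == "G")
}

oracle_revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, NULL)[[1]]), collapse = ""))
}

# A one-row hit tibble with overridable fields.
make_hit <- function(...) {
  defaults <- list(promoter_id = "p1", species_id = "s1", contig = "chr1",
                   start = 0L, end = 10L, strand = "+",
                   percent_identity = 90, alignment_length = 10L,
                   bitscore = 100, evalue = 1e-10)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

# Random hit table for property tests.
random_hit_table <- function(n, n_species = 3, n_promoters = 4) {
  tibble::tibble(
    promoter_id = sample(paste0("p", seq_len(n_promoters)), n, replace = TRUE),
    species_id = sample(paste0("s", seq_len(n_species)), n, replace = TRUE),
    contig = "chr1",
    start = 0L, end = 100L, strand = "+",
    percent_identity = stats::runif(n, 50, 100),
    alignment_length = 100L,
    bitscore = stats::runif(n, 50, 500),
    evalue = 10^stats::runif(n, -50, -1)
  )
}

# Small trained-clock fixture on a synthetic panel.
small_panel <- function(n_species = 60, seed = 11) {
  cfg <- simulation_config(n_species = n_species, n_causal_promoters = 10,
                           n_null_promoters = 30, seed = seed)
  simulate_panel(cfg)
}

published_constants <- list(
  intercept = -4.38996, slope = 2.57328,
  ab = list(
    Aves = c(a = -0.90323, b = 2.14857),
    Fish = c(a = 2.14632, b = -6.58228),
    Mammalia = c(a = -0.92888, b = 2.33508),
    Reptilia = c(a = -0.48958, b = 1.17281)
  )
)
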