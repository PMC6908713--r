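#' Configuration for the synthetic species panel
#'
#' Defaults describe the study conditions the pipeline is validated under: a
#' 250-species vertebrate panel with the five classes in roughly the
#' proportions of real reference-genome collections (mammals most
#' represented, amphibians sparse), lifespans spanning 1.1 to 205 years (the
#' range of published vertebrate records), ln lifespan evolving by Brownian
#' motion on a 500-My-deep tree with classes confounded with clades, and 40
#' causal promoters among 500 whose CpG density is linearly coupled to ln
#' lifespan with noise — planted with both positive and negative slopes in
#' roughly the 22:12 ratio observed among significant promoters.
#'
#' @param n_species Number of species.
#' @param class_proportions Named fractions per vertebrate class (sum to 1).
#' @param n_causal_promoters,n_null_promoters Promoters with and without a
#'   planted lifespan signal.
#' @param effect_slope Mean |slope| of causal promoters, in density units per
#'   ln-year.
#' @param density_noise_sd Density noise standard deviation.
#' @param lifespan_range Attainable lifespans in years, `c(min, max)`.
#' @param brownian_sd Brownian-motion rate for ln lifespan, per sqrt(My).
#' @param genome_length Minimum genome length per species, bases.
#' @param promoter_length Promoter window length, bases (600, the span of the
#'   standard -499..+100 TSS window).
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 250,
                              class_proportions = c(Mammalia = 0.40, Aves = 0.24,
                                                    Fish = 0.24, Reptilia = 0.08,
                                                    Amphibia = 0.04),
                              n_causal_promoters = 40,
                              n_null_promoters = 460,
                              effect_slope = 0.02,
                              density_noise_sd = 0.02,
                              lifespan_range = c(1.1, 205),
                              brownian_sd = 0.05,
                              genome_length = 10000,
                              promoter_length = 600,
                              seed = 1) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            n_species >= 2, n_causal_promoters >= 0, n_null_promoters >= 0,
            lifespan_range[1] > 0, lifespan_range[2] > lifespan_range[1],
            promoter_length >= 20)
  structure(
    list(n_species = n_species, class_proportions = class_proportions,
         n_causal_promoters = n_causal_promoters,
         n_null_promoters = n_null_promoters, effect_slope = effect_slope,
         density_noise_sd = density_noise_sd, lifespan_range = lifespan_range,
         brownian_sd = brownian_sd, genome_length = genome_length,
         promoter_length = promoter_length, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree rescaled to a root-to-tip depth of 500 My, with
#' leaves labelled `sp0001`, `sp0002`, ... Deterministic given the seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] tree.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 2) abort("A tree needs at least 2 species.")
  tree <- withr::with_seed(seed, ape::rphylo(n_species, birth = 0.1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_species)])
  tree$edge.length <- tree$edge.length * 500 / depth
  tree$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tree
}

# Tips in the tree's cladewise plotting order, so contiguous blocks of this
# ordering are (unions of) clades.
tips_cladewise <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  e2 <- tree$edge[, 2]
  tree$tip.label[e2[e2 <= length(tree$tip.label)]]
}

#' Simulate lifespans and class labels on a tree
#'
#' Ln maximum lifespan evolves by Brownian motion around class-specific
#' means and is then min-max rescaled into `log(lifespan_range)`. Classes
#' are assigned to contiguous clades of the tree (not at random), so class
#' and phylogeny are confounded as they are in real vertebrate panels. A
#' lifespan-record source (captivity/wild/unknown) is drawn per species in
#' the proportions of published lifespan databases (roughly 60/33/7).
#'
#' @param tree Ultrametric tree from [simulate_tree()].
#' @param config A [simulation_config()].
#' @return A species tibble: `species_id`, `vertebrate_class`,
#'   `max_lifespan` (years), `source`.
#' @export
simulate_lifespans <- function(tree, config = simulation_config()) {
  n <- length(tree$tip.label)
  props <- config$class_proportions
  sizes <- round(props * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  if (any(sizes < 0)) abort("Class proportions produce a negative class size.")
  ord <- tips_cladewise(tree)
  cls <- stats::setNames(rep(names(props), times = sizes), ord)

  vv <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  class_means <- stats::setNames(
    seq(-1, 1, length.out = length(props)) * 1.2, names(props))
  z <- withr::with_seed(config$seed + 1L, {
    bm <- if (config$brownian_sd > 0) {
      MASS::mvrnorm(1, mu = rep(0, n), Sigma = config$brownian_sd^2 * vv)
    } else rep(0, n)
    class_means[cls[tree$tip.label]] + bm
  })
  ln_rng <- log(config$lifespan_range)
  z_rng <- range(z)
  ln_l <- if (diff(z_rng) == 0) {
    rep(mean(ln_rng), n)
  } else {
    ln_rng[1] + (z - z_rng[1]) * diff(ln_rng) / diff(z_rng)
  }
  source <- withr::with_seed(config$seed + 2L,
    sample(c("captivity", "wild", "unknown"), n, replace = TRUE,
           prob = c(0.60, 0.33, 0.07)))
  tibble(
    species_id = tree$tip.label,
    vertebrate_class = unname(cls[tree$tip.label]),
    max_lifespan = exp(unname(ln_l)),
    source = source
  )
}

#' Simulate a density matrix with a planted lifespan signal
#'
#' Causal promoters get density `clip(base_k + slope_k * ln(years) + noise,
#' 0, 0.4)` with per-promoter base levels and signed slopes (positive and
#' negative slopes in roughly a 22:12 ratio); null promoters are base level
#' plus noise. The 0.4 cap keeps densities realizable as sequences with
#' non-adjacent CpGs.
#'
#' @param species Species tibble from [simulate_lifespans()].
#' @param config A [simulation_config()].
#' @return A list: `densities` (density tibble), `truth` (list with
#'   `causal_ids`, `planted_weights` — the slopes used —, `base_levels`,
#'   `lifespans`).
#' @export
simulate_density_matrix <- function(species, config = simulation_config()) {
  n <- nrow(species)
  ln_l <- log(species$max_lifespan)
  n_c <- config$n_causal_promoters; n_0 <- config$n_null_promoters
  causal_ids <- if (n_c > 0) sprintf("prom_c%03d", seq_len(n_c)) else character()
  null_ids <- if (n_0 > 0) sprintf("prom_n%03d", seq_len(n_0)) else character()
  out <- withr::with_seed(config$seed + 3L, {
    sign_k <- sample(c(1, -1), n_c, replace = TRUE, prob = c(22, 12) / 34)
    slope_k <- sign_k * config$effect_slope * stats::runif(n_c, 0.5, 1.5)
    base_k <- ifelse(sign_k > 0, stats::runif(n_c, 0.05, 0.20),
                     stats::runif(n_c, 0.20, 0.35))
    m_c <- vapply(seq_len(n_c), function(k) {
      pmin(pmax(base_k[k] + slope_k[k] * ln_l +
                  stats::rnorm(n, 0, config$density_noise_sd), 0), 0.4)
    }, numeric(n))
    base_0 <- stats::runif(n_0, 0.05, 0.30)
    m_0 <- vapply(seq_len(n_0), function(k) {
      pmin(pmax(base_0[k] + stats::rnorm(n, 0, config$density_noise_sd), 0), 0.4)
    }, numeric(n))
    list(m = cbind(m_c, m_0), slope_k = slope_k, base_k = base_k)
  })
  m <- matrix(out$m, nrow = n,
              dimnames = list(species$species_id, c(causal_ids, null_ids)))
  list(
    densities = density_tibble(m),
    truth = list(
      causal_ids = causal_ids,
      planted_weights = stats::setNames(out$slope_k, causal_ids),
      base_levels = stats::setNames(out$base_k, causal_ids),
      lifespans = stats::setNames(species$max_lifespan, species$species_id)
    )
  )
}

# A random sequence over {A,C,G,T} of length n containing no CG dinucleotide
# (any G following a C is replaced by A in one left-to-right pass).
random_noncpg_chars <- function(n) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cg <- which(chars[-n] == "C" & chars[-1] == "G")
  while (length(cg) > 0) {
    chars[cg + 1L] <- "A"
    cg <- which(chars[-n] == "C" & chars[-1] == "G")
  }
  chars
}

# One promoter sequence of length len with exactly n_cpg CpGs at random
# non-adjacent positions and CpG-free filler elsewhere.
realize_promoter <- function(len, n_cpg) {
  if (n_cpg > len / 2) {
    abort(sprintf("Cannot place %d non-adjacent CpGs in %d bases.", n_cpg, len))
  }
  chars <- random_noncpg_chars(len)
  if (n_cpg > 0) {
    starts <- sort(sample(seq(1L, len - 1L, by = 2L), n_cpg))
    chars[starts] <- "C"; chars[starts + 1L] <- "G"
    # a planted C preceded by a filler C is fine (CC), a planted G followed
    # by anything is fine (G_), so no new scan is needed
  }
  paste(chars, collapse = "")
}

#' Realize a density matrix as genome sequences and fixtures
#'
#' Turns a density matrix into concrete files/objects the homology and
#' density modules can consume: per species, each promoter becomes a
#' `promoter_length`-base sequence carrying exactly `round(d * length)` CpG
#' dinucleotides at random non-adjacent positions with CpG-free filler, the
#' promoters are embedded in a single-contig genome in random order with
#' CpG-free spacers, and a matching perfect hit table (identity 100) and
#' locus table are emitted. Recomputing densities from these outputs
#' reproduces the input matrix within the 1/`promoter_length` quantization.
#'
#' @param densities Density tibble (entries must be in \[0, 0.4\]).
#' @param config A [simulation_config()] (promoter_length, genome_length,
#'   seed).
#' @param out_dir Optional directory; when given, writes
#'   `genomes/<species>.fa`, `promoters.fa` (the first species' promoter
#'   sequences, usable as homology queries), `hits.tsv` (combined hit table)
#'   and `loci_<species>.bed`.
#' @return A list: `genomes` (named list of single-contig `DNAStringSet`),
#'   `promoter_queries` (named character, first species' promoter
#'   sequences), `hits` (hit tibble), `loci` (tibble with `species_id`,
#'   `promoter_id`, `contig`, `start`, `end`).
#' @export
realize_sequences <- function(densities, config = simulation_config(),
                              out_dir = NULL) {
  m <- density_values(densities)
  if (any(m < 0 | m > 0.4)) abort("Densities must lie in [0, 0.4] to be realizable.")
  len <- config$promoter_length
  withr::with_seed(config$seed + 4L, {
    genomes <- list(); hit_rows <- list(); loci_rows <- list()
    queries <- NULL
    for (sp in rownames(m)) {
      order_p <- sample(colnames(m))
      pieces <- character(); pos <- 0L
      sp_loci <- vector("list", length(order_p))
      sp_seqs <- stats::setNames(character(length(order_p)), order_p)
      for (i in seq_along(order_p)) {
        p <- order_p[i]
        spacer <- paste(random_noncpg_chars(100L + sample.int(100L, 1L)),
                        collapse = "")
        prom <- realize_promoter(len, round(m[sp, p] * len))
        sp_seqs[p] <- prom
        start <- pos + nchar(spacer)
        sp_loci[[i]] <- tibble(species_id = sp, promoter_id = p,
                               contig = "chr1", start = start,
                               end = start + len)
        pieces <- c(pieces, spacer, prom)
        pos <- start + len
      }
      tail_pad <- max(100L, config$genome_length - pos)
      pieces <- c(pieces, paste(random_noncpg_chars(tail_pad), collapse = ""))
      genomes[[sp]] <- Biostrings::DNAStringSet(
        stats::setNames(paste(pieces, collapse = ""), "chr1"))
      loci_sp <- bind_rows(sp_loci)
      loci_rows[[sp]] <- loci_sp
      hit_rows[[sp]] <- tibble(
        promoter_id = loci_sp$promoter_id, species_id = sp, contig = "chr1",
        start = loci_sp$start, end = loci_sp$end, strand = "+",
        percent_identity = 100, alignment_length = len,
        bitscore = 2 * len, evalue = 0
      )
      if (is.null(queries)) queries <- sp_seqs[colnames(m)]
    }
    hits <- bind_rows(hit_rows)
    loci <- bind_rows(loci_rows)
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
                 showWarnings = FALSE)
      for (sp in names(genomes)) {
        Biostrings::writeXStringSet(genomes[[sp]],
                                    file.path(out_dir, "genomes", paste0(sp, ".fa")))
        loci_sp <- loci[loci$species_id == sp, ]
        readr::write_tsv(
          tibble(contig = loci_sp$contig, start = loci_sp$start,
                 end = loci_sp$end, name = loci_sp$promoter_id),
          file.path(out_dir, paste0("loci_", sp, ".bed")), col_names = FALSE)
      }
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(queries),
        file.path(out_dir, "promoters.fa"))
      write_hit_table(hits, file.path(out_dir, "hits.tsv"))
    }
    list(genomes = genomes, promoter_queries = queries, hits = hits, loci = loci)
  })
}

#' Plant CpG-breaking and CpG-creating SNPs in lifespan loci
#'
#' Generates a VCF of biallelic SNPs inside the given loci of a reference
#' genome: `n_cpg_breaking` variants each destroy exactly one CpG (the C of
#' a CpG mutated to T) and `n_cpg_creating` each create exactly one (a base
#' after a lone C mutated to G). Chosen positions are pairwise at least 2
#' bases apart so edits never interact.
#'
#' @param genome Reference genome (as in [extract_hit_sequence()]).
#' @param loci Locus tibble (`contig`, `start`, `end`, 0-based half-open).
#' @param n_cpg_breaking,n_cpg_creating Numbers of planted variants.
#' @param seed Integer seed.
#' @param out_path Optional path; when given, a VCF v4.2 file is written.
#' @return SNP tibble (`contig`, `pos` 1-based, `ref`, `alt`) with a
#'   `planted` column ("break"/"create"), invisibly writing `out_path` if
#'   requested.
#' @export
simulate_ancient_variants <- function(genome, loci, n_cpg_breaking,
                                      n_cpg_creating, seed = 1,
                                      out_path = NULL) {
  gs <- as_genome(genome)
  loci <- as_tibble(loci)
  break_cand <- list(); create_cand <- list()
  for (k in seq_len(nrow(loci))) {
    l <- loci[k, ]
    chars <- strsplit(toupper(slice_contig(gs, l$contig, l$start, l$end)), NULL)[[1]]
    w <- length(chars)
    is_c <- chars == "C"; is_g <- chars == "G"
    cg <- which(is_c[-w] & is_g[-1])                      # CpG start, local 1-based
    break_cand[[k]] <- if (length(cg)) {
      tibble(contig = l$contig, pos = l$start + cg, ref = "C", alt = "T")
    }
    # lone C at i, successor not G, and successor not itself the C of a CpG
    cr <- which(is_c[-w] & !is_g[-1])
    succ <- cr + 1L
    nxt2 <- ifelse(succ + 1L <= w, chars[pmin(succ + 1L, w)], "")
    ok <- chars[succ] %in% c("A", "C", "T") & !(chars[succ] == "C" & nxt2 == "G")
    cr <- cr[ok]
    create_cand[[k]] <- if (length(cr)) {
      tibble(contig = l$contig, pos = l$start + cr + 1L,
             ref = chars[cr + 1L], alt = "G")
    }
  }
  break_cand <- bind_rows(break_cand); create_cand <- bind_rows(create_cand)
  variants <- withr::with_seed(seed, {
    chosen <- tibble(); taken <- integer()
    pick <- function(cand, n_want, label) {
      if (nrow(cand) < n_want) {
        abort(sprintf("Requested %d CpG-%s SNPs but only %d candidate site(s) exist.",
                      n_want, label, nrow(cand)))
      }
      cand <- cand[sample.int(nrow(cand)), ]
      out <- list(); i <- 1
      while (length(out) < n_want && i <= nrow(cand)) {
        if (!any(abs(taken - cand$pos[i]) < 2)) {
          out[[length(out) + 1]] <- cand[i, ]
          taken <<- c(taken, cand$pos[i])
        }
        i <- i + 1
      }
      if (length(out) < n_want) {
        abort(sprintf(
          "Only %d non-interacting CpG-%s site(s) available (%d requested).",
          length(out), label, n_want))
      }
      bind_rows(out)
    }
    br <- if (n_cpg_breaking > 0) {
      mutate(pick(break_cand, n_cpg_breaking, "breaking"), planted = "break")
    }
    cr <- if (n_cpg_creating > 0) {
      mutate(pick(create_cand, n_cpg_creating, "creating"), planted = "create")
    }
    bind_rows(br, cr)
  })
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- tibble(contig = character(), pos = integer(),
                       ref = character(), alt = character(),
                       planted = character())
  }
  variants <- arrange(variants, .data$contig, .data$pos)
  if (!is.null(out_path)) write_vcf(variants, out_path)
  variants
}

#' Write a minimal VCF v4.2 file of biallelic SNPs
#'
#' @param variants SNP tibble (`contig`, `pos` 1-based, `ref`, `alt`).
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cpgclock_simulate",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            variants$contig, variants$pos, variants$ref, variants$alt)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a complete synthetic species panel
#'
#' One-call generator of the study conditions: tree, class labels, lifespans,
#' density matrix with planted signal, and the Brownian covariance, all
#' reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return A list: `tree`, `species` (tibble), `densities` (tibble),
#'   `truth`, `covariance` (Brownian covariance matrix), `divergence`
#'   (pairwise divergence times, My).
#' @export
simulate_panel <- function(config = simulation_config()) {
  tree <- simulate_tree(config$n_species, config$seed)
  species <- simulate_lifespans(tree, config)
  dm <- simulate_density_matrix(species, config)
  vv <- ape::vcv.phylo(tree)
  list(
    tree = tree,
    species = species,
    densities = dm$densities,
    truth = dm$truth,
    covariance = vv,
    divergence = stats::cophenetic(tree) / 2
  )
}
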