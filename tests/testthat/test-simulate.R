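test_that("simulated trees are ultrametric, scaled to depth 500 and seed-stable", {
  tr2 <- simulate_tree(2, seed = 9)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths, c(500, 500))

  tr <- simulate_tree(25, seed = 9)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_equal(max(ape::node.depth.edgelength(tr)[1:25]), 500)
  expect_equal(sort(tr$tip.label), sprintf("sp%04d", 1:25))

  expect_identical(ape::write.tree(simulate_tree(25, seed = 9)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(25, seed = 10)),
                         ape::write.tree(tr)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("lifespans respect the range, class structure and Brownian signal", {
  cfg <- simulation_config(n_species = 60, seed = 13)
  tr <- simulate_tree(60, cfg$seed)
  sp <- simulate_lifespans(tr, cfg)
  expect_equal(nrow(sp), 60L)
  expect_true(all(sp$max_lifespan >= cfg$lifespan_range[1] - 1e-9))
  expect_true(all(sp$max_lifespan <= cfg$lifespan_range[2] + 1e-9))
  expect_setequal(unique(sp$vertebrate_class),
                  names(cfg$class_proportions)[table(sp$vertebrate_class)[
                    names(cfg$class_proportions)] > 0])

  # zero Brownian rate: one lifespan per class
  cfg0 <- simulation_config(n_species = 40, brownian_sd = 0, seed = 14)
  sp0 <- simulate_lifespans(simulate_tree(40, cfg0$seed), cfg0)
  per_class <- tapply(sp0$max_lifespan, sp0$vertebrate_class,
                      function(v) diff(range(v)))
  expect_true(all(per_class < 1e-9))
})

test_that("sister taxa have more similar lifespans than random pairs", {
  diffs <- sapply(1:30, function(s) {
    cfg <- simulation_config(n_species = 40, seed = s)
    tr <- simulate_tree(40, s)
    sp <- simulate_lifespans(tr, cfg)
    lnl <- stats::setNames(log(sp$max_lifespan), sp$species_id)
    # sister pairs: cherries of the tree
    is_tip <- tr$edge[, 2] <= 40
    parents <- tr$edge[is_tip, 1]
    cherries <- names(which(table(parents) == 2))
    sis <- sapply(cherries, function(p) {
      tips <- tr$tip.label[tr$edge[tr$edge[, 1] == as.integer(p) &
                                     tr$edge[, 2] <= 40, 2]]
      abs(diff(lnl[tips]))
    })
    rand <- replicate(50, abs(diff(sample(lnl, 2))))
    mean(sis) - mean(rand)
  })
  expect_lt(mean(diffs), 0)
})

test_that("planted densities are affine in ln lifespan when noiseless", {
  cfg <- simulation_config(n_species = 30, n_causal_promoters = 5,
                           n_null_promoters = 5, density_noise_sd = 0, seed = 15)
  panel <- simulate_panel(cfg)
  lnl <- log(panel$species$max_lifespan)
  for (p in panel$truth$causal_ids) {
    r <- stats::cor(panel$densities[[p]], lnl)
    expect_equal(abs(r), 1, tolerance = 1e-9)
    expect_equal(sign(r), sign(panel$truth$planted_weights[[p]]))
  }
})

test_that("densities are clipped to [0, 0.4] and truth is recorded", {
  cfg <- simulation_config(n_species = 50, n_causal_promoters = 8,
                           n_null_promoters = 12, density_noise_sd = 0.2,
                           seed = 16)
  panel <- simulate_panel(cfg)
  vals <- as.matrix(panel$densities[-1])
  expect_true(all(vals >= 0 & vals <= 0.4))
  expect_true(all(panel$truth$causal_ids %in% colnames(vals)))
  expect_length(panel$truth$planted_weights, 8)
  expect_equal(names(panel$truth$lifespans), panel$species$species_id)
})

test_that("realized sequences reproduce the density matrix within quantization", {
  cfg <- simulation_config(n_species = 6, n_causal_promoters = 4,
                           n_null_promoters = 6, seed = 17)
  panel <- simulate_panel(cfg)
  real <- realize_sequences(panel$densities, cfg)
  prom_ids <- setdiff(names(panel$densities), "species_id")
  dm <- build_density_matrix(real$genomes, real$hits, prom_ids,
                             species_ids = panel$species$species_id)
  orig <- as.matrix(panel$densities[-1])
  back <- as.matrix(dm[-1])
  expect_lt(max(abs(orig - back)), 1 / cfg$promoter_length)

  # zero density realizes with zero CpGs
  zero_dm <- dplyr::bind_cols(tibble::tibble(species_id = "z"),
                              tibble::as_tibble(matrix(0, 1, 2,
                                dimnames = list(NULL, c("pa", "pb")))))
  rz <- realize_sequences(zero_dm, simulation_config(n_species = 2, seed = 18))
  expect_equal(count_cpg(as.character(rz$genomes[["z"]][[1]])), 0L)

  # out-of-range densities are rejected
  bad <- zero_dm; bad$pa <- 0.45
  expect_error(realize_sequences(bad, cfg), "0.4")
})

test_that("sequence realization is byte-identical given the seed", {
  cfg <- simulation_config(n_species = 3, n_causal_promoters = 2,
                           n_null_promoters = 3, seed = 19)
  panel <- simulate_panel(cfg)
  r1 <- realize_sequences(panel$densities, cfg)
  r2 <- realize_sequences(panel$densities, cfg)
  expect_identical(lapply(r1$genomes, as.character),
                   lapply(r2$genomes, as.character))
  expect_identical(r1$hits, r2$hits)
})

test_that("realization writes readable FASTA, BED and hit files", {
  cfg <- simulation_config(n_species = 2, n_causal_promoters = 2,
                           n_null_promoters = 2, seed = 20)
  panel <- simulate_panel(cfg)
  out <- withr::local_tempdir()
  real <- realize_sequences(panel$densities, cfg, out_dir = out)
  sp1 <- panel$species$species_id[1]
  fa <- file.path(out, "genomes", paste0(sp1, ".fa"))
  expect_true(file.exists(fa))
  expect_equal(as.character(Biostrings::readDNAStringSet(fa)[[1]]),
               as.character(real$genomes[[sp1]][[1]]))
  loci <- read_loci_bed(file.path(out, paste0("loci_", sp1, ".bed")))
  expect_setequal(loci$promoter_id, setdiff(names(panel$densities), "species_id"))
  hits <- read_hit_table(file.path(out, "hits.tsv"))
  expect_equal(nrow(hits), 2 * 4)
  expect_true(file.exists(file.path(out, "promoters.fa")))

  # the emitted loci point at the embedded promoter copies
  l1 <- dplyr::filter(real$loci, species_id == sp1)
  for (k in seq_len(nrow(l1))) {
    seq_k <- cpgclock:::slice_contig(real$genomes[[sp1]], l1$contig[k],
                                     l1$start[k], l1$end[k])
    expect_equal(count_cpg(seq_k),
                 round(panel$densities[[l1$promoter_id[k]]][
                   panel$densities$species_id == sp1] * cfg$promoter_length))
  }
})

test_that("planted ancient variants change CpG counts by exactly one each", {
  cfg <- simulation_config(n_species = 2, n_causal_promoters = 2,
                           n_null_promoters = 2, seed = 23)
  panel <- simulate_panel(cfg)
  real <- realize_sequences(panel$densities, cfg)
  sp1 <- panel$species$species_id[1]
  loci <- dplyr::filter(real$loci, species_id == sp1)
  genome <- real$genomes[[sp1]]

  v <- simulate_ancient_variants(genome, loci, n_cpg_breaking = 3,
                                 n_cpg_creating = 3, seed = 24)
  expect_equal(nrow(v), 6L)
  for (k in seq_len(nrow(v))) {
    before <- sum(vapply(seq_len(nrow(loci)), function(j) {
      count_cpg(cpgclock:::slice_contig(genome, loci$contig[j],
                                        loci$start[j], loci$end[j]))
    }, numeric(1)))
    after <- sum(vapply(seq_len(nrow(loci)), function(j) {
      s <- cpgclock:::slice_contig(genome, loci$contig[j], loci$start[j],
                                   loci$end[j])
      count_cpg(apply_snps(s, loci[j, ], v[k, 1:4]))
    }, numeric(1)))
    expect_equal(after - before, ifelse(v$planted[k] == "break", -1, 1))
  }

  # equal break/create counts leave the total unchanged
  after_all <- sum(vapply(seq_len(nrow(loci)), function(j) {
    s <- cpgclock:::slice_contig(genome, loci$contig[j], loci$start[j],
                                 loci$end[j])
    count_cpg(apply_snps(s, loci[j, ], v[, 1:4]))
  }, numeric(1)))
  before_all <- sum(vapply(seq_len(nrow(loci)), function(j) {
    count_cpg(cpgclock:::slice_contig(genome, loci$contig[j], loci$start[j],
                                      loci$end[j]))
  }, numeric(1)))
  expect_equal(after_all, before_all)
})

test_that("breaking every CpG in a locus zeroes its density", {
  seq <- "AACGTTACGGACGTACGA"
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  loci <- tibble::tibble(promoter_id = "p1", contig = "chr1",
                         start = 0L, end = nchar(seq))
  n_cpg <- count_cpg(seq)
  v <- simulate_ancient_variants(genome, loci, n_cpg_breaking = n_cpg,
                                 n_cpg_creating = 0, seed = 25)
  edited <- apply_snps(seq, loci, v[1:4])
  expect_equal(count_cpg(edited), 0L)

  expect_error(
    simulate_ancient_variants(genome, loci, n_cpg_breaking = n_cpg + 10,
                              n_cpg_creating = 0, seed = 25),
    "candidate")
})

test_that("an empty variant request yields an empty, valid VCF", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
  loci <- tibble::tibble(promoter_id = "p1", contig = "chr1", start = 0L, end = 6L)
  tf <- withr::local_tempfile(fileext = ".vcf")
  v <- simulate_ancient_variants(genome, loci, 0, 0, seed = 26, out_path = tf)
  expect_equal(nrow(v), 0L)
  expect_equal(nrow(suppressMessages(read_vcf_snps(tf))), 0L)
})

test_that("the full pipeline recovers the planted clock across seeds", {
  results <- lapply(1:5, function(s) {
    cfg <- simulation_config(seed = s)   # 250 species, 40 causal / 460 null
    panel <- simulate_panel(cfg)
    fit <- suppressWarnings(train_clock(panel$densities, panel$species,
                                        divergence = panel$covariance,
                                        seed = s + 1000))
    m <- as.matrix(panel$densities[-1])
    rownames(m) <- panel$densities$species_id
    cls <- stats::setNames(panel$species$vertebrate_class,
                           panel$species$species_id)
    x <- raw_score(fit$model, m[fit$test_ids, , drop = FALSE])
    lnl_pred <- vapply(fit$test_ids, function(sp) {
      suppressWarnings(predict_ln_lifespan(fit$model, x[[sp]], cls[[sp]]))
    }, numeric(1))
    lnl_known <- log(panel$truth$lifespans[fit$test_ids])
    sel <- names(fit$model$promoter_weights)
    list(r2 = stats::cor(lnl_known, lnl_pred)^2,
         n_causal = sum(sel %in% panel$truth$causal_ids),
         n_sel = length(sel))
  })
  r2s <- vapply(results, `[[`, numeric(1), "r2")
  expect_true(all(r2s >= 0.7))
  pooled_causal <- sum(vapply(results, `[[`, numeric(1), "n_causal")) /
    sum(vapply(results, `[[`, numeric(1), "n_sel"))
  expect_gte(pooled_causal, 0.5)
})
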