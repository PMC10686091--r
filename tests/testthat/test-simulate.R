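test_that("the generator is deterministic under an identical config", {
  cfg <- sim_config(seed = 77, n_mags = 2, genome_length = 10000, n_genes = 6)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$genes, b$genes)
  sa <- simulate_sample_pileups(a, cfg)
  sb <- simulate_sample_pileups(b, cfg)
  expect_identical(sa$pileups, sb$pileups)
  expect_identical(sa$coverage, sb$coverage)
})

test_that("written bundles are byte-identical across regenerations", {
  cfg <- sim_config(seed = 12, n_mags = 1, genome_length = 6000, n_genes = 6,
                    groups = tibble::tibble(site = c("AL", "MA"),
                                            vegetation = "SA",
                                            n_samples = 1L,
                                            library_reads = 1e5))
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  for (d in c(d1, d2)) {
    com <- generate_community(cfg)
    write_sim_bundle(com, simulate_sample_pileups(com, cfg), d)
  }
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("genomes hit the target GC content", {
  cfg <- sim_config(seed = 5, n_mags = 1, genome_length = 100000,
                    n_genes = 0, gc = 0.5)
  com <- generate_community(cfg)
  chars <- strsplit(com$genomes[[1]], "")[[1]]
  gc_obs <- mean(chars %in% c("G", "C"))
  expect_gte(gc_obs, 0.48)
  expect_lte(gc_obs, 0.52)
  expect_equal(nchar(com$genomes[[1]]), 100000)
})

test_that("gene placement is non-overlapping, in-bounds, and covers half the genome", {
  cfg <- sim_config(seed = 9, n_mags = 1, genome_length = 20000, n_genes = 15)
  g <- generate_community(cfg)$genes
  g <- g[order(g$start), ]
  expect_true(all(g$start >= 1 & g$end <= 20000))
  expect_true(all(diff(g$start) > 0))
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_gte(sum(g$end - g$start + 1), 10000)
  # zero genes: valid genome, empty annotation
  cfg0 <- sim_config(seed = 9, n_mags = 1, genome_length = 5000, n_genes = 0)
  expect_equal(nrow(generate_community(cfg0)$genes), 0)
  # infeasible packing is refused
  cfg_bad <- sim_config(seed = 9, n_mags = 1, genome_length = 4000,
                        n_genes = 30)
  expect_error(generate_community(cfg_bad), "infeasible")
})

test_that("site divergence plants fixed differences at the configured rate", {
  cfg <- sim_config(seed = 33, n_mags = 1, genome_length = 50000,
                    n_genes = 0, fixed_diff_rate = 0.01,
                    groups = tibble::tibble(site = c("AL", "MA"),
                                            vegetation = "SA",
                                            n_samples = 1L,
                                            library_reads = 1e5))
  sim <- simulate_sample_pileups(generate_community(cfg), cfg)
  n_diff <- length(sim$truth$site_consensus[["MAG01:MA"]])
  # binomial expectation 500, +-3 sigma ~ +-67
  expect_gte(n_diff, 433)
  expect_lte(n_diff, 567)
  # fixed differences show as near-frequency-1 alternate alleles in MA
  ma <- sim$pileups[sim$pileups$sample_id == "MASA01", ]
  pos <- sim$truth$site_consensus[["MAG01:MA"]][1:50]
  rows <- ma[ma$pos %in% pos, ]
  ref <- strsplit(generate_community(cfg)$genomes[[1]], "")[[1]]
  m <- as.matrix(rows[, paste0("count_", c("A", "C", "G", "T"))])
  ref_count <- m[cbind(seq_len(nrow(m)), match(ref[rows$pos], c("A", "C", "G", "T")))]
  expect_lt(mean(ref_count / rowSums(m)), 0.05)
})

test_that("pileups satisfy the depth identity and respect zero depth", {
  cfg <- sim_config(seed = 3, n_mags = 1, genome_length = 4000, n_genes = 0)
  sim <- simulate_sample_pileups(generate_community(cfg), cfg)
  m <- as.matrix(sim$pileups[, paste0("count_", c("A", "C", "G", "T"))])
  expect_true(all(rowSums(m) > 0))
  expect_true(all(m >= 0))
  cfg0 <- sim_config(seed = 3, n_mags = 1, genome_length = 2000,
                     n_genes = 0, depth = 0)
  sim0 <- simulate_sample_pileups(generate_community(cfg0), cfg0)
  expect_equal(nrow(sim0$pileups), 0)
  expect_true(all(sim0$coverage$mean_coverage == 0))
})

test_that("a planted deletion removes coverage only in its group", {
  ds <- deletion_dataset(seed = 8, del_len = 10000, genome_length = 30000)
  truth <- ds$sim$truth$deletion
  dep <- pileup_depth(ds$sim$pileups)
  in_del <- dep[dep$pos >= truth$start & dep$pos <= truth$end, ]
  for (sid in ds$sim$samples$sample_id) {
    grp <- ds$sim$samples$group[ds$sim$samples$sample_id == sid]
    breadth <- sum(in_del$sample_id == sid) / (truth$end - truth$start + 1)
    if (grp == "MASA") expect_equal(breadth, 0) else expect_gt(breadth, 0.9)
  }
})

test_that("cassette injection validates its inputs", {
  genome <- strrep("ACGT", 3000)
  expect_error(inject_dgr_cassette(genome, list(tr_length = 100,
                                                n_adenine_mismatches = 5), 2000),
               "multiple of 3")
  expect_error(inject_dgr_cassette(genome, list(tr_length = 120,
                                                n_adenine_mismatches = 0), 2000),
               "undetectable")
  expect_error(inject_dgr_cassette(genome, list(tr_length = 12,
                                                n_adenine_mismatches = 4), 2000),
               "too short")
  expect_error(inject_dgr_cassette(genome, list(tr_length = 120,
                                                n_adenine_mismatches = 8), 11500),
               "no room")
})

test_that("injected cassette truth is internally consistent", {
  set.seed(99)
  genome <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  inj <- inject_dgr_cassette(genome, list(tr_length = 120,
                                          n_adenine_mismatches = 8), 5100)
  truth <- inj$truth
  expect_equal(substr(inj$genome, truth$tr[1], truth$tr[2]), truth$tr_seq)
  expect_equal(substr(inj$genome, truth$vr[1], truth$vr[2]), truth$vr_seq)
  trc <- strsplit(truth$tr_seq, "")[[1]]
  vrc <- strsplit(truth$vr_seq, "")[[1]]
  expect_equal(which(trc != vrc), truth$mismatches$offset)
  expect_true(all(trc[truth$mismatches$offset] == "A"))
  expect_true(all(vrc[truth$mismatches$offset] != "A"))
  # the VR is inside the target ORF at a codon boundary
  expect_true(truth$vr[1] >= truth$target[1] && truth$vr[2] <= truth$target[2])
  expect_equal((truth$vr[1] - truth$target[1]) %% 3, 0)
})

test_that("library size and abundance multipliers propagate to coverage", {
  cfg <- sim_config(
    seed = 21, n_mags = 1, genome_length = 10000, n_genes = 0, depth = 20,
    groups = tibble::tibble(site = c("AL", "MA"), vegetation = "SA",
                            n_samples = 1L, library_reads = 1e6),
    abundance_multipliers = tibble::tibble(mag_id = "MAG01",
                                           group = c("ALSA", "MASA"),
                                           mult = c(4, 1)))
  sim <- simulate_sample_pileups(generate_community(cfg), cfg)
  cov <- sim$coverage
  ratio <- cov$mean_coverage[cov$sample_id == "ALSA01"] /
    cov$mean_coverage[cov$sample_id == "MASA01"]
  expect_gt(ratio, 3.6)
  expect_lt(ratio, 4.4)
})
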