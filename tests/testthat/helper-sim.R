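# One 10 kb gene with 50 planted polymorphic sites (minor fraction 0.3) at
# depth 100 and 0.5% error; returns recovered vs true SNVs per kbp.
snv_recovery <- function(seed) {
  cfg <- sim_config(
    seed = seed, n_mags = 1, genome_length = 10000, n_genes = 0,
    groups = tibble::tibble(site = "AL", vegetation = "SA",
                            n_samples = 1L, library_reads = 1e6),
    snv_density = 5, snv_minor_fraction = 0.3, depth = 100,
    error_rate = 0.005, fixed_diff_rate = 0,
    abundance_multipliers = tibble::tibble(mag_id = "MAG01",
                                           group = "ALSA", mult = 1)
  )
  com <- generate_community(cfg)
  sim <- simulate_sample_pileups(com, cfg)
  snvs <- call_snvs(sim$pileups)
  truth_sites <- sim$truth$snv_sites[["MAG01:AL"]]
  list(recovered_per_kbp = nrow(snvs) / 10,
       true_per_kbp = nrow(truth_sites) / 10)
}

# Random genome with one injected DGR cassette; returns the truth plus the
# detector's view of the contig.
cassette_roundtrip <- function(seed, tr_length = 120, n_mismatches = 8,
                               genome_length = 13000, rt_start = 5100) {
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), genome_length, TRUE),
                  collapse = "")
  inj <- inject_dgr_cassette(genome,
                             list(tr_length = tr_length,
                                  n_adenine_mismatches = n_mismatches),
                             rt_start, mag_id = "ctg", contig_id = "ctg")
  scr <- detect_dgr(inj$genome, inj$truth$rt, inj$genes,
                    window = 5000, contig_id = "ctg")
  list(inj = inj, screen = scr)
}

# Two-group study with a planted group-specific deletion; small but at the
# scale where window-level breadth is informative.
deletion_dataset <- function(seed, del_len = 20000, genome_length = 50000) {
  cfg <- sim_config(
    seed = seed, n_mags = 1, genome_length = genome_length,
    n_genes = genome_length %/% 2500,
    groups = tibble::tibble(site = c("AL", "MA"), vegetation = c("SA", "SA"),
                            n_samples = 2L, library_reads = 1e6),
    depth = 10, fixed_diff_rate = 0.005, snv_density = 1,
    abundance_multipliers = tibble::tibble(mag_id = "MAG01",
                                           group = c("ALSA", "MASA"),
                                           mult = 1),
    deletion_spec = list(group = "MASA", length = del_len)
  )
  com <- generate_community(cfg)
  sim <- simulate_sample_pileups(com, cfg)
  list(community = com, sim = sim, cfg = cfg)
}
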