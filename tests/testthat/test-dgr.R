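test_that("codon accessibility agrees with brute-force enumeration for all 64 codons", {
  for (codon in all_codons()) {
    if (codon %in% c("TAA", "TAG", "TGA")) {
      expect_error(accessible_amino_acids(codon), "stop codon")
    } else {
      acc <- accessible_amino_acids(codon)
      expect_identical(acc$accessible[[1]], oracle_accessible(codon),
                       label = codon)
      expect_equal(acc$count, length(oracle_accessible(codon)))
      # the codon's own amino acid is always reachable
      expect_true(acc$amino_acid %in% acc$accessible[[1]])
    }
  }
})

test_that("worked accessibility examples and ambiguity handling", {
  expect_equal(accessible_amino_acids("AAC")$count, 15)
  atc <- accessible_amino_acids("ATC")
  expect_equal(sort(atc$accessible[[1]]), sort(c("F", "L", "I", "V")))
  ggg <- accessible_amino_acids("GGG")
  expect_equal(ggg$accessible[[1]], "G")
  expect_equal(ggg$count, 1)
  expect_equal(accessible_amino_acids("AAA")$count, 20)
  # AAY is resolution-invariant (AAC and AAT give the same 15-aa set)
  expect_equal(accessible_amino_acids("AAY")$count, 15)
  expect_identical(accessible_amino_acids("AAY")$accessible[[1]],
                   accessible_amino_acids("AAC")$accessible[[1]])
  # ARA resolves to AAA (20) vs AGA (5): rejected, with both counts named
  expect_error(accessible_amino_acids("ARA"), "20 vs 5")
  expect_error(accessible_amino_acids("XYZ"), "invalid codon")
})

test_that("theoretical diversity reproduces the 15-variable-codon target region", {
  tr <- c(rep("AAY", 9), "ATC", "CAA", "TAT", "CAY", "CAY", "GAT")
  td <- theoretical_diversity(tr)
  expect_equal(td$d_max_exact, "196830000000000")
  expect_equal(td$d_max, 1.9683e14)
  expect_equal(td$d_max_rendered, "~1.97 × 10^14")
  expect_equal(td$n_variable, 15)
  expect_equal(td$n_codons, 15)
})

test_that("theoretical diversity degenerate inputs", {
  expect_equal(theoretical_diversity(c("GGG", "CCC"))$d_max, 1)
  expect_equal(theoretical_diversity(c("GGG", "CCC"))$n_variable, 0)
  expect_equal(theoretical_diversity("AAA")$d_max, 20)
  # in-frame string input splits into codons
  expect_equal(theoretical_diversity("GGGCCC")$n_codons, 2)
  expect_error(theoretical_diversity("GGGC"), "multiple of 3")
})

test_that("an exact planted duplication is recovered with exact coordinates", {
  set.seed(21)
  rep_seq <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  # flanks chosen so the copies are delimited by mismatches on both sides
  left <- paste(sample(c("A", "C", "G", "T"), 2999, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 4900, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  ctg <- paste0(left, "C", rep_seq, "G", mid, "T", rep_seq, "A", right)
  s1 <- 3001
  s2 <- 3001 + 100 + 1 + nchar(mid) + 1
  substr(ctg, s1 - 1, s1 - 1) <- "C"; substr(ctg, s2 - 1, s2 - 1) <- "T"
  substr(ctg, s1 + 100, s1 + 100) <- "G"; substr(ctg, s2 + 100, s2 + 100) <- "A"
  pairs <- suppressWarnings(
    find_repeat_pairs(ctg, c(s1 - 500, s1 - 400), window = 20000))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$start_1, s1)
  expect_equal(pairs$end_1, s1 + 99)
  expect_equal(pairs$start_2, s2)
  expect_equal(pairs$end_2, s2 + 99)
  expect_equal(pairs$identity, 1)
  expect_equal(pairs$n_mismatches, 0L)
})

test_that("a planted 90%-identity duplication is recovered with its mismatch columns", {
  rt <- cassette_roundtrip(seed = 31, tr_length = 120, n_mismatches = 12)
  truth <- rt$inj$truth
  pairs <- rt$screen$pairs
  expect_gte(nrow(pairs), 1)
  hit <- pairs[pairs$start_1 == truth$tr[1], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end_1, truth$tr[2])
  expect_equal(hit$start_2, truth$vr[1])
  expect_equal(hit$end_2, truth$vr[2])
  expect_equal(hit$identity, 0.9)
  expect_equal(hit$mismatches[[1]]$offset, truth$mismatches$offset)
})

test_that("random sequence yields no repeat pairs in at least 95% of seeds", {
  fails <- 0L
  for (seed in 1:20) {
    set.seed(seed + 400)
    ctg <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
    pairs <- suppressWarnings(
      find_repeat_pairs(ctg, c(9500, 10400), window = 20000))
    if (nrow(pairs) > 0) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("repeat coordinates are translation invariant", {
  rt <- cassette_roundtrip(seed = 55, genome_length = 30000, rt_start = 9000)
  pad <- 500
  shifted <- paste0(strrep("ACGT", pad / 4), rt$inj$genome)
  p0 <- find_repeat_pairs(rt$inj$genome, rt$inj$truth$rt, window = 5000)
  p1 <- find_repeat_pairs(shifted, rt$inj$truth$rt + pad, window = 5000)
  expect_equal(nrow(p0), nrow(p1))
  expect_equal(p1$start_1, p0$start_1 + pad)
  expect_equal(p1$end_2, p0$end_2 + pad)
})

make_pair <- function(n_mm, adenines_in_1, s1 = 1000, s2 = 3000, len = 100) {
  seq1 <- strrep("C", len)
  seq2 <- strrep("C", len)
  off <- seq(5, by = 7, length.out = n_mm)
  b1 <- c(rep("A", adenines_in_1), rep("G", n_mm - adenines_in_1))
  b2 <- rep("T", n_mm)
  list(contig_id = "ctg", start_1 = s1, end_1 = s1 + len - 1,
       start_2 = s2, end_2 = s2 + len - 1, length = len,
       n_mismatches = n_mm, identity = 1 - n_mm / len,
       seq_1 = seq1, seq_2 = seq2,
       mismatches = tibble::tibble(offset = off, base_1 = b1, base_2 = b2))
}

test_that("TR/VR assignment follows adenine polarity and the target-ORF rule", {
  orfs <- tibble::tibble(gene_id = "tgt", start = 2900, end = 3400,
                         strand = "+")
  cas <- assign_tr_vr(make_pair(8, adenines_in_1 = 8), orfs)
  expect_true(cas$accepted)
  expect_equal(cas$adenine_polarity, 1)
  expect_equal(cas$tr_start, 1000)
  expect_equal(cas$vr_start, 3000)
  expect_equal(cas$target_gene_id, "tgt")
  expect_equal(cas$vr_frame, (3000 - 2900) %% 3)
  expect_equal(cas$mismatches$tr_base, rep("A", 8))

  low <- assign_tr_vr(make_pair(8, adenines_in_1 = 2), orfs)
  expect_false(low$accepted)
  expect_match(low$reason, "polarity")
  few <- assign_tr_vr(make_pair(3, adenines_in_1 = 3), orfs)
  expect_false(few$accepted)
  expect_match(few$reason, "too few")
  no_orf <- assign_tr_vr(make_pair(8, adenines_in_1 = 8),
                         tibble::tibble(gene_id = "far", start = 9000,
                                        end = 9500, strand = "+"))
  expect_equal(no_orf$reason, "no target ORF")
  # equal polarity on both members cannot be oriented
  tie <- make_pair(8, adenines_in_1 = 0)
  tie$mismatches$base_1 <- rep(c("A", "G"), 4)
  tie$mismatches$base_2 <- rep(c("G", "A"), 4)
  expect_equal(assign_tr_vr(tie, orfs)$reason, "ambiguous orientation")
})

test_that("injected cassettes are recovered end to end with polarity exactly 1", {
  for (seed in c(7, 19)) {
    rt <- cassette_roundtrip(seed)
    truth <- rt$inj$truth
    expect_equal(length(rt$screen$cassettes), 1)
    cas <- rt$screen$cassettes[[1]]
    expect_equal(cas$adenine_polarity, 1)
    expect_equal(c(cas$tr_start, cas$tr_end), truth$tr)
    expect_equal(c(cas$vr_start, cas$vr_end), truth$vr)
    expect_equal(cas$target_gene_id, truth$target_gene_id)
    expect_equal(cas$vr_frame, 0L)
    expect_equal(cas$tr_seq, truth$tr_seq)
    expect_equal(cas$vr_seq, truth$vr_seq)
  }
})

test_that("observed recoding recovers planted per-position variant sets", {
  rt <- cassette_roundtrip(seed = 47)
  cas <- rt$screen$cassettes[[1]]
  reads <- simulate_vr_reads(cas, variants_per_position = c(2, 8),
                             n_reads = 60, seed = 3)
  obs <- observed_recoding(reads$reads, cas)
  expect_equal(obs$positions$codon_index, reads$truth$codon_index)
  for (i in seq_len(nrow(obs$positions))) {
    expect_identical(obs$positions$observed[[i]], reads$truth$variants[[i]])
  }
  expect_equal(obs$d_obs, prod(lengths(reads$truth$variants)))
  expect_false(any(obs$positions$flagged))
})

test_that("uniform two-variant recoding gives D_obs = 2^k and no recoding gives 1", {
  rt <- cassette_roundtrip(seed = 13)
  cas <- rt$screen$cassettes[[1]]
  two <- simulate_vr_reads(cas, variants_per_position = c(2, 2),
                           n_reads = 20, seed = 5)
  obs2 <- observed_recoding(two$reads, cas)
  expect_equal(obs2$d_obs, 2^nrow(obs2$positions))
  one <- simulate_vr_reads(cas, variants_per_position = c(1, 1),
                           n_reads = 10, seed = 5)
  obs1 <- observed_recoding(one$reads, cas)
  expect_equal(obs1$d_obs, 1)
  # reads identical to the TR translation imply every count is 1
  expect_true(all(obs1$positions$n_observed == 1))
})

test_that("observed diversity never exceeds theoretical diversity", {
  rt <- cassette_roundtrip(seed = 29)
  cas <- rt$screen$cassettes[[1]]
  rep_full <- diversity_report(
    cas, simulate_vr_reads(cas, c(3, 6), n_reads = 50, seed = 8)$reads)
  expect_lte(rep_full$observed$d_obs, rep_full$theoretical$d_max)
  # string comparison of the exact products (same length => lexicographic ok)
  expect_lte(nchar(rep_full$observed$d_obs_exact),
             nchar(rep_full$theoretical$d_max_exact))
})

test_that("recoding request validation and coverage errors", {
  fake <- list(tr_seq = "ATCGGGATC", vr_seq = "TTCGGGGTC", vr_frame = 0L)
  expect_error(simulate_vr_reads(fake, c(16, 16), n_reads = 20),
               "ATC")
  expect_error(simulate_vr_reads(fake, c(2, 8), n_reads = 3),
               "n_reads")
  rt <- cassette_roundtrip(seed = 61)
  cas <- rt$screen$cassettes[[1]]
  far <- tibble::tibble(read_id = "r1", seq = "ACGT", offset = -2000L)
  expect_error(observed_recoding(far, cas), "no read covers")
})
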