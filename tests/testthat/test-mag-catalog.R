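test_that("quality score is completeness minus five times contamination, with strict gates", {
  expect_equal(quality_score(92, 1)$score, 87)
  expect_true(quality_score(92, 1)$passes)
  # both completeness and contamination gates are strict at their boundary
  at_boundary <- quality_score(90, 5)
  expect_equal(at_boundary$score, 65)
  expect_false(at_boundary$passes)
  # contamination gate alone fails a high-score MAG
  expect_equal(quality_score(98, 6)$score, 68)
  expect_false(quality_score(98, 6)$passes)
  expect_error(quality_score(-1, 0), "completeness")
  expect_error(quality_score(101, 0), "completeness")
  expect_error(quality_score(50, -2), "contamination")
})

test_that("quality score is affine in contamination", {
  for (c0 in c(50, 90, 100)) {
    x <- seq(0, 10, by = 0.5)
    expect_equal(quality_score(rep(c0, length(x)), x)$score - quality_score(c0, 0)$score,
                 -5 * x)
  }
})

test_that("mag_quality collapses per-contig manifests and rejects conflicts", {
  manifest <- tibble::tibble(
    mag_id = c("m1", "m1", "m2"), contig_id = c("c1", "c2", "c3"),
    completeness = c(95, 95, 80), contamination = c(1, 1, 0))
  q <- mag_quality(manifest)
  expect_equal(nrow(q), 2)
  expect_equal(q$passes, c(TRUE, FALSE))
  manifest$contamination[2] <- 2
  expect_error(mag_quality(manifest), "conflicting")
})

test_that("sulfur guilds follow the marker-gene repertoires", {
  srb <- tibble::tibble(gene = c("sat", "aprA", "aprB", "dsrA", "dsrB"),
                        copies = 1)
  expect_equal(classify_sulfur_guild(srb)$guild, "SRB")
  both <- tibble::tibble(
    gene = c("soxA", "soxX", "soxY", "soxZ", "soxB",
             "dsrA", "dsrB", "sat", "aprA", "aprB"),
    copies = c(1, 1, 1, 1, 1, 2, 2, 1, 1, 1))
  expect_equal(classify_sulfur_guild(both)$guild, "SRB+SOX")
  empty <- classify_sulfur_guild(tibble::tibble(gene = character(),
                                                copies = numeric()))
  expect_equal(empty$guild, "none")
  expect_setequal(empty$missing_srb[[1]],
                  c("sat", "aprA", "aprB", "dsrA", "dsrB"))
  expect_setequal(empty$missing_sox[[1]],
                  c("soxA", "soxX", "soxY", "soxZ", "soxB"))
})

test_that("zero-copy and unknown genes are handled", {
  gp <- tibble::tibble(gene = c("sat", "aprA", "aprB", "dsrA", "dsrB", "notAGene"),
                       copies = c(1, 1, 1, 1, 0, 1))
  expect_warning(res <- classify_sulfur_guild(gp), "notAGene")
  expect_equal(res$guild, "none")
  expect_equal(res$missing_srb[[1]], "dsrB")
  # hdr subunits are part of the vocabulary, no warning
  expect_no_warning(classify_sulfur_guild(
    tibble::tibble(gene = c("hdrB2", "sqr"), copies = 1)))
})

test_that("gcpm is the length-weighted mean coverage per million reads", {
  one <- tibble::tibble(contig_id = "c1", length = 5000)
  expect_equal(gcpm(tibble::tibble(contig_id = "c1", mean_coverage = 10),
                    one, 1e6), 10)
  mag <- tibble::tibble(contig_id = c("c1", "c2"), length = c(1000, 3000))
  cov <- tibble::tibble(contig_id = c("c1", "c2"), mean_coverage = c(4, 8))
  expect_equal(gcpm(cov, mag, 2e6), 3.5)
  # per-base summation oracle: total covered bases / total length
  per_base_mean <- (4 * 1000 + 8 * 3000) / (1000 + 3000)
  expect_equal(gcpm(cov, mag, 2e6), per_base_mean * 1e6 / 2e6)
  expect_error(gcpm(cov[1, ], mag, 1e6), "c2")
  expect_error(gcpm(cov, mag, 0), "library_reads")
})

test_that("gcpm invariances: proportional scaling and abundance homogeneity", {
  set.seed(42)
  for (i in 1:10) {
    nc <- sample(2:6, 1)
    mag <- tibble::tibble(contig_id = paste0("c", 1:nc),
                          length = sample(500:5000, nc))
    cov <- tibble::tibble(contig_id = mag$contig_id,
                          mean_coverage = runif(nc, 0, 30))
    lib <- sample(1e5:1e7, 1)
    g <- gcpm(cov, mag, lib)
    k <- runif(1, 0.1, 10)
    scaled <- dplyr::mutate(cov, mean_coverage = mean_coverage * k)
    expect_equal(gcpm(scaled, mag, lib * k), g)
    expect_equal(gcpm(dplyr::mutate(cov, mean_coverage = mean_coverage * 2),
                      mag, lib), 2 * g)
  }
})

test_that("abundance matrix equals element-wise gcpm and applies the detection mask", {
  set.seed(7)
  mags <- tibble::tibble(mag_id = rep(c("m1", "m2"), each = 2),
                         contig_id = paste0("c", 1:4),
                         length = c(1000, 2000, 1500, 500))
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            library_reads = c(1e6, 2e6, 5e5))
  cov <- tidyr::expand_grid(sample_id = samples$sample_id,
                            contig_id = mags$contig_id)
  cov$mean_coverage <- runif(nrow(cov), 0, 10)
  ab <- build_abundance_matrix(cov, mags, samples)
  for (i in seq_len(nrow(ab))) {
    expect_equal(ab$gcpm[i], gcpm(
      cov[cov$sample_id == ab$sample_id[i], ],
      mags[mags$mag_id == ab$mag_id[i], c("contig_id", "length")],
      samples$library_reads[samples$sample_id == ab$sample_id[i]]))
  }
  expect_equal(ab$detected, ab$gcpm >= 2)
  # a value just below the threshold is masked
  cov19 <- cov
  cov19$mean_coverage <- 1.9 * samples$library_reads[
    match(cov19$sample_id, samples$sample_id)] / 1e6
  ab19 <- build_abundance_matrix(cov19, mags, samples)
  expect_equal(ab19$gcpm, rep(1.9, nrow(ab19)))
  expect_false(any(ab19$detected))
})

test_that("abundance matrix edge cases: zeros, threshold 0, duplicates", {
  mags <- tibble::tibble(mag_id = "m1", contig_id = "c1", length = 1000)
  samples <- tibble::tibble(sample_id = c("s1", "s2"), library_reads = 1e6)
  cov0 <- tidyr::expand_grid(sample_id = samples$sample_id, contig_id = "c1")
  cov0$mean_coverage <- 0
  ab0 <- build_abundance_matrix(cov0, mags, samples)
  expect_equal(ab0$gcpm, c(0, 0))
  expect_false(any(ab0$detected))
  cov <- dplyr::mutate(cov0, mean_coverage = c(3, 0))
  abt0 <- build_abundance_matrix(cov, mags, samples, threshold = 0)
  expect_true(all(abt0$detected[abt0$gcpm > 0]))
  expect_error(build_abundance_matrix(
    cov, mags, dplyr::bind_rows(samples, samples[1, ])), "duplicate")
})

test_that("Bray-Curtis matches hand arithmetic and an independent implementation", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 0))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 4 / 6)
  expect_equal(bray_curtis(cbind(a = c(2, 0), b = c(0, 2)))["a", "b"], 1)
  expect_equal(bray_curtis(cbind(a = c(1, 5), b = c(1, 5)))["a", "b"], 0)
  set.seed(11)
  mm <- matrix(runif(40, 0, 10), nrow = 8,
               dimnames = list(NULL, paste0("s", 1:5)))
  d2 <- bray_curtis(mm)
  ref <- as.matrix(vegan::vegdist(t(mm), method = "bray"))
  expect_equal(unname(d2), unname(ref), tolerance = 1e-12)
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_equal(d2, t(d2))
  expect_equal(unname(diag(d2)), rep(0, 5))
})

test_that("Bray-Curtis degenerate inputs", {
  expect_warning(d <- bray_curtis(cbind(a = c(0, 0), b = c(0, 0))), "all-zero")
  expect_equal(d["a", "b"], 0)
  expect_error(bray_curtis(matrix(1:4, ncol = 1)), "2 samples")
})
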