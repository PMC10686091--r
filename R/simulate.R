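#' Configuration for the synthetic salt-marsh community generator
#'
#' Defines a seeded, fully deterministic synthetic study: a small set of
#' MAG genomes observed across samples from two sites times two
#' vegetation zones, with site-specific fixed nucleotide divergence,
#' within-site polymorphic (SNV) sites, Poisson sequencing depth,
#' uniform sequencing error, and optional planted group-specific
#' deletions and DGR cassettes. Every planted feature is recorded in a
#' machine-readable truth set so downstream operations can be scored
#' against it.
#'
#' @param seed Master seed; every artifact draws from a named substream
#'   derived from it, so regenerating one artifact never perturbs
#'   another.
#' @param n_mags Number of MAG genomes (one contig each).
#' @param genome_length Genome length in bp.
#' @param gc Target GC fraction.
#' @param n_genes Genes per genome (non-overlapping, covering >= 50% of
#'   the genome).
#' @param groups Study design: tibble with `site`, `vegetation`,
#'   `n_samples`, `library_reads`. The default mirrors a two-site,
#'   two-vegetation rhizosphere design (AL-JR, AL-SA, MA-SA, MA-SP) with
#'   2 samples per group and 1e6-read libraries. The first site is the
#'   reference site.
#' @param fixed_diff_rate Per-bp rate of fixed (frequency-1) differences
#'   between the non-reference site's population and the reference.
#' @param snv_density True polymorphic sites per kbp within each site.
#' @param snv_minor_fraction Minor allele fraction at polymorphic sites.
#' @param depth Mean per-base coverage per sample before the per-sample
#'   abundance multiplier.
#' @param error_rate Per-base sequencing error, spread uniformly over the
#'   three wrong bases.
#' @param read_length Nominal read length used to convert summed depth to
#'   a mapped-read count.
#' @param abundance_multipliers Optional tibble (`mag_id`, `group` or
#'   `sample_id`, `mult`) fixing per-sample relative abundance; when
#'   absent, multipliers are drawn log-normally (meanlog 0, sdlog 0.4).
#' @param deletion_spec Optional `list(group =, length =, mag_index = 1)`
#'   planting a deletion (zero depth) in the named group's samples.
#' @param dgr_spec Optional `list(tr_length = 120,
#'   n_adenine_mismatches = 8)` injecting a DGR cassette into MAG 1.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_mags = 2, genome_length = 50000, gc = 0.5,
                       n_genes = 40,
                       groups = default_groups(),
                       fixed_diff_rate = 0.01, snv_density = 2,
                       snv_minor_fraction = 0.3, depth = 20,
                       error_rate = 0.005, read_length = 150,
                       abundance_multipliers = NULL,
                       deletion_spec = NULL, dgr_spec = NULL) {
  check_fraction(gc, "gc")
  check_fraction(fixed_diff_rate, "fixed_diff_rate")
  check_fraction(snv_minor_fraction, "snv_minor_fraction")
  check_fraction(error_rate, "error_rate")
  stopifnot(n_mags >= 1, genome_length > 0, n_genes >= 0, depth >= 0,
            snv_density >= 0, read_length > 0)
  check_cols(groups, c("site", "vegetation", "n_samples", "library_reads"),
             "`groups`")
  if (any(groups$library_reads <= 0)) abort("library_reads must be > 0")
  if (!is.null(deletion_spec)) {
    stopifnot(is.list(deletion_spec), !is.null(deletion_spec$group),
              deletion_spec$length > 0)
    deletion_spec$mag_index <- deletion_spec$mag_index %||% 1L
  }
  if (!is.null(dgr_spec)) {
    dgr_spec$tr_length <- dgr_spec$tr_length %||% 120L
    dgr_spec$n_adenine_mismatches <- dgr_spec$n_adenine_mismatches %||% 8L
  }
  structure(list(
    seed = as.integer(seed), n_mags = n_mags, genome_length = genome_length,
    gc = gc, n_genes = n_genes, groups = as_tibble(groups),
    fixed_diff_rate = fixed_diff_rate, snv_density = snv_density,
    snv_minor_fraction = snv_minor_fraction, depth = depth,
    error_rate = error_rate, read_length = read_length,
    abundance_multipliers = abundance_multipliers,
    deletion_spec = deletion_spec, dgr_spec = dgr_spec
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_groups <- function() {
  tibble(site = c("AL", "AL", "MA", "MA"),
         vegetation = c("JR", "SA", "SA", "SP"),
         n_samples = 2L, library_reads = 1e6)
}

#' Sample table implied by a simulation config
#'
#' @param config A `sim_config`.
#' @return A tibble: `sample_id`, `site`, `vegetation`, `group`,
#'   `library_reads`.
#' @export
sim_samples <- function(config) {
  purrr::pmap_dfr(config$groups, function(site, vegetation, n_samples,
                                          library_reads) {
    tibble(sample_id = sprintf("%s%s%02d", site, vegetation,
                               seq_len(n_samples)),
           site = site, vegetation = vegetation,
           group = paste0(site, vegetation),
           library_reads = library_reads)
  })
}

random_seq <- function(len, gc) {
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the synthetic community
#'
#' Draws `n_mags` i.i.d. genomes at the target GC content, places
#' non-overlapping genes covering at least half of each genome, assigns
#' alternating sulfur-guild marker-gene repertoires (sulfate-reduction
#' pathway vs truncated thiosulfate-oxidation system) and quality values
#' that pass the screening gates, and (when configured) injects a DGR
#' cassette into MAG 1. Byte-identical output under an identical config.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_community`: `genomes` (named character),
#'   `genes`, `mags` (manifest with completeness/contamination),
#'   `gene_presence`, `truth`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- character(0)
  genes <- list()
  mags <- list()
  presence <- list()
  truth <- list(mags = list())
  srb_set <- c("sat", "aprA", "aprB", "dsrA", "dsrB", "sqr")
  sox_set <- c("soxA", "soxX", "soxY", "soxZ", "soxB", "fccA", "fccB")
  for (i in seq_len(config$n_mags)) {
    mag_id <- sprintf("MAG%02d", i)
    contig_id <- paste0(mag_id, "_c1")
    g <- with_substream(config$seed, paste0("genome_", i), {
      list(seq = random_seq(config$genome_length, config$gc),
           genes = place_genes(config$n_genes, config$genome_length,
                               mag_id, contig_id),
           completeness = round(runif(1, 91, 99.5), 1),
           contamination = round(runif(1, 0, 4), 1))
    })
    mag_truth <- list(contig_id = contig_id)
    if (i == 1 && !is.null(config$dgr_spec)) {
      rt_start <- max(1, floor(config$genome_length * 0.4))
      inj <- with_substream(config$seed, paste0("dgr_", i), {
        inject_dgr_cassette(g$seq, config$dgr_spec, rt_start,
                            mag_id = mag_id, contig_id = contig_id)
      })
      g$seq <- inj$genome
      keep <- !(g$genes$start <= inj$footprint[2] &
                  g$genes$end >= inj$footprint[1])
      g$genes <- bind_rows(g$genes[keep, ], inj$genes)
      mag_truth$dgr <- inj$truth
    }
    genomes[contig_id] <- g$seq
    genes[[i]] <- g$genes
    mags[[i]] <- tibble(mag_id = mag_id, contig_id = contig_id,
                        length = config$genome_length,
                        completeness = g$completeness,
                        contamination = g$contamination)
    set <- if (i %% 2 == 1) srb_set else sox_set
    presence[[i]] <- tibble(mag_id = mag_id, gene = set, copies = 1L)
    mag_truth$guild <- if (i %% 2 == 1) "SRB" else "SOX"
    truth$mags[[mag_id]] <- mag_truth
  }
  structure(list(genomes = genomes, genes = bind_rows(genes),
                 mags = bind_rows(mags), gene_presence = bind_rows(presence),
                 truth = truth, config = config),
            class = "sim_community")
}

place_genes <- function(n_genes, genome_length, mag_id, contig_id) {
  if (n_genes == 0) {
    return(tibble(gene_id = character(), mag_id = character(),
                  contig_id = character(), start = numeric(),
                  end = numeric(), strand = character()))
  }
  lens <- sample(seq(300, 1500, by = 3), n_genes, replace = TRUE)
  if (sum(lens) > 0.9 * genome_length) {
    abort("infeasible gene packing: requested genes exceed 90% of the genome")
  }
  if (sum(lens) < 0.5 * genome_length) {
    # inflate to reach >= 50% genic fraction, keeping frame-sized lengths
    f <- 0.55 * genome_length / sum(lens)
    lens <- 3 * floor(lens * f / 3)
  }
  gap_total <- genome_length - sum(lens)
  gaps <- as.vector(stats::rmultinom(1, gap_total, rep(1, n_genes + 1)))
  starts <- cumsum(gaps[-(n_genes + 1)]) + cumsum(c(0, lens[-n_genes])) + 1
  tibble(gene_id = sprintf("%s_g%03d", mag_id, seq_len(n_genes)),
         mag_id = mag_id, contig_id = contig_id,
         start = starts, end = starts + lens - 1,
         strand = sample(c("+", "-"), n_genes, replace = TRUE))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_orf_codons <- function(n) {
  all64 <- names(Biostrings::GENETIC_CODE)
  sample(setdiff(all64, STOP_CODONS), n, replace = TRUE)
}

#' Inject a DGR cassette into a genome
#'
#' Writes, within a 20 kbp span, an RT placeholder gene, an intergenic
#' template region (TR) containing at least `n_adenine_mismatches`
#' adenines, and a target ORF whose interior carries the variable region
#' (VR): a copy of the TR with the chosen adenine positions substituted
#' by non-adenine bases (never creating an in-frame stop). The VR sits at
#' a codon boundary of the target ORF (frame 0, plus strand). The bases
#' flanking the TR are set to differ from the bases flanking the VR so
#' the true repeat boundary is unambiguous in the truth set.
#'
#' @param genome A genome sequence (single character string).
#' @param dgr_spec `list(tr_length, n_adenine_mismatches)`; `tr_length`
#'   must be a multiple of 3.
#' @param rt_start 1-based start of the RT placeholder gene.
#' @param mag_id,contig_id Labels for the emitted gene rows.
#' @return A list: `genome` (modified), `genes` (RT + target ORF rows),
#'   `footprint` (span overwritten), `truth` (coordinates, TR/VR
#'   sequences, frame, strand, mismatch columns).
#' @export
inject_dgr_cassette <- function(genome, dgr_spec, rt_start,
                                mag_id = "MAG01", contig_id = "MAG01_c1") {
  tr_len <- dgr_spec$tr_length
  n_mm <- dgr_spec$n_adenine_mismatches
  if (tr_len %% 3 != 0) abort("tr_length must be a multiple of 3")
  if (is.null(n_mm) || n_mm < 1) {
    abort("n_adenine_mismatches must be >= 1 (a cassette with no mismatch is undetectable)")
  }
  gc_tab <- codon_table()
  L <- nchar(genome)
  rt_end <- rt_start + 899
  tr_start <- rt_end + 201
  tr_end <- tr_start + tr_len - 1
  orf_start <- tr_end + 301
  vr_lead <- 300 # in-ORF bp before the VR; multiple of 3 keeps frame 0
  orf_len <- vr_lead + tr_len + 300
  orf_end <- orf_start + orf_len - 1
  if (rt_start < 2 || orf_end >= L) abort("no room for the cassette in the genome")

  # TR codons: non-stop and adenine-free except at the codons hosting the
  # mismatches, which are drawn from adenine-rich codons (>= 13 accessible
  # amino acids) so any 2-8 variants-per-position draw is realizable.
  # Mismatches are kept >= 5 columns apart and >= 9 columns from either
  # repeat end so the planted alignment boundary is the maximal-scoring one.
  n_cod <- tr_len / 3
  cods <- random_orf_codons(n_cod)
  cods <- vapply(strsplit(cods, "", fixed = TRUE), function(cc) {
    cc[cc == "A"] <- sample(c("C", "G", "T"), sum(cc == "A"), replace = TRUE)
    paste(cc, collapse = "")
  }, character(1))
  lo <- 9L
  hi <- tr_len - 8L
  span <- hi - lo + 1L - (n_mm - 1L) * 4L
  if (span < n_mm) abort("TR too short to host the requested adenine mismatches")
  mm_pos <- sort(sample(span, n_mm)) + (seq_len(n_mm) - 1L) * 4L + lo - 1L
  for (p in mm_pos) {
    ci <- (p - 1) %/% 3 + 1
    within <- (p - 1) %% 3 + 1
    cods[ci] <- if (within == 3) "AAA" else
      sample(c("AAA", "AAC", "AAT", "AAG"), 1)
  }
  tr_seq <- paste(cods, collapse = "")
  tr_chars <- strsplit(tr_seq, "", fixed = TRUE)[[1]]

  vr_chars <- tr_chars
  for (p in mm_pos) {
    ci <- (p - 1) %/% 3
    within <- (p - 1) %% 3 + 1
    cand <- setdiff(DNA_BASES, "A")
    ok <- vapply(cand, function(b) {
      cc <- vr_chars[(ci * 3 + 1):(ci * 3 + 3)]
      cc[within] <- b
      !(paste(cc, collapse = "") %in% STOP_CODONS)
    }, logical(1))
    vr_chars[p] <- sample(cand[ok], 1)
  }
  vr_seq <- paste(vr_chars, collapse = "")

  rt_seq <- paste(random_orf_codons(900 / 3), collapse = "")
  lead <- paste(random_orf_codons(vr_lead / 3), collapse = "")
  trail <- paste(random_orf_codons(100), collapse = "")
  orf_seq <- paste0(lead, vr_seq, trail)
  vr_start <- orf_start + vr_lead
  vr_end <- vr_start + tr_len - 1

  sub_in <- function(s, at, piece) {
    paste0(substr(s, 1, at - 1), piece, substr(s, at + nchar(piece), nchar(s)))
  }
  genome <- sub_in(genome, rt_start, rt_seq)
  genome <- sub_in(genome, tr_start, tr_seq)
  genome <- sub_in(genome, orf_start, orf_seq)

  # force the TR's flanking bases (intergenic) to mismatch the VR's flanks,
  # pinning the true repeat boundaries
  flank_diff <- function(s, at, other_base) {
    b <- sample(setdiff(DNA_BASES, other_base), 1)
    sub_in(s, at, b)
  }
  for (off in 1:2) {
    genome <- flank_diff(genome, tr_start - off,
                         substr(genome, vr_start - off, vr_start - off))
    genome <- flank_diff(genome, tr_end + off,
                         substr(genome, vr_end + off, vr_end + off))
  }

  genes <- tibble(
    gene_id = paste0(mag_id, c("_rt", "_dgr_target")),
    mag_id = mag_id, contig_id = contig_id,
    start = c(rt_start, orf_start), end = c(rt_end, orf_end),
    strand = "+"
  )
  truth <- list(
    rt = c(rt_start, rt_end), tr = c(tr_start, tr_end),
    vr = c(vr_start, vr_end), target = c(orf_start, orf_end),
    target_gene_id = paste0(mag_id, "_dgr_target"),
    strand = "+", vr_frame = 0L,
    tr_seq = tr_seq, vr_seq = vr_seq,
    mismatches = tibble(offset = mm_pos, tr_base = "A",
                        vr_base = vr_chars[mm_pos])
  )
  list(genome = genome, genes = genes,
       footprint = c(rt_start, orf_end), truth = truth)
}

# vectorized multinomial via sequential binomial thinning
rmultinom_vec <- function(size, prob) {
  n <- length(size)
  out <- matrix(0L, nrow = n, ncol = 4)
  rem <- size
  pleft <- rep(1, n)
  for (b in 1:3) {
    pb <- ifelse(pleft > 0, pmin(1, pmax(0, prob[, b] / pleft)), 0)
    cnt <- rbinom(n, rem, pb)
    out[, b] <- cnt
    rem <- rem - cnt
    pleft <- pleft - prob[, b]
  }
  out[, 4] <- rem
  out
}

#' Simulate per-sample pileups and coverage tables
#'
#' For every sample and MAG: the sample's site determines the consensus
#' (the non-reference site carries fixed frequency-1.0 substitutions at
#' `fixed_diff_rate`); within-site polymorphic sites are planted at
#' `snv_density` per kbp with minor fraction `snv_minor_fraction`;
#' per-position depth is Poisson with mean `depth` times the sample's
#' abundance multiplier; base counts are multinomial with the error rate
#' spread equally over the three wrong bases. A configured deletion
#' zeroes depth over its interval in the named group's samples only.
#'
#' @param community A `sim_community` from [generate_community()].
#' @param config The same [sim_config()] (defaults to the community's).
#' @return A list of class `sim_dataset`: `pileups` (one tibble:
#'   `sample_id`, `contig_id`, `pos`, `count_A..count_T`), `coverage`
#'   (`sample_id`, `contig_id`, `mean_coverage`, `mapped_reads`),
#'   `samples`, `truth` (abundance multipliers, SNV sites and fractions,
#'   fixed-difference positions, deletion interval).
#' @export
simulate_sample_pileups <- function(community, config = community$config) {
  stopifnot(inherits(community, "sim_community"))
  samples <- sim_samples(config)
  sites <- unique(config$groups$site)
  ref_site <- sites[1]
  truth <- list(site_consensus = list(), snv_sites = list(),
                multipliers = list(), deletion = NULL)
  pileups <- list()
  coverage <- list()
  for (m in seq_len(nrow(community$mags))) {
    mag_id <- community$mags$mag_id[m]
    contig_id <- community$mags$contig_id[m]
    ref <- strsplit(community$genomes[[contig_id]], "", fixed = TRUE)[[1]]
    len <- length(ref)
    consensus <- list()
    consensus[[ref_site]] <- ref
    for (s in setdiff(sites, ref_site)) {
      consensus[[s]] <- with_substream(config$seed, paste0("fixed_", mag_id, "_", s), {
        cc <- ref
        idx <- which(runif(len) < config$fixed_diff_rate)
        if (length(idx) > 0) {
          cc[idx] <- vapply(cc[idx], function(b) sample(setdiff(DNA_BASES, b), 1),
                            character(1))
        }
        attr(cc, "diff_pos") <- idx
        cc
      })
      truth$site_consensus[[paste(mag_id, s, sep = ":")]] <-
        attr(consensus[[s]], "diff_pos")
    }
    snv <- list()
    for (s in sites) {
      snv[[s]] <- with_substream(config$seed, paste0("snv_", mag_id, "_", s), {
        n_sites <- round(config$snv_density * len / 1000)
        pos <- sort(sample(len, min(n_sites, len)))
        minor <- vapply(consensus[[s]][pos],
                        function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
        tibble(pos = pos, minor = unname(minor),
               minor_fraction = config$snv_minor_fraction)
      })
      truth$snv_sites[[paste(mag_id, s, sep = ":")]] <- snv[[s]]
    }
    for (r in seq_len(nrow(samples))) {
      sid <- samples$sample_id[r]
      site <- samples$site[r]
      grp <- samples$group[r]
      res <- with_substream(config$seed, paste0("pile_", mag_id, "_", sid), {
        mult <- lookup_multiplier(config, mag_id, sid, grp)
        dvec <- rpois(len, config$depth * mult)
        del <- config$deletion_spec
        if (!is.null(del) && del$group == grp && del$mag_index == m) {
          del_start <- floor(len / 3)
          dvec[del_start:(del_start + del$length - 1)] <- 0L
        }
        q <- matrix(0, nrow = len, ncol = 4,
                    dimnames = list(NULL, DNA_BASES))
        q[cbind(seq_len(len), match(consensus[[site]], DNA_BASES))] <- 1
        st <- snv[[site]]
        if (nrow(st) > 0) {
          q[cbind(st$pos, match(consensus[[site]][st$pos], DNA_BASES))] <-
            1 - st$minor_fraction
          q[cbind(st$pos, match(st$minor, DNA_BASES))] <- st$minor_fraction
        }
        e <- config$error_rate
        p <- q * (1 - 4 * e / 3) + e / 3
        counts <- rmultinom_vec(dvec, p)
        list(mult = mult, dvec = dvec, counts = counts)
      })
      truth$multipliers[[paste(mag_id, sid, sep = ":")]] <- res$mult
      keep <- res$dvec > 0
      pileups[[length(pileups) + 1]] <- tibble(
        sample_id = sid, contig_id = contig_id, pos = which(keep),
        count_A = res$counts[keep, 1], count_C = res$counts[keep, 2],
        count_G = res$counts[keep, 3], count_T = res$counts[keep, 4]
      )
      coverage[[length(coverage) + 1]] <- tibble(
        sample_id = sid, contig_id = contig_id,
        mean_coverage = sum(res$dvec) / len,
        mapped_reads = max(1L, as.integer(round(sum(res$dvec) / config$read_length)))
      )
    }
  }
  if (!is.null(config$deletion_spec)) {
    m <- config$deletion_spec$mag_index
    len <- community$mags$length[m]
    del_start <- floor(len / 3)
    truth$deletion <- list(
      contig_id = community$mags$contig_id[m],
      group = config$deletion_spec$group,
      start = del_start, end = del_start + config$deletion_spec$length - 1
    )
  }
  structure(list(pileups = bind_rows(pileups), coverage = bind_rows(coverage),
                 samples = samples, truth = truth, config = config),
            class = "sim_dataset")
}

lookup_multiplier <- function(config, mag_id, sample_id, group) {
  am <- config$abundance_multipliers
  if (is.null(am)) return(stats::rlnorm(1, 0, 0.4))
  am <- as_tibble(am)
  hit <- if ("sample_id" %in% names(am)) {
    am[am$mag_id == mag_id & am$sample_id == sample_id, ]
  } else {
    am[am$mag_id == mag_id & am$group == group, ]
  }
  if (nrow(hit) == 0) 1 else hit$mult[1]
}

#' Simulate reads over a DGR variable region with planted recoding
#'
#' For each variable codon (TR codons containing adenine) a set of `k`
#' distinct amino-acid variants (`k` uniform over `variants_per_position`,
#' always including the TR's own translation) is drawn from the codon's
#' accessible set; reads spanning the whole VR are then emitted realizing
#' every drawn variant at least once (variants are assigned round-robin
#' across reads, each realized by a codon reachable by adenine
#' substitution). The truth lists the exact per-position sets.
#'
#' @param cassette An accepted `dgr_cassette`, or the `truth` element of
#'   [inject_dgr_cassette()] (fields `tr_seq`, `vr_seq`, `vr_frame`).
#' @param variants_per_position Length-2 integer range for `k`
#'   (default `c(2, 8)`).
#' @param n_reads Reads to emit; must be at least `max(k)`.
#' @param seed Seed for the draw.
#' @return A list: `reads` (tibble `read_id`, `seq`, `offset` = 0),
#'   `truth` (tibble `codon_index`, `coding_pos`, `tr_codon`, list-column
#'   `variants`).
#' @export
simulate_vr_reads <- function(cassette, variants_per_position = c(2, 8),
                              n_reads = 40, seed = 1) {
  if (inherits(cassette, "dgr_cassette")) {
    tr <- cassette$tr_seq_coding
    vr <- cassette$vr_seq_coding
    frame <- cassette$vr_frame
  } else {
    tr <- cassette$tr_seq
    vr <- cassette$vr_seq
    frame <- cassette$vr_frame %||% 0L
  }
  vpp <- as.integer(variants_per_position)
  stopifnot(length(vpp) == 2, vpp[1] >= 1, vpp[1] <= vpp[2])
  if (n_reads < vpp[2]) {
    abort("n_reads must be at least the largest requested variant count")
  }
  gc_tab <- codon_table()
  grid <- vr_codon_grid(list(tr_seq_coding = tr, vr_seq_coding = vr,
                             vr_frame = frame))
  var_idx <- which(grepl("A", grid$tr_codon))
  if (length(var_idx) == 0) abort("cassette has no variable codon positions")

  with_substream(seed, "vr_reads", {
    sets <- list()
    for (ci in var_idx) {
      trc <- grid$tr_codon[ci]
      acc <- accessible_amino_acids(trc)
      k <- if (vpp[1] == vpp[2]) vpp[1] else sample(vpp[1]:vpp[2], 1)
      if (k > acc$count) {
        abort(sprintf("requested %d variants but codon %s gives access to only %d amino acids",
                      k, trc, acc$count))
      }
      own <- unname(gc_tab[trc])
      pool <- setdiff(acc$accessible[[1]], own)
      sets[[as.character(ci)]] <-
        c(own, if (k > 1) sample(pool, k - 1))
    }
    # codons realizing each amino acid via adenine substitution, per position
    realizations <- lapply(var_idx, function(ci) {
      trc <- grid$tr_codon[ci]
      letters <- strsplit(trc, "", fixed = TRUE)[[1]]
      apos <- which(letters == "A")
      gridA <- as.matrix(expand.grid(rep(list(DNA_BASES), length(apos)),
                                     stringsAsFactors = FALSE))
      cods <- apply(gridA, 1, function(b) {
        l <- letters; l[apos] <- b
        paste(l, collapse = "")
      })
      split(cods, unname(gc_tab[cods]))
    })
    names(realizations) <- as.character(var_idx)

    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      chars <- strsplit(vr, "", fixed = TRUE)[[1]]
      for (ci in var_idx) {
        key <- as.character(ci)
        set <- sets[[key]]
        aa <- set[(i - 1) %% length(set) + 1]
        cands <- realizations[[key]][[aa]]
        cod <- if (length(cands) == 1) cands else sample(cands, 1)
        p <- grid$coding_pos[ci]
        chars[p:(p + 2)] <- strsplit(cod, "", fixed = TRUE)[[1]]
      }
      reads[i] <- paste(chars, collapse = "")
    }
    list(
      reads = tibble(read_id = sprintf("read%04d", seq_len(n_reads)),
                     seq = reads, offset = 0L),
      truth = tibble(codon_index = var_idx,
                     coding_pos = grid$coding_pos[var_idx],
                     tr_codon = grid$tr_codon[var_idx],
                     variants = lapply(as.character(var_idx),
                                       function(k) sort(sets[[k]])))
    )
  })
}
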