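#' Find near-identical ungapped repeat pairs near a reverse-transcriptase locus
#'
#' Diversity-generating retroelements (DGRs) carry two near-identical
#' repeats — a template region (TR) and a variable region (VR) — close to a
#' reverse-transcriptase (RT) gene. This function enumerates candidate
#' repeat pairs inside a window around the RT locus by exact k-mer
#' seeding followed by ungapped X-drop extension (match +1, mismatch -3),
#' trimming each alignment back to its maximal-scoring, match-delimited
#' extent. Pairs are reported once, leftmost member first; extension is
#' deterministic, so the result is too.
#'
#' @param seq Contig sequence, a single character string over A/C/G/T.
#' @param rt_locus Length-2 numeric `c(start, end)`, 1-based inclusive,
#'   inside the contig.
#' @param window Search distance in bp on each side of the RT locus
#'   (default 20000); clipped to the contig with a warning.
#' @param min_len Minimum aligned repeat length in bp (default 50).
#' @param min_identity Minimum fraction of matching columns (default 0.8).
#' @param k Exact seed length (default 12).
#' @param contig_id Label stored in the output (default "contig").
#' @return A tibble, one row per repeat pair: `contig_id`, `start_1`,
#'   `end_1`, `start_2`, `end_2` (1-based inclusive, member 1 leftmost),
#'   `length`, `n_mismatches`, `identity`, `seq_1`, `seq_2`, and a
#'   list-column `mismatches` of tibbles (`offset`, `base_1`, `base_2`).
#' @export
find_repeat_pairs <- function(seq, rt_locus, window = 20000, min_len = 50,
                              min_identity = 0.8, k = 12,
                              contig_id = "contig") {
  stopifnot(is.character(seq), length(seq) == 1)
  L <- nchar(seq)
  if (length(rt_locus) != 2 || rt_locus[1] < 1 || rt_locus[2] > L ||
      rt_locus[1] > rt_locus[2]) {
    abort("`rt_locus` must be c(start, end) inside the contig")
  }
  if (window <= 0 || min_len <= 0) abort("`window` and `min_len` must be > 0")
  check_fraction(min_identity, "min_identity", lo = 0, hi = 1, lo_open = TRUE)
  rs <- rt_locus[1] - window
  re <- rt_locus[2] + window
  if (rs < 1 || re > L) {
    warn("search window exceeds contig; clipped to contig bounds")
    rs <- max(1, rs); re <- min(L, re)
  }
  S <- toupper(substr(seq, rs, re))
  ch <- strsplit(S, "", fixed = TRUE)[[1]]
  n <- length(ch)
  empty <- tibble(contig_id = character(), start_1 = numeric(),
                  end_1 = numeric(), start_2 = numeric(), end_2 = numeric(),
                  length = numeric(), n_mismatches = integer(),
                  identity = numeric(), seq_1 = character(),
                  seq_2 = character(), mismatches = list())
  if (n < 2 * k) return(empty)

  starts <- seq_len(n - k + 1)
  kmers <- substring(S, starts, starts + k - 1)
  valid <- !grepl("[^ACGT]", kmers)
  groups <- split(starts[valid], kmers[valid])
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) return(empty)

  mism_penalty <- 3
  xdrop <- 15
  found <- list()      # keyed by coords
  done <- new.env()    # per-diagonal covered seed spans

  for (g in groups) {
    g <- sort(g)
    for (ii in seq_len(length(g) - 1)) {
      for (jj in (ii + 1):length(g)) {
        i <- g[ii]; j <- g[jj]; d <- j - i
        key <- as.character(d)
        spans <- if (is.null(done[[key]])) NULL else done[[key]]
        if (!is.null(spans) && any(i >= spans[, 1] & i <= spans[, 2])) next
        maxp <- n - d
        eqd <- function(p) ch[p] == ch[p + d]
        # right extension from seed end
        b <- i + k - 1
        score <- 0; best <- 0; best_b <- b; p <- b + 1
        while (p <= maxp) {
          score <- score + if (eqd(p)) 1 else -mism_penalty
          if (score > best) { best <- score; best_b <- p }
          if (best - score >= xdrop) break
          p <- p + 1
        }
        # left extension from seed start
        a <- i
        score <- 0; best <- 0; best_a <- a; p <- a - 1
        while (p >= 1) {
          score <- score + if (eqd(p)) 1 else -mism_penalty
          if (score > best) { best <- score; best_a <- p }
          if (best - score >= xdrop) break
          p <- p - 1
        }
        a1 <- best_a; b1 <- best_b
        eqv <- ch[a1:b1] == ch[(a1 + d):(b1 + d)]
        while (length(eqv) > 0 && !eqv[1]) { a1 <- a1 + 1; eqv <- eqv[-1] }
        while (length(eqv) > 0 && !eqv[length(eqv)]) {
          b1 <- b1 - 1; eqv <- eqv[-length(eqv)]
        }
        len <- b1 - a1 + 1
        done[[key]] <- rbind(spans, c(a1, b1))
        if (len < min_len || len > d) next
        mm <- which(!eqv)
        identity <- 1 - length(mm) / len
        if (identity < min_identity) next
        coord_key <- paste(a1, b1, d)
        if (!is.null(found[[coord_key]])) next
        found[[coord_key]] <- tibble(
          contig_id = contig_id,
          start_1 = a1 + rs - 1, end_1 = b1 + rs - 1,
          start_2 = a1 + d + rs - 1, end_2 = b1 + d + rs - 1,
          length = len, n_mismatches = length(mm), identity = identity,
          seq_1 = substr(S, a1, b1), seq_2 = substr(S, a1 + d, b1 + d),
          mismatches = list(tibble(offset = mm,
                                   base_1 = ch[a1 + mm - 1],
                                   base_2 = ch[a1 + d + mm - 1]))
        )
      }
    }
  }
  if (length(found) == 0) return(empty)
  arrange(bind_rows(found), .data$start_1, .data$start_2)
}

#' Orient a repeat pair into a DGR cassette by adenine polarity
#'
#' In a genuine DGR the mismatches between the two repeats concentrate at
#' adenine positions of the template region (TR), because retrohoming
#' misincorporates opposite TR adenines. For each orientation the adenine
#' polarity is the fraction of mismatch columns at which that member's
#' base is A; the member with the higher polarity is the TR and the other
#' member — which must lie inside a protein-coding ORF — is the variable
#' region (VR). The pair is accepted as a cassette when it has at least
#' `min_mismatches` mismatch columns, TR polarity of at least
#' `min_polarity`, and a target ORF; otherwise a rejection with a reason
#' is returned.
#'
#' @param pair One row of [find_repeat_pairs()] output (a one-row data
#'   frame or an equivalent list).
#' @param orfs ORF annotation: data frame with `gene_id`, `start`, `end`,
#'   and optionally `strand` (`"+"`/`"-"`, default `"+"`) and `contig_id`.
#' @param min_mismatches Minimum mismatch columns (default 4).
#' @param min_polarity Minimum TR adenine polarity (default 0.75).
#' @return An object of class `dgr_cassette`: a list with `accepted`
#'   (logical) and `reason` (when rejected), and when accepted the fields
#'   `contig_id`, `tr_start/tr_end`, `vr_start/vr_end`, `tr_seq`,
#'   `vr_seq`, coding-strand `tr_seq_coding`/`vr_seq_coding`,
#'   `target_gene_id`, `strand`, `vr_frame` (0-2, offset of the VR start
#'   within the ORF codon grid), `n_mismatches`, `adenine_polarity`, and a
#'   `mismatches` tibble (`offset`, `tr_base`, `vr_base`).
#' @export
assign_tr_vr <- function(pair, orfs, min_mismatches = 4, min_polarity = 0.75) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1)
    pair <- as.list(pair)
    pair$mismatches <- pair$mismatches[[1]]
  }
  mm <- pair$mismatches
  if (is.null(mm) || nrow(mm) == 0) abort("pair has no mismatch columns")
  check_fraction(min_polarity, "min_polarity")
  orfs <- as_tibble(orfs)
  check_cols(orfs, c("gene_id", "start", "end"), "`orfs`")
  if (!"strand" %in% names(orfs)) orfs$strand <- "+"

  reject <- function(reason) {
    structure(list(accepted = FALSE, reason = reason, pair = pair),
              class = "dgr_cassette")
  }
  pol1 <- mean(mm$base_1 == "A")
  pol2 <- mean(mm$base_2 == "A")
  if (pol1 == pol2) return(reject("ambiguous orientation"))
  tr_is_1 <- pol1 > pol2
  polarity <- max(pol1, pol2)
  if (nrow(mm) < min_mismatches) return(reject("too few mismatches"))
  if (polarity < min_polarity) return(reject("insufficient adenine polarity"))

  vr <- if (tr_is_1) c(pair$start_2, pair$end_2) else c(pair$start_1, pair$end_1)
  tr <- if (tr_is_1) c(pair$start_1, pair$end_1) else c(pair$start_2, pair$end_2)
  hit <- orfs[orfs$start <= vr[1] & orfs$end >= vr[2], ]
  if (!is.null(pair$contig_id) && "contig_id" %in% names(hit)) {
    hit <- hit[hit$contig_id == pair$contig_id, ]
  }
  if (nrow(hit) == 0) return(reject("no target ORF"))
  orf <- hit[1, ]
  frame <- if (orf$strand == "+") (vr[1] - orf$start) %% 3 else (orf$end - vr[2]) %% 3
  tr_seq <- if (tr_is_1) pair$seq_1 else pair$seq_2
  vr_seq <- if (tr_is_1) pair$seq_2 else pair$seq_1
  mism <- tibble(offset = mm$offset,
                 tr_base = if (tr_is_1) mm$base_1 else mm$base_2,
                 vr_base = if (tr_is_1) mm$base_2 else mm$base_1)
  structure(list(
    accepted = TRUE, reason = NA_character_,
    contig_id = pair$contig_id %||% "contig",
    tr_start = tr[1], tr_end = tr[2],
    vr_start = vr[1], vr_end = vr[2],
    tr_seq = tr_seq, vr_seq = vr_seq,
    tr_seq_coding = if (orf$strand == "+") tr_seq else revcomp(tr_seq),
    vr_seq_coding = if (orf$strand == "+") vr_seq else revcomp(vr_seq),
    target_gene_id = orf$gene_id, strand = orf$strand,
    vr_frame = as.integer(frame),
    n_mismatches = nrow(mism), adenine_polarity = polarity,
    mismatches = mism
  ), class = "dgr_cassette")
}

#' @export
print.dgr_cassette <- function(x, ...) {
  if (!x$accepted) {
    cat("<dgr_cassette> rejected:", x$reason, "\n")
  } else {
    cat(sprintf("<dgr_cassette> %s TR %d-%d / VR %d-%d in %s (%s), %d mismatches, polarity %.2f\n",
                x$contig_id, x$tr_start, x$tr_end, x$vr_start, x$vr_end,
                x$target_gene_id, x$strand, x$n_mismatches, x$adenine_polarity))
  }
  invisible(x)
}

#' Detect DGR cassettes on a contig
#'
#' Convenience composition of [find_repeat_pairs()] and [assign_tr_vr()]
#' for one RT locus; every candidate pair is screened and the accepted
#' cassettes plus per-pair rejection reasons are returned.
#'
#' @inheritParams find_repeat_pairs
#' @inheritParams assign_tr_vr
#' @param rt_loci A data frame with `start`, `end` (one row per RT locus),
#'   or a single `c(start, end)`.
#' @return An object of class `dgr_screen`: list with `cassettes` (list of
#'   accepted `dgr_cassette`), `rejections` (tibble of reasons), `pairs`
#'   (all repeat pairs). Use [tidy()] for a cassette table.
#' @export
detect_dgr <- function(seq, rt_loci, orfs, window = 20000, min_len = 50,
                       min_identity = 0.8, k = 12, min_mismatches = 4,
                       min_polarity = 0.75, contig_id = "contig") {
  if (!is.data.frame(rt_loci)) {
    rt_loci <- tibble(start = rt_loci[1], end = rt_loci[2])
  }
  pairs <- purrr::pmap_dfr(rt_loci[, c("start", "end")], function(start, end) {
    find_repeat_pairs(seq, c(start, end), window = window, min_len = min_len,
                      min_identity = min_identity, k = k,
                      contig_id = contig_id)
  })
  pairs <- distinct(pairs, .data$start_1, .data$end_1, .data$start_2,
                    .data$end_2, .keep_all = TRUE)
  cassettes <- list()
  rejections <- list()
  for (i in seq_len(nrow(pairs))) {
    cas <- assign_tr_vr(pairs[i, ], orfs, min_mismatches = min_mismatches,
                        min_polarity = min_polarity)
    if (cas$accepted) {
      cassettes[[length(cassettes) + 1]] <- cas
    } else {
      rejections[[length(rejections) + 1]] <-
        tibble(start_1 = pairs$start_1[i], start_2 = pairs$start_2[i],
               reason = cas$reason)
    }
  }
  structure(list(cassettes = cassettes,
                 rejections = bind_rows(rejections),
                 pairs = pairs),
            class = "dgr_screen")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

resolve_codon <- function(codon) {
  maps <- list(A = "A", C = "C", G = "G", T = "T",
               Y = c("C", "T"), R = c("A", "G"))
  letters <- strsplit(toupper(codon), "", fixed = TRUE)[[1]]
  if (length(letters) != 3 || !all(letters %in% names(maps))) {
    abort(sprintf("invalid codon '%s' (3 letters over A/C/G/T, Y/R allowed)", codon))
  }
  grid <- expand.grid(maps[[letters[1]]], maps[[letters[2]]], maps[[letters[3]]],
                      stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}

accessible_set_unambig <- function(codon, gc) {
  letters <- strsplit(codon, "", fixed = TRUE)[[1]]
  apos <- which(letters == "A")
  if (length(apos) == 0) return(sort(unname(gc[codon])))
  subs <- rep(list(DNA_BASES), length(apos))
  grid <- as.matrix(expand.grid(subs, stringsAsFactors = FALSE))
  aas <- apply(grid, 1, function(b) {
    l <- letters; l[apos] <- b
    gc[paste(l, collapse = "")]
  })
  sort(unique(unname(aas[aas != "*"])))
}

#' Amino acids accessible by adenine mutagenesis of one codon
#'
#' A DGR rewrites the adenine positions of each template-region codon with
#' arbitrary nucleotides. For a codon this enumerates every substitution
#' of its adenine positions by each of A/C/G/T, translates with the
#' standard genetic code, and drops stop codons — yielding the set of
#' amino acids the corresponding target-protein residue can be recoded to.
#' Codons without adenine are invariant (count 1). IUPAC Y/R letters are
#' accepted only when every resolution yields the identical accessible
#' set (e.g. AAY: AAC and AAT both give 15).
#'
#' @param codon A 3-letter codon over A/C/G/T (Y/R allowed, see above).
#'   Stop codons are rejected.
#' @return A one-row tibble: `codon`, `amino_acid` (the codon's own),
#'   `n_adenines`, list-column `accessible`, and `count`.
#' @examples
#' accessible_amino_acids("AAC")$count # 15
#' accessible_amino_acids("GGG")$count # 1
#' @export
accessible_amino_acids <- function(codon) {
  gc <- codon_table()
  res <- resolve_codon(codon)
  if (any(gc[res] == "*")) {
    abort(sprintf("'%s' is (or resolves to) a stop codon", codon))
  }
  sets <- lapply(res, accessible_set_unambig, gc = gc)
  if (length(sets) > 1 &&
      !all(vapply(sets[-1], identical, logical(1), sets[[1]]))) {
    abort(sprintf(
      "ambiguity code in '%s' is not resolution-invariant (counts %s)",
      codon, paste(vapply(sets, length, integer(1)), collapse = " vs ")))
  }
  own <- unique(unname(gc[res]))
  letters <- strsplit(toupper(codon), "", fixed = TRUE)[[1]]
  tibble(codon = toupper(codon), amino_acid = paste(own, collapse = "/"),
         n_adenines = sum(letters == "A"),
         accessible = sets[1], count = length(sets[[1]]))
}

#' Codon accessibility for a vector of codons
#'
#' @param codons Character vector of codons, or a single in-frame sequence
#'   whose length is a multiple of 3.
#' @return A tibble with one row per codon (see
#'   [accessible_amino_acids()]), plus `index`.
#' @export
codon_accessibility <- function(codons) {
  codons <- split_codons(codons)
  out <- purrr::map_dfr(codons, accessible_amino_acids)
  mutate(out, index = row_number(), .before = 1)
}

split_codons <- function(codons) {
  if (length(codons) == 1 && nchar(codons) > 3) {
    if (nchar(codons) %% 3 != 0) abort("sequence length is not a multiple of 3")
    codons <- substring(codons, seq(1, nchar(codons), 3),
                        seq(3, nchar(codons), 3))
  }
  if (any(nchar(codons) != 3)) abort("codons must have 3 letters")
  toupper(codons)
}

#' Theoretical amino-acid diversity of a DGR target region
#'
#' The number of distinct target-protein variants a DGR can generate is
#' the product, over template-region codons, of the number of amino acids
#' accessible by adenine mutagenesis of that codon ([codon
#' accessibility][accessible_amino_acids()]). Codons without adenine
#' contribute a factor of 1. The product is computed exactly (decimal
#' string) alongside a numeric value and a 3-significant-digit scientific
#' rendering.
#'
#' @param tr_codons Codons of the template region (vector or in-frame
#'   string), as for [codon_accessibility()].
#' @return An object of class `dgr_diversity`: list with `codons` (the
#'   accessibility tibble), `n_codons`, `n_variable` (codons containing
#'   adenine), `d_max` (numeric), `d_max_exact` (decimal string),
#'   `d_max_rendered`.
#' @examples
#' theoretical_diversity(c("AAC", "GGG"))$d_max # 15
#' @export
theoretical_diversity <- function(tr_codons) {
  acc <- codon_accessibility(tr_codons)
  exact <- exact_product(acc$count)
  structure(list(
    codons = acc,
    n_codons = nrow(acc),
    n_variable = sum(acc$n_adenines >= 1),
    d_max = prod(acc$count),
    d_max_exact = exact,
    d_max_rendered = render_scientific(exact)
  ), class = "dgr_diversity")
}

#' @export
print.dgr_diversity <- function(x, ...) {
  cat(sprintf("<dgr_diversity> %d codons (%d variable): D_max = %s (%s)\n",
              x$n_codons, x$n_variable, x$d_max_exact, x$d_max_rendered))
  invisible(x)
}

#' Observed amino-acid recoding from reads over a variable region
#'
#' Quantifies realized DGR diversity: for every variable codon position
#' (template-region codons containing adenine), each read that fully and
#' unambiguously covers the codon — and is consistent with adenine
#' mutagenesis, i.e. agrees with the TR codon at its non-adenine
#' positions — is translated, and the distinct amino acids with at least
#' `min_reads_per_variant` supporting reads are collected. The observed
#' diversity `D_obs` is the exact product of per-position counts;
#' positions with no qualifying observation contribute 1 and are flagged.
#' By construction `D_obs <= D_max`.
#'
#' @param reads A data frame with `read_id`, `seq` (coding-strand read
#'   sequence) and `offset` (0-based position of the read's first base
#'   relative to the VR start, coding orientation; may be negative).
#' @param cassette An accepted `dgr_cassette` from [assign_tr_vr()].
#' @param min_reads_per_variant Minimum supporting reads per amino acid
#'   (default 1).
#' @return An object of class `dgr_diversity_obs`: list with `positions`
#'   (tibble: `codon_index`, `coding_pos`, `tr_codon`, `tr_aa`,
#'   list-column `observed`, `n_observed`, `n_reads`, `flagged`), `d_obs`
#'   (numeric), `d_obs_exact`, `d_obs_rendered`.
#' @export
observed_recoding <- function(reads, cassette, min_reads_per_variant = 1) {
  stopifnot(inherits(cassette, "dgr_cassette"), isTRUE(cassette$accepted))
  reads <- as_tibble(reads)
  check_cols(reads, c("read_id", "seq", "offset"), "`reads`")
  gc <- codon_table()
  grid <- vr_codon_grid(cassette)
  var_idx <- which(vapply(grid$tr_codon, function(cd) grepl("A", cd), logical(1)))
  if (length(var_idx) == 0) abort("cassette has no variable codon positions")

  pos_rows <- list()
  any_covered <- FALSE
  for (ci in var_idx) {
    p <- grid$coding_pos[ci]
    trc <- grid$tr_codon[ci]
    letters <- strsplit(trc, "", fixed = TRUE)[[1]]
    nonA <- which(letters != "A")
    covers <- reads$offset + 1 <= p & reads$offset + nchar(reads$seq) >= p + 2
    obs <- character(0)
    if (any(covers)) {
      any_covered <- TRUE
      rc <- substr(reads$seq[covers], p - reads$offset[covers],
                   p - reads$offset[covers] + 2)
      rc <- toupper(rc)
      ok <- !grepl("[^ACGT]", rc)
      if (length(nonA) > 0) {
        ok <- ok & vapply(rc, function(x) {
          all(strsplit(x, "", fixed = TRUE)[[1]][nonA] == letters[nonA])
        }, logical(1))
      }
      aas <- unname(gc[rc[ok]])
      aas <- aas[aas != "*"]
      tab <- table(aas)
      obs <- sort(names(tab)[tab >= min_reads_per_variant])
    }
    pos_rows[[length(pos_rows) + 1]] <- tibble(
      codon_index = ci, coding_pos = p, tr_codon = trc,
      tr_aa = unname(gc[trc]), observed = list(obs),
      n_observed = max(1L, length(obs)), n_reads = sum(covers),
      flagged = length(obs) == 0
    )
  }
  if (!any_covered) abort("no read covers any variable position")
  positions <- bind_rows(pos_rows)
  exact <- exact_product(positions$n_observed)
  structure(list(
    positions = positions,
    d_obs = prod(positions$n_observed),
    d_obs_exact = exact,
    d_obs_rendered = render_scientific(exact)
  ), class = "dgr_diversity_obs")
}

# codon grid of the VR/TR alignment in coding orientation:
# coding_pos is the 1-based offset of each full codon's first base within
# the VR (frame accounts for where the VR sits in the ORF's codon grid)
vr_codon_grid <- function(cassette) {
  len <- nchar(cassette$vr_seq_coding)
  f <- cassette$vr_frame
  p0 <- if (f == 0) 1L else 4L - f
  starts <- seq.int(p0, len - 2, by = 3)
  tibble(
    coding_pos = starts,
    tr_codon = substring(cassette$tr_seq_coding, starts, starts + 2),
    vr_codon = substring(cassette$vr_seq_coding, starts, starts + 2)
  )
}

#' Full diversity report for one cassette
#'
#' Combines [theoretical_diversity()] over the cassette's in-frame TR
#' codons with [observed_recoding()] over a read set.
#'
#' @inheritParams observed_recoding
#' @return A list of class `dgr_diversity_report` with elements
#'   `theoretical` and `observed` (the latter `NULL` when `reads` is).
#' @export
diversity_report <- function(cassette, reads = NULL,
                             min_reads_per_variant = 1) {
  stopifnot(inherits(cassette, "dgr_cassette"), isTRUE(cassette$accepted))
  grid <- vr_codon_grid(cassette)
  theo <- theoretical_diversity(grid$tr_codon)
  obs <- if (!is.null(reads)) {
    observed_recoding(reads, cassette, min_reads_per_variant)
  }
  structure(list(theoretical = theo, observed = obs),
            class = "dgr_diversity_report")
}
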