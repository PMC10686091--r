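# Independent brute-force oracle for codon accessibility: enumerate every
# substitution of the adenine positions with nested loops and translate via
# Biostrings::translate (a different path than the package's lookup).
oracle_accessible <- function(codon) {
  letters <- strsplit(codon, "")[[1]]
  apos <- which(letters == "A")
  variants <- codon
  for (p in apos) {
    variants <- unlist(lapply(variants, function(v) {
      vapply(c("A", "C", "G", "T"), function(b) {
        l <- strsplit(v, "")[[1]]
        l[p] <- b
        paste(l, collapse = "")
      }, character(1))
    }))
  }
  aas <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(variants), no.init.codon = TRUE))
  sort(unique(aas[aas != "*"]))
}

all_codons <- function() {
  g <- expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                   c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  apply(g[, 3:1], 1, paste, collapse = "")
}
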