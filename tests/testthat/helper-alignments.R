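# Build a haplotype_alignment from a character vector of sequences.
make_aln <- function(seqs, gene_id = "g", species_id = "sp", cds = NULL) {
  names(seqs) <- paste0("hap_", seq_along(seqs))
  haplotype_alignment(seqs, gene_id = gene_id, species_id = species_id,
                      cds = cds)
}

# Alignment whose haplotypes are given as rows of allele pairs at two sites,
# padded into a 2-column alignment; counts = c(n11, n12, n21, n22) with
# alleles A/C at both sites (A = reference).
aln_from_counts <- function(counts) {
  combos <- rbind(c("A", "A"), c("A", "C"), c("C", "A"), c("C", "C"))
  rows <- combos[rep(1:4, counts), , drop = FALSE]
  make_aln(apply(rows, 1L, paste0, collapse = ""))
}

# Random 2x2 haplotype table with both margins polymorphic.
random_table <- function(max_n = 40) {
  repeat {
    n <- sample(4:max_n, 1L)
    cnt <- as.vector(stats::rmultinom(1L, n, runif(4, 0.05, 1)))
    rA <- cnt[1] + cnt[2]; cB <- cnt[1] + cnt[3]
    if (rA > 0 && rA < n && cB > 0 && cB < n) return(cnt)
  }
}

# 0/1 site vectors implied by a 2x2 table (for the correlation oracle).
table_to_vectors <- function(cnt) {
  x <- rep(c(1, 1, 0, 0), cnt)
  y <- rep(c(1, 0, 1, 0), cnt)
  list(x = x, y = y)
}
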