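# Standard genetic code, codons in TCAG order; '*' = stop.
GENETIC_CODE_STD <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", TCT="S", TCC="S", TCA="S", TCG="S",
  TAT="Y", TAC="Y", TAA="*", TAG="*", TGT="C", TGC="C", TGA="*", TGG="W",
  CTT="L", CTC="L", CTA="L", CTG="L", CCT="P", CCC="P", CCA="P", CCG="P",
  CAT="H", CAC="H", CAA="Q", CAG="Q", CGT="R", CGC="R", CGA="R", CGG="R",
  ATT="I", ATC="I", ATA="I", ATG="M", ACT="T", ACC="T", ACA="T", ACG="T",
  AAT="N", AAC="N", AAA="K", AAG="K", AGT="S", AGC="S", AGA="R", AGG="R",
  GTT="V", GTC="V", GTA="V", GTG="V", GCT="A", GCC="A", GCA="A", GCG="A",
  GAT="D", GAC="D", GAA="E", GAG="E", GGT="G", GGC="G", GGA="G", GGG="G")

#' Count distinct haplotypes
#'
#' Distinct sequences by exact string equality over the full aligned sequence
#' (gaps and Ns included in the comparison).
#'
#' @param aln a [haplotype_alignment()] object.
#' @return Integer number of distinct haplotypes, between 1 and `aln$n`.
#' @export
count_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  length(unique(apply(aln$seq, 1L, paste0, collapse = "")))
}

# 0/1/N coding helper: rows of the alignment restricted to ACGT-comparable use
pair_diff <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(diff = sum(a[ok] != b[ok]), comp = sum(ok))
}

#' Nucleotide diversity (pi)
#'
#' Average, over all pairs of haplotypes, of the proportion of differing
#' sites among pairwise-comparable columns (both states in `A,C,G,T`); no
#' multiple-hit correction is applied, matching the plain per-site "Pi"
#' convention. With `partition = "coding"` the Nei-Gojobori (1986)
#' codon-pathway method is applied to the coding intervals and per-synonymous-
#' and per-nonsynonymous-site diversities are returned.
#'
#' @param aln a [haplotype_alignment()] object with `n >= 2`.
#' @param partition `"all"` (default) for total per-site pi, or `"coding"`
#'   for the synonymous/non-synonymous partition (requires `aln$cds`).
#' @return For `"all"`, a single number. For `"coding"`, a list with
#'   `pi_syn`, `pi_nonsyn`, and the mean per-pair counts of synonymous and
#'   non-synonymous sites (`syn_sites`, `nonsyn_sites`).
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
nucleotide_diversity <- function(aln, partition = c("all", "coding")) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  partition <- match.arg(partition)
  if (aln$n < 2L)
    stop("insufficient data: pi requires at least 2 haplotypes", call. = FALSE)
  if (partition == "all") {
    pairs <- combn(aln$n, 2L)
    vals <- apply(pairs, 2L, function(ij) {
      d <- pair_diff(aln$seq[ij[1L], ], aln$seq[ij[2L], ])
      if (d[["comp"]] == 0L) NA_real_ else d[["diff"]] / d[["comp"]]
    })
    return(mean(vals, na.rm = TRUE))
  }
  if (is.null(aln$cds))
    stop("configuration error: coding partition requested but alignment has no cds intervals",
         call. = FALSE)
  coding_diversity(aln)
}

# Splice cds intervals into one coding matrix; frame of the first interval
# shifts the reading start; trailing partial codon dropped.
splice_coding <- function(aln) {
  cols <- unlist(lapply(seq_len(nrow(aln$cds)), function(i)
    seq.int(aln$cds$start[i] + 1L, aln$cds$end[i])))
  m <- aln$seq[, cols, drop = FALSE]
  off <- aln$cds$frame[1L]
  if (off > 0L) m <- m[, -seq_len(off), drop = FALSE]
  nc <- ncol(m) - ncol(m) %% 3L
  m[, seq_len(nc), drop = FALSE]
}

# Per-codon counts of synonymous/nonsynonymous sites (NG86): for each of the
# three positions, the fraction of the three possible single-nucleotide
# changes that are synonymous; changes to stop codons count as nonsynonymous.
codon_sites <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  if (aa == "*") return(c(syn = NA_real_, nonsyn = NA_real_))
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GENETIC_CODE_STD[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# Average synonymous/nonsynonymous differences between two codons over all
# mutational pathways with equal weights; pathways crossing a stop codon are
# excluded (if every pathway crosses a stop, all are used as a fallback).
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1L) list(pos) else
    lapply(seq_len(factorial(nd)), function(i) perm_index(pos, i))
  score_path <- function(ord) {
    cur <- c1; s <- 0; ns <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE_STD[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) s <- s + 1
      else ns <- ns + 1
      cur <- nxt
    }
    c(s, ns)
  }
  sc <- Filter(Negate(is.null), lapply(paths, score_path))
  if (!length(sc)) {  # all pathways hit a stop; fall back to unrestricted
    score_any <- function(ord) {
      cur <- c1; s <- 0; ns <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GENETIC_CODE_STD[[nxt]] != "*" && GENETIC_CODE_STD[[cur]] != "*" &&
            GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) s <- s + 1
        else ns <- ns + 1
        cur <- nxt
      }
      c(s, ns)
    }
    sc <- lapply(paths, score_any)
  }
  mm <- colMeans(do.call(rbind, sc))
  c(syn = mm[1L], nonsyn = mm[2L])
}

# i-th permutation (1..n!) of a vector, lexicographic
perm_index <- function(v, i) {
  n <- length(v); out <- integer(0); i <- i - 1L
  avail <- v
  for (k in n:1) {
    f <- factorial(k - 1)
    idx <- i %/% f + 1L
    out <- c(out, avail[idx]); avail <- avail[-idx]
    i <- i %% f
  }
  out
}

coding_diversity <- function(aln) {
  m <- splice_coding(aln)
  ncod <- ncol(m) %/% 3L
  if (ncod == 0L)
    return(list(pi_syn = NA_real_, pi_nonsyn = NA_real_,
                syn_sites = 0, nonsyn_sites = 0))
  codons <- vapply(seq_len(ncod), function(k)
    apply(m[, (3L * k - 2L):(3L * k), drop = FALSE], 1L, paste0, collapse = ""),
    FUN.VALUE = character(aln$n))
  # codons: n x ncod matrix of codon strings
  sites_cache <- new.env(parent = emptyenv())
  get_sites <- function(cd) {
    if (is.null(sites_cache[[cd]])) sites_cache[[cd]] <- codon_sites(cd)
    sites_cache[[cd]]
  }
  pairs <- combn(aln$n, 2L)
  ps <- pn <- numeric(ncol(pairs))
  ss_bar <- ns_bar <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    Sd <- Nd <- Ssites <- Nsites <- 0
    for (k in seq_len(ncod)) {
      c1 <- codons[i, k]; c2 <- codons[j, k]
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next  # gap/N: skip codon
      s1 <- get_sites(c1); s2 <- get_sites(c2)
      if (anyNA(s1) || anyNA(s2)) next                        # stop codon: skip
      Ssites <- Ssites + (s1[["syn"]] + s2[["syn"]]) / 2
      Nsites <- Nsites + (s1[["nonsyn"]] + s2[["nonsyn"]]) / 2
      if (c1 != c2) {
        d <- codon_path_diffs(c1, c2)
        Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
      }
    }
    ps[q] <- if (Ssites > 0) Sd / Ssites else NA_real_
    pn[q] <- if (Nsites > 0) Nd / Nsites else NA_real_
    ss_bar[q] <- Ssites; ns_bar[q] <- Nsites
  }
  list(pi_syn = mean(ps, na.rm = TRUE), pi_nonsyn = mean(pn, na.rm = TRUE),
       syn_sites = mean(ss_bar), nonsyn_sites = mean(ns_bar))
}

#' One-row polymorphism summary of an alignment
#'
#' Combines sample size, aligned length, distinct-haplotype count, number of
#' polymorphic sites S, and nucleotide diversity (total, and synonymous /
#' non-synonymous when coding intervals are annotated) into one row of the
#' standard per-gene summary table.
#'
#' @param aln a [haplotype_alignment()] object.
#' @param drop_singletons passed to [extract_sites()] for the usable-site
#'   count `k` reported alongside `S`.
#' @return A one-row data frame with columns `gene_id`, `species_id`, `n`,
#'   `L`, `n_haplotypes`, `S`, `k_usable`, `pi_total`, `pi_syn`, `pi_nonsyn`.
#' @export
polymorphism_summary <- function(aln, drop_singletons = FALSE) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  st <- extract_sites(aln, drop_singletons = drop_singletons)
  cod <- if (!is.null(aln$cds)) nucleotide_diversity(aln, "coding") else
    list(pi_syn = NA_real_, pi_nonsyn = NA_real_)
  data.frame(gene_id = aln$gene_id, species_id = aln$species_id,
             n = aln$n, L = aln$L,
             n_haplotypes = count_haplotypes(aln),
             S = attr(st, "S"), k_usable = attr(st, "k"),
             pi_total = nucleotide_diversity(aln),
             pi_syn = cod$pi_syn, pi_nonsyn = cod$pi_nonsyn,
             stringsAsFactors = FALSE)
}
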