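#' hapld: short-range LD analysis of phased haplotype alignments
#'
#' Tools for quantifying linkage disequilibrium between SNPs at short
#' (intra-gene) distances from experimentally phased haplotype sequences,
#' as used for immunity genes of the *Anopheles gambiae* species complex:
#' polymorphism summaries, pairwise r-squared with Fisher exact significance,
#' LD-decay modelling, haploblock grids, segment-based group comparisons,
#' and a coalescent simulator for self-contained testing.
#'
#' @importFrom stats cor dhyper optimize nls coef predict residuals rexp
#'   rpois runif sd wilcox.test setNames p.adjust lm
#' @importFrom utils combn write.table read.table
#' @keywords internal
"_PACKAGE"

VALID_SYMBOLS <- c("A", "C", "G", "T", "-", "N")

#' Construct a phased haplotype alignment
#'
#' Builds the container used throughout the package: a set of phased,
#' gap-aligned haplotype sequences for one gene in one species/population.
#' Each individual typically contributes up to two records (cloned
#' haplotypes).
#'
#' @param seqs named character vector of aligned sequences (equal length,
#'   alphabet `A,C,G,T,-,N`; case-insensitive), or a character matrix with one
#'   row per haplotype and one column per aligned position.
#' @param gene_id,species_id text labels for the dataset.
#' @param cds optional data frame with columns `start`, `end` (0-based,
#'   half-open aligned-column intervals) and `frame` (0, 1 or 2), marking
#'   coding regions for synonymous/non-synonymous diversity.
#' @return An object of class `"haplotype_alignment"`: a list with elements
#'   `gene_id`, `species_id`, `seq` (character matrix, haplotypes x columns),
#'   `labels`, `n` (haplotype count) and `L` (aligned length in bp).
#' @seealso [read_alignment()], [extract_sites()]
#' @export
haplotype_alignment <- function(seqs, gene_id = "gene", species_id = "species",
                                cds = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    labels <- rownames(m)
  } else {
    seqs <- toupper(as.character(seqs))
    if (length(seqs) < 2L)
      stop("insufficient data: need at least 2 haplotype records", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    labels <- names(seqs)
  }
  if (nrow(m) < 2L)
    stop("insufficient data: need at least 2 haplotype records", call. = FALSE)
  if (is.null(labels)) labels <- paste0("hap_", seq_len(nrow(m)))
  bad <- setdiff(unique(as.vector(m)), VALID_SYMBOLS)
  if (length(bad))
    stop("invalid symbol(s) in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rownames(m) <- labels
  cds <- validate_cds(cds, ncol(m))
  structure(list(gene_id = gene_id, species_id = species_id,
                 seq = m, labels = labels,
                 n = nrow(m), L = ncol(m), cds = cds),
            class = "haplotype_alignment")
}

validate_cds <- function(cds, L) {
  if (is.null(cds)) return(NULL)
  cds <- as.data.frame(cds)
  if (!all(c("start", "end") %in% names(cds)))
    stop("cds must have columns start, end (and optionally frame)", call. = FALSE)
  if (is.null(cds$frame)) cds$frame <- 0L
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(cds$start < 0L) || any(cds$end > L) || any(cds$end <= cds$start))
    stop("cds intervals must satisfy 0 <= start < end <= L", call. = FALSE)
  if (nrow(cds) > 1L && any(cds$start[-1L] < cds$end[-nrow(cds)]))
    stop("cds intervals must be non-overlapping", call. = FALSE)
  cds
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("Phased haplotype alignment: %s / %s\n", x$gene_id, x$species_id))
  cat(sprintf("  %d haplotypes x %d aligned bp\n", x$n, x$L))
  if (!is.null(x$cds))
    cat(sprintf("  %d coding interval(s), %d coding bp\n",
                nrow(x$cds), sum(x$cds$end - x$cds$start)))
  invisible(x)
}

#' Read a phased haplotype alignment from multi-FASTA
#'
#' Reads an aligned multi-FASTA file (one record per haplotype), uppercases
#' sequences, and validates equal lengths and the `A,C,G,T,-,N` alphabet.
#' Record order is preserved.
#'
#' @param path path to an aligned multi-FASTA file with >= 2 records.
#' @param gene_id,species_id dataset labels; default to the file name.
#' @param cds optional coding annotation, either a data frame as in
#'   [haplotype_alignment()] or the path to a tab-separated file with columns
#'   `gene_id`, `cds_start`, `cds_end`, `frame` (rows for other genes are
#'   ignored).
#' @return A [haplotype_alignment()] object.
#' @export
read_alignment <- function(path, gene_id = NULL, species_id = "unknown",
                           cds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) < 2L)
    stop("insufficient data: need at least 2 FASTA records", call. = FALSE)
  seqs <- vapply(as.character(dna), paste0, collapse = "", FUN.VALUE = "")
  if (is.null(gene_id))
    gene_id <- sub("\\.(fa|fasta|fas)$", "", basename(path))
  if (is.character(cds) && length(cds) == 1L) {
    ann <- read.table(cds, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    ann <- ann[ann$gene_id == gene_id, , drop = FALSE]
    cds <- if (nrow(ann)) data.frame(start = ann$cds_start, end = ann$cds_end,
                                     frame = ann$frame) else NULL
  }
  haplotype_alignment(seqs, gene_id = gene_id, species_id = species_id,
                      cds = cds)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln a [haplotype_alignment()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  dna <- ape::as.DNAbin(aln$seq)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Classify every aligned column of a haplotype alignment
#'
#' Each column is classified as `monomorphic`, `usable_biallelic` (exactly two
#' states among `A,C,G,T` and no gap or `N` in any haplotype — the sites that
#' enter LD analysis), `excluded_gap`, `excluded_ambiguous` (contains `N`),
#' `excluded_multiallelic` (three or more nucleotide states), or, when
#' `drop_singletons = TRUE`, `excluded_singleton` (biallelic with minor-allele
#' count 1). The polymorphic-site count S counts columns with at least two
#' distinct states among `A,C,G,T`, whether or not the column also contains a
#' gap; the usable count k is therefore always <= S.
#'
#' @param aln a [haplotype_alignment()] object.
#' @param drop_singletons if `TRUE`, biallelic sites whose minor allele occurs
#'   exactly once are excluded from the usable set (default `FALSE`);
#'   shorthand for `min_minor_count = 2`.
#' @param min_minor_count minimum minor-allele count for a biallelic site to
#'   be usable (default 1, i.e. every biallelic site). Values above 1 give
#'   the minor-allele-frequency conditioning under which the drift-
#'   recombination expectation of r-squared is a good approximation; sites
#'   below the cutoff are classed `excluded_rare`.
#' @return A data frame of class `"site_table"` with one row per aligned
#'   column: `column` (0-based index), `alleles` (e.g. `"A/G"`), `counts`
#'   (e.g. `"27/5"`, same order as `alleles`), `class`. Attributes `S`
#'   (polymorphic sites), `k` (usable sites) and `n_excluded` summarise the
#'   filter.
#' @export
extract_sites <- function(aln, drop_singletons = FALSE, min_minor_count = 1L) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  min_minor_count <- max(as.integer(min_minor_count),
                         if (drop_singletons) 2L else 1L)
  m <- aln$seq
  cls <- character(aln$L)
  alleles <- character(aln$L)
  counts <- character(aln$L)
  poly <- logical(aln$L)
  for (j in seq_len(aln$L)) {
    col <- m[, j]
    tab <- table(factor(col, levels = VALID_SYMBOLS))
    nt <- tab[c("A", "C", "G", "T")]
    nt <- nt[nt > 0L]
    poly[j] <- length(nt) >= 2L
    alleles[j] <- paste(names(nt), collapse = "/")
    counts[j]  <- paste(as.integer(nt), collapse = "/")
    cls[j] <- if (tab[["-"]] > 0L) "excluded_gap"
      else if (tab[["N"]] > 0L) "excluded_ambiguous"
      else if (length(nt) == 1L) "monomorphic"
      else if (length(nt) > 2L) "excluded_multiallelic"
      else if (min(nt) < min_minor_count) "excluded_rare"
      else "usable_biallelic"
  }
  st <- data.frame(column = seq_len(aln$L) - 1L, alleles = alleles,
                   counts = counts, class = cls, stringsAsFactors = FALSE)
  class(st) <- c("site_table", "data.frame")
  attr(st, "S") <- sum(poly)
  attr(st, "k") <- sum(cls == "usable_biallelic")
  attr(st, "n_excluded") <- table(cls[!cls %in% c("monomorphic", "usable_biallelic")])
  attr(st, "gene_id") <- aln$gene_id
  attr(st, "species_id") <- aln$species_id
  st
}

#' Usable-site columns of a site table
#'
#' @param sites a site table from [extract_sites()].
#' @return Integer vector of 0-based column indices classified
#'   `usable_biallelic`, in genomic order.
#' @export
usable_sites <- function(sites) {
  stopifnot(inherits(sites, "site_table"))
  sites$column[sites$class == "usable_biallelic"]
}

#' Write a site table as TSV
#'
#' @param sites a site table from [extract_sites()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
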