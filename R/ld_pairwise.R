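#' Two-locus haplotype counts for a pair of usable sites
#'
#' Builds the 2x2 table of haplotype counts underlying all pairwise LD
#' statistics. The reference allele at each site (A and B) is the
#' alphabetically first observed state, giving deterministic labelling.
#' Haplotypes with a gap or `N` at either site are excluded pairwise (this
#' cannot occur for sites passing the default usable filter).
#'
#' @param aln a [haplotype_alignment()] object.
#' @param site_i,site_j 0-based aligned-column indices; both must be
#'   biallelic over `A,C,G,T` among the included haplotypes.
#' @return An object of class `"two_locus_table"`: list with `counts`
#'   (named numeric: `n11, n12, n21, n22` for allele combinations AB, Ab,
#'   aB, ab), `alleles_i`, `alleles_j` (major = alphabetically first), and
#'   `site_i`, `site_j`.
#' @export
two_locus_counts <- function(aln, site_i, site_j) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  x <- aln$seq[, site_i + 1L]
  y <- aln$seq[, site_j + 1L]
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]; y <- y[keep]
  ax <- sort(unique(x)); ay <- sort(unique(y))
  if (length(ax) != 2L || length(ay) != 2L)
    stop("filter error: site ", if (length(ax) != 2L) site_i else site_j,
         " is not biallelic over A,C,G,T among included haplotypes",
         call. = FALSE)
  counts <- c(n11 = sum(x == ax[1L] & y == ay[1L]),
              n12 = sum(x == ax[1L] & y == ay[2L]),
              n21 = sum(x == ax[2L] & y == ay[1L]),
              n22 = sum(x == ax[2L] & y == ay[2L]))
  structure(list(counts = counts, alleles_i = ax, alleles_j = ay,
                 site_i = site_i, site_j = site_j),
            class = "two_locus_table")
}

as_counts <- function(table) {
  if (inherits(table, "two_locus_table")) table$counts
  else if (is.numeric(table) && length(table) == 4L)
    setNames(as.numeric(table), c("n11", "n12", "n21", "n22"))
  else stop("expected a two_locus_table or a numeric vector of 4 counts",
            call. = FALSE)
}

#' Pairwise LD statistics from a 2x2 haplotype table
#'
#' Computes the classical two-locus disequilibrium statistics from phased
#' haplotype counts: `D = p_AB - p_A p_B`; `D' = |D| / Dmax` with
#' `Dmax = min(p_A p_b, p_a p_B)` when `D > 0` and `min(p_A p_B, p_a p_b)`
#' when `D < 0`; `r = D / sqrt(p_A p_a p_B p_b)`; and `r2 = r^2`, the squared
#' correlation of allelic states across haplotypes.
#'
#' @param table a [two_locus_counts()] result, or a numeric vector of 4
#'   counts `(n11, n12, n21, n22)`.
#' @return Named numeric vector `(D, D_prime, r, r2)`.
#' @export
ld_stats <- function(table) {
  n <- as_counts(table)
  N <- sum(n)
  pA <- (n[["n11"]] + n[["n12"]]) / N
  pB <- (n[["n11"]] + n[["n21"]]) / N
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("undefined statistic: monomorphic margin", call. = FALSE)
  D <- n[["n11"]] / N - pA * pB
  Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  Dp <- if (D == 0) 0 else abs(D) / Dmax
  r <- D / sqrt(pA * pa * pB * pb)
  c(D = D, D_prime = Dp, r = r, r2 = r * r)
}

#' Fisher exact test for a 2x2 haplotype table
#'
#' Exact two-tailed test of association with both margins fixed. The default
#' `"prob"` convention sums hypergeometric probabilities of every table whose
#' point probability does not exceed that of the observed table (the
#' probability-mass method); `"doubling"` doubles the smaller one-sided tail
#' (capped at 1).
#'
#' @param table a [two_locus_counts()] result or numeric vector of 4 counts.
#' @param method two-tailed convention, `"prob"` (default) or `"doubling"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table, method = c("prob", "doubling")) {
  method <- match.arg(method)
  n <- as_counts(table)
  N <- sum(n)
  rA <- n[["n11"]] + n[["n12"]]   # margin of allele A at site i
  cB <- n[["n11"]] + n[["n21"]]   # margin of allele B at site j
  lo <- max(0L, rA + cB - N); hi <- min(rA, cB)
  supp <- lo:hi
  pr <- dhyper(supp, cB, N - cB, rA)
  p_obs <- dhyper(n[["n11"]], cB, N - cB, rA)
  if (method == "prob") {
    p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(pr[supp <= n[["n11"]]])
    upper <- sum(pr[supp >= n[["n11"]]])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, max(p, .Machine$double.xmin))
}

#' All-pairs LD scan over the usable sites of an alignment
#'
#' Computes, for every pair of usable biallelic sites, the distance in
#' aligned bp, D, D', r, r-squared, the Fisher exact p-value, and nominal and
#' Bonferroni-corrected significance flags. The Bonferroni family is the set
#' of all pairwise tests within this one dataset (threshold
#' `alpha / n_pairs`).
#'
#' @param aln a [haplotype_alignment()] object.
#' @param alpha nominal significance level (default 0.05).
#' @param drop_singletons,min_minor_count passed to [extract_sites()].
#' @param fisher_method passed to [fisher_exact_2x2()].
#' @return An object of class `"pairwise_ld"`: list with `pairs` (data frame,
#'   one row per site pair) and `summary` (list: `k_usable`, `n_pairs`,
#'   `n_sig_nominal`, `n_sig_bonferroni`, `mean_r2`, `sd_r2`; the means are
#'   `NA` when `n_pairs = 0`).
#' @export
pairwise_ld_scan <- function(aln, alpha = 0.05, drop_singletons = FALSE,
                             min_minor_count = 1L, fisher_method = "prob") {
  stopifnot(inherits(aln, "haplotype_alignment"))
  st <- extract_sites(aln, drop_singletons = drop_singletons,
                      min_minor_count = min_minor_count)
  us <- usable_sites(st)
  k <- length(us)
  empty <- data.frame(site_i = integer(0), site_j = integer(0),
                      distance = integer(0), D = numeric(0),
                      D_prime = numeric(0), r = numeric(0), r2 = numeric(0),
                      fisher_p = numeric(0), sig_nominal = logical(0),
                      sig_bonferroni = logical(0))
  if (k < 2L) {
    out <- list(pairs = empty,
                summary = list(gene_id = aln$gene_id,
                               species_id = aln$species_id,
                               n = aln$n, k_usable = k, n_pairs = 0L,
                               n_sig_nominal = 0L, n_sig_bonferroni = 0L,
                               mean_r2 = NA_real_, sd_r2 = NA_real_))
    class(out) <- "pairwise_ld"
    return(out)
  }
  # 0/1 coding: 1 = alphabetically-first allele at each site
  X <- matrix(0L, aln$n, k)
  for (q in seq_len(k)) {
    col <- aln$seq[, us[q] + 1L]
    X[, q] <- as.integer(col == sort(unique(col))[1L])
  }
  idx <- combn(k, 2L)
  np <- ncol(idx)
  D <- Dp <- r <- r2 <- p <- numeric(np)
  for (q in seq_len(np)) {
    a <- idx[1L, q]; b <- idx[2L, q]
    x <- X[, a]; y <- X[, b]
    cnt <- c(n11 = sum(x & y), n12 = sum(x & !y),
             n21 = sum(!x & y), n22 = sum(!x & !y))
    s <- ld_stats(cnt)
    D[q] <- s[["D"]]; Dp[q] <- s[["D_prime"]]
    r[q] <- s[["r"]]; r2[q] <- s[["r2"]]
    p[q] <- fisher_exact_2x2(cnt, method = fisher_method)
  }
  bonf <- alpha / np
  pairs <- data.frame(site_i = us[idx[1L, ]], site_j = us[idx[2L, ]],
                      distance = us[idx[2L, ]] - us[idx[1L, ]],
                      D = D, D_prime = Dp, r = r, r2 = r2, fisher_p = p,
                      sig_nominal = p < alpha, sig_bonferroni = p < bonf)
  out <- list(pairs = pairs,
              summary = list(gene_id = aln$gene_id,
                             species_id = aln$species_id,
                             n = aln$n, k_usable = k, n_pairs = np,
                             n_sig_nominal = sum(pairs$sig_nominal),
                             n_sig_bonferroni = sum(pairs$sig_bonferroni),
                             mean_r2 = mean(r2), sd_r2 = sd(r2)))
  class(out) <- "pairwise_ld"
  out
}

#' @export
print.pairwise_ld <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pairwise LD scan: %s / %s (n = %d haplotypes)\n",
              s$gene_id, s$species_id, s$n))
  cat(sprintf("  %d usable sites, %d pairs; significant: %d nominal, %d after Bonferroni\n",
              s$k_usable, s$n_pairs, s$n_sig_nominal, s$n_sig_bonferroni))
  if (s$n_pairs > 0)
    cat(sprintf("  mean r2 = %.3f (SD %.3f)\n", s$mean_r2, s$sd_r2))
  invisible(x)
}

#' LD grid and haploblocks
#'
#' Arranges pairwise r-squared values as a symmetric matrix over the usable
#' sites in genomic order (diagonal 1 by convention) and detects haploblocks:
#' maximal runs of at least two consecutive usable sites whose within-run
#' pairwise r-squared values are all at or above `block_r2_threshold`. Blocks
#' are disjoint; the scan is greedy from the left. This is a deliberate
#' simplification of confidence-interval-based block definitions: the block
#' rule is an r-squared threshold on consecutive sites.
#'
#' @param pairs a [pairwise_ld_scan()] result.
#' @param block_r2_threshold minimum within-block pairwise r-squared
#'   (default 0.8).
#' @return An object of class `"ld_grid"`: list with `sites` (0-based
#'   columns), `r2` (symmetric matrix) and `blocks` (data frame: first/last
#'   site index into `sites`, start/end columns, `n_sites`, `span_bp`).
#' @export
build_grid <- function(pairs, block_r2_threshold = 0.8) {
  stopifnot(inherits(pairs, "pairwise_ld"))
  pr <- pairs$pairs
  us <- sort(unique(c(pr$site_i, pr$site_j)))
  k <- length(us)
  if (k < 2L) stop("need at least 2 usable sites to build a grid", call. = FALSE)
  M <- matrix(NA_real_, k, k, dimnames = list(us, us))
  diag(M) <- 1
  ii <- match(pr$site_i, us); jj <- match(pr$site_j, us)
  M[cbind(ii, jj)] <- pr$r2
  M[cbind(jj, ii)] <- pr$r2
  blocks <- data.frame(first = integer(0), last = integer(0),
                       start_col = integer(0), end_col = integer(0),
                       n_sites = integer(0), span_bp = integer(0))
  i <- 1L
  while (i < k) {
    j <- i
    while (j < k && all(M[i:(j + 1L), i:(j + 1L)] >= block_r2_threshold))
      j <- j + 1L
    if (j > i) {
      blocks <- rbind(blocks, data.frame(
        first = i, last = j, start_col = us[i], end_col = us[j],
        n_sites = j - i + 1L, span_bp = us[j] - us[i]))
      i <- j + 1L
    } else i <- i + 1L
  }
  structure(list(sites = us, r2 = M, blocks = blocks,
                 block_r2_threshold = block_r2_threshold),
            class = "ld_grid")
}

#' @export
print.ld_grid <- function(x, ...) {
  cat(sprintf("LD grid over %d usable sites; %d haploblock(s) at r2 >= %g\n",
              length(x$sites), nrow(x$blocks), x$block_r2_threshold))
  if (nrow(x$blocks)) print(x$blocks)
  invisible(x)
}

#' Plot an LD grid as a raster heatmap
#'
#' Linear grey scale in r-squared from 0 (white) to 1 (black).
#'
#' @param x an [build_grid()] result.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.ld_grid <- function(x, main = "LD grid (r2)", ...) {
  k <- length(x$sites)
  graphics::image(seq_len(k), seq_len(k), x$r2[, k:1, drop = FALSE],
                  col = grDevices::grey(seq(1, 0, length.out = 101)),
                  zlim = c(0, 1), axes = FALSE, xlab = "site", ylab = "site",
                  main = main, ...)
  invisible(x)
}

#' Write pairwise LD results as TSV
#'
#' @param pairs a [pairwise_ld_scan()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairwise_ld <- function(pairs, path) {
  stopifnot(inherits(pairs, "pairwise_ld"))
  write.table(pairs$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD grid matrix as TSV
#'
#' @param grid a [build_grid()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ld_grid"))
  write.table(grid$r2, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
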