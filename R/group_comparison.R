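#' Segment boundaries that partition an alignment into near-equal parts
#'
#' @param L aligned length in bp.
#' @param n_segments number of segments (default 4).
#' @return Data frame with 0-based half-open `start`, `end` columns; segment
#'   lengths differ by at most one column, with the remainder given to the
#'   leftmost segments.
#' @export
segment_bounds <- function(L, n_segments = 4L) {
  if (L < n_segments)
    stop("configuration error: L must be >= n_segments", call. = FALSE)
  base <- L %/% n_segments
  rem <- L %% n_segments
  sizes <- base + (seq_len(n_segments) <= rem)
  ends <- cumsum(sizes)
  data.frame(segment_index = seq_len(n_segments) - 1L,
             start = c(0L, ends[-n_segments]), end = ends)
}

#' Mean r-squared per equal-length alignment segment
#'
#' Cuts the alignment into `n_segments` consecutive, near-equal-length
#' segments and averages r-squared over the SNP pairs whose two sites both
#' fall inside the same segment; pairs straddling a boundary are discarded.
#' This yields several roughly independent LD values per dataset for group
#' comparisons.
#'
#' @param pairs a [pairwise_ld_scan()] result or data frame with `site_i`,
#'   `site_j`, `r2`.
#' @param L aligned length of the underlying alignment (bp).
#' @param n_segments number of segments (default 4).
#' @param gene_id,species_id labels carried into the output (taken from the
#'   scan summary when available).
#' @return Data frame with one row per segment: `gene_id`, `species_id`,
#'   `segment_index`, `start`, `end`, `n_pairs_in_segment`, `mean_r2` (`NA`
#'   when a segment contains no pair).
#' @export
segment_means <- function(pairs, L, n_segments = 4L, gene_id = NA_character_,
                          species_id = NA_character_) {
  if (inherits(pairs, "pairwise_ld")) {
    gene_id <- pairs$summary$gene_id
    species_id <- pairs$summary$species_id
    df <- pairs$pairs
  } else df <- as.data.frame(pairs)
  sb <- segment_bounds(L, n_segments)
  seg_of <- function(col) findInterval(col, sb$start)  # 1-based segment id
  si <- seg_of(df$site_i); sj <- seg_of(df$site_j)
  out <- sb
  out$n_pairs_in_segment <- vapply(seq_len(n_segments), function(s)
    sum(si == s & sj == s), 0L)
  out$mean_r2 <- vapply(seq_len(n_segments), function(s) {
    v <- df$r2[si == s & sj == s]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  cbind(data.frame(gene_id = gene_id, species_id = species_id,
                   stringsAsFactors = FALSE), out)
}

#' Wilcoxon rank-sum test between two value lists
#'
#' Unpaired two-sided Wilcoxon (Mann-Whitney) test. The exact distribution is
#' used when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction is used, and the
#' method actually applied is reported. `NA` values are removed first.
#'
#' @param values_a,values_b numeric vectors (non-empty after `NA` removal).
#' @return List with `W`, `p` (two-sided), `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b))
    stop("insufficient data: empty value list after NA removal", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all values tied: zero variance, no evidence
  list(W = unname(wt$statistic), p = p,
       method = if (exact) "exact" else "normal_approx",
       n_a = length(a), n_b = length(b))
}

#' Pairwise Wilcoxon comparisons of mean r-squared between genes or species
#'
#' Pools segment-level (or whole-sequence) mean r-squared values by gene
#' (across species) or by species (across genes) and runs a two-sided
#' Wilcoxon rank-sum test for every pair of groups. With the study design of
#' 4 genes x 7 species and 4 segments, per-gene lists hold up to 28 values
#' and per-species lists up to 16; `NA` segments are dropped. No correction
#' for the multiple group-pair tests is applied by default.
#'
#' @param segment_summaries data frame stacking [segment_means()] rows for
#'   all datasets (columns `gene_id`, `species_id`, `mean_r2`). For the
#'   coarser whole-sequence variant pass one row per dataset with its overall
#'   mean r-squared in `mean_r2`.
#' @param grouping `"by_gene"` or `"by_species"`.
#' @param p_adjust_method multiplicity correction across group pairs
#'   (default `"none"`; any [stats::p.adjust()] method).
#' @return An object of class `"group_comparison"`: list with `grouping`,
#'   `values` (named list of pooled value vectors) and `tests` (data frame:
#'   `group_a`, `group_b`, `n_a`, `n_b`, `W`, `p`, `p_adj`, `method`).
#'   Group pairs where either side has no non-`NA` values are reported with
#'   `method = "untestable"` and `NA` statistics.
#' @export
compare_groups <- function(segment_summaries,
                           grouping = c("by_gene", "by_species"),
                           p_adjust_method = "none") {
  grouping <- match.arg(grouping)
  df <- as.data.frame(segment_summaries)
  key <- if (grouping == "by_gene") "gene_id" else "species_id"
  groups <- unique(df[[key]])
  values <- lapply(groups, function(g) {
    v <- df$mean_r2[df[[key]] == g]
    v[!is.na(v)]
  })
  names(values) <- groups
  if (length(groups) < 2L)
    stop("need at least 2 groups to compare", call. = FALSE)
  cmb <- combn(length(groups), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(q) {
    ga <- groups[cmb[1L, q]]; gb <- groups[cmb[2L, q]]
    va <- values[[ga]]; vb <- values[[gb]]
    if (!length(va) || !length(vb))
      return(data.frame(group_a = ga, group_b = gb, n_a = length(va),
                        n_b = length(vb), W = NA_real_, p = NA_real_,
                        method = "untestable", stringsAsFactors = FALSE))
    wt <- wilcoxon_rank_sum(va, vb)
    data.frame(group_a = ga, group_b = gb, n_a = wt$n_a, n_b = wt$n_b,
               W = wt$W, p = wt$p, method = wt$method,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$p_adj <- p.adjust(tests$p, method = p_adjust_method)
  structure(list(grouping = grouping, values = values, tests = tests),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s): %d groups, %d pairwise Wilcoxon tests\n",
              x$grouping, length(x$values), nrow(x$tests)))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
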