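#' Configuration for a full LD analysis run
#'
#' @param manifest either a data frame with columns `gene_id`, `species_id`
#'   and `path` (aligned multi-FASTA per dataset), or a `"study_bundle"` from
#'   [simulate_study()].
#' @param out_dir output directory (created if missing).
#' @param alpha nominal significance level for the Fisher tests (default 0.05).
#' @param n_segments number of equal-length segments for the group
#'   comparison (default 4).
#' @param block_r2_threshold haploblock threshold passed to [build_grid()].
#' @param decay_model `"hill-weir"` or `"sved"` for the parametric fit.
#' @param drop_singletons passed to [extract_sites()].
#' @param seed integer seed recorded in the run log.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(manifest, out_dir, alpha = 0.05, n_segments = 4L,
                       block_r2_threshold = 0.8, decay_model = "hill-weir",
                       drop_singletons = FALSE, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(manifest = manifest, out_dir = out_dir, alpha = alpha,
                 n_segments = n_segments,
                 block_r2_threshold = block_r2_threshold,
                 decay_model = decay_model,
                 drop_singletons = drop_singletons, seed = seed),
            class = "run_config")
}

fmt4 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 4, format = "fg"))

#' Run the full LD analysis over a gene x species design
#'
#' For every dataset: reads (or takes) the phased alignment, classifies
#' sites, computes the polymorphism summary, scans all pairwise LD with
#' exact-test significance, fits parametric and nonparametric decay curves,
#' builds the r-squared grid with haploblocks, and computes per-segment mean
#' r-squared; then runs the by-gene and by-species Wilcoxon comparisons.
#' Outputs are plain tab-separated files with `NA` for undefined cells:
#' `table1.tsv` (polymorphism summaries), `table2.tsv` (pair counts,
#' significant counts, mean and SD of r-squared), `pairwise/`, `decay/`,
#' `grids/`, `segments.tsv`, `comparison_by_gene.tsv`,
#' `comparison_by_species.tsv` and `run_log.txt` (every excluded site count
#' and non-converged fit). Headline floating-point values are printed at 4
#' significant digits; the per-pair and per-curve files keep full precision.
#' A dataset that fails to load is marked failed in the log and the run
#' continues.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, a list with `table1`, `table2`, `segments`,
#'   `comparisons`, `decay_fits`, `grids`, `scans`, `failed`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("pairwise", "decay", "grids"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  log_lines <- c(sprintf("hapld run, seed %d, alpha %g, %d segments",
                         config$seed, config$alpha, config$n_segments))
  bundle <- config$manifest
  if (inherits(bundle, "study_bundle")) {
    alns <- bundle$alignments
    man <- bundle$manifest
  } else {
    man <- as.data.frame(bundle)
    if (!nrow(man)) stop("configuration error: empty manifest", call. = FALSE)
    alns <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
      alns[[i]] <- tryCatch(
        read_alignment(man$path[i], gene_id = man$gene_id[i],
                       species_id = man$species_id[i]),
        error = function(e) e)
    }
    names(alns) <- paste(man$gene_id, man$species_id, sep = "_")
  }
  table1 <- list(); table2 <- list(); segments <- list()
  decay_fits <- list(); grids <- list(); scans <- list()
  failed <- character(0)
  for (i in seq_along(alns)) {
    id <- names(alns)[i]
    aln <- alns[[i]]
    if (inherits(aln, "error")) {
      failed <- c(failed, id)
      log_lines <- c(log_lines, sprintf("FAILED %s: %s", id,
                                        conditionMessage(aln)))
      next
    }
    st <- extract_sites(aln, drop_singletons = config$drop_singletons)
    excl <- attr(st, "n_excluded")
    log_lines <- c(log_lines, sprintf(
      "%s: S=%d usable=%d excluded={%s}", id, attr(st, "S"), attr(st, "k"),
      paste(names(excl), as.integer(excl), sep = ":", collapse = ", ")))
    table1[[id]] <- polymorphism_summary(aln,
                                         drop_singletons = config$drop_singletons)
    scan <- pairwise_ld_scan(aln, alpha = config$alpha,
                             drop_singletons = config$drop_singletons)
    scans[[id]] <- scan
    s <- scan$summary
    table2[[id]] <- data.frame(gene_id = s$gene_id, species_id = s$species_id,
                               n = s$n, n_pairs = s$n_pairs,
                               n_sig_bonferroni = s$n_sig_bonferroni,
                               n_sig_nominal = s$n_sig_nominal,
                               mean_r2 = s$mean_r2, sd_r2 = s$sd_r2,
                               stringsAsFactors = FALSE)
    write_pairwise_ld(scan, file.path(config$out_dir, "pairwise",
                                      paste0(id, ".tsv")))
    segments[[id]] <- segment_means(scan, L = aln$L,
                                    n_segments = config$n_segments)
    if (s$n_pairs >= 3L && length(unique(scan$pairs$distance)) >= 4L) {
      pfit <- fit_parametric_decay(scan, n = aln$n, model = config$decay_model)
      npfit <- tryCatch(fit_nonparametric_decay(scan),
                        error = function(e) NULL)
      decay_fits[[id]] <- list(parametric = pfit, nonparametric = npfit)
      if (!isTRUE(pfit$converged) || pfit$boundary)
        log_lines <- c(log_lines, sprintf(
          "%s: parametric decay fit %s", id,
          if (!isTRUE(pfit$converged)) paste("failed:", pfit$failure_reason)
          else "converged at boundary"))
      if (isTRUE(pfit$converged))
        write_decay_fit(pfit, file.path(config$out_dir, "decay",
                                        paste0(id, "_parametric.tsv")))
      if (!is.null(npfit))
        write_decay_fit(npfit, file.path(config$out_dir, "decay",
                                         paste0(id, "_nonparametric.tsv")))
    } else {
      log_lines <- c(log_lines, sprintf("%s: too few pairs for decay fits", id))
    }
    if (s$k_usable >= 2L) {
      g <- build_grid(scan, block_r2_threshold = config$block_r2_threshold)
      grids[[id]] <- g
      write_grid(g, file.path(config$out_dir, "grids", paste0(id, ".tsv")))
      if (nrow(g$blocks))
        log_lines <- c(log_lines, sprintf(
          "%s: %d haploblock(s), max span %d bp", id, nrow(g$blocks),
          max(g$blocks$span_bp)))
    }
  }
  t1 <- do.call(rbind, table1); rownames(t1) <- NULL
  t2 <- do.call(rbind, table2); rownames(t2) <- NULL
  segs <- do.call(rbind, segments); rownames(segs) <- NULL
  comparisons <- list()
  if (length(unique(segs$gene_id)) >= 2L)
    comparisons$by_gene <- compare_groups(segs, "by_gene")
  if (length(unique(segs$species_id)) >= 2L)
    comparisons$by_species <- compare_groups(segs, "by_species")

  t1_out <- t1
  for (cn in c("pi_total", "pi_syn", "pi_nonsyn")) t1_out[[cn]] <- fmt4(t1[[cn]])
  write.table(t1_out, file.path(config$out_dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  t2_out <- t2
  for (cn in c("mean_r2", "sd_r2")) t2_out[[cn]] <- fmt4(t2[[cn]])
  write.table(t2_out, file.path(config$out_dir, "table2.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  segs_out <- segs
  segs_out$mean_r2 <- fmt4(segs$mean_r2)
  write.table(segs_out, file.path(config$out_dir, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(comparisons)) {
    cmp_out <- comparisons[[nm]]$tests
    cmp_out$p <- fmt4(cmp_out$p); cmp_out$p_adj <- fmt4(cmp_out$p_adj)
    write.table(cmp_out,
                file.path(config$out_dir, paste0("comparison_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(table1 = t1, table2 = t2, segments = segs,
                 comparisons = comparisons, decay_fits = decay_fits,
                 grids = grids, scans = scans, failed = failed))
}
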