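#' Simulation parameters for the coalescent haplotype generator
#'
#' @param n number of sampled haplotypes (>= 2).
#' @param L sequence length in bp (>= 1).
#' @param theta per-bp population mutation rate (4Nu per site); the expected
#'   per-site pairwise diversity.
#' @param rho per-bp population recombination rate (4Nc per site); `rho * d`
#'   is the scaled recombination distance `C` between sites `d` bp apart,
#'   directly comparable to the decay-model estimate.
#' @param seed integer seed; identical `(params, seed)` give identical output.
#' @param gene_id,species_id labels for the generated alignment.
#' @param growth_rate backward exponential-growth rate in units of 1/(2N)
#'   generations (0 = constant population size). Positive values shrink the
#'   population back in time, i.e. model rapid growth, which lowers LD.
#' @param gap_rate per-cell probability of replacing a base by an alignment
#'   gap, to exercise the site-exclusion filters (default 0).
#' @param finite_sites if `TRUE`, mutations landing on an already-mutated
#'   column pick a new derived base, so recurrent mutation can create
#'   multiallelic columns (default `FALSE`: infinite sites, every segregating
#'   site biallelic).
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n, L, theta, rho, seed = NULL, gene_id = "sim_gene",
                       species_id = "sim_species", growth_rate = 0,
                       gap_rate = 0, finite_sites = FALSE) {
  stopifnot(n >= 2, L >= 1, theta >= 0, rho >= 0, growth_rate >= 0,
            gap_rate >= 0, gap_rate < 1)
  structure(list(n = as.integer(n), L = as.integer(L), theta = theta,
                 rho = rho, seed = seed, gene_id = gene_id,
                 species_id = species_id, growth_rate = growth_rate,
                 gap_rate = gap_rate, finite_sites = finite_sites),
            class = "sim_params")
}

# --- ancestral recombination graph -----------------------------------------
# Lineages carry disjoint segments of ancestral material on the continuous
# interval [0, L); each segment records the set of sampled haplotypes that
# descend from it. Time runs backward in units of 2N generations:
#   coalescence    rate 1 per lineage pair (x exp(beta t) under growth),
#   recombination  rate rho/2 per bp of breakable span per lineage,
#   mutation       rate theta/2 per bp per lineage (placed on the fly).
# Segments whose descendant set reaches the full sample have found their
# MRCA and are dropped, so mutations above the root are never produced.

seg_span <- function(segs) {
  c(min(vapply(segs, `[[`, 0, "left")), max(vapply(segs, `[[`, 0, "right")))
}

# Merge the segment lists of two coalescing lineages.
merge_segs <- function(sa, sb, n) {
  pts <- sort(unique(c(vapply(sa, `[[`, 0, "left"), vapply(sa, `[[`, 0, "right"),
                       vapply(sb, `[[`, 0, "left"), vapply(sb, `[[`, 0, "right"))))
  cover <- function(segs, mp) {
    for (s in segs) if (s$left <= mp && mp < s$right) return(s$desc)
    NULL
  }
  out <- list()
  for (i in seq_len(length(pts) - 1L)) {
    mp <- (pts[i] + pts[i + 1L]) / 2
    da <- cover(sa, mp); db <- cover(sb, mp)
    if (is.null(da) && is.null(db)) next
    desc <- sort(unique(c(da, db)))
    if (length(desc) == n) next  # region has reached its MRCA
    last <- if (length(out)) out[[length(out)]] else NULL
    if (!is.null(last) && last$right == pts[i] && identical(last$desc, desc))
      out[[length(out)]]$right <- pts[i + 1L]
    else
      out[[length(out) + 1L]] <- list(left = pts[i], right = pts[i + 1L],
                                      desc = desc)
  }
  out
}

#' Simulate phased haplotypes under the coalescent with recombination
#'
#' Samples `n` haplotypes of length `L` from the standard neutral coalescent
#' with intra-gene recombination: the ancestral recombination graph is
#' generated backward in time (recombination splits a lineage's ancestral
#' material at a uniform breakpoint, coalescence merges two lineages),
#' infinite-sites mutations are placed on branches at rate `theta/2` per bp
#' per lineage, and each mutation becomes a biallelic column with ancestral
#' state `A` and derived state `C`. Output is deterministic given the seed.
#'
#' @param params a [sim_params()] object, or `n` when using the individual
#'   arguments below.
#' @param ... individual parameters passed to [sim_params()] when `params`
#'   is not a `"sim_params"` object (e.g. `simulate_haplotypes(n = 10, L =
#'   1000, theta = 0.01, rho = 0.01, seed = 1)`).
#' @return A [haplotype_alignment()] object; attribute `"sim"` carries the
#'   parameters, continuous mutation positions, the haplotype-by-mutation 0/1
#'   matrix, and the count of mutations dropped by column collisions.
#' @export
simulate_haplotypes <- function(params, ...) {
  if (!inherits(params, "sim_params")) params <- sim_params(params, ...)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n; L <- params$L
  theta <- params$theta; rho <- params$rho; beta <- params$growth_rate
  lineages <- lapply(seq_len(n), function(i)
    list(list(left = 0, right = L, desc = i)))
  muts_pos <- numeric(0); muts_desc <- list()
  Tnow <- 0
  while (length(lineages) >= 2L) {
    k <- length(lineages)
    spans <- vapply(lineages, function(ln) diff(seg_span(ln)), 0)
    rec_rates <- rho / 2 * spans
    rec_total <- sum(rec_rates)
    k2 <- k * (k - 1) / 2
    t_rec <- if (rec_total > 0) rexp(1, rec_total) else Inf
    E <- rexp(1)
    t_coal <- if (beta == 0) E / k2 else {
      z <- 1 + beta * E * exp(-beta * Tnow) / k2
      log(z) / beta
    }
    dt <- min(t_rec, t_coal)
    # mutations on every live segment during dt
    if (theta > 0) {
      for (ln in lineages) for (s in ln) {
        m <- rpois(1L, theta / 2 * (s$right - s$left) * dt)
        if (m > 0L) {
          muts_pos <- c(muts_pos, runif(m, s$left, s$right))
          muts_desc <- c(muts_desc, rep(list(s$desc), m))
        }
      }
    }
    Tnow <- Tnow + dt
    if (t_rec < t_coal) {
      li <- sample.int(k, 1L, prob = rec_rates)
      segs <- lineages[[li]]
      sp <- seg_span(segs)
      x <- runif(1, sp[1L], sp[2L])
      left <- list(); right <- list()
      for (s in segs) {
        if (s$right <= x) left[[length(left) + 1L]] <- s
        else if (s$left >= x) right[[length(right) + 1L]] <- s
        else {
          left[[length(left) + 1L]] <- list(left = s$left, right = x, desc = s$desc)
          right[[length(right) + 1L]] <- list(left = x, right = s$right, desc = s$desc)
        }
      }
      if (length(left) && length(right)) {
        lineages[[li]] <- left
        lineages[[length(lineages) + 1L]] <- right
      }  # breakpoint in trapped material at an edge: no-op split avoided
    } else {
      pair <- sample.int(k, 2L)
      merged <- merge_segs(lineages[[pair[1L]]], lineages[[pair[2L]]], n)
      lineages[[pair[1L]]] <- merged
      lineages[[pair[2L]]] <- NULL
    }
    lineages <- Filter(length, lineages)
  }
  # realize mutations as alignment columns
  m <- matrix("A", n, L)
  dropped <- 0L
  if (length(muts_pos)) {
    ord <- order(muts_pos)
    muts_pos <- muts_pos[ord]; muts_desc <- muts_desc[ord]
    col_state <- new.env(parent = emptyenv())
    derived_cycle <- c("C", "G", "T")
    for (q in seq_along(muts_pos)) {
      cl <- floor(muts_pos[q]) + 1L
      key <- as.character(cl)
      hits <- if (is.null(col_state[[key]])) 0L else col_state[[key]]
      if (hits > 0L && !params$finite_sites) { dropped <- dropped + 1L; next }
      if (hits >= 3L) { dropped <- dropped + 1L; next }
      m[muts_desc[[q]], cl] <- derived_cycle[hits + 1L]
      col_state[[key]] <- hits + 1L
    }
  }
  if (params$gap_rate > 0) {
    gap <- runif(length(m)) < params$gap_rate
    m[gap] <- "-"
  }
  rownames(m) <- paste0("hap_", seq_len(n))
  aln <- haplotype_alignment(m, gene_id = params$gene_id,
                             species_id = params$species_id)
  geno <- if (length(muts_pos))
    do.call(cbind, lapply(muts_desc, function(d) as.integer(seq_len(n) %in% d)))
  else matrix(0L, n, 0L)
  attr(aln, "sim") <- list(params = params, positions = muts_pos,
                           genotypes = geno, n_collision_dropped = dropped)
  aln
}

#' Default gene x species simulation design
#'
#' A 4-gene x 7-taxon design mirroring a short-range LD study of immunity
#' genes across the *Anopheles gambiae* complex: per-gene aligned lengths and
#' per-bp diversities match the reported M-form values (Gambicin 1108 bp /
#' 0.0253, NOS 1238 bp / 0.0247, REL2 834 bp / 0.0099, FBN9 735 bp / 0.0159),
#' sample sizes are twice the reported individual counts (cloned phased
#' haplotypes: 32 for the M form, 10-28 elsewhere), and one dataset (REL2 in
#' *An. bwambae*) is monomorphic as observed. The default recombination rate
#' `rho = 0.01` per bp places the decay of expected r-squared below 0.3
#' within about 200 bp, the regime reported for these populations.
#'
#' @param rho per-bp recombination rate used for every dataset (default 0.01).
#' @return Data frame with one row per gene x species dataset: `gene_id`,
#'   `species_id`, `n_individuals`, `n` (haplotypes), `L`, `theta`, `rho`.
#' @export
default_study_design <- function(rho = 0.01) {
  genes <- c("Gambicin", "NOS", "REL2", "FBN9")
  L <- c(Gambicin = 1108L, NOS = 1238L, REL2 = 834L, FBN9 = 735L)
  theta <- c(Gambicin = 0.0253, NOS = 0.0247, REL2 = 0.0099, FBN9 = 0.0159)
  species <- c("gambiae_M", "gambiae_S", "arabiensis", "bwambae",
               "melas", "merus", "quadriannulatus")
  n_ind <- rbind(
    Gambicin = c(16L, 5L, 6L, 6L, 6L, 5L, 5L),
    NOS      = c(16L, 6L, 5L, 7L, 5L, 6L, 5L),
    REL2     = c(16L, 14L, 10L, 6L, 8L, 7L, 8L),
    FBN9     = c(16L, 7L, 7L, 7L, 7L, 7L, 7L))
  colnames(n_ind) <- species
  des <- expand.grid(gene_id = genes, species_id = species,
                     stringsAsFactors = FALSE)
  des$n_individuals <- n_ind[cbind(des$gene_id, des$species_id)]
  des$n <- 2L * des$n_individuals
  des$L <- L[des$gene_id]
  des$theta <- theta[des$gene_id]
  des$theta[des$gene_id == "REL2" & des$species_id == "bwambae"] <- 0
  des$rho <- rho
  rownames(des) <- NULL
  des
}

#' Simulate a full gene x species study bundle
#'
#' Runs [simulate_haplotypes()] for every row of a design (by default the
#' 4 x 7 [default_study_design()]), optionally writing one FASTA per dataset
#' plus a tab-separated manifest, so the complete analysis pipeline can run
#' end to end with no external data. Reruns with the same design and seed are
#' byte-identical.
#'
#' @param design a design data frame as from [default_study_design()].
#' @param seed master integer seed; per-dataset seeds are derived from it.
#' @param dir optional output directory for FASTA files and `manifest.tsv`.
#' @return A list of class `"study_bundle"`: `alignments` (named list of
#'   [haplotype_alignment()] objects) and `manifest` (design plus per-dataset
#'   seeds and file paths).
#' @export
simulate_study <- function(design = default_study_design(), seed = 1,
                           dir = NULL) {
  set.seed(seed)
  design$dataset_seed <- sample.int(.Machine$integer.max - 1L, nrow(design))
  alns <- vector("list", nrow(design))
  names(alns) <- paste(design$gene_id, design$species_id, sep = "_")
  for (i in seq_len(nrow(design))) {
    p <- sim_params(n = design$n[i], L = design$L[i], theta = design$theta[i],
                    rho = design$rho[i], seed = design$dataset_seed[i],
                    gene_id = design$gene_id[i],
                    species_id = design$species_id[i])
    alns[[i]] <- simulate_haplotypes(p)
  }
  design$path <- NA_character_
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(design))) {
      f <- file.path(dir, paste0(names(alns)[i], ".fa"))
      write_alignment(alns[[i]], f)
      design$path[i] <- f
    }
    write.table(design, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  structure(list(alignments = alns, manifest = design, seed = seed),
            class = "study_bundle")
}

#' Write a simulated alignment in ms-like text form
#'
#' Emits the segregating-site representation (`segsites`, `positions` on
#' [0,1), and one 0/1 haplotype row per sample) so simulator output can be
#' cross-checked against established coalescent simulators.
#'
#' @param aln an alignment produced by [simulate_haplotypes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ms_like <- function(aln, path) {
  sim <- attr(aln, "sim")
  if (is.null(sim)) stop("alignment was not produced by simulate_haplotypes",
                         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("//", paste("segsites:", length(sim$positions)),
               paste("positions:",
                     paste(sprintf("%.6f", sim$positions / aln$L),
                           collapse = " "))), con)
  if (length(sim$positions))
    writeLines(apply(sim$genotypes, 1L, paste0, collapse = ""), con)
  invisible(path)
}
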