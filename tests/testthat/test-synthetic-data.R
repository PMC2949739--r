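test_that("generator honours degenerate parameters and the seed contract", {
  mono <- simulate_haplotypes(sim_params(n = 8, L = 200, theta = 0, rho = 0.01,
                                         seed = 1))
  expect_equal(attr(extract_sites(mono), "S"), 0L)
  expect_true(all(mono$seq == "A"))

  a1 <- simulate_haplotypes(sim_params(n = 10, L = 300, theta = 0.02,
                                       rho = 0.01, seed = 99))
  a2 <- simulate_haplotypes(sim_params(n = 10, L = 300, theta = 0.02,
                                       rho = 0.01, seed = 99))
  expect_identical(a1$seq, a2$seq)
  a3 <- simulate_haplotypes(sim_params(n = 10, L = 300, theta = 0.02,
                                       rho = 0.01, seed = 100))
  expect_false(identical(a1$seq, a3$seq))

  expect_error(sim_params(n = 1, L = 10, theta = 0.01, rho = 0))
  expect_error(sim_params(n = 4, L = 10, theta = -1, rho = 0))

  # exponential-growth mode produces a valid, seeded alignment
  g1 <- simulate_haplotypes(sim_params(n = 8, L = 300, theta = 0.02,
                                       rho = 0.01, seed = 44, growth_rate = 5))
  g2 <- simulate_haplotypes(sim_params(n = 8, L = 300, theta = 0.02,
                                       rho = 0.01, seed = 44, growth_rate = 5))
  expect_identical(g1$seq, g2$seq)
  expect_s3_class(g1, "haplotype_alignment")
})

test_that("with two haplotypes and no recombination all pairs are in perfect LD", {
  for (seed in 1:5) {
    a <- simulate_haplotypes(sim_params(n = 2, L = 500, theta = 0.02, rho = 0,
                                        seed = seed))
    sc <- pairwise_ld_scan(a)
    if (sc$summary$n_pairs > 0)
      expect_true(all(abs(sc$pairs$r2 - 1) < 1e-12))
  }
})

test_that("segregating sites and diversity match Watterson/neutral expectations", {
  n <- 10; L <- 1000; theta <- 0.01; reps <- 120
  S <- pi <- numeric(reps)
  for (i in seq_len(reps)) {
    a <- simulate_haplotypes(sim_params(n = n, L = L, theta = theta, rho = 0,
                                        seed = 8000 + i))
    S[i] <- ncol(attr(a, "sim")$genotypes)
    pi[i] <- nucleotide_diversity(a)
  }
  ES <- theta * L * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - ES), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi) - theta), 3 * sd(pi) / sqrt(reps))
})

test_that("the site-frequency spectrum is proportional to 1/i", {
  n <- 10; reps <- 250
  sfs <- numeric(n - 1)
  for (i in seq_len(reps)) {
    a <- simulate_haplotypes(sim_params(n = n, L = 400, theta = 0.02, rho = 0,
                                        seed = 300 + i))
    g <- attr(a, "sim")$genotypes
    if (ncol(g)) for (d in colSums(g)) sfs[d] <- sfs[d] + 1
  }
  expected <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  observed <- sfs / sum(sfs)
  # multinomial 3-SE check per class
  se <- sqrt(expected * (1 - expected) / sum(sfs))
  expect_true(all(abs(observed - expected) < 3.5 * se))
})

test_that("recombination lowers pairwise LD at long range", {
  mean_far_r2 <- function(rho) {
    v <- sapply(1:30, function(i) {
      a <- simulate_haplotypes(sim_params(n = 16, L = 500, theta = 0.02,
                                          rho = rho, seed = 700 * (rho * 100 + 1) + i))
      sc <- pairwise_ld_scan(a)
      far <- sc$pairs$r2[sc$pairs$distance > 250]
      if (length(far)) mean(far) else NA
    })
    median(v, na.rm = TRUE)
  }
  m0 <- mean_far_r2(0); m1 <- mean_far_r2(0.02); m2 <- mean_far_r2(0.1)
  expect_gt(m0, m1)
  expect_gt(m1, m2)
})

test_that("gap injection and finite-sites mode exercise the exclusion filters", {
  a <- simulate_haplotypes(sim_params(n = 12, L = 600, theta = 0.03, rho = 0.01,
                                      seed = 17, gap_rate = 0.03))
  st <- extract_sites(a)
  expect_gt(sum(st$class == "excluded_gap"), 0L)
  expect_true(attr(st, "S") >= attr(st, "k"))
  # finite-sites mode can stack mutations into multiallelic columns
  hit <- FALSE
  for (seed in 1:8) {
    b <- simulate_haplotypes(sim_params(n = 12, L = 30, theta = 0.2, rho = 0,
                                        seed = seed, finite_sites = TRUE))
    if (any(extract_sites(b)$class == "excluded_multiallelic")) hit <- TRUE
  }
  expect_true(hit)
})

test_that("study bundles replicate the gene x species design deterministically", {
  des <- default_study_design()
  expect_equal(nrow(des), 28L)
  expect_equal(sort(unique(des$gene_id)),
               sort(c("Gambicin", "NOS", "REL2", "FBN9")))
  expect_equal(des$n, 2L * des$n_individuals)
  expect_equal(des$n[des$gene_id == "Gambicin" &
                     des$species_id == "gambiae_M"], 32L)
  expect_equal(des$theta[des$gene_id == "REL2" & des$species_id == "bwambae"], 0)

  small <- des[des$gene_id %in% c("REL2", "FBN9") &
               des$species_id %in% c("bwambae", "melas"), ]
  small$L <- 150L
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- simulate_study(small, seed = 5, dir = d1)
  b2 <- simulate_study(small, seed = 5, dir = d2)
  f1 <- list.files(d1, pattern = "\\.fa$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "\\.fa$", full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  # manifests agree apart from the output paths
  m1 <- read.table(file.path(d1, "manifest.tsv"), header = TRUE, sep = "\t")
  m2 <- read.table(file.path(d2, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_identical(m1[setdiff(names(m1), "path")],
                   m2[setdiff(names(m2), "path")])
  aln <- b1$alignments[[1]]
  expect_s3_class(aln, "haplotype_alignment")
  expect_equal(aln$L, 150L)
})

test_that("ms-like output matches the realized segregating sites", {
  a <- simulate_haplotypes(sim_params(n = 6, L = 200, theta = 0.02, rho = 0.01,
                                      seed = 23))
  f <- tempfile()
  write_ms_like(a, f)
  lines <- readLines(f)
  nseg <- as.integer(sub("segsites: ", "", lines[2]))
  expect_equal(nseg, length(attr(a, "sim")$positions))
  if (nseg > 0) {
    expect_equal(length(lines), 3L + a$n)
    expect_equal(nchar(lines[4]), nseg)
  }
})
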