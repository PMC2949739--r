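test_that("two-locus tables count allele combinations deterministically", {
  a <- aln_from_counts(c(5, 0, 0, 5))
  tab <- two_locus_counts(a, 0L, 1L)
  expect_equal(unname(tab$counts), c(5, 0, 0, 5))
  tab2 <- two_locus_counts(aln_from_counts(c(3, 3, 3, 3)), 0L, 1L)
  expect_equal(unname(tab2$counts), c(3, 3, 3, 3))
  # relabeling alleles at site j (swap C<->G so G sorts after C) swaps columns
  b <- aln_from_counts(c(4, 1, 1, 4))
  m <- b$seq
  m[, 2] <- ifelse(m[, 2] == "A", "T", m[, 2])  # old major A becomes minor T
  tab3 <- two_locus_counts(haplotype_alignment(m), 0L, 1L)
  expect_equal(unname(tab3$counts), c(1, 4, 4, 1))
  expect_error(two_locus_counts(make_aln(c("AA", "AC")), 0L, 1L),
               "filter error")
})

test_that("ld_stats matches hand-computed D, D', r and r2", {
  s <- ld_stats(c(5, 0, 0, 5))
  expect_equal(unname(s), c(0.25, 1, 1, 1))
  s0 <- ld_stats(c(3, 3, 3, 3))
  expect_equal(s0[["D"]], 0)
  expect_equal(s0[["r2"]], 0)
  s1 <- ld_stats(c(4, 1, 1, 4))
  expect_equal(s1[["D"]], 0.15)
  expect_equal(s1[["D_prime"]], 0.6)
  expect_equal(s1[["r2"]], 0.36)
  expect_error(ld_stats(c(5, 5, 0, 0)), "monomorphic margin")
})

test_that("r2 equals the squared 0/1-correlation oracle; D flips sign under relabeling", {
  set.seed(42)
  for (i in 1:1000) {
    cnt <- random_table()
    s <- ld_stats(cnt)
    v <- table_to_vectors(cnt)
    expect_lt(abs(s[["r2"]] - cor(v$x, v$y)^2), 1e-12)
    sw <- ld_stats(cnt[c(2, 1, 4, 3)])        # relabel site j
    expect_equal(sw[["D"]], -s[["D"]])
    expect_equal(sw[["r2"]], s[["r2"]], tolerance = 1e-12)
    expect_equal(sw[["D_prime"]], s[["D_prime"]], tolerance = 1e-12)
  }
})

test_that("Fisher exact p matches enumeration-derived values and the stats oracle", {
  expect_equal(fisher_exact_2x2(c(3, 3, 3, 3)), 1)
  expect_equal(fisher_exact_2x2(c(8, 0, 0, 8)), 2 / choose(16, 8))
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5)), 2 / choose(10, 5))
  set.seed(7)
  for (i in 1:200) {
    cnt <- random_table()
    p <- fisher_exact_2x2(cnt)
    expect_true(p > 0 && p <= 1)
    ref <- fisher.test(matrix(cnt, 2, byrow = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-10)
    # doubling convention equals twice the smaller hypergeometric tail
    N <- sum(cnt); rA <- cnt[1] + cnt[2]; cB <- cnt[1] + cnt[3]
    lower <- phyper(cnt[1], cB, N - cB, rA)
    upper <- 1 - phyper(cnt[1] - 1, cB, N - cB, rA)
    expect_equal(fisher_exact_2x2(cnt, method = "doubling"),
                 min(1, 2 * min(lower, upper)), tolerance = 1e-8)
  }
})

test_that("pairwise scan reports combinatorially consistent summaries", {
  a <- aln_from_counts(c(5, 0, 0, 5))
  sc <- pairwise_ld_scan(a)
  expect_equal(sc$summary$n_pairs, 1L)
  expect_equal(sc$summary$mean_r2, 1)
  expect_equal(sc$pairs$distance, 1L)

  mono <- pairwise_ld_scan(make_aln(rep("ACGT", 5)))
  expect_equal(mono$summary$n_pairs, 0L)
  expect_true(is.na(mono$summary$mean_r2))

  b <- simulate_haplotypes(sim_params(n = 16, L = 500, theta = 0.02,
                                      rho = 0.02, seed = 9))
  sc2 <- pairwise_ld_scan(b)
  k <- sc2$summary$k_usable
  expect_equal(sc2$summary$n_pairs, k * (k - 1) / 2)
  expect_lte(sc2$summary$n_sig_bonferroni, sc2$summary$n_sig_nominal)
  expect_lte(sc2$summary$n_sig_nominal, sc2$summary$n_pairs)
  expect_true(all(sc2$pairs$r2 >= 0 & sc2$pairs$r2 <= 1))
  expect_true(all(sc2$pairs$distance > 0))
  # Bonferroni flag implies nominal flag
  expect_true(all(!sc2$pairs$sig_bonferroni | sc2$pairs$sig_nominal))
})

test_that("LD grids are symmetric with unit diagonal and detect haploblocks", {
  # 3 consecutive sites in perfect LD -> one block of 3
  a <- make_aln(c("AAA", "AAA", "CCC", "CCC"))
  g <- build_grid(pairwise_ld_scan(a))
  expect_equal(g$r2, t(g$r2))
  expect_equal(unname(diag(g$r2)), rep(1, 3))
  expect_equal(nrow(g$blocks), 1L)
  expect_equal(g$blocks$n_sites, 3L)
  expect_equal(g$blocks$span_bp, 2L)

  # independence everywhere -> zero blocks
  b <- aln_from_counts(c(3, 3, 3, 3))
  g2 <- build_grid(pairwise_ld_scan(b))
  expect_equal(nrow(g2$blocks), 0L)

  # blocks are disjoint runs of >= 2 sites
  set.seed(13)
  c3 <- simulate_haplotypes(sim_params(n = 16, L = 600, theta = 0.02,
                                       rho = 0.01, seed = 13))
  sc <- pairwise_ld_scan(c3)
  g3 <- build_grid(sc)
  if (nrow(g3$blocks) > 1L)
    expect_true(all(g3$blocks$first[-1L] > g3$blocks$last[-nrow(g3$blocks)]))
  expect_true(all(g3$blocks$n_sites >= 2L))
})

test_that("pairwise and grid outputs serialize to TSV", {
  a <- simulate_haplotypes(sim_params(n = 8, L = 300, theta = 0.02,
                                      rho = 0.01, seed = 21))
  sc <- pairwise_ld_scan(a)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_pairwise_ld(sc, f1)
  expect_equal(nrow(read.table(f1, header = TRUE)), sc$summary$n_pairs)
  g <- build_grid(sc)
  write_grid(g, f2)
  m <- as.matrix(read.table(f2, header = TRUE, row.names = 1))
  expect_equal(dim(m), dim(g$r2))
})
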