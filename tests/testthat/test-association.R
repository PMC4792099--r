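test_that("control carrier counting is per distinct sample, class- and overlap-aware", {
  v <- data.frame(
    sample_id = c("S1", "S2", "S3", "S3", "S4"),
    chrom = c("1", "1", "1", "1", "1"),
    start = c(100, 290, 100, 295, 240),
    end = c(260, 400, 255, 380, 310),
    class = c("loss", "loss", "loss", "loss", "gain"),
    stringsAsFactors = FALSE)
  cs <- control_set(v)
  # S1 and S2 each overlap (250, 300) with a loss; S3 twice but counts once;
  # S4 is a gain and does not count
  expect_equal(count_control_carriers("1", 250, 300, "loss", cs), 3)
  expect_equal(count_control_carriers("1", 250, 300, "gain", cs), 1)
  expect_equal(count_control_carriers("2", 250, 300, "loss", cs), 0)
  # abutting variant does not carry
  expect_equal(count_control_carriers("1", 400, 500, "loss", cs), 0)
})

test_that("one-sided Fisher p equals the hypergeometric tail and the enumeration oracle", {
  expect_equal(fisher_exact_greater(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_greater(0, 5, 5, 0), 1.0)
  # identity with the hypergeometric upper tail on random small tables,
  # cross-checked against stats::fisher.test as an independent oracle
  set.seed(99)
  for (i in 1:100) {
    a <- sample(0:5, 1); b <- sample(0:5, 1)
    c <- sample(0:5, 1); d <- sample(0:5, 1)
    if (a + b + c + d == 0) next
    p <- fisher_exact_greater(a, b, c, d)
    expect_equal(p, hypergeom_tail(a, a + b, a + c, a + b + c + d),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2), alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_greater(0, 0, 0, 0), "empty")
})

test_that("BH adjustment reproduces hand-worked step-up lists", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 4 * 0.02 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  # element-wise: raw <= BH <= Bonferroni; monotone on sorted input
  set.seed(5)
  p <- sort(stats::runif(20))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= bonferroni(p, length(p))))
  expect_true(all(diff(q) >= -1e-15))
  expect_error(bh_adjust(c(0.2, 1.4)), "outside")
})

test_that("penetrance estimator behaves per the frequency-ratio formula", {
  # no control carriers: 100% regardless of prevalence
  for (pi in c(0.01, 0.053, 0.3))
    expect_equal(penetrance(15, 6564, 0, 5072, pi), 100)
  # equal case and control frequencies collapse to 100 * pi
  expect_equal(penetrance(30, 100, 15, 50, 0.3), 30)
  # no case carriers: 0
  expect_equal(penetrance(0, 100, 5, 50, 0.1), 0)
  # monotone: increasing in k_case, decreasing in m_ctrl
  ks <- penetrance(1:20, 100, 5, 500, 0.053)
  expect_true(all(diff(ks) > 0))
  ms <- penetrance(10, 100, 0:20, 500, 0.053)
  expect_true(all(diff(ms) < 0))
  expect_error(penetrance(1, 10, 1, 10, 1.5), "prevalence")
})

test_that("reduced-penetrance values are mutually consistent at one baseline prevalence", {
  # solving the frequency-ratio estimator for the baseline prevalence from
  # three observed (carrier count, penetrance) pairs on a 6564-case /
  # 5072-control population gives the same value, the package default
  solve_pi <- function(k, pen) {
    f_case <- k / 6564; f_ctrl <- 1 / 5072; p <- pen / 100
    p * f_ctrl / (f_case * (1 - p) + p * f_ctrl)
  }
  pis <- c(solve_pi(10, 30.2), solve_pi(9, 28), solve_pi(8, 25.7))
  expect_lt(max(pis) - min(pis), 1e-3)
  expect_equal(mean(pis), 0.053, tolerance = 0.01)
  # and the default prevalence reproduces the three penetrance values
  expect_equal(penetrance(10, 6564, 1, 5072), 30.2, tolerance = 0.01)
  expect_equal(penetrance(9, 6564, 1, 5072), 28, tolerance = 0.015)
  expect_equal(penetrance(8, 6564, 1, 5072), 25.7, tolerance = 0.015)
})

test_that("association assembly joins enrichment, Fisher, BH and penetrance", {
  onto <- mk_chain_ontology(1)
  loci <- list(list(members = paste0("P", 1:6), class = "loss", chrom = "1",
                    start = 100, end = 300, clique_id = "CL1",
                    assigned = NULL))
  enr <- clique_enrichment(
    paste0("P", 1:6),
    stats::setNames(replicate(6, c("T1", "T0"), simplify = FALSE),
                    paste0("P", 1:6)),
    c(T0 = 10L, T1 = 6L), 10, onto)
  # no control carriers anywhere
  cs <- control_set(data.frame(sample_id = "S1", chrom = "2", start = 1,
                               end = 5, class = "loss",
                               stringsAsFactors = FALSE), n_ctrl = 50)
  assoc <- associate_pels(list(loci = loci), list(CL1 = enr), cs, onto)
  expect_equal(nrow(assoc), 1)
  expect_equal(assoc$k_case, 6)
  expect_equal(assoc$m_ctrl, 0)
  expect_equal(assoc$penetrance_pct, 100)
  expect_true(assoc$significant)
  expect_equal(assoc$p_fisher_raw,
               hypergeom_tail(6, 6, 6, 6 + 0 + 0 + 50), tolerance = 1e-12)
  expect_equal(assoc$pel_id, "PEL1")

  # a locus carried by 40% of controls with an only moderate case excess:
  # the one-sided Fisher p is large and the association is dropped
  cs2 <- control_set(data.frame(sample_id = paste0("S", 1:20),
                                chrom = "1", start = 150, end = 200,
                                class = "loss", stringsAsFactors = FALSE),
                     n_ctrl = 50)
  enr2 <- data.frame(term_id = "T1", k = 3L, n = 6L, K = 6L, N = 10L,
                     p_raw = 0.01, p_adj = 0.01, n_tests = 1L, kept = TRUE,
                     rejection_reason = NA_character_,
                     stringsAsFactors = FALSE)
  assoc2 <- associate_pels(list(loci = loci), list(CL1 = enr2), cs2, onto)
  expect_equal(assoc2$m_ctrl, 20)
  expect_equal(assoc2$p_fisher_raw, hypergeom_tail(3, 6, 23, 56),
               tolerance = 1e-12)
  expect_gt(assoc2$p_fisher_raw, 0.05)
  expect_false(assoc2$significant)

  # no enriched cliques: empty but well-formed result
  empty <- associate_pels(list(loci = list()), list(), cs, onto)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("pel_id", "p_fisher_bh", "penetrance_pct") %in%
                  names(empty)))
})

test_that("syndrome overlap requires same class and >= 1 bp", {
  assoc <- data.frame(pel_id = c("PEL1", "PEL2"), chrom = c("1", "1"),
                      start = c(100, 100), end = c(300, 300),
                      class = c("loss", "gain"), stringsAsFactors = FALSE)
  syn <- data.frame(name = c("SynA", "SynB"), chrom = c("1", "1"),
                    start = c(250, 100), end = c(600, 300),
                    mutation_type = c("loss", "gain"),
                    source = "catalogue", stringsAsFactors = FALSE)
  ov <- syndrome_overlap(assoc, syn)
  expect_equal(ov$PEL1, "SynA")   # class must match, so not SynB
  expect_equal(ov$PEL2, "SynB")
  # empty catalogue: everything is a candidate novel locus
  ov0 <- syndrome_overlap(assoc, syn[0, ])
  expect_true(all(lengths(ov0) == 0))
})
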