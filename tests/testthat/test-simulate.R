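test_that("toy ontology has the promised shape", {
  onto <- make_toy_ontology(2, 3)
  expect_length(onto$ids, 13)                       # 1 + 3 + 9
  expect_equal(sum(onto$depth == 2), 9)
  chain <- make_toy_ontology(1, 1)
  expect_length(chain$ids, 2)
  # every leaf's ancestor set size equals the depth
  onto3 <- make_toy_ontology(3, 2)
  leaves <- ontology_leaves(onto3)
  expect_true(all(lengths(onto3$ancestors[leaves]) == 3))
  # OBO round-trip preserves structure
  d <- withr::local_tempdir()
  write_obo(onto, file.path(d, "toy.obo"))
  back <- read_obo(file.path(d, "toy.obo"))
  expect_setequal(back$ids, onto$ids)
  expect_equal(back$depth[onto$ids], onto$depth[onto$ids])
})

test_that("simulation honours implant structure and annotation guarantees", {
  onto <- make_toy_ontology()
  sp <- cohort_spec(n_patients = 50, n_controls = 60,
                    implants = list(implant_spec("chr1", 2e7, 2.05e7, "loss",
                                                 "HP:0000002",
                                                 n_carriers = 10,
                                                 penetrance = 1.0)),
                    noise_terms_per_patient = 0, seed = 31)
  sim <- simulate_cohort(sp, onto)
  expect_equal(nrow(sim$truth), 1)
  carriers <- strsplit(sim$truth$carriers, "|", fixed = TRUE)[[1]]
  expect_length(carriers, 10)
  # at penetrance 1 every carrier is annotated with the implant term and
  # every carrier CNV covers the locus
  for (p in carriers) {
    expect_true("HP:0000002" %in% sim$cohort$phenotypes[[p]])
    cn <- sim$cohort$cnvs[sim$cohort$cnvs$patient_id == p &
                          sim$cohort$cnvs$chrom == "chr1" &
                          sim$cohort$cnvs$class == "loss", ]
    expect_true(any(cn$start <= 2e7 & cn$end >= 2.05e7))
  }
  # every patient still has >= 1 term and >= 1 CNV even with noise off
  expect_true(all(lengths(sim$cohort$phenotypes) >= 1))
  expect_true(all(cohort_patients(sim$cohort) %in% sim$cohort$cnvs$patient_id))
  # zero-implant cohorts are valid too
  sim0 <- simulate_cohort(cohort_spec(n_patients = 20, n_controls = 20,
                                      implants = list(), seed = 3), onto)
  expect_equal(nrow(sim0$truth), 0)
  expect_true(all(lengths(sim0$cohort$phenotypes) >= 1))
})

test_that("same spec and seed give byte-identical emitted files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2))
    write_cohort_files(simulate_cohort(cohort_spec(n_patients = 60,
                                                   n_controls = 30,
                                                   seed = 17)), d)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # and a different seed changes the cohort
  a <- simulate_cohort(cohort_spec(n_patients = 60, n_controls = 30, seed = 1))
  b <- simulate_cohort(cohort_spec(n_patients = 60, n_controls = 30, seed = 2))
  expect_false(identical(a$cohort$cnvs, b$cohort$cnvs))
})

test_that("case CNVs are much longer than control variants under defaults", {
  sim <- simulate_cohort(cohort_spec(n_patients = 100, n_controls = 100,
                                     seed = 23))
  case_len <- with(sim$cohort$cnvs, end - start)
  ctrl_len <- with(sim$controls$variants, end - start)
  expect_gt(mean(case_len), 10 * mean(ctrl_len))
})

test_that("carrier annotation counts behave binomially across seeds", {
  # with penetrance p and n carriers the number of term-positive carriers is
  # Binomial(n, p): the empirical mean over seeds stays within 3 standard
  # errors of n * p
  n <- 12; p <- 0.7; reps <- 60
  onto <- make_toy_ontology()
  ks <- vapply(seq_len(reps), function(s) {
    sim <- simulate_cohort(cohort_spec(
      n_patients = 40, n_controls = 10,
      implants = list(implant_spec("chr2", 1e7, 1.06e7, "gain", "HP:0000003",
                                   n_carriers = n, penetrance = p)),
      noise_terms_per_patient = 0, control_cnv_rate = 1, seed = 4000 + s), onto)
    carriers <- strsplit(sim$truth$carriers, "|", fixed = TRUE)[[1]]
    sum(vapply(carriers, function(q)
      "HP:0000003" %in% sim$cohort$phenotypes[[q]], logical(1)))
  }, numeric(1))
  se <- sqrt(n * p * (1 - p) / reps)
  expect_lt(abs(mean(ks) - n * p), 3 * se)
})

test_that("recovery scoring matches loci by overlap, class and term lineage", {
  onto <- make_toy_ontology()
  truth <- data.frame(implant_id = "IMP1", chrom = "chr1", start = 100,
                      end = 300, class = "loss", term_id = "HP:0000050",
                      carriers = "P1|P2|P3", stringsAsFactors = FALSE)
  base <- data.frame(chrom = "chr1", start = 250, end = 400, class = "loss",
                     term_id = "HP:0000050", significant = TRUE,
                     pel_id = "PEL1", stringsAsFactors = FALSE)
  ev <- evaluate_recovery(base, truth, onto)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # an ancestor of the implant term also counts as recovery
  anc <- base; anc$term_id <- ancestors(onto, "HP:0000050")[1]
  expect_equal(evaluate_recovery(anc, truth, onto)$recall, 1)
  # wrong class does not
  wrong <- base; wrong$class <- "gain"
  expect_equal(evaluate_recovery(wrong, truth, onto)$recall, 0)
  # disjoint locus does not
  far <- base; far$start <- 1000; far$end <- 1200
  expect_equal(evaluate_recovery(far, truth, onto)$recall, 0)
  # empty association set: recall 0, precision reported as 1 and flagged
  none <- base[0, ]
  ev0 <- evaluate_recovery(none, truth, onto)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_true(ev0$empty_denominator[["associations"]])
})
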