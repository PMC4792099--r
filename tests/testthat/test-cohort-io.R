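test_that("patient CNV + annotation reading converts coordinates and drops unannotated patients", {
  d <- withr::local_tempdir()
  writeLines(c("patient_id\tchrom\tstart\tend\tclass\tinheritance",
               "P1\t1\t100\t200\tloss\tde_novo",
               "P2\t1\t150\t300\tgain\tunknown",
               "P3\t2\t500\t900\tloss\tinherited_unaffected"),
             file.path(d, "cnvs.tsv"))
  writeLines(c("patient_id\tterms",
               "P1\tHP:0000001|HP:0000002",
               "P2\tHP:0000001"),
             file.path(d, "ann.tsv"))
  co <- read_patient_cnvs(file.path(d, "cnvs.tsv"), file.path(d, "ann.tsv"))

  # 1-based inclusive 100..200 becomes half-open (99, 200), 101 bp
  expect_equal(co$cnvs$start[co$cnvs$patient_id == "P1"], 99)
  expect_equal(co$cnvs$end[co$cnvs$patient_id == "P1"], 200)
  expect_equal(diff(unlist(co$cnvs[1, c("start", "end")])), 101,
               ignore_attr = TRUE)
  # P3 has no annotation: dropped and counted
  expect_setequal(cohort_patients(co), c("P1", "P2"))
  expect_equal(co$dropped, "P3")
  expect_equal(length(co$dropped) + length(cohort_patients(co)), 3)
  expect_setequal(co$phenotypes$P1, c("HP:0000001", "HP:0000002"))
})

test_that("malformed patient files fail with informative errors", {
  d <- withr::local_tempdir()
  ann <- file.path(d, "ann.tsv")
  writeLines(c("patient_id\tterms", "P1\tHP:1"), ann)
  bad_coord <- file.path(d, "bad1.tsv")
  writeLines(c("patient_id\tchrom\tstart\tend\tclass\tinheritance",
               "P1\t1\t300\t200\tloss\tde_novo"), bad_coord)
  expect_error(read_patient_cnvs(bad_coord, ann), "end < start")
  bad_class <- file.path(d, "bad2.tsv")
  writeLines(c("patient_id\tchrom\tstart\tend\tclass\tinheritance",
               "P1\t1\t100\t200\tinversion\tde_novo"), bad_class)
  expect_error(read_patient_cnvs(bad_class, ann), "gain, loss")
  bad_inh <- file.path(d, "bad3.tsv")
  writeLines(c("patient_id\tchrom\tstart\tend\tclass\tinheritance",
               "P1\t1\t100\t200\tloss\tmaternal"), bad_inh)
  expect_error(read_patient_cnvs(bad_inh, ann), "de_novo")
  bad_num <- file.path(d, "bad4.tsv")
  writeLines(c("patient_id\tchrom\tstart\tend\tclass\tinheritance",
               "P1\t1\txx\t200\tloss\tde_novo"), bad_num)
  expect_error(read_patient_cnvs(bad_num, ann), "line 2")
})

test_that("control reading maps subtypes, skips unknowns and counts samples", {
  d <- withr::local_tempdir()
  writeLines(c("chr\tstart\tend\tvariantsubtype\tsamples",
               "1\t100\t200\tduplication\tS1",
               "1\t150\t300\tdeletion\tS1",
               "2\t500\t900\tinversion\tS2",
               "2\t10\t40\tloss\tS3",
               "3\t10\t40\tgain\tS3"),
             file.path(d, "ctrl.tsv"))
  cs <- read_control_variants(file.path(d, "ctrl.tsv"))
  expect_equal(nrow(cs$variants), 4)           # inversion skipped
  expect_equal(cs$n_skipped, 1L)
  expect_setequal(unique(cs$variants$class), c("gain", "loss"))
  expect_equal(cs$variants$class[1], "gain")   # duplication -> gain
  expect_equal(cs$n_ctrl, 2L)                  # distinct samples S1, S3 (S2 row skipped)
  # n_ctrl override honoured (control sizes need not equal sample counts)
  cs2 <- read_control_variants(file.path(d, "ctrl.tsv"), n_ctrl = 5072)
  expect_equal(cs2$n_ctrl, 5072L)
  # missing column errors by name
  writeLines(c("chr\tstart\tend", "1\t1\t2"), file.path(d, "noc.tsv"))
  expect_error(read_control_variants(file.path(d, "noc.tsv")),
               "variantsubtype")
})

test_that("a single-sample multi-record control file keeps one distinct sample", {
  d <- withr::local_tempdir()
  writeLines(c("chr\tstart\tend\tvariantsubtype\tsamples",
               paste0(1:5, "\t10\t90\tdeletion\tS9")),
             file.path(d, "one.tsv"))
  cs <- read_control_variants(file.path(d, "one.tsv"))
  expect_equal(nrow(cs$variants), 5)
  expect_equal(cs$n_ctrl, 1L)
})

test_that("cohort write/read round-trip reproduces records field by field", {
  sim <- small_sim(seed = 5)
  d <- withr::local_tempdir()
  write_patient_cnvs(sim$cohort, file.path(d, "c.tsv"), file.path(d, "a.tsv"))
  back <- read_patient_cnvs(file.path(d, "c.tsv"), file.path(d, "a.tsv"))
  expect_equal(back$cnvs, sim$cohort$cnvs)
  expect_equal(back$phenotypes, sim$cohort$phenotypes)
  # coordinate conversion is an involution on the printed values
  raw <- utils::read.delim(file.path(d, "c.tsv"))
  expect_equal(to_external_start(to_internal_start(raw$start)), raw$start)
})

test_that("PEL table writing orders rows, converts coordinates and emits BED", {
  d <- withr::local_tempdir()
  assoc <- data.frame(
    pel_id = c("PEL2", "PEL1"), clique_id = c("CL1", "CL2"),
    chrom = c("1", "2"), start = c(250, 100), end = c(300, 400),
    class = c("loss", "gain"), term_id = c("T1", "T2"),
    term_name = c("t one", "t two"), k_case = c(3L, 4L),
    n_clique = c(3L, 5L), K_case = c(10L, 9L), N_case = c(100L, 100L),
    m_ctrl = c(0L, 1L), N_ctrl = c(50L, 50L),
    p_enrich = c(1e-4, 1e-5), p_fisher_raw = c(0.002, 0.001),
    p_fisher_bh = c(0.004, 0.002), penetrance_pct = c(100, 88),
    significant = c(TRUE, TRUE), stringsAsFactors = FALSE)
  write_pel_table(assoc, file.path(d, "pels.tsv"), file.path(d, "pels.bed"))
  tab <- utils::read.delim(file.path(d, "pels.tsv"))
  expect_equal(tab$pel_id, c("PEL1", "PEL2"))        # ascending BH p
  expect_equal(tab$start, c(101, 251))               # 1-based in the table
  bed <- utils::read.delim(file.path(d, "pels.bed"), header = FALSE)
  expect_equal(bed$V2[bed$V4 == "PEL2"], 250)        # 0-based in BED
  expect_equal(bed$V3[bed$V4 == "PEL2"], 300)

  # empty association list: header-only table, empty BED
  empty <- assoc[0, ]
  write_pel_table(empty, file.path(d, "e.tsv"), file.path(d, "e.bed"))
  expect_equal(nrow(utils::read.delim(file.path(d, "e.tsv"))), 0)
  expect_equal(file.size(file.path(d, "e.bed")), 0)
})
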