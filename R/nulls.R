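## Five randomization null models and the repeated-experiment harness.
## Each model preserves a stated set of marginals exactly:
##   dgv_cnvs          - patient ids, per-patient CNV counts, phenotypes
##   case_location     - CNV lengths, per-chromosome counts, ownership
##   control_location  - as above, on the control set
##   rewire_patient_cnv- global CNV multiset, per-patient CNV counts
##   shuffle_phenotypes- phenotype profiles as whole sets, term frequencies

NULL_KINDS <- c("dgv_cnvs", "case_location", "control_location",
                "rewire_patient_cnv", "shuffle_phenotypes")

#' Null model: replace patient CNVs by control variants
#'
#' Each case CNV is replaced by a control variant drawn without replacement
#' (interval and class taken from the control record); patient ids,
#' per-patient CNV counts, inheritance labels and phenotype profiles are
#' unchanged.
#'
#' @param cohort a [pel_cohort].
#' @param controls a [control_set] with at least as many variants as the
#'   cohort has CNVs.
#' @param seed integer RNG seed.
#' @return a new [pel_cohort].
#' @export
null_dgv_cnvs <- function(cohort, controls, seed) {
  v <- controls$variants
  ncnv <- nrow(cohort$cnvs)
  if (nrow(v) < ncnv)
    stop("need at least ", ncnv, " control variants, have ", nrow(v))
  set.seed(seed)
  pick <- sample.int(nrow(v), ncnv, replace = FALSE)
  cnvs <- cohort$cnvs
  cnvs$chrom <- v$chrom[pick]
  cnvs$start <- v$start[pick]
  cnvs$end <- v$end[pick]
  cnvs$class <- v$class[pick]
  pel_cohort(cnvs, cohort$phenotypes, dropped = cohort$dropped)
}

#' Null model: shuffle CNV locations along their chromosomes
#'
#' Every CNV keeps its chromosome, length and class; its start is redrawn
#' uniformly from the positions at which it still fits the chromosome. This
#' preserves the CNV length distribution and the per-chromosome CNV counts
#' exactly.
#'
#' @param cnvs data.frame with chrom/start/end columns (case CNVs or
#'   control variants).
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param seed integer RNG seed.
#' @return the data.frame with new start/end columns.
#' @export
null_shuffle_locations <- function(cnvs, genome, seed) {
  len <- cnvs$end - cnvs$start
  chrom_len <- genome[cnvs$chrom]
  if (anyNA(chrom_len)) stop("chromosome missing from genome: ",
                             cnvs$chrom[which(is.na(chrom_len))[1]])
  if (any(len > chrom_len))
    stop("CNV longer than its chromosome")
  set.seed(seed)
  # uniform over {0, ..., chrom_len - len}
  new_start <- floor(stats::runif(nrow(cnvs)) * (chrom_len - len + 1))
  new_start <- pmin(new_start, chrom_len - len)
  cnvs$start <- new_start
  cnvs$end <- new_start + len
  cnvs
}

#' @rdname null_shuffle_locations
#' @param cohort a [pel_cohort].
#' @export
null_case_locations <- function(cohort, genome, seed) {
  pel_cohort(null_shuffle_locations(cohort$cnvs, genome, seed),
             cohort$phenotypes, dropped = cohort$dropped)
}

#' @rdname null_shuffle_locations
#' @param controls a [control_set].
#' @export
null_control_locations <- function(controls, genome, seed) {
  control_set(null_shuffle_locations(controls$variants, genome, seed),
              n_ctrl = controls$n_ctrl, n_skipped = controls$n_skipped)
}

#' Null model: rewire patient-CNV relations
#'
#' The multiset of CNVs (interval, class, inheritance) is randomly permuted
#' across patients while each patient keeps its CNV count; phenotypes are
#' unchanged.
#'
#' @param cohort a [pel_cohort].
#' @param seed integer RNG seed.
#' @return a new [pel_cohort].
#' @export
null_rewire_patient_cnv <- function(cohort, seed) {
  if (length(cohort$phenotypes) < 2L) stop("need at least 2 patients")
  set.seed(seed)
  cnvs <- cohort$cnvs
  perm <- sample.int(nrow(cnvs))
  shuffled <- cnvs[perm, setdiff(names(cnvs), "patient_id"), drop = FALSE]
  shuffled$patient_id <- cnvs$patient_id
  shuffled <- shuffled[, names(cnvs), drop = FALSE]
  rownames(shuffled) <- NULL
  pel_cohort(shuffled, cohort$phenotypes, dropped = cohort$dropped)
}

#' Null model: shuffle phenotype profiles across patients
#'
#' Whole phenotype term sets are permuted across patients, so every profile
#' survives intact and every term keeps exactly its original patient
#' frequency; genotypes are unchanged.
#'
#' @param cohort a [pel_cohort].
#' @param seed integer RNG seed.
#' @return a new [pel_cohort].
#' @export
null_shuffle_phenotypes <- function(cohort, seed) {
  ids <- names(cohort$phenotypes)
  set.seed(seed)
  perm <- sample.int(length(ids))
  phen <- stats::setNames(cohort$phenotypes[perm], ids)
  pel_cohort(cohort$cnvs, phen, dropped = cohort$dropped)
}

#' Generate one null dataset of a given kind
#'
#' @param kind one of \code{"dgv_cnvs"}, \code{"case_location"},
#'   \code{"control_location"}, \code{"rewire_patient_cnv"},
#'   \code{"shuffle_phenotypes"}.
#' @param cohort a [pel_cohort].
#' @param controls a [control_set].
#' @param genome chromosome lengths (needed for the location kinds).
#' @param seed integer RNG seed.
#' @return list with elements \code{cohort} and \code{controls} (one of them
#'   randomized).
#' @export
make_null_dataset <- function(kind, cohort, controls, genome = NULL, seed) {
  kind <- match.arg(kind, NULL_KINDS)
  if (kind %in% c("case_location", "control_location") && is.null(genome))
    stop("genome is required for location-shuffling nulls")
  switch(kind,
    dgv_cnvs = list(cohort = null_dgv_cnvs(cohort, controls, seed),
                    controls = controls),
    case_location = list(cohort = null_case_locations(cohort, genome, seed),
                         controls = controls),
    control_location = list(cohort = cohort,
                            controls = null_control_locations(controls,
                                                              genome, seed)),
    rewire_patient_cnv = list(cohort = null_rewire_patient_cnv(cohort, seed),
                              controls = controls),
    shuffle_phenotypes = list(cohort = null_shuffle_phenotypes(cohort, seed),
                              controls = controls))
}

#' Run repeated null experiments
#'
#' For each repetition a null dataset of the requested kind is generated and
#' the full discovery pipeline is run; the number of significant PELs and
#' the sub-threshold Fisher p-values are recorded. Repetition seeds are
#' derived deterministically from \code{seed}, so (kind, seed) fixes every
#' output.
#'
#' @param cohort a [pel_cohort].
#' @param ontology a [phenotype_ontology].
#' @param controls a [control_set].
#' @param kind null-model kind (see [make_null_dataset]).
#' @param n_reps number of repetitions (the original study design uses
#'   1000; tests and examples use 20-50).
#' @param seed master seed.
#' @param genome chromosome lengths for the location kinds.
#' @param config a [pel_config].
#' @return object of class \code{"null_run"}: list with \code{kind},
#'   \code{pel_counts} (significant-PEL count per rep) and \code{fisher_p}
#'   (list of the per-rep significant Fisher p-values).
#' @export
run_null_experiments <- function(cohort, ontology, controls, kind,
                                 n_reps = 1000L, seed = 1L, genome = NULL,
                                 config = pel_config()) {
  kind <- match.arg(kind, NULL_KINDS)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  counts <- integer(n_reps)
  fisher_p <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    nd <- make_null_dataset(kind, cohort, controls, genome, rep_seeds[r])
    res <- find_pels(nd$cohort, ontology, nd$controls, config = config)
    sig <- significant_associations(res)
    counts[r] <- length(unique(sig$pel_id))
    fisher_p[[r]] <- sig$p_fisher_raw
  }
  structure(list(kind = kind, pel_counts = counts, fisher_p = fisher_p,
                 n_reps = n_reps, seed = seed),
            class = "null_run")
}

#' @export
print.null_run <- function(x, ...) {
  cat(sprintf("Null run '%s': %d reps; significant PELs per rep: median %s (range %s-%s)\n",
              x$kind, x$n_reps, stats::median(x$pel_counts),
              min(x$pel_counts), max(x$pel_counts)))
  invisible(x)
}

#' Write a null-run summary TSV
#' @param runs a \code{null_run} or list of them.
#' @param path output path.
#' @export
write_null_summary <- function(runs, path) {
  if (inherits(runs, "null_run")) runs <- list(runs)
  rows <- do.call(rbind, lapply(runs, function(x)
    data.frame(kind = x$kind, rep = seq_along(x$pel_counts),
               n_pels = x$pel_counts,
               n_significant = lengths(x$fisher_p),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
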