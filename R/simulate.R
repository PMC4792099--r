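## Seeded synthetic cohorts with implanted ground-truth loci. The generator
## emulates the structure of real case/control CNV studies: heavy-tailed
## (log-normal) CNV lengths with case CNVs around two orders of magnitude
## longer than control variants, patients carrying one or a few CNVs, sparse
## multi-term phenotype profiles, implanted loci whose carriers share a
## phenotype at a set penetrance, and a near-uniform control background.

#' Default synthetic genome
#'
#' Eight chromosomes of 125 Mb (1 Gb total): a scaled-down stand-in for a
#' mammalian genome. The size is chosen so that, with the default cohort
#' parameters, the background CNV-overlap network has a density within an
#' order of magnitude of large real patient networks (~0.005) rather than
#' the much denser graphs a small toy genome would produce.
#' @return named numeric vector of chromosome lengths.
#' @export
default_genome <- function() {
  stats::setNames(rep(1.25e8, 8), paste0("chr", 1:8))
}

#' Build a deterministic toy ontology
#'
#' A rooted tree with \code{branching} children per term down to
#' \code{depth} levels (so \code{branching^d} terms at depth d), with
#' sequential HP-style ids. Useful as a stand-in for a real phenotype
#' ontology in simulations and tests. The default size (depth 3, branching
#' 6: 259 terms, 216 leaves) keeps per-leaf annotation frequencies around
#' one percent of the cohort under the default noise rate, emulating the
#' sparsity of real clinical-ontology annotation, where cohorts carry
#' thousands of distinct terms.
#'
#' @param depth tree depth (root has depth 0).
#' @param branching children per internal term.
#' @return a [phenotype_ontology].
#'
#' @examples
#' make_toy_ontology(2, 3)  # 1 + 3 + 9 = 13 terms
#' @export
make_toy_ontology <- function(depth = 3L, branching = 6L) {
  stopifnot(depth >= 1, branching >= 1)
  counter <- 1L
  new_id <- function() {
    id <- sprintf("HP:%07d", counter); counter <<- counter + 1L; id
  }
  parents <- list()
  level <- new_id()
  parents[[level]] <- character(0)
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) for (b in seq_len(branching)) {
      id <- new_id()
      parents[[id]] <- p
      nxt <- c(nxt, id)
    }
    level <- nxt
  }
  nm <- stats::setNames(paste("synthetic term", names(parents)),
                        names(parents))
  phenotype_ontology(parents, names = nm)
}

#' Leaf terms of an ontology
#' @param ontology a [phenotype_ontology].
#' @return character vector of terms that are no other term's parent.
#' @export
ontology_leaves <- function(ontology) {
  setdiff(ontology$ids, unique(unlist(ontology$parents, use.names = FALSE)))
}

#' Write an ontology as an OBO flat file
#' @param ontology a [phenotype_ontology].
#' @param path output path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in ontology$ids) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", ontology$term_name[[id]]),
                 paste0("is_a: ", ontology$parents[[id]])), con)
  }
  invisible(NULL)
}

#' Specify an implanted ground-truth locus
#'
#' @param chrom,start,end the locus (0-based half-open).
#' @param class "gain" or "loss".
#' @param term_id phenotype term shared by carriers.
#' @param n_carriers number of carrier patients (>= 3 for a recoverable
#'   implant, since cliques need three members).
#' @param penetrance probability that a carrier is annotated with the term.
#' @param flank_scale mean (bp) of the exponential random extension of each
#'   carrier CNV beyond the locus; variable breakpoints are what make the
#'   minimal common intersection of the carrier CNVs hug the implant.
#' @return a list of class \code{"implant_spec"}.
#' @export
implant_spec <- function(chrom, start, end, class, term_id, n_carriers = 12L,
                         penetrance = 0.9, flank_scale = 2e5) {
  stopifnot(start >= 0, end > start, class %in% CNV_CLASSES,
            n_carriers >= 1, penetrance > 0, penetrance <= 1,
            flank_scale > 0)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 class = class, term_id = term_id,
                 n_carriers = as.integer(n_carriers),
                 penetrance = penetrance, flank_scale = flank_scale),
            class = "implant_spec")
}

#' Default ground-truth implants
#'
#' Three loci of 0.5-0.8 Mb on distinct chromosomes (two deletions, one
#' duplication), each with 12 carriers at penetrance 0.9, tagged with three
#' distinct leaf terms of the ontology.
#'
#' @param ontology a [phenotype_ontology].
#' @return list of [implant_spec].
#' @export
default_implants <- function(ontology) {
  leaves <- ontology_leaves(ontology)
  pick <- leaves[round(c(1, (1 + length(leaves)) / 2, length(leaves)))]
  list(
    implant_spec("chr1", 3.0e7, 3.08e7, "loss", pick[1]),
    implant_spec("chr2", 5.0e7, 5.06e7, "gain", pick[2]),
    implant_spec("chr3", 1.0e7, 1.05e7, "loss", pick[3]))
}

#' Specify a synthetic cohort
#'
#' Defaults emulate a scaled-down case/control CNV study: 200 patients and
#' 500 control samples; case background CNVs log-normal with mean ~3 Mb and
#' control variants log-normal with mean ~31 kb (the two-orders-of-magnitude
#' case/control length contrast of real repositories); about one background
#' CNV per patient (every patient carries at least one CNV) and sparse
#' phenotype profiles averaging ~1.5 terms with at least one term each.
#'
#' @param genome named chromosome lengths.
#' @param n_patients,n_controls cohort sizes.
#' @param implants list of [implant_spec], or NULL for [default_implants]
#'   built on the ontology at simulation time.
#' @param background_cnv_rate mean background CNVs per patient (Poisson;
#'   non-carriers are topped up to one CNV).
#' @param control_cnv_rate mean variants per control sample (Poisson, min
#'   1). The default of 98 matches the per-sample variant count of large
#'   population structural-variant repositories (hundreds of thousands of
#'   mostly short variants over a few thousand samples), giving the control
#'   population genome-wide coverage; chance case loci then always have
#'   control carriers, which is what lets the case-control Fisher stage
#'   separate implanted loci from background ones.
#' @param case_length_log_mean,case_length_log_sd log-scale parameters of
#'   case background CNV lengths.
#' @param control_length_log_mean,control_length_log_sd same for control
#'   variants.
#' @param noise_terms_per_patient mean number of uniformly drawn leaf noise
#'   terms per patient (Poisson; empty profiles are topped up to one term).
#' @param leak_rate probability that a control sample carries a variant
#'   covering each implant locus (0 by default: implants are absent from
#'   controls, giving 100% estimated penetrance; raise it to exercise
#'   reduced penetrance and Fisher rejection).
#' @param seed integer RNG seed.
#' @return a list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(genome = default_genome(), n_patients = 200L,
                        n_controls = 500L, implants = NULL,
                        background_cnv_rate = 1.0, control_cnv_rate = 98,
                        case_length_log_mean = log(1.5e6),
                        case_length_log_sd = 1.2,
                        control_length_log_mean = log(2e4),
                        control_length_log_sd = 0.9,
                        noise_terms_per_patient = 1.0,
                        leak_rate = 0, seed = 1L) {
  stopifnot(n_patients > 0, n_controls > 0, background_cnv_rate >= 0,
            control_cnv_rate >= 0, leak_rate >= 0, leak_rate <= 1)
  structure(list(genome = genome, n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls), implants = implants,
                 background_cnv_rate = background_cnv_rate,
                 control_cnv_rate = control_cnv_rate,
                 case_length_log_mean = case_length_log_mean,
                 case_length_log_sd = case_length_log_sd,
                 control_length_log_mean = control_length_log_mean,
                 control_length_log_sd = control_length_log_sd,
                 noise_terms_per_patient = noise_terms_per_patient,
                 leak_rate = leak_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one batch of background CNV rows at uniform positions / log-normal lengths
random_cnvs <- function(n, genome, log_mean, log_sd, p_loss) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = genome / sum(genome))
  chrom_len <- genome[chrom]
  len <- pmax(1, round(stats::rlnorm(n, log_mean, log_sd)))
  len <- pmin(len, floor(chrom_len / 2))   # cap pathological tail draws
  start <- floor(stats::runif(n) * (chrom_len - len + 1))
  data.frame(chrom = chrom, start = start, end = start + len,
             class = ifelse(stats::runif(n) < p_loss, "loss", "gain"),
             stringsAsFactors = FALSE)
}

#' Simulate a case cohort, control population and ground-truth table
#'
#' For each implant, \code{n_carriers} patients receive a CNV covering the
#' full locus extended on both sides by exponential flanks, and carry the
#' implant term with probability \code{penetrance}. All patients receive
#' Poisson background CNVs and Poisson uniform leaf noise terms (topped up
#' so every patient has >= 1 CNV and >= 1 term). Controls receive background
#' variants from the (much shorter) control length distribution, plus
#' implant-covering variants at rate \code{leak_rate}. Inheritance labels
#' and gain/loss class proportions are drawn to match the typical case and
#' control composition of real repositories. Identical (spec, seed) pairs
#' give identical output.
#'
#' @param spec a [cohort_spec].
#' @param ontology a [phenotype_ontology]; default [make_toy_ontology].
#' @return a list of class \code{"pel_simulation"} with \code{cohort}
#'   ([pel_cohort]), \code{controls} ([control_set]), \code{truth}
#'   (data.frame of implants with carrier ids), \code{ontology} and
#'   \code{spec}.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            ontology = make_toy_ontology()) {
  stopifnot(inherits(spec, "cohort_spec"))
  implants <- spec$implants
  if (is.null(implants)) implants <- default_implants(ontology)
  for (im in implants) {
    if (!im$chrom %in% names(spec$genome) || im$end > spec$genome[im$chrom])
      stop("implant locus does not fit chromosome ", im$chrom)
    if (!im$term_id %in% ontology$ids)
      stop("implant term not in ontology: ", im$term_id)
  }
  set.seed(spec$seed)
  ids <- sprintf("P%04d", seq_len(spec$n_patients))
  leaves <- ontology_leaves(ontology)
  inh_probs <- c(de_novo = 0.30, inherited_unaffected = 0.23,
                 inherited_affected = 0.03, unknown = 0.44)

  # implant carriers: disjoint across implants
  pool <- ids
  carrier_sets <- list()
  for (i in seq_along(implants)) {
    im <- implants[[i]]
    if (length(pool) < im$n_carriers) stop("not enough patients for implants")
    carrier_sets[[i]] <- sort(sample(pool, im$n_carriers))
    pool <- setdiff(pool, carrier_sets[[i]])
  }

  cnv_rows <- list()
  phenotypes <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(implants)) {
    im <- implants[[i]]
    for (p in carrier_sets[[i]]) {
      s <- max(0, im$start - round(stats::rexp(1, 1 / im$flank_scale)))
      e <- min(spec$genome[[im$chrom]],
               im$end + round(stats::rexp(1, 1 / im$flank_scale)))
      cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
        patient_id = p, chrom = im$chrom, start = s, end = e,
        class = im$class, stringsAsFactors = FALSE)
      if (stats::runif(1) < im$penetrance)
        phenotypes[[p]] <- c(phenotypes[[p]], im$term_id)
    }
  }
  carriers_all <- unlist(carrier_sets)

  n_bg <- stats::rpois(length(ids), spec$background_cnv_rate)
  n_bg[!(ids %in% carriers_all)] <- pmax(1L, n_bg[!(ids %in% carriers_all)])
  bg <- random_cnvs(sum(n_bg), spec$genome, spec$case_length_log_mean,
                    spec$case_length_log_sd, p_loss = 0.55)
  bg$patient_id <- rep(ids, n_bg)
  cols <- c("patient_id", "chrom", "start", "end", "class")
  cnvs <- bg[, cols]
  if (length(cnv_rows))
    cnvs <- rbind(do.call(rbind, cnv_rows)[, cols], cnvs)
  cnvs$inheritance <- sample(names(inh_probs), nrow(cnvs), replace = TRUE,
                             prob = inh_probs)
  cnvs <- cnvs[order(match(cnvs$patient_id, ids), cnvs$chrom, cnvs$start), ]
  rownames(cnvs) <- NULL

  n_noise <- stats::rpois(length(ids), spec$noise_terms_per_patient)
  noise <- sample(leaves, sum(n_noise), replace = TRUE)
  split_noise <- split(noise, rep(seq_along(ids), n_noise))
  for (j in seq_along(ids)) {
    extra <- if (as.character(j) %in% names(split_noise))
      split_noise[[as.character(j)]] else character(0)
    phenotypes[[j]] <- unique(c(phenotypes[[j]], extra))
    if (!length(phenotypes[[j]]))          # guarantee >= 1 term
      phenotypes[[j]] <- sample(leaves, 1)
  }

  cid <- sprintf("C%04d", seq_len(spec$n_controls))
  n_cv <- pmax(1L, stats::rpois(spec$n_controls, spec$control_cnv_rate))
  cv <- random_cnvs(sum(n_cv), spec$genome, spec$control_length_log_mean,
                    spec$control_length_log_sd, p_loss = 0.69)
  cv$sample_id <- rep(cid, n_cv)
  if (spec$leak_rate > 0) {
    for (im in implants) {
      leak <- cid[stats::runif(spec$n_controls) < spec$leak_rate]
      if (!length(leak)) next
      s <- pmax(0, im$start - round(stats::rexp(length(leak),
                                                1 / im$flank_scale)))
      e <- pmin(spec$genome[[im$chrom]],
                im$end + round(stats::rexp(length(leak), 1 / im$flank_scale)))
      cv <- rbind(cv, data.frame(chrom = im$chrom, start = s, end = e,
                                 class = im$class, sample_id = leak,
                                 stringsAsFactors = FALSE))
    }
  }
  controls <- control_set(cv[, c("sample_id", "chrom", "start", "end",
                                 "class")],
                          n_ctrl = spec$n_controls)

  truth <- do.call(rbind, lapply(seq_along(implants), function(i) {
    im <- implants[[i]]
    data.frame(implant_id = paste0("IMP", i), chrom = im$chrom,
               start = im$start, end = im$end, class = im$class,
               term_id = im$term_id,
               carriers = paste(carrier_sets[[i]], collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(implant_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        class = character(0), term_id = character(0),
                        carriers = character(0), stringsAsFactors = FALSE)
  cohort <- pel_cohort(cnvs, phenotypes)
  attr(cohort, "genome") <- spec$genome
  structure(list(cohort = cohort, controls = controls, truth = truth,
                 ontology = ontology, spec = spec),
            class = "pel_simulation")
}

#' @export
print.pel_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort (seed %d): %d patients / %d controls, %d implanted loci\n",
              x$spec$seed, x$spec$n_patients, x$spec$n_controls,
              nrow(x$truth)))
  print(x$cohort)
  invisible(x)
}

#' Score recovery of implanted loci
#'
#' An implant counts as recovered when some significant association overlaps
#' its locus by >= 1 bp with the same gain/loss class and a term equal to
#' (or an ancestor of) the implant term. Recall is recovered / implants;
#' precision is matched significant associations / all significant
#' associations. Empty denominators are reported as 1 and flagged.
#'
#' @param associations data.frame from [associate_pels] or a
#'   \code{pel_result}.
#' @param truth truth table from [simulate_cohort].
#' @param ontology the [phenotype_ontology] used in the run.
#' @return list with \code{recall}, \code{precision}, \code{recovered}
#'   (logical per implant), \code{matched} (logical per significant
#'   association) and \code{empty_denominator} flags.
#' @export
evaluate_recovery <- function(associations, truth, ontology) {
  if (inherits(associations, "pel_result"))
    associations <- associations$associations
  sig <- associations[associations$significant, , drop = FALSE]
  match_one <- function(i) {
    ok_term <- sig$term_id == truth$term_id[i] |
      vapply(sig$term_id, function(t)
        t %in% ontology$ancestors[[truth$term_id[i]]], logical(1))
    ok <- sig$chrom == truth$chrom[i] & sig$class == truth$class[i] &
      sig$start < truth$end[i] & sig$end > truth$start[i] & ok_term
    ok
  }
  hits <- matrix(FALSE, nrow = nrow(sig), ncol = nrow(truth))
  for (i in seq_len(nrow(truth))) hits[, i] <- match_one(i)
  recovered <- apply(hits, 2, any)
  matched <- apply(hits, 1, any)
  empty <- c(implants = nrow(truth) == 0L, associations = nrow(sig) == 0L)
  list(recall = if (nrow(truth)) mean(recovered) else 1.0,
       precision = if (nrow(sig)) mean(matched) else 1.0,
       recovered = recovered, matched = matched,
       empty_denominator = empty)
}

#' Write all synthetic-cohort files
#'
#' Emits the exact input formats of the readers: \code{cnvs.tsv} and
#' \code{annotations.tsv} (patient cohort), \code{controls.tsv} (DGV
#' dialect), \code{ontology.obo}, plus \code{truth.tsv} and a
#' \code{spec.yaml} echo of the generating parameters.
#'
#' @param sim a \code{pel_simulation}.
#' @param dir output directory.
#' @export
write_cohort_files <- function(sim, dir) {
  stopifnot(inherits(sim, "pel_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_cnvs(sim$cohort, file.path(dir, "cnvs.tsv"),
                     file.path(dir, "annotations.tsv"))
  write_control_variants(sim$controls, file.path(dir, "controls.tsv"))
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  tr <- sim$truth
  tr$start <- to_external_start(tr$start)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- sim$spec
  sp$implants <- lapply(if (is.null(sp$implants))
    default_implants(sim$ontology) else sp$implants, unclass)
  sp$genome <- as.list(sp$genome)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(NULL)
}
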