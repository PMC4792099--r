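## PEL characterization: case-control Fisher association of each enriched
## clique locus against the control population, BH correction across all
## candidate associations, Cooper-style penetrance, and syndrome overlap.

#' Count control samples carrying a variant over a locus
#'
#' Number of distinct control samples having at least one variant of the
#' same class overlapping the locus by >= 1 bp. When the control file had no
#' sample column each record counts as its own sample.
#'
#' @param chrom,start,end the locus (0-based half-open).
#' @param cnv_class "gain" or "loss".
#' @param controls a [control_set].
#' @return integer count.
#' @export
count_control_carriers <- function(chrom, start, end, cnv_class, controls) {
  v <- controls$variants
  hit <- v$chrom == chrom & v$class == cnv_class &
    v$start < end & v$end > start
  length(unique(v$sample_id[hit]))
}

#' One-sided (cases-enriched) Fisher exact test
#'
#' Exact upper-tail p for the 2x2 table \code{[[a, b], [c, d]]} with
#' a = phenotype-positive clique members, b = remaining cohort patients with
#' the phenotype, c = control carriers of the locus, d = remaining controls.
#' Computed from the hypergeometric distribution of \code{a} given the table
#' margins (the same kernel as [hypergeom_tail]).
#'
#' @param a,b,c,d non-negative cell counts (vectorised).
#' @param alternative \code{"greater"} (default, cases enriched) or
#'   \code{"two.sided"}.
#' @return exact p-value.
#' @examples
#' fisher_exact_greater(3, 1, 1, 3)  # 17/70
#' @export
fisher_exact_greater <- function(a, b, c, d,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  N <- a + b + c + d
  if (any(N == 0)) stop("empty contingency table")
  if (alternative == "greater")
    return(hypergeom_tail(a, a + b, a + c, N))
  # two-sided: sum of all outcome probabilities <= that of the observed table
  mapply(function(a, b, c, d) {
    supp <- max(0, a + b - (b + d)):min(a + b, a + c)
    dens <- stats::dhyper(supp, a + c, b + d, a + b)
    sum(dens[dens <= stats::dhyper(a, a + c, b + d, a + b) * (1 + 1e-7)])
  }, a, b, c, d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cooper-style penetrance estimate
#'
#' Frequency-ratio estimator: with case carrier frequency
#' f_case = k_case / N_case, control carrier frequency
#' f_ctrl = m_ctrl / N_ctrl and baseline phenotype prevalence \code{pi},
#' the penetrance is \code{100 * f_case * pi / (f_case * pi + f_ctrl *
#' (1 - pi))}. It is 100 whenever no control carries the locus, and 0 when
#' no case does.
#'
#' @param k_case phenotype-positive clique members.
#' @param N_case annotated cohort size.
#' @param m_ctrl control carriers of the locus.
#' @param N_ctrl control population size.
#' @param prevalence baseline prevalence pi in (0, 1); default 0.053.
#' @return penetrance as a percentage in [0, 100] (vectorised).
#' @export
penetrance <- function(k_case, N_case, m_ctrl, N_ctrl, prevalence = 0.053) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly between 0 and 1")
  if (any(N_case <= 0 | N_ctrl <= 0)) stop("population sizes must be positive")
  f_case <- k_case / N_case
  f_ctrl <- m_ctrl / N_ctrl
  num <- f_case * prevalence
  den <- num + f_ctrl * (1 - prevalence)
  ifelse(den == 0, 0, 100 * num / den)
}

#' Turn enriched cliques into PEL associations
#'
#' One candidate association is generated per (qualified clique locus,
#' surviving enriched term). Each is tested against the control population
#' with the one-sided Fisher exact test; BH adjustment is applied across all
#' candidate associations jointly, associations with adjusted p below
#' \code{alpha} are flagged pathogenic, and penetrance is estimated for all.
#' PEL identifiers are assigned by ascending adjusted p, then genomic order.
#'
#' @param loci result of [clique_loci] (or its \code{loci} element).
#' @param enrichments named list clique_id -> enrichment data.frame from
#'   [clique_enrichment].
#' @param controls a [control_set].
#' @param ontology a [phenotype_ontology] (for term names).
#' @param alpha association significance threshold (default 0.05).
#' @param prevalence baseline prevalence for [penetrance].
#' @param alternative Fisher sidedness, \code{"greater"} by default.
#' @return data.frame of candidate associations (one row each) with locus
#'   coordinates, counts, p_enrich, p_fisher_raw, p_fisher_bh,
#'   penetrance_pct and the \code{significant} flag.
#' @export
associate_pels <- function(loci, enrichments, controls, ontology,
                           alpha = 0.05, prevalence = 0.053,
                           alternative = "greater") {
  if (!is.null(loci$loci)) loci <- loci$loci
  rows <- list()
  for (l in loci) {
    enr <- enrichments[[l$clique_id]]
    if (is.null(enr)) next
    enr <- enr[enr$kept, , drop = FALSE]
    if (!nrow(enr)) next
    m_ctrl <- count_control_carriers(l$chrom, l$start, l$end, l$class,
                                     controls)
    for (i in seq_len(nrow(enr))) {
      rows[[length(rows) + 1L]] <- data.frame(
        clique_id = l$clique_id, chrom = l$chrom, start = l$start,
        end = l$end, class = l$class, term_id = enr$term_id[i],
        term_name = unname(ontology$term_name[enr$term_id[i]]),
        k_case = enr$k[i], n_clique = enr$n[i], K_case = enr$K[i],
        N_case = enr$N[i], m_ctrl = m_ctrl, N_ctrl = controls$n_ctrl,
        p_enrich = enr$p_adj[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pel_id = character(0), clique_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      term_id = character(0), term_name = character(0),
                      k_case = integer(0), n_clique = integer(0),
                      K_case = integer(0), N_case = integer(0),
                      m_ctrl = integer(0), N_ctrl = integer(0),
                      p_enrich = numeric(0), p_fisher_raw = numeric(0),
                      p_fisher_bh = numeric(0), penetrance_pct = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_fisher_raw <- fisher_exact_greater(
    out$k_case, out$K_case - out$k_case, out$m_ctrl,
    out$N_ctrl - out$m_ctrl, alternative = alternative)
  out$p_fisher_bh <- bh_adjust(out$p_fisher_raw)
  out$penetrance_pct <- penetrance(out$k_case, out$N_case, out$m_ctrl,
                                   out$N_ctrl, prevalence = prevalence)
  out$significant <- out$p_fisher_bh < alpha
  ord <- order(out$p_fisher_bh, out$chrom, out$start, out$end, out$term_id)
  out <- out[ord, , drop = FALSE]
  # one PEL id per distinct locus, numbered in the sorted order
  locus_key <- paste(out$chrom, out$start, out$end, out$class, sep = "\r")
  out$pel_id <- paste0("PEL", match(locus_key, unique(locus_key)))
  rownames(out) <- NULL
  out[, c("pel_id", setdiff(names(out), "pel_id"))]
}

#' Overlap PELs with a known-syndrome catalogue
#'
#' A PEL matches a syndrome when their intervals overlap by >= 1 bp and the
#' PEL's CNV class equals the syndrome's mutation type (a deletion locus is
#' only matched by deletion syndromes). PELs matching nothing are candidate
#' novel loci.
#'
#' @param associations data.frame from [associate_pels].
#' @param syndromes data.frame from [read_syndromes] (may have 0 rows).
#' @return named list pel_id -> character vector of matching syndrome names
#'   (possibly empty).
#' @export
syndrome_overlap <- function(associations, syndromes) {
  pels <- associations[!duplicated(associations$pel_id),
                       c("pel_id", "chrom", "start", "end", "class")]
  res <- lapply(seq_len(nrow(pels)), function(i) {
    if (is.null(syndromes) || !nrow(syndromes)) return(character(0))
    hit <- syndromes$chrom == pels$chrom[i] &
      syndromes$mutation_type == pels$class[i] &
      syndromes$start < pels$end[i] & syndromes$end > pels$start[i]
    syndromes$name[hit]
  })
  stats::setNames(res, pels$pel_id)
}
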