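## Phenotype enrichment of cliques: exact hypergeometric upper tail,
## Bonferroni correction per clique, and the three selection thresholds
## (adjusted P < alpha, >= 3 annotated members, >= 50% of the clique).

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability of observing \code{k} or more annotated patients in a sample
#' of \code{n} drawn without replacement from a population of \code{N}
#' patients of which \code{K} are annotated. This is the enrichment
#' statistic and also the kernel of the one-sided Fisher exact test.
#'
#' @param k observed annotated patients in the sample (vectorised).
#' @param n sample size (clique size).
#' @param K annotated patients in the population.
#' @param N population size.
#' @return P(X >= k), exact upper tail.
#' @examples
#' hypergeom_tail(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 1 | k > n | k > K | n > N | K > N))
    stop("hypergeom_tail: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m number of tests in the family (>= 1).
#' @return min(1, p * m).
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(1, p * m)
}

#' Phenotype enrichment of one clique
#'
#' Every term carried (after propagation) by at least one clique member is
#' tested with [hypergeom_tail] against its cohort-wide frequency; the
#' per-clique Bonferroni family size m is the number of terms tested.
#' A term is kept when (1) its (by default Bonferroni-adjusted) p is below
#' \code{alpha}, (2) at least \code{min_annotated} members carry it and
#' (3) at least \code{min_fraction} of the clique carries it. Survivors are
#' then pruned for ontological redundancy ([prune_redundant]), keeping the
#' most significant representative of every ancestor-descendant pair.
#'
#' @param members character vector of clique member ids.
#' @param annotations named list patient id -> (propagated) term set.
#' @param cohort_term_counts named integer vector term -> number of cohort
#'   patients carrying the term (under the same propagation setting).
#' @param N annotated cohort size.
#' @param ontology a [phenotype_ontology] (for redundancy pruning).
#' @param alpha significance threshold (default 0.05).
#' @param min_annotated minimum annotated members (default 3).
#' @param min_fraction minimum annotated fraction of the clique (default 0.5).
#' @param threshold_on \code{"adjusted"} (default) thresholds the
#'   Bonferroni-adjusted p, \code{"raw"} the raw p.
#' @return data.frame with one row per tested term: term_id, k, n, K, N,
#'   p_raw, p_adj, n_tests, kept, rejection_reason; pruned terms are marked
#'   \code{kept = FALSE} with reason \code{"redundant"}.
#' @export
clique_enrichment <- function(members, annotations, cohort_term_counts, N,
                              ontology, alpha = 0.05, min_annotated = 3L,
                              min_fraction = 0.5,
                              threshold_on = c("adjusted", "raw")) {
  threshold_on <- match.arg(threshold_on)
  miss <- setdiff(members, names(annotations))
  if (length(miss)) stop("member missing from annotation map: ", miss[1])
  n <- length(members)
  term_k <- table(unlist(annotations[members], use.names = FALSE))
  terms <- names(term_k)
  m <- length(terms)
  k <- as.integer(term_k)
  K <- as.integer(cohort_term_counts[terms])
  if (anyNA(K) || any(k > K))
    stop("cohort term counts inconsistent with clique annotation counts")
  p_raw <- hypergeom_tail(k, n, K, N)
  p_adj <- bonferroni(p_raw, m)
  p_sel <- if (threshold_on == "adjusted") p_adj else p_raw
  kept <- p_sel < alpha & k >= min_annotated & k / n >= min_fraction
  reason <- rep(NA_character_, m)
  reason[p_sel >= alpha] <- "p"
  reason[k < min_annotated & is.na(reason)] <- "min_annotated"
  reason[k / n < min_fraction & is.na(reason)] <- "min_fraction"
  if (any(kept)) {
    surv <- prune_redundant(ontology, terms[kept], p_raw[kept])
    pruned <- which(kept)[!surv]
    kept[pruned] <- FALSE
    reason[pruned] <- "redundant"
  }
  data.frame(term_id = terms, k = k, n = n, K = K, N = N,
             p_raw = p_raw, p_adj = p_adj, n_tests = m, kept = kept,
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Cohort-wide term counts
#'
#' Number of patients carrying each term, from a propagated (or raw)
#' annotation map; used as the population counts K of the enrichment test.
#'
#' @param annotations named list patient id -> term set.
#' @return named integer vector.
#' @export
cohort_term_counts <- function(annotations) {
  tab <- table(unlist(lapply(annotations, unique), use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}
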