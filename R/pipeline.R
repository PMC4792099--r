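## End-to-end PEL discovery: network -> cliques -> enrichment -> association.

#' Pipeline configuration
#'
#' Thresholds and correction choices of the discovery pipeline. Defaults:
#' enrichment alpha 0.05 applied to the per-clique Bonferroni-adjusted p, at
#' least 3 annotated members covering at least 50% of the clique; Fisher
#' association one-sided (cases enriched) with BH adjustment across all
#' candidate associations at alpha 0.05; annotation propagation on;
#' penetrance baseline prevalence 0.053.
#'
#' @param alpha_enrich enrichment significance threshold.
#' @param min_annotated minimum annotated clique members.
#' @param min_fraction minimum annotated fraction of the clique.
#' @param alpha_assoc association (Fisher, BH-adjusted) threshold.
#' @param prevalence baseline phenotype prevalence for [penetrance].
#' @param min_clique minimum clique size.
#' @param propagate propagate annotations up the ontology before counting.
#' @param threshold_on threshold enrichment on \code{"adjusted"} or
#'   \code{"raw"} p-values.
#' @param fisher_alternative \code{"greater"} or \code{"two.sided"}.
#' @return a list of class \code{"pel_config"}.
#' @export
pel_config <- function(alpha_enrich = 0.05, min_annotated = 3L,
                       min_fraction = 0.5, alpha_assoc = 0.05,
                       prevalence = 0.053, min_clique = 3L,
                       propagate = TRUE,
                       threshold_on = c("adjusted", "raw"),
                       fisher_alternative = c("greater", "two.sided")) {
  stopifnot(alpha_enrich > 0, alpha_enrich <= 1, alpha_assoc > 0,
            alpha_assoc <= 1, min_fraction > 0, min_fraction <= 1,
            prevalence > 0, prevalence < 1, min_clique >= 2)
  structure(list(alpha_enrich = alpha_enrich,
                 min_annotated = as.integer(min_annotated),
                 min_fraction = min_fraction, alpha_assoc = alpha_assoc,
                 prevalence = prevalence, min_clique = as.integer(min_clique),
                 propagate = isTRUE(propagate),
                 threshold_on = match.arg(threshold_on),
                 fisher_alternative = match.arg(fisher_alternative)),
            class = "pel_config")
}

#' Discover Phenotypically Enriched Loci (PELs)
#'
#' Runs the full discovery pipeline on a patient cohort: builds the
#' CNV-overlap patient network, enumerates maximal cliques (size >=
#' \code{config$min_clique}), keeps cliques whose members share a common
#' mutated region, scores every clique for phenotype enrichment
#' (hypergeometric + per-clique Bonferroni + the three selection
#' thresholds), tests each surviving locus-phenotype pair against the
#' control population (one-sided Fisher, BH across all candidates) and
#' estimates penetrance. Optionally overlaps the significant PELs with a
#' known-syndrome catalogue.
#'
#' @param cohort a [pel_cohort].
#' @param ontology a [phenotype_ontology] covering all annotated terms.
#' @param controls a [control_set].
#' @param config a [pel_config].
#' @param syndromes optional syndrome data.frame from [read_syndromes].
#' @param topology also compute network topology statistics (skipped when
#'   FALSE to save time in repeated null runs).
#' @return an object of class \code{"pel_result"}: list with
#'   \code{associations} (data.frame, all candidates with a
#'   \code{significant} flag), \code{loci}, \code{enrichments},
#'   \code{graph}, \code{topology}, \code{syndrome_matches}, \code{counts}
#'   (the stage-by-stage funnel) and \code{config}.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_patients = 60, n_controls = 100,
#'                                    seed = 1))
#' res <- find_pels(sim$cohort, sim$ontology, sim$controls)
#' res
#' @export
find_pels <- function(cohort, ontology, controls, config = pel_config(),
                      syndromes = NULL, topology = FALSE) {
  stopifnot(inherits(cohort, "pel_cohort"),
            inherits(ontology, "phenotype_ontology"),
            inherits(controls, "control_set"),
            inherits(config, "pel_config"))
  annotations <- if (config$propagate)
    propagate_annotations(ontology, cohort) else cohort$phenotypes
  term_counts <- cohort_term_counts(annotations)
  N <- length(annotations)

  graph <- build_patient_graph(cohort)
  topo <- if (topology && igraph::ecount(graph$graph) > 0)
    topology_stats(graph) else NULL

  loci <- if (igraph::ecount(graph$graph) > 0)
    clique_loci(graph, cohort, min_size = config$min_clique)
  else list(loci = list(), n_cliques = 0L, n_rejected = 0L)

  enrichments <- list()
  for (l in loci$loci) {
    enrichments[[l$clique_id]] <- clique_enrichment(
      l$members, annotations, term_counts, N, ontology,
      alpha = config$alpha_enrich, min_annotated = config$min_annotated,
      min_fraction = config$min_fraction,
      threshold_on = config$threshold_on)
  }
  associations <- associate_pels(loci, enrichments, controls, ontology,
                                 alpha = config$alpha_assoc,
                                 prevalence = config$prevalence,
                                 alternative = config$fisher_alternative)
  sig <- associations[associations$significant, , drop = FALSE]
  matches <- if (!is.null(syndromes)) syndrome_overlap(sig, syndromes) else NULL
  counts <- list(
    n_patients = length(cohort$phenotypes),
    n_dropped = length(cohort$dropped),
    n_nodes = igraph::vcount(graph$graph),
    n_isolated = length(graph$isolated),
    n_edges = igraph::ecount(graph$graph),
    n_cliques = loci$n_cliques,
    n_rejected_cliques = loci$n_rejected,
    n_qualified_loci = length(loci$loci),
    n_candidate_associations = nrow(associations),
    n_significant_associations = nrow(sig),
    n_pels = length(unique(sig$pel_id)))
  structure(list(associations = associations, loci = loci,
                 enrichments = enrichments, graph = graph, topology = topo,
                 syndrome_matches = matches, counts = counts,
                 config = config),
            class = "pel_result")
}

#' @export
print.pel_result <- function(x, ...) {
  ct <- x$counts
  cat("PEL discovery\n")
  cat(sprintf("  cohort: %d patients (%d dropped without phenotypes)\n",
              ct$n_patients, ct$n_dropped))
  cat(sprintf("  network: %d nodes / %d edges (%d isolated patients excluded)\n",
              ct$n_nodes, ct$n_edges, ct$n_isolated))
  cat(sprintf("  cliques: %d maximal (>= %d members), %d without a common region, %d qualified loci\n",
              ct$n_cliques, x$config$min_clique, ct$n_rejected_cliques,
              ct$n_qualified_loci))
  cat(sprintf("  associations: %d candidate -> %d significant (BH p < %g) across %d PELs\n",
              ct$n_candidate_associations, ct$n_significant_associations,
              x$config$alpha_assoc, ct$n_pels))
  if (!is.null(x$syndrome_matches)) {
    nm <- sum(lengths(x$syndrome_matches) > 0)
    cat(sprintf("  syndrome overlap: %d of %d PELs match a known syndrome; %d candidate novel\n",
                nm, length(x$syndrome_matches),
                length(x$syndrome_matches) - nm))
  }
  invisible(x)
}

#' Summarise a discovery run
#' @param object a \code{pel_result}.
#' @param n number of top associations to display.
#' @param ... unused.
#' @method summary pel_result
#' @export
summary.pel_result <- function(object, n = 10L, ...) {
  sig <- object$associations[object$associations$significant, , drop = FALSE]
  print(object)
  if (nrow(sig)) {
    cat(sprintf("\nTop associations (of %d significant):\n", nrow(sig)))
    show <- utils::head(sig[, c("pel_id", "class", "chrom", "start", "end",
                                "term_id", "k_case", "n_clique", "m_ctrl",
                                "p_fisher_bh", "penetrance_pct")], n)
    show$start <- to_external_start(show$start)
    show$p_fisher_bh <- signif(show$p_fisher_bh, 3)
    show$penetrance_pct <- round(show$penetrance_pct, 1)
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' All candidate associations of a result as a data.frame
#' @param x a \code{pel_result}.
#' @param ... unused.
#' @method as.data.frame pel_result
#' @export
as.data.frame.pel_result <- function(x, ...) x$associations

#' Significant associations of a result
#' @param x a \code{pel_result}.
#' @return data.frame of associations with BH-adjusted Fisher p below the
#'   configured threshold.
#' @export
significant_associations <- function(x) {
  stopifnot(inherits(x, "pel_result"))
  x$associations[x$associations$significant, , drop = FALSE]
}

#' Write all artifacts of a discovery run
#'
#' Writes the association TSV + BED ([write_pel_table]), the clique dump,
#' the network edge list, topology statistics as JSON and a JSON run
#' summary with the stage-by-stage funnel counts and configuration.
#'
#' @param result a \code{pel_result}.
#' @param dir output directory (created if needed).
#' @export
write_pel_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pel_table(result$associations, file.path(dir, "associations.tsv"),
                  file.path(dir, "pels.bed"))
  write_clique_table(result$loci, file.path(dir, "cliques.tsv"))
  write_edge_list(result$graph, file.path(dir, "edges.tsv"))
  if (!is.null(result$topology))
    jsonlite::write_json(unclass(result$topology),
                         file.path(dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA)
  summary <- c(result$counts, list(config = unclass(result$config)))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
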