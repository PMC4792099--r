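## Genotype-based patient network: nodes are patients, an edge connects two
## patients whenever some CNV of one overlaps (>= 1 bp, same chromosome,
## same gain/loss class) some CNV of the other.

#' Do two CNVs overlap?
#'
#' Two CNVs overlap when they lie on the same chromosome, belong to the same
#' class (both gains or both losses) and share at least one base pair
#' (half-open test: \code{a$start < b$end && b$start < a$end}).
#'
#' @param a,b lists/rows with fields \code{chrom}, \code{start}, \code{end},
#'   \code{class} (0-based half-open coordinates).
#' @return logical.
#' @export
cnvs_overlap <- function(a, b) {
  isTRUE(a$chrom == b$chrom) && isTRUE(a$class == b$class) &&
    a$start < b$end && b$start < a$end
}

# All same-class same-chromosome overlapping CNV row pairs (i < j) of a CNV
# data.frame, found with an IRanges self-overlap join per (chrom, class).
overlapping_cnv_pairs <- function(cnvs) {
  groups <- split(seq_len(nrow(cnvs)),
                  paste(cnvs$chrom, cnvs$class, sep = "\r"))
  pairs <- lapply(groups, function(idx) {
    if (length(idx) < 2L) return(NULL)
    ir <- IRanges::IRanges(start = cnvs$start[idx] + 1L, end = cnvs$end[idx])
    hits <- IRanges::findOverlaps(ir, ir, minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sel <- qi < si
    if (!any(sel)) return(NULL)
    cbind(idx[qi[sel]], idx[si[sel]])
  })
  do.call(rbind, pairs)
}

#' Build the CNV-overlap patient network
#'
#' An edge is created between two distinct patients whenever any CNV of one
#' overlaps any CNV of the other per [cnvs_overlap]; every supporting CNV
#' pair is recorded. Patients with no overlap partner are not network nodes
#' (they cannot enter any clique) but are listed in the \code{isolated}
#' field.
#'
#' @param cohort a [pel_cohort].
#' @return object of class \code{"patient_graph"}: list with \code{graph}
#'   (an undirected \pkg{igraph} graph whose vertex names are patient ids),
#'   \code{support} (data.frame patient_a/patient_b/cnv_a/cnv_b/class, CNV
#'   columns indexing rows of \code{cohort$cnvs}), and \code{isolated}.
#' @export
build_patient_graph <- function(cohort) {
  stopifnot(inherits(cohort, "pel_cohort"))
  if (length(cohort$phenotypes) < 2L) stop("need at least 2 patients")
  cnvs <- cohort$cnvs
  pr <- overlapping_cnv_pairs(cnvs)
  support <- if (is.null(pr)) {
    data.frame(patient_a = character(0), patient_b = character(0),
               cnv_a = integer(0), cnv_b = integer(0),
               class = character(0), stringsAsFactors = FALSE)
  } else {
    pa <- cnvs$patient_id[pr[, 1]]; pb <- cnvs$patient_id[pr[, 2]]
    sel <- pa != pb            # a patient's own CNVs never make a self-edge
    swap <- pa[sel] > pb[sel]  # canonical order for unordered pairs
    a <- ifelse(swap, pb[sel], pa[sel]); b <- ifelse(swap, pa[sel], pb[sel])
    ca <- ifelse(swap, pr[sel, 2], pr[sel, 1])
    cb <- ifelse(swap, pr[sel, 1], pr[sel, 2])
    data.frame(patient_a = a, patient_b = b, cnv_a = ca, cnv_b = cb,
               class = cnvs$class[pr[sel, 1]], stringsAsFactors = FALSE)
  }
  edges <- unique(support[, c("patient_a", "patient_b")])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  isolated <- setdiff(cohort_patients(cohort), igraph::V(g)$name)
  structure(list(graph = g, support = support, isolated = isolated),
            class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat(sprintf("Patient network: %d nodes, %d edges, %d supporting CNV pairs, %d isolated patients excluded\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$support), length(x$isolated)))
  invisible(x)
}

#' Write the network as an edge-list TSV
#' @param graph a \code{patient_graph}.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  s <- graph$support
  key <- paste(s$patient_a, s$patient_b, sep = "\t")
  agg <- data.frame(patient_a = s$patient_a, patient_b = s$patient_b,
                    stringsAsFactors = FALSE)[!duplicated(key), ]
  agg$n_supports <- as.integer(table(key)[paste(agg$patient_a, agg$patient_b,
                                                sep = "\t")])
  agg$classes <- vapply(paste(agg$patient_a, agg$patient_b, sep = "\t"),
                        function(k) paste(sort(unique(s$class[key == k])),
                                          collapse = "|"), character(1))
  utils::write.table(agg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Topological parameters of the patient network
#'
#' Density and average degree follow the usual undirected-graph formulas
#' (2E / N(N-1) and 2E / N); the clustering coefficient is the mean local
#' clustering over all nodes (degree-<2 nodes contribute 0); the diameter is
#' the maximum eccentricity within the largest connected component; shortest
#' paths are counted and averaged over ordered pairs of distinct nodes lying
#' in the same component.
#'
#' @param graph a \code{patient_graph} or an \pkg{igraph} graph.
#' @param paths compute the (more expensive) shortest-path statistics;
#'   default TRUE.
#' @return object of class \code{"topology_stats"} (a named list).
#' @export
topology_stats <- function(graph, paths = TRUE) {
  g <- if (inherits(graph, "patient_graph")) graph$graph else graph
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (e == 0L) stop("topology_stats: graph has no edges")
  comp <- igraph::components(g)
  biggest <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  out <- list(
    n_nodes = n, n_edges = e,
    density = 2 * e / (n * (n - 1)),
    avg_degree = 2 * e / n,
    avg_clustering = igraph::transitivity(g, type = "localaverage",
                                          isolates = "zero"),
    n_components = comp$no,
    diameter = if (paths) igraph::diameter(biggest, directed = FALSE) else NA,
    n_shortest_paths = sum(comp$csize * (comp$csize - 1)),
    avg_shortest_path = if (paths)
      igraph::mean_distance(g, directed = FALSE, unconnected = TRUE) else NA)
  structure(out, class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat("Network topology\n")
  cat(sprintf("  nodes %d  edges %d  components %d\n",
              x$n_nodes, x$n_edges, x$n_components))
  cat(sprintf("  density %.3f  avg degree %.3f  avg clustering %.3f\n",
              x$density, x$avg_degree, x$avg_clustering))
  cat(sprintf("  diameter %s  shortest paths %s  avg path length %s\n",
              format(x$diameter), format(x$n_shortest_paths),
              format(round(x$avg_shortest_path, 3))))
  invisible(x)
}
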