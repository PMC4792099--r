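## Clique mining: maximal cliques of size >= 3, filtered down to cliques
## whose members all carry a same-class CNV over one common genomic region
## ("qualified" cliques); each such region yields a candidate locus.

#' Maximal cliques of the patient network
#'
#' Enumerates every maximal clique with at least \code{min_size} members,
#' each member set reported exactly once, with no upper size cap. Collecting
#' the maximal cliques containing each node and merging identical member
#' sets yields the same list; enumerating deduplicated maximal cliques
#' directly is equivalent and cheaper.
#'
#' @param graph a \code{patient_graph} or \pkg{igraph} graph.
#' @param min_size minimum clique size (default 3).
#' @return list of character vectors of patient ids (sorted within clique).
#' @export
maximal_cliques <- function(graph, min_size = 3L) {
  if (min_size < 2L) stop("min_size must be >= 2")
  g <- if (inherits(graph, "patient_graph")) graph$graph else graph
  cl <- igraph::max_cliques(g, min = min_size)
  lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
}

#' Resolve the common locus (or loci) of a clique
#'
#' Pairwise CNV overlap does not guarantee that all clique members share one
#' genomic region (a long CNV can bridge members that overlap it at disjoint
#' positions). For each gain/loss class and chromosome this function sweeps
#' the members' CNV coverage and keeps the positions covered by at least one
#' CNV of that class from \emph{every} member. Each maximal run of such
#' positions yields one candidate locus: every member is assigned one CNV
#' overlapping the run (ties broken by longest, then leftmost CNV) and the
#' locus is the minimal common intersection (max start, min end) of the
#' assigned CNVs. A clique with no commonly covered position is rejected.
#'
#' For members carrying a single CNV on the chromosome, pairwise overlap
#' implies a common point (1-D Helly property), so single-CNV cliques always
#' resolve.
#'
#' @param members character vector of patient ids (the clique).
#' @param cohort a [pel_cohort].
#' @return list of clique-locus records, each a list with \code{members},
#'   \code{class}, \code{chrom}, \code{start}, \code{end} (the locus) and
#'   \code{assigned} (data.frame patient_id/cnv row index/start/end);
#'   empty list when the clique is rejected.
#' @export
resolve_clique_locus <- function(members, cohort) {
  cnvs <- cohort$cnvs
  rows <- cnvs[cnvs$patient_id %in% members, , drop = FALSE]
  rows$row <- as.integer(rownames(rows))
  out <- list()
  for (cls in unique(rows$class)) {
    sub_c <- rows[rows$class == cls, , drop = FALSE]
    for (chr in unique(sub_c$chrom)) {
      sub <- sub_c[sub_c$chrom == chr, , drop = FALSE]
      if (length(unique(sub$patient_id)) < length(members)) next
      # positions covered by every member: intersect per-member coverage
      cov <- NULL
      ok <- TRUE
      for (m in members) {
        mi <- sub[sub$patient_id == m, , drop = FALSE]
        ir <- IRanges::reduce(IRanges::IRanges(mi$start + 1L, mi$end))
        cov <- if (is.null(cov)) ir else IRanges::intersect(cov, ir)
        if (!length(cov)) { ok <- FALSE; break }
      }
      if (!ok) next
      for (ri in seq_along(cov)) {
        r_start <- IRanges::start(cov)[ri] - 1L  # back to half-open
        r_end <- IRanges::end(cov)[ri]
        assigned <- do.call(rbind, lapply(members, function(m) {
          mi <- sub[sub$patient_id == m, , drop = FALSE]
          hit <- mi[mi$start < r_end & mi$end > r_start, , drop = FALSE]
          hit <- hit[order(-(hit$end - hit$start), hit$start), , drop = FALSE]
          hit[1, c("patient_id", "row", "start", "end"), drop = FALSE]
        }))
        locus <- tryCatch(common_intersection(chr, assigned$start, assigned$end),
                          error = function(e) NULL)
        if (is.null(locus)) next
        out[[length(out) + 1L]] <- list(
          members = sort(members), class = cls, chrom = chr,
          start = locus$start, end = locus$end, assigned = assigned)
      }
    }
  }
  out
}

#' Find all qualified clique loci of a cohort
#'
#' Convenience wrapper: enumerate maximal cliques of \code{graph} and
#' resolve each through [resolve_clique_locus], deduplicating identical
#' (members, class, locus) records.
#'
#' @param graph a \code{patient_graph}.
#' @param cohort the [pel_cohort] the graph was built from.
#' @param min_size minimum clique size.
#' @return list with \code{loci} (list of clique-locus records, each given a
#'   \code{clique_id}), \code{n_cliques} (maximal cliques found) and
#'   \code{n_rejected} (cliques with no common region).
#' @export
clique_loci <- function(graph, cohort, min_size = 3L) {
  cliques <- maximal_cliques(graph, min_size = min_size)
  loci <- list(); n_rejected <- 0L
  for (cl in cliques) {
    res <- resolve_clique_locus(cl, cohort)
    if (!length(res)) n_rejected <- n_rejected + 1L else
      loci <- c(loci, res)
  }
  if (length(loci)) {
    key <- vapply(loci, function(l)
      paste(paste(l$members, collapse = "|"), l$class, l$chrom, l$start,
            l$end, sep = "\r"), character(1))
    loci <- loci[!duplicated(key)]
    for (i in seq_along(loci)) loci[[i]]$clique_id <- paste0("CL", i)
  }
  list(loci = loci, n_cliques = length(cliques), n_rejected = n_rejected)
}

#' Write the clique-locus dump
#' @param loci result of [clique_loci].
#' @param path output TSV path.
#' @export
write_clique_table <- function(loci, path) {
  rows <- lapply(loci$loci, function(l)
    data.frame(clique_id = l$clique_id, size = length(l$members),
               members = paste(l$members, collapse = "|"), class = l$class,
               chrom = l$chrom, locus_start = l$start, locus_end = l$end,
               stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clique_id = character(0), size = integer(0),
               members = character(0), class = character(0),
               chrom = character(0), locus_start = numeric(0),
               locus_end = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
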