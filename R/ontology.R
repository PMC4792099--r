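## Phenotype ontology: OBO loading, ancestor closure, annotation propagation
## and redundancy pruning. The ontology is a DAG (multiple is_a parents are
## supported); depth is the shortest distance to a root.

#' Construct a phenotype ontology from its parent relation
#'
#' @param parents named list: term id -> character vector of parent term ids
#'   (empty for roots).
#' @param names named character vector of term names (optional).
#' @return object of class \code{"phenotype_ontology"} with precomputed
#'   strict-ancestor sets and depths.
#' @export
phenotype_ontology <- function(parents, names = NULL) {
  ids <- base::names(parents)
  if (is.null(ids) || anyDuplicated(ids)) stop("parents must be uniquely named")
  undef <- setdiff(unique(unlist(parents)), ids)
  if (length(undef)) stop("is_a target undefined: ", undef[1])

  # topological order via repeated root-stripping; detects cycles
  indeg <- lengths(parents)
  children <- vector("list", length(ids)); base::names(children) <- ids
  for (id in ids) for (p in parents[[id]])
    children[[p]] <- c(children[[p]], id)
  order <- character(0)
  queue <- ids[indeg == 0L]
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  depth[queue] <- 0
  remaining <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      depth[ch] <- min(depth[ch], depth[t] + 1, na.rm = TRUE)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- setdiff(ids, order)
    stop("ontology cycle detected involving term ", cyc[1])
  }
  anc <- vector("list", length(ids)); base::names(anc) <- ids
  for (t in order) {
    ps <- parents[[t]]
    anc[[t]] <- if (length(ps)) unique(c(ps, unlist(anc[ps], use.names = FALSE)))
                else character(0)
  }
  if (is.null(names)) names <- stats::setNames(ids, ids)
  structure(list(ids = ids, term_name = names, parents = parents,
                 ancestors = anc, depth = depth,
                 roots = ids[indeg == 0L]),
            class = "phenotype_ontology")
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat(sprintf("Phenotype ontology: %d terms, %d root(s), max depth %d\n",
              length(x$ids), length(x$roots), max(x$depth)))
  invisible(x)
}

#' Read an ontology from an OBO flat file
#'
#' Parses \code{[Term]} stanzas with \code{id:}, \code{name:}, \code{is_a:}
#' and \code{is_obsolete:} tags (trailing \code{!} comments on is_a lines are
#' ignored). Obsolete terms are skipped. Any id prefix is accepted.
#'
#' @param path path to an OBO file.
#' @return a [phenotype_ontology].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  parents <- list(); nm <- character(0)
  for (i in seq_along(starts)) {
    stanza <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    stanza <- stanza[!grepl("^\\[", stanza)]
    get <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                             grep(paste0("^", tag, ":"), stanza, value = TRUE))
    if (any(grepl("^is_obsolete:\\s*true", stanza))) next
    id <- get("id")
    if (length(id) != 1L) stop("stanza without a single id near line ", bounds[i])
    isa <- get("is_a")
    isa <- trimws(sub("!.*$", "", isa))
    parents[[id]] <- isa[nzchar(isa)]
    n <- get("name")
    nm[id] <- if (length(n)) n[1] else id
  }
  # is_a links pointing at obsolete (unloaded) terms are validated here
  phenotype_ontology(parents, names = nm)
}

#' Strict ancestors of a term
#'
#' All terms reachable from \code{term} by following is_a links upwards,
#' excluding the term itself; ancestors reachable along several paths are
#' returned once.
#'
#' @param ontology a [phenotype_ontology].
#' @param term a term id.
#' @return character vector of ancestor term ids.
#' @export
ancestors <- function(ontology, term) {
  if (!term %in% ontology$ids) stop("unknown term: ", term)
  ontology$ancestors[[term]]
}

#' Term depth (shortest distance to a root)
#' @rdname ancestors
#' @export
term_depth <- function(ontology, term) {
  if (!all(term %in% ontology$ids)) stop("unknown term")
  unname(ontology$depth[term])
}

#' Propagate patient annotations up the ontology
#'
#' Each patient's annotation set is closed under the ancestor relation:
#' direct terms plus all their strict ancestors. This is what lets general
#' terms accumulate patient counts from more specific annotations, so that
#' enrichment can be detected at whichever ontological level patients'
#' descriptions co-occur.
#'
#' @param ontology a [phenotype_ontology].
#' @param phenotypes named list patient id -> character vector of term ids,
#'   or a [pel_cohort].
#' @return named list patient id -> closed term set.
#' @export
propagate_annotations <- function(ontology, phenotypes) {
  if (inherits(phenotypes, "pel_cohort")) phenotypes <- phenotypes$phenotypes
  out <- lapply(base::names(phenotypes), function(pid) {
    terms <- phenotypes[[pid]]
    unknown <- setdiff(terms, ontology$ids)
    if (length(unknown))
      stop("patient ", pid, " annotated with unknown term ", unknown[1])
    unique(c(terms, unlist(ontology$ancestors[terms], use.names = FALSE)))
  })
  stats::setNames(out, base::names(phenotypes))
}

#' Remove ontologically redundant enriched terms
#'
#' When two enriched terms of one clique stand in an ancestor-descendant
#' relation they carry overlapping information; only the more significant
#' (lower p) member of every such pair is kept, the deeper (more specific)
#' term winning ties. Terms unrelated to every other input term always
#' survive.
#'
#' @param ontology a [phenotype_ontology].
#' @param term_ids character vector of enriched term ids.
#' @param p numeric vector of their p-values.
#' @return logical vector marking the surviving terms.
#' @export
prune_redundant <- function(ontology, term_ids, p) {
  stopifnot(length(term_ids) == length(p), all(p >= 0 & p <= 1))
  if (!length(term_ids)) return(logical(0))
  d <- term_depth(ontology, term_ids)
  ord <- order(p, -d)
  keep <- logical(length(term_ids))
  kept_terms <- character(0)
  for (i in ord) {
    t <- term_ids[i]
    anc_t <- ontology$ancestors[[t]]
    related <- any(kept_terms %in% anc_t) ||
      any(vapply(kept_terms, function(k) t %in% ontology$ancestors[[k]],
                 logical(1)))
    if (!related) {
      keep[i] <- TRUE
      kept_terms <- c(kept_terms, t)
    }
  }
  keep
}
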