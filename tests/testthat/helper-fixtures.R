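# Fixture builders and independent brute-force oracles used across tests.

# tiny cohort from a compact CNV description; every patient gets a default
# phenotype unless named in `phen`
mk_cohort <- function(cnvs, phen = NULL) {
  df <- do.call(rbind, lapply(cnvs, function(x)
    data.frame(patient_id = x[[1]], chrom = x[[2]],
               start = as.numeric(x[[3]]), end = as.numeric(x[[4]]),
               class = if (length(x) >= 5) x[[5]] else "loss",
               inheritance = "unknown", stringsAsFactors = FALSE)))
  ids <- unique(df$patient_id)
  if (is.null(phen))
    phen <- stats::setNames(replicate(length(ids), "T1", simplify = FALSE),
                            ids)
  pel_cohort(df, phen)
}

# chain ontology root <- T1 ... of given depth, ids "T0" (root) .. "Td"
mk_chain_ontology <- function(depth) {
  parents <- list(T0 = character(0))
  for (d in seq_len(depth))
    parents[[paste0("T", d)]] <- paste0("T", d - 1)
  phenotype_ontology(parents)
}

# exhaustive-enumeration oracle for the hypergeometric upper tail P(X >= k):
# enumerate every size-n draw from a population of K successes among N
hyper_tail_enum <- function(k, n, K, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  mean(colSums(matrix(pop[draws], nrow = n)) >= k)
}

# brute-force maximal cliques of an adjacency matrix via 2^n subset
# enumeration; returns a sorted list of sorted member index vectors
brute_maximal_cliques <- function(adj, min_size = 3L) {
  n <- nrow(adj)
  is_clique <- function(v) all(adj[v, v][upper.tri(matrix(0, length(v),
                                                          length(v)))] == 1)
  subsets <- lapply(seq_len(2^n - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  cl <- Filter(function(v) length(v) >= 2 && is_clique(v), subsets)
  maximal <- Filter(function(v) {
    !any(vapply(setdiff(seq_len(n), v), function(w)
      is_clique(sort(c(v, w))), logical(1)))
  }, cl)
  maximal <- Filter(function(v) length(v) >= min_size, maximal)
  unique(lapply(maximal, sort))
}

# random Erdos-Renyi patient graph as an igraph object with names "P1"...
random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("P", seq_len(n))
  list(graph = g, adj = adj)
}

# small standard simulation used by several suites (fast: ~0.3 s)
small_sim <- function(seed = 1, ...) {
  simulate_cohort(cohort_spec(n_patients = 80, n_controls = 150,
                              implants = list(
                                implant_spec("chr1", 3.0e7, 3.08e7, "loss",
                                             "HP:0000010", n_carriers = 8)),
                              seed = seed, ...))
}
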