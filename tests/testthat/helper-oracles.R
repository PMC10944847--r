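# Brute-force transitive-closure oracle for strongly connected components:
# Floyd-Warshall boolean closure, then mutual-reachability classes. Kept
# deliberately naive and independent of the package's igraph-based path.
oracle_largest_scc <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  for (k in seq_len(n)) {
    reach <- reach | outer(reach[, k], reach[k, ], "&")
  }
  mutual <- reach & t(reach)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[mutual[i, ]] <- cid
    }
  }
  max(tabulate(comp))
}

adjacency_from_edges <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) adj[edges] <- TRUE
  adj
}

# build a simulation_state around explicit opinions/sources
make_state <- function(opinions, sources, beta = 0,
                       spec = make_model_spec("galton", n = length(opinions))) {
  g <- structure(list(n = length(opinions), k = ncol(sources),
                      sources = sources, topology = "random"),
                 class = "source_graph")
  simulation_state(spec, g, opinions, beta)
}

# a small random valid state for property loops
random_state <- function(n = 12, k = 3, beta = 0.5,
                         spec = make_model_spec("galton", n = n)) {
  g <- init_sources(n, k)
  simulation_state(spec, g, sample_initial_opinions(spec), beta)
}
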