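#' Social association networks
#'
#' A `social_network` is an unweighted, undirected graph on `n_agents` nodes
#' stored as a dense binary adjacency matrix. It constrains which productions
#' an agent can observe and from whom it can acquire the novel behaviour.
#' Edge weights are fixed at 1; the diagonal is zero (agents do not observe
#' their own productions through the network).
#'
#' @param adjacency square binary matrix, symmetric with zero diagonal.
#' @param architecture label describing how the network was built.
#' @return An object of class `social_network` with fields `n_agents`,
#'   `adjacency`, `degree` (the common degree if the graph is regular,
#'   otherwise `NA`) and `architecture`.
#' @export
social_network <- function(adjacency, architecture = "other") {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  deg <- rowSums(adjacency)
  structure(
    list(
      n_agents = n,
      adjacency = unname(adjacency),
      degree = if (length(unique(deg)) == 1L) deg[1] else NA_real_,
      architecture = architecture
    ),
    class = "social_network"
  )
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf(
    "<social_network> %d agents, architecture '%s', degree %s, %d edges\n",
    x$n_agents, x$architecture,
    if (is.na(x$degree)) "mixed" else format(x$degree),
    sum(x$adjacency) / 2
  ))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Generate a connected random regular network
#'
#' Samples a k-regular graph by the standard pairing model and resamples
#' until the graph is connected, so that a diffusion seeded anywhere can
#' reach every agent.
#'
#' @param n_agents number of agents (N).
#' @param degree common degree (k); `n_agents * degree` must be even and
#'   `degree < n_agents`.
#' @param rng_seed optional integer seed; same seed gives an identical
#'   adjacency matrix.
#' @return A connected [social_network()] in which every row of the adjacency
#'   matrix sums to `degree`.
#' @export
generate_random_regular <- function(n_agents, degree, rng_seed = NULL) {
  if (degree >= n_agents || degree < 0 || (n_agents * degree) %% 2 != 0) {
    stop(sprintf("no %d-regular graph on %d nodes exists", degree, n_agents))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  repeat {
    g <- igraph::sample_k_regular(n_agents, degree)
    if (igraph::is_connected(g)) break
  }
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  social_network(adj, architecture = "random_regular")
}

#' Generate a ring lattice network
#'
#' Each agent is connected to `degree / 2` neighbours on either side of a
#' ring. Used as the alternative architecture with longer path lengths.
#'
#' @inheritParams generate_random_regular
#' @export
generate_ring_lattice <- function(n_agents, degree) {
  if (degree %% 2 != 0) stop("ring lattice degree must be even")
  if (degree >= n_agents) {
    # saturates at the complete graph
    adj <- matrix(1, n_agents, n_agents) - diag(n_agents)
    return(social_network(adj, architecture = "ring_lattice"))
  }
  adj <- matrix(0, n_agents, n_agents)
  half <- degree / 2
  for (d in seq_len(half)) {
    i <- seq_len(n_agents)
    j <- ((i - 1 + d) %% n_agents) + 1
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  social_network(adj, architecture = "ring_lattice")
}

#' Neighbours of an agent
#'
#' @param net a [social_network()].
#' @param agent agent index in `1:n_agents`.
#' @return Integer vector of neighbouring agent indices.
#' @export
agent_neighbors <- function(net, agent) {
  if (agent < 1 || agent > net$n_agents) stop("agent index out of range")
  which(net$adjacency[agent, ] == 1)
}

#' Mean shortest path length of a network
#'
#' @param net a [social_network()].
#' @export
mean_path_length <- function(net) {
  igraph::mean_distance(as_igraph(net))
}

#' Read and write networks as edge lists
#'
#' The on-disk format is a two-column CSV of 0-based agent indices, one row
#' per undirected edge (`from < to`).
#'
#' @param net a [social_network()].
#' @param path file path.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  el <- data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L)
  el <- el[order(el$from, el$to), ]
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' @param n_agents number of agents; defaults to one more than the largest
#'   index present in the file.
#' @param architecture label for the reconstructed network.
#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n_agents = NULL, architecture = "other") {
  el <- utils::read.csv(path)
  if (is.null(n_agents)) n_agents <- max(el) + 1L
  adj <- matrix(0, n_agents, n_agents)
  adj[cbind(el$from + 1L, el$to + 1L)] <- 1
  adj[cbind(el$to + 1L, el$from + 1L)] <- 1
  social_network(adj, architecture = architecture)
}
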