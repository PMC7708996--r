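#' Build the social interaction network
#'
#' Wires an undirected graph over the agents by seeded random stub matching:
#' every agent contributes `target_degree` stubs; stubs are visited in random
#' order and paired with a uniformly random compatible partner, subject to no
#' self-loops, no duplicate edges, and — for depressed agents — per-type
#' neighbour quotas. A depressed agent reserves a fraction `pi` of its slots
#' for depressed partners and splits the remainder equally across the other
#' three types, reflecting the homophily observed among depressed
#' individuals. Stubs that cannot be paired are dropped, so realized degrees
#' approximate targets (heterogeneous degree sequences are generally not
#' exactly graphical); residuals are reported in the returned object.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param agents Population tibble from [spawn_population()].
#' @param pi Connection diversity of depressed agents: fraction of their
#'   neighbours that are depressed. Infeasible values (a maximally connected
#'   depressed agent would need more depressed partners than exist) are
#'   rejected.
#' @param max_retries Matching attempts; the attempt with the fewest dropped
#'   stubs is kept (an attempt with none short-circuits).
#' @return An object of class `social_network`: a list with `edges` (tibble
#'   of unordered id pairs), `adjacency` (list of neighbour id vectors) and
#'   `agents` (the input tibble plus `realized_degree` and, for depressed
#'   agents, `depressed_neighbour_frac`).
#' @export
build_network <- function(agents, pi = 0.25, max_retries = 3) {
  best <- NULL
  for (attempt in seq_len(max_retries)) {
    net <- build_network_once(agents, pi)
    if (is.null(best) || net$dropped_stubs < best$dropped_stubs) best <- net
    if (best$dropped_stubs == 0L) break
  }
  best
}

build_network_once <- function(agents, pi) {
  n <- nrow(agents)
  types <- c("rational", "manic", "depressed", "bipolar")
  type_int <- match(agents$type, types)
  is_dep <- agents$type == "depressed"
  n_dep <- sum(is_dep)
  target <- agents$target_degree

  if (n_dep > 0 && pi > 0) {
    # a depressed agent at the maximal depressed degree (half the society)
    # must be able to fill its depressed quota from the other depressed agents
    if (round(pi * 0.5 * n) > n_dep) {
      stop(sprintf(
        "infeasible diversity: pi = %g requires %d depressed partners but only %d exist",
        pi, round(pi * 0.5 * n), n_dep
      ), call. = FALSE)
    }
  }

  # capacities: depressed agents hold per-partner-type quotas, others a pool
  cap_any <- ifelse(is_dep, 0L, target)
  cap_type <- matrix(0L, n, 4)
  for (i in which(is_dep)) {
    q_dep <- round(pi * target[i])
    rest <- target[i] - q_dep
    q_other <- rep(rest %/% 3, 3)
    extra <- rest %% 3
    if (extra > 0) {
      bump <- sample.int(3, extra)
      q_other[bump] <- q_other[bump] + 1L
    }
    quota <- integer(4)
    quota[3] <- q_dep
    quota[-3] <- q_other
    cap_type[i, ] <- quota
  }

  # stub list: one row per slot; depressed stubs are labelled with the
  # partner type they want (1..4), others are unlabelled (0)
  stub_agent <- integer(0)
  stub_want <- integer(0)
  for (i in seq_len(n)) {
    if (is_dep[i]) {
      w <- rep.int(1:4, cap_type[i, ])
    } else {
      w <- rep.int(0L, target[i])
    }
    stub_agent <- c(stub_agent, rep.int(i, length(w)))
    stub_want <- c(stub_want, w)
  }
  ord <- sample.int(length(stub_agent))
  stub_agent <- stub_agent[ord]
  stub_want <- stub_want[ord]

  adj <- matrix(FALSE, n, n)
  from <- integer(0)
  to <- integer(0)
  ids <- seq_len(n)

  for (s in seq_along(stub_agent)) {
    a <- stub_agent[s]
    w <- stub_want[s]
    ta <- type_int[a]
    # the stub may already be consumed from the other side
    if (is_dep[a]) {
      if (w == 0L || cap_type[a, w] == 0L) next
    } else if (cap_any[a] == 0L) next

    can_accept <- ifelse(is_dep, cap_type[, ta] > 0L, cap_any > 0L)
    ok <- can_accept & !adj[, a] & ids != a
    if (w > 0L) ok <- ok & type_int == w
    cand <- which(ok)
    if (length(cand) == 0) next # unpairable stub, dropped
    # uniform over *stubs*: weight candidates by their remaining capacity
    if (length(cand) == 1) {
      b <- cand
    } else {
      w <- ifelse(is_dep[cand], cap_type[cand, ta], cap_any[cand])
      b <- cand[sample.int(length(cand), 1, prob = w)]
    }

    adj[a, b] <- adj[b, a] <- TRUE
    from <- c(from, min(a, b))
    to <- c(to, max(a, b))
    if (is_dep[a]) cap_type[a, type_int[b]] <- cap_type[a, type_int[b]] - 1L else cap_any[a] <- cap_any[a] - 1L
    if (is_dep[b]) cap_type[b, ta] <- cap_type[b, ta] - 1L else cap_any[b] <- cap_any[b] - 1L
  }

  adjacency <- lapply(seq_len(n), function(i) which(adj[i, ]))
  realized <- lengths(adjacency)
  agents$realized_degree <- realized
  agents$depressed_neighbour_frac <- NA_real_
  for (i in which(is_dep)) {
    if (realized[i] > 0) {
      agents$depressed_neighbour_frac[i] <-
        mean(agents$type[adjacency[[i]]] == "depressed")
    }
  }

  structure(
    list(
      edges = tibble::tibble(from = from, to = to),
      adjacency = adjacency,
      agents = agents,
      pi = pi,
      dropped_stubs = sum(target) - 2L * length(from)
    ),
    class = "social_network"
  )
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf(
    "<social_network> %d agents, %d edges, %d stubs dropped (%.1f%% of targets)\n",
    nrow(x$agents), nrow(x$edges), x$dropped_stubs,
    100 * x$dropped_stubs / max(1, sum(x$agents$target_degree))
  ))
  invisible(x)
}

#' Convert a social network to an igraph object
#'
#' @param network A [build_network()] result.
#' @return An undirected `igraph` graph with agent attributes.
#' @export
as_igraph <- function(network) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for `as_igraph()`", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(
    as.matrix(network$edges), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, nrow(network$agents) - igraph::vcount(g)))
  igraph::set_vertex_attr(g, "type", value = network$agents$type)
}

#' Write a network to plain-text files
#'
#' Exports the edge list (tab-separated id pairs) and a node attribute table
#' (CSV with id, type, trait sensitivity, target and realized degree).
#'
#' @param network A [build_network()] result.
#' @param edge_file,node_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, edge_file, node_file) {
  utils::write.table(network$edges, edge_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  nodes <- network$agents[, c("id", "type", "beta0", "target_degree",
                              "realized_degree")]
  utils::write.csv(nodes, node_file, row.names = FALSE)
  invisible(c(edge_file, node_file))
}
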