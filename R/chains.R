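# Maximum circuit depth: longest repressor-distinct paths in the
# compatibility graph under context restrictions.

#' Build a compatibility graph from a score matrix
#'
#' Nodes are operational gate-contexts (optionally restricted by a context
#' filter); edges are ordered pairs with strictly positive compatibility
#' score (the 0/1 table read as an adjacency matrix).
#'
#' @param cm A `compatibility_matrix`, or a fits data.frame (then the
#'   matrix is computed first).
#' @param context_filter Optional predicate on node rows (applied when `cm`
#'   is a fits data.frame, or to subset an existing matrix's nodes).
#' @param ... Passed to [compatibility_matrix()] when building from fits.
#' @return A `compatibility_graph`: `nodes` data.frame, `adjacency` 0/1
#'   matrix, `repressor_of` character vector.
#' @export
build_graph <- function(cm, context_filter = NULL, ...) {
  if (is.data.frame(cm)) {
    cm <- compatibility_matrix(cm, context_filter = context_filter, ...)
  } else if (!is.null(context_filter)) {
    keep <- vapply(seq_len(nrow(cm$nodes)),
                   function(i) isTRUE(context_filter(cm$nodes[i, ])), TRUE)
    cm$nodes <- cm$nodes[keep, , drop = FALSE]
    cm$compatible <- cm$compatible[keep, keep, drop = FALSE]
  }
  if (nrow(cm$nodes) == 0) {
    stop("no operational gate-contexts left after filtering", call. = FALSE)
  }
  structure(list(nodes = cm$nodes, adjacency = cm$compatible,
                 repressor_of = cm$nodes$repressor_family),
            class = "compatibility_graph")
}

#' Longest repressor-distinct chains in a compatibility graph
#'
#' Exhaustive depth-first search over simple paths in which no repressor
#' family occurs twice (a repressor reused within a chain would crosstalk
#' with its earlier cognate promoter). With R distinct families in the
#' graph, depth is bounded by R. Depth counts gates, so an edgeless graph
#' has depth 1. The search memoizes the best achievable depth per
#' (node, used-family-set) state, and enumeration of maximal chains is
#' pruned by that memo, so it touches only extensions that can still reach
#' the maximum. Returned chains are in lexicographic node-index order.
#'
#' @param g A `compatibility_graph`.
#' @param enumerate Also enumerate all maximal chains (default TRUE).
#' @param max_chains Cap on the number of chains returned (deterministic:
#'   the lexicographically first ones); `Inf` for all.
#' @return List with `max_depth`, `chains` (list of character vectors of
#'   node labels; empty if `enumerate = FALSE`), and `n_chains_truncated`.
#' @export
longest_chains <- function(g, enumerate = TRUE, max_chains = 10000) {
  n <- nrow(g$nodes)
  adj <- g$adjacency
  fams <- factor(g$repressor_of)
  n_fam <- nlevels(fams)
  if (n_fam > 20) stop("more than 20 repressor families; chain search not supported",
                       call. = FALSE)
  fam_bit <- bitwShiftL(1L, as.integer(fams) - 1L)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))
  labels <- rownames(adj)
  if (is.null(labels)) labels <- paste(g$nodes$gate, g$nodes$backbone,
                                       g$nodes$host, sep = "|")

  # memo[node, used + 1]: longest chain from `node` given the family set
  # already used (including the node's own family); 0 = not yet computed
  memo <- matrix(0L, nrow = max(n, 1L), ncol = bitwShiftL(1L, n_fam))
  depth_from <- function(node, used) {
    hit <- memo[node, used + 1L]
    if (hit > 0L) return(hit)
    best <- 1L
    for (nb in nbrs[[node]]) {
      if (bitwAnd(used, fam_bit[nb]) == 0L) {
        d <- 1L + depth_from(nb, bitwOr(used, fam_bit[nb]))
        if (d > best) best <- d
      }
    }
    memo[node, used + 1L] <<- best
    best
  }

  if (n == 0) return(list(max_depth = 0L, chains = list(), n_chains_truncated = 0L))
  start_depths <- vapply(seq_len(n), function(i) depth_from(i, fam_bit[i]), 0L)
  max_depth <- max(start_depths)

  chains <- list()
  truncated <- 0L
  if (enumerate) {
    extend <- function(path, used, remaining) {
      if (remaining == 0L) {
        if (length(chains) < max_chains) {
          chains[[length(chains) + 1L]] <<- labels[path]
        } else {
          truncated <<- truncated + 1L
        }
        return(invisible())
      }
      for (nb in nbrs[[path[length(path)]]]) {
        if (bitwAnd(used, fam_bit[nb]) == 0L &&
            depth_from(nb, bitwOr(used, fam_bit[nb])) >= remaining) {
          extend(c(path, nb), bitwOr(used, fam_bit[nb]), remaining - 1L)
        }
      }
    }
    for (i in which(start_depths == max_depth)) {
      extend(i, fam_bit[i], max_depth - 1L)
    }
  }
  list(max_depth = max_depth, chains = chains, n_chains_truncated = truncated)
}

#' Maximum depth under a set of context policies
#'
#' Runs the longest-chain search once per policy (e.g. single backbone and
#' host; any backbone within one host; all contexts). Relaxing a policy by
#' set inclusion can only add nodes and edges, so depth is non-decreasing
#' along nested policies.
#'
#' @param fits Fits/thresholds data.frame ([fit_library()]).
#' @param policies Named list of predicates on fit rows (NULL = no
#'   restriction).
#' @param ... Passed to [compatibility_matrix()].
#' @return data.frame with policy, n_nodes, n_compatible and max_depth; a
#'   `chains` attribute holds each policy's maximal chains.
#' @export
depth_by_context_policy <- function(fits, policies, ...) {
  stopifnot(length(policies) >= 1)
  if (is.null(names(policies))) names(policies) <- paste0("policy", seq_along(policies))
  all_chains <- list()
  rows <- lapply(names(policies), function(nm) {
    cmat <- compatibility_matrix(fits, context_filter = policies[[nm]], ...)
    g <- build_graph(cmat)
    lc <- longest_chains(g)
    all_chains[[nm]] <<- lc$chains
    data.frame(policy = nm, n_nodes = nrow(g$nodes),
               n_compatible = cmat$n_compatible, max_depth = lc$max_depth)
  })
  out <- do.call(rbind, rows)
  attr(out, "chains") <- all_chains
  out
}

#' Annotate a chain for multicellular feasibility
#'
#' Reports how many host switches a chain requires (each needs an
#' inter-cellular connection, e.g. an orthogonal quorum-sensing channel)
#' and the backbones used per host (plasmids sharing a host must carry
#' distinct origins of replication). These are annotations only; the depth
#' search itself does not constrain on them.
#'
#' @param chain Character vector of node labels "gate|backbone|host".
#' @return List with `n_host_switches` and `backbones_by_host`.
#' @export
annotate_chain <- function(chain) {
  parts <- strsplit(chain, "|", fixed = TRUE)
  hosts <- vapply(parts, `[`, "", 3L)
  backbones <- vapply(parts, `[`, "", 2L)
  list(
    n_host_switches = sum(hosts[-1] != hosts[-length(hosts)]),
    backbones_by_host = lapply(split(backbones, hosts), unique)
  )
}
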