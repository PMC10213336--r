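#' Strength centrality of every node
#'
#' Strength of node i is the sum of absolute weights of its incident edges,
#' \eqn{s_i = \sum_j |w_{ij}|} -- the sole centrality index used for these
#' symptom networks.  Ranks break ties by node order.
#'
#' @param network A `symptom_network`, or a symmetric weight matrix.
#' @return A `centrality_table` data frame: `node`, `strength`, `rank`
#'   (1 = most central), `z` (standardized strength).
#' @export
strength_centrality <- function(network) {
  W <- if (inherits(network, "symptom_network")) network$weights
       else as.matrix(network)
  nodes <- colnames(W)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(W)))
  s <- rowSums(abs(W))
  rk <- rank(-s, ties.method = "first")
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
  structure(data.frame(node = nodes, strength = as.numeric(s),
                       rank = as.integer(rk), z = as.numeric(z)),
            class = c("centrality_table", "data.frame"))
}

#' Flow layout: direct edges between a target node and the rest
#'
#' Extracts the edges incident to one target node (for these analyses,
#' global QOL added to the symptom network), ranked by absolute weight,
#' with the remaining nodes assigned to layers: 0 = target, 1 = direct
#' neighbors, 2 = nodes with no direct edge to the target.
#'
#' @param network A `symptom_network` containing the target node.
#' @param target Node label.
#' @param k Optionally return only the top-k direct edges.
#' @return A `flow_layout` list: `target`, `direct` (data frame `neighbor`,
#'   `weight`, ranked), `layers` (named integer vector over all nodes).
#' @export
flow_edges <- function(network, target, k = NULL) {
  W <- network$weights
  nodes <- network$nodes
  if (!target %in% nodes)
    stop("unknown target node: ", target, call. = FALSE)
  ti <- match(target, nodes)
  w <- W[ti, -ti]
  nb <- nodes[-ti]
  nz <- which(w != 0)
  ord <- nz[order(-abs(w[nz]), nz)]
  direct <- data.frame(neighbor = nb[ord], weight = as.numeric(w[ord]))
  if (!is.null(k)) direct <- head(direct, k)
  layers <- setNames(rep(2L, length(nodes)), nodes)
  layers[target] <- 0L
  layers[nb[nz]] <- 1L
  structure(list(target = target, direct = direct, layers = layers),
            class = "flow_layout")
}

#' @export
print.flow_layout <- function(x, ...) {
  cat("Flow layout for target '", x$target, "'\n", sep = "")
  if (nrow(x$direct)) {
    cat("  direct edges (by |weight|):\n")
    print(x$direct, row.names = FALSE)
  } else cat("  no direct edges\n")
  invisible(x)
}
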