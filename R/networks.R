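## Community detection, centrality, and community-matrix construction for the
## three network variants (raw co-presence counts, binary affiliative
## co-presence, signed joining).

#' Build a community matrix
#'
#' Three variants: `"raw_counts"` takes a co-presence count matrix and zeroes
#' its diagonal (within-species totals are reported by
#' [copresence_counts()] but excluded from community detection input);
#' `"affiliative_binary"` sets `M[i, j] = M[j, i] = 1` iff a significant
#' affiliative edge exists in either direction between i and j;
#' `"join_signed"` sets +1 for an affiliative join edge, -1 for an avoidant
#' one and 0 otherwise (if a pair carries both signs in opposite directions,
#' the affiliative entry takes precedence).
#'
#' @param x a co-presence count matrix (`raw_counts`) or an `edge_set`
#'   (other variants).
#' @param variant one of `"raw_counts"`, `"affiliative_binary"`,
#'   `"join_signed"`.
#' @param species species labels (required for edge-set variants; defaults to
#'   the focal codes).
#' @return a square numeric matrix with species dimnames and attribute
#'   `variant`.
#' @export
build_community_matrix <- function(x,
                                   variant = c("raw_counts",
                                               "affiliative_binary",
                                               "join_signed"),
                                   species = focal_species()) {
  variant <- match.arg(variant)
  if (variant == "raw_counts") {
    stopifnot(is.matrix(x), isSymmetric(unname(x * 1.0)))
    M <- x
    diag(M) <- 0L
  } else {
    stopifnot(inherits(x, "edge_set"))
    n <- length(species)
    M <- matrix(0, n, n, dimnames = list(species, species))
    sig <- x[x$significant, , drop = FALSE]
    for (k in seq_len(nrow(sig))) {
      i <- sig$focal[k]; j <- sig$predictor[k]
      v <- if (sig$sign[k] == "affiliative") 1 else -1
      if (variant == "affiliative_binary") {
        if (v > 0) M[i, j] <- M[j, i] <- 1
      } else {
        # affiliative precedence on sign conflicts between the two directions
        if (v > 0 || (M[i, j] == 0 && M[j, i] == 0)) {
          M[i, j] <- M[j, i] <- v
        }
      }
    }
  }
  attr(M, "variant") <- variant
  M
}

#' Leading-eigenvector community detection
#'
#' Newman's leading-eigenvector modularity partition on an undirected
#' weighted graph, splitting recursively while a split increases modularity.
#' Signed matrices are reduced to their positive part first (communities are
#' detected among the affiliative edges only). A graph with no edges returns
#' every node in its own community.
#'
#' @param M a symmetric non-negative (or signed, see above) community matrix
#'   with species dimnames.
#' @return named integer vector of community memberships.
#' @export
leading_eigenvector_communities <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  W <- pmax(unclass(M), 0)
  diag(W) <- 0
  if (!isSymmetric(unname(W * 1.0))) stop("community matrix must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0L) {
    return(stats::setNames(seq_len(nrow(W)), rownames(W)))
  }
  cl <- igraph::cluster_leading_eigen(
    g, options = list(maxiter = 1000000L))
  stats::setNames(as.integer(igraph::membership(cl)), rownames(W))
}

#' Modularity of a membership vector on a community matrix
#'
#' Convenience wrapper used to check that a detected partition is at least as
#' modular as the trivial one-community partition.
#'
#' @param M symmetric non-negative matrix.
#' @param membership integer memberships as from
#'   [leading_eigenvector_communities()].
#' @return modularity value.
#' @export
community_modularity <- function(M, membership) {
  W <- pmax(unclass(M), 0)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

#' Degree and betweenness centrality on the affiliative subgraph
#'
#' Degree is the total number of incoming plus outgoing significant
#' affiliative edges; betweenness counts shortest paths through each node on
#' the affiliative subgraph (directed by default).
#'
#' @param edges an `edge_set`.
#' @param species node label set (defaults to the focal codes).
#' @param directed treat the affiliative subgraph as directed for
#'   betweenness.
#' @return a `data.frame` with columns `species`, `degree`, `betweenness`.
#' @export
centrality_scores <- function(edges, species = focal_species(),
                              directed = TRUE) {
  stopifnot(inherits(edges, "edge_set"))
  aff <- edges[edges$significant & edges$sign == "affiliative", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    aff[, c("focal", "predictor")], directed = TRUE,
    vertices = data.frame(name = species))
  data.frame(species = species,
             degree = as.integer(igraph::degree(g, v = species,
                                                mode = "all")),
             betweenness = as.numeric(igraph::betweenness(g, v = species,
                                                          directed = directed)),
             stringsAsFactors = FALSE)
}
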