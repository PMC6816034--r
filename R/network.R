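#' Induce the PPI subnetwork of a protein set
#'
#' Keeps every interactome edge whose two endpoints both belong to
#' `proteins`; the subnetwork's nodes are the endpoints of those edges.
#' Proteins of the set with no partner inside the set (including proteins
#' absent from the interactome altogether) are excluded, so every node of
#' the result has degree at least 1.
#'
#' @param interactome An undirected igraph (vertex names = accessions).
#' @param proteins Non-empty character vector of protein accessions.
#' @param patient_id Identifier stored on the graph (attribute
#'   `patient_id`).
#' @return An undirected simple igraph; errors with class
#'   `empty_subnetwork_error` when no edge is induced.
#' @export
induce_subnetwork <- function(interactome, proteins, patient_id = NA_character_) {
  if (length(proteins) == 0) ne_abort("protein set is empty", "precondition_error")
  present <- intersect(unique(proteins), igraph::V(interactome)$name)
  sub <- igraph::induced_subgraph(interactome, present)
  iso <- igraph::degree(sub) == 0
  n_excluded <- (length(unique(proteins)) - length(present)) + sum(iso)
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[iso])
  if (igraph::ecount(sub) == 0) {
    ne_abort(sprintf("no interactions among the %d protein(s): empty subnetwork",
                     length(unique(proteins))),
             "empty_subnetwork_error")
  }
  if (n_excluded > 0) {
    inform(sprintf("induce_subnetwork: %d protein(s) without induced interaction excluded",
                   n_excluded))
  }
  sub$patient_id <- patient_id
  sub
}

#' Degree distribution p(k) of a subnetwork
#'
#' For each observed degree value k, `p(k)` is the fraction of subnetwork
#' nodes with exactly k incident edges. Only observed degrees are in the
#' support, so probabilities are positive and sum to 1.
#'
#' @param sub A subnetwork (igraph) or a named/plain integer vector of node
#'   degrees.
#' @return A tibble with columns `k`, `count`, `p`, carrying `n_nodes` as an
#'   attribute, class `degree_distribution`.
#' @export
degree_distribution <- function(sub) {
  deg <- if (inherits(sub, "igraph")) igraph::degree(sub) else sub
  if (length(deg) == 0) ne_abort("empty subnetwork has no degree distribution",
                                 "precondition_error")
  tab <- table(deg)
  structure(
    tibble(k = as.integer(names(tab)),
           count = as.integer(tab),
           p = as.integer(tab) / length(deg)),
    n_nodes = length(deg),
    class = c("degree_distribution", class(tibble()))
  )
}

#' Shannon entropy of a degree distribution
#'
#' \deqn{H = -\sum_k p(k) \log_2 p(k)}
#'
#' where the sum runs over observed degrees (so no 0 log 0 term arises).
#' H depends only on the proportions p(k), never on network size, and is
#' reported in bits.
#'
#' @param x A `degree_distribution`, a subnetwork (igraph), or a numeric
#'   vector of degrees.
#' @return An `entropy_result`: list with `H` (bits) and `distribution`.
#'   `H` is 0 for regular graphs and at most `log2(|support|)`.
#' @export
shannon_entropy <- function(x) {
  dist <- if (inherits(x, "degree_distribution")) x else degree_distribution(x)
  H <- -sum(dist$p * log2(dist$p))
  structure(list(H = H, distribution = dist), class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> H = %.6f bits over %d degree class(es), %d nodes\n",
              x$H, nrow(x$distribution), attr(x$distribution, "n_nodes")))
  invisible(x)
}

# Bare numeric entropy of a degree vector; 0 for an empty graph by the
# emptied-subnetwork convention used along removal trajectories.
entropy_of_degrees <- function(deg) {
  if (length(deg) == 0) return(0)
  p <- tabulate(factor(deg)) / length(deg)
  -sum(p * log2(p))
}

#' Rank subnetwork hubs by degree
#'
#' Deterministic ranking: descending induced degree, ties broken by
#' ascending accession so identical subnetworks always rank identically.
#'
#' @param sub A subnetwork (igraph).
#' @param n Number of top hubs to return (truncated to the node count).
#' @return A tibble with columns `accession`, `degree`.
#' @export
rank_hubs <- function(sub, n) {
  if (n < 1) ne_abort("n must be at least 1", "precondition_error")
  deg <- igraph::degree(sub)
  ord <- order(-deg, names(deg), method = "radix")
  head(tibble(accession = names(deg)[ord], degree = unname(deg)[ord]), n)
}

#' Export a subnetwork to GraphML
#'
#' @param sub A subnetwork (igraph).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(sub, path) {
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.degree_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "degree k", y = "p(k)") +
    ggplot2::theme_minimal()
}
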