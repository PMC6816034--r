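#' Remove nodes from a subnetwork (simulated target inactivation)
#'
#' Deletes the victim nodes and all their incident edges, then drops any
#' node left with no edge, preserving the subnetwork invariant that every
#' node has degree at least 1. The result may be an empty graph.
#'
#' @param sub A subnetwork (igraph).
#' @param victims Character vector of accessions to remove; must all be
#'   present in the subnetwork.
#' @return The reduced subnetwork (igraph; possibly 0 nodes).
#' @export
remove_nodes <- function(sub, victims) {
  victims <- unique(victims)
  absent <- setdiff(victims, igraph::V(sub)$name)
  if (length(absent) > 0) {
    ne_abort(sprintf("victim(s) not in subnetwork: %s", paste(absent, collapse = ", ")),
             "precondition_error")
  }
  out <- igraph::delete_vertices(sub, victims)
  iso <- igraph::degree(out) == 0
  igraph::delete_vertices(out, igraph::V(out)[iso])
}

#' Entropy after removing the top-degree hubs
#'
#' Removes the first `n_hubs` nodes of the deterministic hub ranking (see
#' [rank_hubs()]) and returns the Shannon entropy of what is left. An
#' emptied subnetwork reports entropy 0 with `emptied = TRUE`.
#'
#' @param sub A subnetwork (igraph).
#' @param n_hubs Number of top hubs to remove (`<=` node count).
#' @return List with `entropy` (bits), `emptied` (logical), `removed`
#'   (accessions taken out).
#' @export
hub_removal_entropy <- function(sub, n_hubs) {
  n <- igraph::vcount(sub)
  if (n_hubs > n) ne_abort("n_hubs exceeds subnetwork size", "precondition_error")
  hubs <- rank_hubs(sub, n_hubs)$accession
  left <- remove_nodes(sub, hubs)
  emptied <- igraph::vcount(left) == 0
  list(entropy = if (emptied) 0 else shannon_entropy(left)$H,
       emptied = emptied,
       removed = hubs)
}

#' Random-removal empirical null for hub inactivation
#'
#' Builds the empirical distribution of subnetwork entropies after removing
#' `n_remove` nodes drawn uniformly without replacement, repeated `reps`
#' times, and compares it with the entropy observed after removing the top
#' `n_remove` hubs. The one-sided empirical p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{H_{null} \le H_{hub}\}) / (1 + reps)}, so it
#' can never be exactly 0 and is bounded below by `1/(reps+1)`.
#'
#' Replicates are deterministic given `seed` and the subnetwork's patient
#' id: the RNG stream is derived from both, so per-patient results do not
#' depend on the order in which a cohort is processed.
#'
#' @param sub A subnetwork (igraph).
#' @param n_remove Nodes removed per replicate (default 5; must be
#'   `< vcount(sub)`).
#' @param reps Number of replicates (default 1000; below 100 triggers an
#'   unstable-null warning).
#' @param seed Master integer seed.
#' @return A `null_distribution`: list with `entropies`, `removed_per_rep`,
#'   `seed`, `observed_hub_entropy`, `empirical_p`, `patient_id`.
#' @export
random_removal_null <- function(sub, n_remove = 5, reps = 1000, seed = 1) {
  n <- igraph::vcount(sub)
  if (n_remove >= n) {
    ne_abort("n_remove must be smaller than the subnetwork size", "precondition_error")
  }
  if (reps < 100) ne_warn("fewer than 100 replicates: null distribution is unstable",
                          "unstable_null_warning")
  pid <- sub$patient_id %||% ""
  if (is.na(pid)) pid <- ""
  # Removing victims changes a survivor's degree by its number of victim
  # neighbours only, so per-replicate entropies are computed from the
  # baseline adjacency without rebuilding the graph (remove_nodes() is the
  # reference path; the two agree exactly).
  deg <- unname(igraph::degree(sub))
  adj <- igraph::as_adj_list(sub)
  adj_idx <- lapply(adj, as.integer)
  entropies <- withr::with_seed(derive_seed(seed, pid), {
    vapply(seq_len(reps), function(r) {
      victims <- sample.int(n, n_remove)
      hits <- tabulate(unlist(adj_idx[victims], use.names = FALSE), nbins = n)
      newdeg <- deg - hits
      newdeg[victims] <- 0L
      entropy_of_degrees(newdeg[newdeg > 0])
    }, numeric(1))
  })
  obs <- hub_removal_entropy(sub, n_remove)
  structure(list(entropies = entropies,
                 removed_per_rep = n_remove,
                 seed = seed,
                 observed_hub_entropy = obs$entropy,
                 observed_emptied = obs$emptied,
                 empirical_p = (1 + sum(entropies <= obs$entropy)) / (1 + reps),
                 patient_id = sub$patient_id %||% NA_character_),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d reps of %d-node removal; null median H = %.4f; hub H = %.4f; empirical p = %.4g\n",
    length(x$entropies), x$removed_per_rep, stats::median(x$entropies),
    x$observed_hub_entropy, x$empirical_p))
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(replicate = seq_along(x$entropies), entropy = x$entropies)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(patient_id = x$patient_id,
         reps = length(x$entropies),
         removed_per_rep = x$removed_per_rep,
         null_median = stats::median(x$entropies),
         observed_hub_entropy = x$observed_hub_entropy,
         empirical_p = x$empirical_p)
}

#' @exportS3Method ggplot2::autoplot
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$entropy)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_hub_entropy,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "entropy after random removal (bits)", y = "frequency",
                  subtitle = sprintf("hub removal H = %.3f, empirical p = %.3g",
                                     object$observed_hub_entropy, object$empirical_p)) +
    ggplot2::theme_minimal()
}
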