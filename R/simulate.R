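#' Simulate single-gain / multiple-loss gene-content evolution
#'
#' Generates binary phyletic patterns under the generative model the
#' inference assumes: each component is gained once (at the root with
#' probability `p_root`, otherwise on an edge drawn uniformly) and is then
#' lost independently along branches as a Poisson process with rate
#' `loss_rate` per unit branch length; once lost on an edge the whole
#' descendant subtree lacks it (no regain).  Multiple loss events on one
#' branch collapse to a single loss.  Optionally, truly present components in
#' genomes of status `P` (ongoing sequencing) are censored to observed
#' absence with probability `censor_missing`, emulating incomplete genomes.
#'
#' The full randomness lattice (gain draw, one Poisson per edge, one censor
#' uniform per status-P tip) is consumed on every draw regardless of
#' parameter values, so runs at the same seed are coupled across parameter
#' settings (censor levels are nested, loss sets are comparable).
#'
#' @param tree a `reference_tree`; edges without branch lengths count as
#'   length 1.
#' @param n_components number of components to simulate.
#' @param p_root probability a component is gained at the root.
#' @param loss_rate expected loss events per unit branch length (>= 0).
#' @param censor_missing per status-P genome, probability that a truly
#'   present component goes unobserved.
#' @param tip_status optional named character vector of genome statuses
#'   (`C`/`A`/`P`) per tip; only `P` tips are censored.
#' @param seed mandatory integer seed.
#' @return list with `matrix` (the *observed*, possibly censored,
#'   `presence_matrix`, tips x components) and `truth` (class `sim_truth`):
#'   per component the true `gain_node`, `loss_edges`, uncensored
#'   `tip_presence`, and `censored_tips`.
#' @export
simulate_content <- function(tree, n_components, p_root = 1, loss_rate = 0,
                             censor_missing = 0, tip_status = NULL,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (loss_rate < 0) stop("loss_rate must be >= 0")
  for (p in c(p_root, censor_missing))
    if (p < 0 || p > 1) stop("probabilities must be in [0,1]")
  set.seed(as.integer(seed))

  tips <- tree_tips(tree)
  p_tips <- if (is.null(tip_status)) character(0) else
    names(tip_status)[tip_status == "P"]
  elen <- .edge_lengths(tree)
  edges <- names(elen)                      # child labels, preorder

  truth <- vector("list", n_components)
  mat <- matrix(0L, length(tips), n_components)
  dimnames(mat) <- list(tips, if (n_components > 0L)
    paste0("comp", seq_len(n_components)) else NULL)
  for (cmp in seq_len(n_components)) {
    u_gain <- stats::runif(1)
    pick <- sample.int(length(edges), 1L)     # always drawn (coupling)
    gain <- if (u_gain <= p_root) tree$root else edges[pick]

    alive <- stats::setNames(logical(length(tree$labels)), tree$labels)
    alive[gain] <- TRUE
    loss_edges <- character(0)
    for (e in edges) {
      n_events <- stats::rpois(1L, loss_rate * elen[[e]])  # always drawn
      par <- parent_of(tree, e)
      below_gain <- is_ancestor(tree, gain, e) && e != gain
      if (below_gain && alive[par]) {
        if (n_events > 0L) loss_edges <- c(loss_edges, e) else alive[e] <- TRUE
      }
    }
    tip_presence <- stats::setNames(as.integer(alive[tips]), tips)
    cens <- stats::runif(length(p_tips))      # always drawn
    censored <- p_tips[cens < censor_missing & tip_presence[p_tips] == 1L]
    observed <- tip_presence
    observed[censored] <- 0L
    mat[, cmp] <- observed[tips]
    truth[[cmp]] <- list(component = colnames(mat)[cmp], gain_node = gain,
                         loss_edges = sort(loss_edges),
                         tip_presence = tip_presence,
                         censored_tips = censored)
  }
  names(truth) <- colnames(mat)
  list(matrix = presence_matrix(mat),
       truth = structure(truth, class = "sim_truth", tree_root = tree$root))
}

.edge_lengths <- function(tree) {
  labs <- tree_nodes(tree)
  children <- setdiff(labs, tree$root)
  out <- stats::setNames(rep(1, length(children)), children)
  if (!is.null(tree$edge_length)) {
    ids <- tree$phy$edge[, 2L]
    out[tree$labels[ids]] <- tree$edge_length
    out <- out[children]
  }
  out
}

#' Analytic expected loss count per component (root gain)
#'
#' For a component gained at the root, the expected number of recorded loss
#' events is the sum over edges of P(parent lineage still carries it) *
#' P(>=1 Poisson loss event on the edge), with survival multiplying down
#' root-to-node paths.  Used as the independent calibration oracle for
#' [simulate_content()].
#'
#' @param tree a `reference_tree`.
#' @param loss_rate Poisson loss rate per unit branch length.
#' @export
expected_loss_count <- function(tree, loss_rate) {
  elen <- .edge_lengths(tree)
  surv <- stats::setNames(rep(1, length(tree$labels)), tree$labels)
  total <- 0
  for (e in names(elen)) {                  # preorder: parents first
    p_alive_parent <- surv[[parent_of(tree, e)]]
    p_loss_here <- 1 - exp(-loss_rate * elen[[e]])
    total <- total + p_alive_parent * p_loss_here
    surv[e] <- p_alive_parent * (1 - p_loss_here)
  }
  total
}

#' Simulate occupancy-scaffold alignments for a presence matrix
#'
#' For each component present in at least one taxon, emits an alignment of
#' uniform random amino-acid residues for exactly the present taxa (all rows
#' the requested length).  Components present nowhere are omitted.  No
#' substitution model is intended: these alignments only carry occupancy
#' structure for supermatrix tests.
#'
#' @param mat a `presence_matrix` (taxa x components).
#' @param lengths integer vector of alignment lengths (recycled over
#'   components), all >= 1.
#' @param seed mandatory integer seed.
#' @return named list of `Biostrings::AAStringSet`.
#' @export
simulate_alignments <- function(mat, lengths, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (any(lengths < 1L)) stop("alignment lengths must be >= 1")
  set.seed(as.integer(seed))
  lengths <- rep_len(as.integer(lengths), ncol(mat))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  out <- list()
  for (j in seq_len(ncol(mat))) {
    taxa <- rownames(mat)[mat[, j] == 1L]
    if (!length(taxa)) next
    seqs <- vapply(taxa, function(t)
      paste(sample(aa, lengths[j], replace = TRUE), collapse = ""), "")
    out[[colnames(mat)[j]]] <- Biostrings::AAStringSet(stats::setNames(seqs, taxa))
  }
  out
}

#' Compare inferred histories with simulation truth
#'
#' Per component: whether the inferred gain node equals the true one, whether
#' it is tipward (descendant-or-equal) of the true gain — parsimony can never
#' place a gain rootward of the truth — and the inferred-minus-true loss
#' count difference (<= 0 without censoring, by Dollo minimality).
#'
#' @param truth a `sim_truth` from [simulate_content()].
#' @param histories named list of `event_history` (same components).
#' @param tree the `reference_tree`.
#' @return list with `per_component` data.frame (component, observed,
#'   gain_recovered, gain_tipward, loss_diff) and `aggregate` (named numeric:
#'   n, n_observed, gain_recovery_rate, mean_loss_diff over observed
#'   components).
#' @export
recovery_report <- function(truth, histories, tree) {
  if (!setequal(names(truth), names(histories)))
    stop("truth and inferred histories cover different components")
  rows <- lapply(names(truth), function(comp) {
    tr <- truth[[comp]]; h <- histories[[comp]]
    if (is.na(h$gain_node)) {
      return(data.frame(component = comp, observed = FALSE,
                        gain_recovered = NA, gain_tipward = NA,
                        loss_diff = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(component = comp, observed = TRUE,
               gain_recovered = identical(h$gain_node, tr$gain_node),
               gain_tipward = is_ancestor(tree, tr$gain_node, h$gain_node),
               loss_diff = h$n_losses - length(tr$loss_edges),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  obs <- per[per$observed, , drop = FALSE]
  list(per_component = per,
       aggregate = c(n = nrow(per), n_observed = nrow(obs),
                     gain_recovery_rate = mean(obs$gain_recovered),
                     mean_loss_diff = mean(obs$loss_diff)))
}
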