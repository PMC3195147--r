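#' Single-gain (Dollo) parsimony reconstruction of one component's history
#'
#' Under the assumption that horizontal transfer between eukaryotes is rare,
#' each component is gained exactly once and may only be lost afterwards.
#' The gain node is then the MRCA of all tips carrying the component; an
#' internal node is reconstructed PRESENT iff it lies in the gain subtree and
#' has at least one present descendant tip; losses are the edges leading to
#' maximal all-absent subtrees inside the gain subtree.  This minimizes the
#' loss count among all single-gain placements.
#'
#' @param tree a `reference_tree`.
#' @param presence named 0/1 (or logical) vector over *all* tips of `tree`.
#' @param component component name carried into the history (default
#'   attribute-free `"component"`).
#' @return an object of class `event_history`: list with `component`,
#'   `gain_node` (label, or `NA` if the component is absent everywhere),
#'   `loss_edges` (child labels of loss edges, sorted), `n_losses`, and
#'   `node_states` (named PRESENT/ABSENT over all nodes).
#' @examples
#' tr <- read_ref_tree(system.file("extdata", "fig2.nwk", package = "lecatrace"),
#'                     sides = c(Unikonta = "UNIKONT", Bikonta = "BIKONT"))
#' pres <- setNames(as.integer(tree_tips(tr) %in% c("Metazoa", "Dikarya")),
#'                  tree_tips(tr))
#' dollo_infer(tr, pres, "toy")$gain_node  # "Opisthokonta"
#' @export
dollo_infer <- function(tree, presence, component = "component") {
  tips <- tree_tips(tree)
  if (is.logical(presence)) presence <- as.integer(presence)
  if (is.null(names(presence)) || !setequal(names(presence), tips) ||
      length(presence) != length(tips))
    stop("presence vector must be named by exactly the tree's tips")
  if (!all(presence %in% c(0L, 1L))) stop("presence values must be 0/1")
  presence <- presence[tips]

  n_all <- length(tree$labels)
  npres <- integer(n_all)                       # present descendant tips
  npres[seq_len(tree$n_tips)] <- presence
  for (id in rev(tree$preorder))                # postorder accumulation
    if (id > tree$n_tips) npres[id] <- sum(npres[tree$children[[id]]])

  states <- stats::setNames(rep("ABSENT", n_all), tree$labels)
  if (npres[.id(tree, tree$root)] == 0L) {
    return(structure(list(component = component, gain_node = NA_character_,
                          loss_edges = character(0), n_losses = 0L,
                          node_states = states),
                     class = "event_history"))
  }

  gain <- mrca_node(tree, tips[presence == 1L])
  # membership in gain subtree via preorder propagation
  in_sub <- logical(n_all)
  in_sub[.id(tree, gain)] <- TRUE
  for (id in tree$preorder) {
    if (in_sub[id]) for (ch in tree$children[[id]]) in_sub[ch] <- TRUE
  }
  states[in_sub & npres > 0L] <- "PRESENT"

  loss <- character(0)
  for (id in which(in_sub & npres == 0L)) {
    p <- tree$parent[id]
    if (!is.na(p) && in_sub[p] && npres[p] > 0L)   # maximal absent subtree
      loss <- c(loss, tree$labels[id])
  }
  structure(list(component = component, gain_node = gain,
                 loss_edges = sort(loss), n_losses = length(loss),
                 node_states = states),
            class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat("event_history '", x$component, "': gain at ",
      ifelse(is.na(x$gain_node), "NONE", x$gain_node), ", ", x$n_losses,
      " loss(es)", if (x$n_losses) paste0(" [",
      paste(x$loss_edges, collapse = ", "), "]"), "\n", sep = "")
  invisible(x)
}

#' Exhaustive single-gain oracle (small trees)
#'
#' Independent brute-force check for [dollo_infer()]: enumerates every
#' candidate gain node ancestral to all present tips (the MRCA and its
#' ancestors), counts maximal absent subtrees under each by direct recursion
#' over subtree tip sets, and returns the minimum and its argmin set.
#'
#' @inheritParams dollo_infer
#' @param max_tips refuse larger trees (enumeration is meant for small cases).
#' @return list with `min_losses` and `gain_nodes` (argmin labels).
#' @export
dollo_oracle <- function(tree, presence, max_tips = 12L) {
  if (tree$n_tips > max_tips) stop("dollo_oracle limited to ", max_tips, " tips")
  tips <- tree_tips(tree)
  presence <- presence[tips]
  present_tips <- tips[presence == 1L]
  if (!length(present_tips))
    return(list(min_losses = 0L, gain_nodes = character(0)))
  has_present <- function(node) any(subtree_tips(tree, node) %in% present_tips)
  count_losses <- function(node) {         # maximal absent subtrees below node
    if (!has_present(node)) return(1L)
    ch <- children_of(tree, node)
    if (!length(ch)) return(0L)
    sum(vapply(ch, count_losses, integer(1)))
  }
  m <- mrca_node(tree, present_tips)
  candidates <- c(m, ancestors_of(tree, m))
  counts <- vapply(candidates, count_losses, integer(1))
  list(min_losses = min(counts), gain_nodes = candidates[counts == min(counts)])
}

#' Rule for deciding presence in the root ancestor (LECA)
#'
#' `MRCA` mode calls a component present in the root ancestor iff its gain
#' node is the root itself, i.e. iff at least one lineage on each side of the
#' root bipartition carries it.  `CONSERVATIVE` mode requires at least `k`
#' major lineages on *each* side (the "at least two bikont and two unikont
#' major lineages" criterion with the default `k = 2`).
#'
#' @param mode `"MRCA"` or `"CONSERVATIVE"`.
#' @param k minimum lineages per root side (CONSERVATIVE only), `k >= 1`.
#' @export
leca_rule <- function(mode = c("MRCA", "CONSERVATIVE"), k = 2L) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  structure(list(mode = mode, k = as.integer(k)), class = "leca_rule")
}

#' Classify a component's status in the root ancestor
#'
#' @param history an `event_history` from [dollo_infer()].
#' @param tree the `reference_tree` it was inferred on.
#' @param rule a [leca_rule()].
#' @param tm optional `taxon_map`; needed when tips are species so that
#'   presence is counted per major lineage.  Tips already at lineage level
#'   need no map (each tip is its own lineage).
#' @return `"PRESENT"`, `"ABSENT"`, or `"NO_DATA"` (component absent from
#'   every tip).
#' @export
classify_leca <- function(history, tree, rule = leca_rule("MRCA"), tm = NULL) {
  if (is.na(history$gain_node)) return("NO_DATA")
  if (rule$mode == "MRCA")
    return(if (history$gain_node == tree$root) "PRESENT" else "ABSENT")
  tips <- tree_tips(tree)
  present_tips <- tips[history$node_states[tips] == "PRESENT"]
  lin <- if (is.null(tm)) present_tips else lineage_of(tm, present_tips)
  side_of_tip <- tip_sides(tree)
  side <- side_of_tip[present_tips]
  if (anyNA(side)) stop("tip(s) without a root side: ",
                        paste(present_tips[is.na(side)], collapse = ", "))
  n_uni <- length(unique(lin[side == "UNIKONT"]))
  n_bik <- length(unique(lin[side == "BIKONT"]))
  if (n_uni >= rule$k && n_bik >= rule$k) "PRESENT" else "ABSENT"
}

#' Infer origins for every component of a presence matrix
#'
#' Runs [dollo_infer()] per column and classifies each component's root
#' status under both rule modes.  Components listed in `inventory` but
#' missing from the matrix are reported `NO_DATA` with no events.
#'
#' @param tree a `reference_tree`.
#' @param mat a `presence_matrix` whose taxa are the tree's tips.
#' @param tm optional `taxon_map` (species-level data).
#' @param k threshold for the CONSERVATIVE column.
#' @param inventory optional character vector of all component names to
#'   report (defaults to the matrix columns).
#' @return list with `table` (data.frame: component, gain_node, n_losses,
#'   leca_mrca, leca_conservative) and `histories` (named list of
#'   `event_history`, matrix components only).
#' @export
infer_origins <- function(tree, mat, tm = NULL, k = 2L,
                          inventory = colnames(mat)) {
  tips <- tree_tips(tree)
  if (!setequal(rownames(mat), tips))
    stop("matrix taxa do not match tree tips; unmatched: ",
         paste(c(setdiff(rownames(mat), tips), setdiff(tips, rownames(mat))),
               collapse = ", "))
  rule_m <- leca_rule("MRCA")
  rule_c <- leca_rule("CONSERVATIVE", k)
  histories <- list()
  rows <- lapply(inventory, function(comp) {
    if (!comp %in% colnames(mat)) {
      return(data.frame(component = comp, gain_node = NA_character_,
                        n_losses = 0L, leca_mrca = "NO_DATA",
                        leca_conservative = "NO_DATA",
                        stringsAsFactors = FALSE))
    }
    h <- dollo_infer(tree, stats::setNames(mat[tips, comp], tips), comp)
    h$leca_status <- classify_leca(h, tree, rule_m, tm)
    histories[[comp]] <<- h
    data.frame(component = comp, gain_node = h$gain_node,
               n_losses = h$n_losses,
               leca_mrca = h$leca_status,
               leca_conservative = classify_leca(h, tree, rule_c, tm),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), histories = histories)
}

#' Aggregate gains and losses per branch across components
#'
#' Tallies, for every node, how many components were gained on the edge above
#' it (the root counts gains placed at the root itself) and how many were
#' lost on that edge.  A loss is *tentative* when every genome in the lost
#' subtree has status `P` (ongoing sequencing): absence there may reflect
#' incomplete data rather than a true loss.
#'
#' @param histories list of `event_history` objects on the same tree.
#' @param tree the `reference_tree`.
#' @param tm optional `taxon_map` providing species genome statuses; a tip is
#'   all-`P` iff it has at least one mapped species and all of them are `P`.
#' @return data.frame (one row per node, preorder): node, gains, losses,
#'   tentative_losses.
#' @export
map_events <- function(histories, tree, tm = NULL) {
  labs <- tree_nodes(tree)
  for (h in histories) {
    if (!all(c(h$gain_node[!is.na(h$gain_node)], h$loss_edges) %in% labs))
      stop("history '", h$component, "' does not live on this tree")
  }
  tip_all_p <- .tips_all_p(tree, tm)
  gains <- losses <- tentative <- stats::setNames(integer(length(labs)), labs)
  for (h in histories) {
    if (is.na(h$gain_node)) next
    gains[h$gain_node] <- gains[h$gain_node] + 1L
    for (e in h$loss_edges) {
      losses[e] <- losses[e] + 1L
      sub <- subtree_tips(tree, e)
      if (length(sub) && all(tip_all_p[sub]))
        tentative[e] <- tentative[e] + 1L
    }
  }
  data.frame(node = labs, gains = unname(gains), losses = unname(losses),
             tentative_losses = unname(tentative), stringsAsFactors = FALSE)
}

.tips_all_p <- function(tree, tm) {
  tips <- tree_tips(tree)
  out <- stats::setNames(rep(FALSE, length(tips)), tips)
  if (is.null(tm) || is.null(tm$species)) return(out)
  lin <- lineage_of(tm, tm$species$species)
  for (tp in tips) {
    st <- tm$species$status[lin == tp | tm$species$species == tp]
    if (length(st) && all(!is.na(st) & st == "P")) out[tp] <- TRUE
  }
  out
}

#' Annotate tentative losses on a history
#'
#' Adds a `tentative_losses` field: the subset of loss edges whose subtrees
#' contain only status-`P` genomes.
#' @inheritParams map_events
#' @param history an `event_history`.
#' @export
flag_tentative <- function(history, tree, tm = NULL) {
  tip_all_p <- .tips_all_p(tree, tm)
  history$tentative_losses <- history$loss_edges[vapply(
    history$loss_edges,
    function(e) { s <- subtree_tips(tree, e); length(s) > 0 && all(tip_all_p[s]) },
    logical(1))]
  history
}
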