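#' Rooted reference tree with a declared root bipartition
#'
#' A `reference_tree` wraps an [ape::read.tree()] phylogeny and adds the
#' bookkeeping the ancestral-content inference needs: unique labels on every
#' node (unlabeled internal nodes are auto-labeled `N<preorder index>`), fast
#' parent/children lookups, and a partition of the root's child subtrees into
#' the two sides of the root (`UNIKONT` / `BIKONT`).  Multifurcations are
#' preserved as-is; the constructor never resolves them.
#'
#' @param phy an object of class `phylo` (rooted; multifurcations allowed).
#' @param sides how to assign each root child to a side. Either a named
#'   character vector mapping root-child labels to `"UNIKONT"`/`"BIKONT"`, an
#'   unnamed character vector in root-child order, or a `taxon_map` (see
#'   [read_taxon_map()]), in which case each root-child subtree must contain
#'   tips of a single side.
#' @return an object of class `reference_tree`.
#' @export
ref_tree <- function(phy, sides) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a 'phylo' object")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stop("tree must have at least two tips")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  n_node <- phy$Nnode
  root_id <- n_tip + 1L
  if (!all(sort(unique(phy$edge[, 1L])) >= root_id) ||
      root_id %in% phy$edge[, 2L])
    stop("input tree has no unique root; refusing unrooted topology")

  parent <- integer(n_tip + n_node)
  parent[] <- NA_integer_
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- vector("list", n_tip + n_node)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])

  # preorder ids (root first, children in edge order)
  preorder <- integer(0)
  stack <- root_id
  while (length(stack)) {
    id <- stack[1L]; stack <- stack[-1L]
    preorder <- c(preorder, id)
    stack <- c(children[[id]], stack)
  }

  node_label <- phy$node.label
  if (is.null(node_label)) node_label <- rep("", n_node)
  node_label[is.na(node_label)] <- ""
  labels <- c(phy$tip.label, node_label)
  # auto-label unlabeled internals by preorder position
  for (k in seq_along(preorder)) {
    id <- preorder[k]
    if (id > n_tip && !nzchar(labels[id])) labels[id] <- paste0("N", k)
  }
  if (anyDuplicated(labels))
    stop("node labels not unique after auto-labeling: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))

  root_children <- children[[root_id]]
  root_sides <- .resolve_sides(sides, labels, root_children, children, n_tip)

  tr <- structure(list(
    phy = phy, n_tips = n_tip, labels = labels,
    id = stats::setNames(seq_along(labels), labels),
    parent = parent, children = children,
    preorder = preorder, root = labels[root_id],
    root_sides = root_sides,
    edge_length = phy$edge.length
  ), class = "reference_tree")
  tr
}

.resolve_sides <- function(sides, labels, root_children, children, n_tip) {
  ok <- c("UNIKONT", "BIKONT")
  if (inherits(sides, "taxon_map")) {
    assign <- character(length(root_children))
    for (i in seq_along(root_children)) {
      tips <- labels[.desc_tips_ids(root_children[i], children, n_tip)]
      s <- unique(unname(sides$sides[lineage_of(sides, tips)]))
      if (length(s) != 1L || is.na(s))
        stop("root child '", labels[root_children[i]],
             "' mixes sides or has unmapped tips; cannot derive root_sides")
      assign[i] <- s
    }
  } else {
    sides <- stats::setNames(toupper(as.character(sides)), names(sides))
    if (!all(sides %in% ok))
      stop("sides must be UNIKONT or BIKONT")
    if (!is.null(names(sides))) {
      missing <- setdiff(labels[root_children], names(sides))
      if (length(missing))
        stop("sides config does not cover root child(ren): ",
             paste(missing, collapse = ", "),
             "; tree rejected as effectively unrooted")
      assign <- unname(sides[labels[root_children]])
    } else {
      if (length(sides) != length(root_children))
        stop("unnamed sides must have one entry per root child (",
             length(root_children), ")")
      assign <- sides
    }
  }
  if (!all(ok %in% assign))
    stop("root_sides must contain both a UNIKONT and a BIKONT subtree")
  list(UNIKONT = labels[root_children[assign == "UNIKONT"]],
       BIKONT  = labels[root_children[assign == "BIKONT"]])
}

.desc_tips_ids <- function(id, children, n_tip) {
  out <- integer(0); stack <- id
  while (length(stack)) {
    x <- stack[1L]; stack <- stack[-1L]
    if (x <= n_tip) out <- c(out, x) else stack <- c(children[[x]], stack)
  }
  out
}

#' Read a rooted reference tree from a Newick file
#'
#' @param path path to a Newick file.
#' @inheritParams ref_tree
#' @return a `reference_tree`.
#' @examples
#' tr <- read_ref_tree(system.file("extdata", "fig2.nwk", package = "lecatrace"),
#'                     sides = c(Unikonta = "UNIKONT", Bikonta = "BIKONT"))
#' tree_tips(tr)
#' @export
read_ref_tree <- function(path, sides) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("cannot parse Newick file: ", path)
  ref_tree(phy, sides)
}

#' @export
print.reference_tree <- function(x, ...) {
  cat("reference_tree:", x$n_tips, "tips,",
      length(x$labels) - x$n_tips, "internal nodes, root =", x$root, "\n")
  cat("  UNIKONT side:", paste(x$root_sides$UNIKONT, collapse = ", "), "\n")
  cat("  BIKONT side: ", paste(x$root_sides$BIKONT, collapse = ", "), "\n")
  invisible(x)
}

#' Tree accessors
#'
#' `tree_tips()` returns tip labels, `tree_root()` the root label,
#' `tree_nodes()` all labels in preorder, `children_of()`/`parent_of()`
#' navigate by label, `subtree_tips()` lists the tips below a node (a tip is
#' below itself), and `ancestors_of()` lists strict ancestors from parent up
#' to the root.
#'
#' @param tree a `reference_tree`.
#' @param label a node label.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
tree_tips <- function(tree) tree$labels[seq_len(tree$n_tips)]

#' @rdname tree-accessors
#' @export
tree_root <- function(tree) tree$root

#' @rdname tree-accessors
#' @export
tree_nodes <- function(tree) tree$labels[tree$preorder]

.id <- function(tree, label) {
  id <- tree$id[label]
  if (anyNA(id)) stop("node(s) not in tree: ",
                      paste(label[is.na(id)], collapse = ", "))
  unname(id)
}

#' @rdname tree-accessors
#' @export
children_of <- function(tree, label)
  tree$labels[tree$children[[.id(tree, label)]]]

#' @rdname tree-accessors
#' @export
parent_of <- function(tree, label) {
  p <- tree$parent[.id(tree, label)]
  if (is.na(p)) NA_character_ else tree$labels[p]
}

#' @rdname tree-accessors
#' @export
subtree_tips <- function(tree, label)
  tree$labels[.desc_tips_ids(.id(tree, label), tree$children, tree$n_tips)]

#' @rdname tree-accessors
#' @export
ancestors_of <- function(tree, label) {
  out <- character(0)
  id <- .id(tree, label)
  repeat {
    id <- tree$parent[id]
    if (is.na(id)) break
    out <- c(out, tree$labels[id])
  }
  out
}

#' Is node `a` an ancestor of (or equal to) node `b`?
#' @param tree a `reference_tree`.
#' @param a,b node labels.
#' @export
is_ancestor <- function(tree, a, b) a == b || a %in% ancestors_of(tree, b)

#' Side of the root bipartition each tip falls on
#' @param tree a `reference_tree`.
#' @return named character vector over tips with values UNIKONT/BIKONT.
#' @export
tip_sides <- function(tree) {
  out <- stats::setNames(rep(NA_character_, tree$n_tips), tree_tips(tree))
  for (side in names(tree$root_sides))
    for (child in tree$root_sides[[side]])
      out[subtree_tips(tree, child)] <- side
  out
}

#' Most recent common ancestor of a set of tips
#'
#' The deepest node ancestral to every tip in `tips`; for a single tip, the
#' tip itself.  This is the gain node under single-gain parsimony: observing a
#' component in two lineages implies its presence in their last common
#' ancestor.
#'
#' @param tree a `reference_tree`.
#' @param tips non-empty character vector of tip labels.
#' @return the MRCA node label.
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == 0L) stop("mrca_node: empty tip set")
  ids <- .id(tree, tips)
  if (!all(ids <= tree$n_tips)) stop("mrca_node: not all labels are tips")
  # chain = ancestors-or-self of the running MRCA, ordered tipward->root
  chain <- c(ids[1L], .anc_ids(tree, ids[1L]))
  for (id in ids[-1L]) {
    cur <- id
    while (!(cur %in% chain)) cur <- tree$parent[cur]
    chain <- chain[which(chain == cur):length(chain)]
  }
  tree$labels[chain[1L]]
}

.anc_ids <- function(tree, id) {
  out <- integer(0)
  repeat {
    id <- tree$parent[id]
    if (is.na(id)) break
    out <- c(out, id)
  }
  out
}

# Deterministic Newick serializer; `tags` is an optional named character
# vector of NHX comment strings (without brackets) keyed by node label.
.serialize_newick <- function(tree, tags = NULL, lengths = TRUE) {
  has_len <- lengths && !is.null(tree$edge_length)
  edge_len <- function(id) {
    if (!has_len) return("")
    i <- which(tree$phy$edge[, 2L] == id)
    if (!length(i)) return("")
    paste0(":", format(tree$edge_length[i], digits = 15))
  }
  rec <- function(id) {
    lab <- tree$labels[id]
    tag <- if (!is.null(tags) && lab %in% names(tags) && nzchar(tags[[lab]]))
      paste0("[&&NHX:", tags[[lab]], "]") else ""
    if (id <= tree$n_tips) return(paste0(lab, tag, edge_len(id)))
    inner <- vapply(tree$children[[id]], rec, character(1))
    paste0("(", paste(inner, collapse = ","), ")", lab, tag, edge_len(id))
  }
  paste0(rec(.id(tree, tree$root)), ";")
}

#' Write a reference tree to Newick
#'
#' Output is deterministic (stable child order, fixed number formatting) so
#' identical trees serialize byte-identically.
#'
#' @param tree a `reference_tree`.
#' @param path output file path.
#' @export
write_ref_tree <- function(tree, path) {
  writeLines(.serialize_newick(tree), path)
  invisible(path)
}
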