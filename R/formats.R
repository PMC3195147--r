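#' Read a binary presence/absence matrix from TSV
#'
#' First column holds taxon names (header `taxon` by convention), remaining
#' columns one component each; cells must be 0/1.  Row and column order are
#' preserved.
#'
#' @param path path to a tab-delimited UTF-8 file.
#' @return an integer matrix (taxa x components) of class `presence_matrix`.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (nrow(df) == 0L) stop("presence matrix has an empty data section: ", path)
  if (ncol(df) < 2L) stop("presence matrix needs a taxon column plus >=1 component")
  taxa <- trimws(df[[1L]])
  if (anyDuplicated(taxa))
    stop("duplicate taxon in presence matrix: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  comp <- colnames(df)[-1L]
  if (anyDuplicated(comp))
    stop("duplicate component column: ",
         paste(unique(comp[duplicated(comp)]), collapse = ", "))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[] <- trimws(cells)
  nonbin <- !(cells %in% c("0", "1"))
  dim(nonbin) <- dim(cells)
  bad <- which(nonbin, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary cell at row '", taxa[bad[1L, 1L]], "', column '",
         comp[bad[1L, 2L]], "': '", cells[bad[1L, , drop = FALSE]], "'")
  }
  presence_matrix(matrix(as.integer(cells), nrow = length(taxa),
                         dimnames = list(taxa, comp)))
}

#' Construct/validate a presence matrix
#' @param x an integer/numeric matrix with taxa as rownames and components as
#'   colnames; cells 0/1.
#' @export
presence_matrix <- function(x) {
  if (!is.matrix(x)) stop("presence matrix must be a matrix")
  if (is.null(rownames(x)) || (ncol(x) > 0L && is.null(colnames(x))))
    stop("presence matrix needs row (taxa) and column (component) names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate taxa or components")
  if (!all(x %in% c(0L, 1L))) stop("presence matrix cells must be 0/1")
  storage.mode(x) <- "integer"
  class(x) <- c("presence_matrix", "matrix")
  x
}

#' @export
write_presence_matrix <- function(x, path) {
  .write_tsv_matrix(unclass(x), path, first = "taxon")
  invisible(path)
}

.write_tsv_matrix <- function(m, path, first) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste(c(first, colnames(m)), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con, sep = "\n")
}

# --- categorical lineage profiles ------------------------------------------

.PROFILE_LEVELS <- c("ABSENT", "LT_HALF", "GEQ_HALF", "ALL")

.normalize_token <- function(tok) {
  t <- gsub("[[:space:] ]+", "", tok)
  if (t == "") return("ABSENT")
  if (t == "100") return("ALL")
  if (t %in% c("≥50", ">=50", ">50", "50", "Half", "half", "HALF"))
    return("GEQ_HALF")
  if (t %in% c("<50")) return("LT_HALF")
  NA_character_
}

#' Read a categorical lineage profile from TSV
#'
#' Accepts the printed table dialect: `100` (all sampled species), `>=50` /
#' `≥50` / `>50` / `Half` / `50` (at least half), `< 50` (fewer than
#' half), and blank (none).  Tokens are whitespace-insensitive; both the
#' typographic `≥` glyph and ASCII `>=` are accepted.  Cells normalize
#' to `ALL`, `GEQ_HALF`, `LT_HALF`, `ABSENT`.
#'
#' @param path path to a tab-delimited file; first column `lineage`, header
#'   row component names.
#' @return a character matrix (lineages x components) of class
#'   `lineage_profile` with cells in the four categories.
#' @export
read_lineage_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("profile has an empty data section: ", path)
  lineages <- trimws(df[[1L]])
  comp <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  out <- matrix(NA_character_, nrow(cells), ncol(cells),
                dimnames = list(lineages, comp))
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    v <- .normalize_token(cells[i, j])
    if (is.na(v))
      stop("unknown profile token '", cells[i, j], "' at row '", lineages[i],
           "', column '", comp[j], "'")
    out[i, j] <- v
  }
  lineage_profile(out)
}

#' Construct/validate a lineage profile
#' @param x a character matrix with cells in
#'   `ALL`/`GEQ_HALF`/`LT_HALF`/`ABSENT`, lineages as rownames and components
#'   as colnames.
#' @export
lineage_profile <- function(x) {
  if (!is.matrix(x) || !is.character(x)) stop("profile must be a character matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("profile needs lineage rownames and component colnames")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate lineages or components")
  bad <- setdiff(unique(as.vector(x)), .PROFILE_LEVELS)
  if (length(bad)) stop("invalid profile categories: ", paste(bad, collapse = ", "))
  class(x) <- c("lineage_profile", "matrix")
  x
}

#' @export
write_lineage_profile <- function(x, path) {
  tok <- c(ABSENT = "", LT_HALF = "<50", GEQ_HALF = ">=50", ALL = "100")
  m <- matrix(tok[unclass(x)], nrow(x), ncol(x), dimnames = dimnames(x))
  .write_tsv_matrix(m, path, first = "lineage")
  invisible(path)
}

# --- taxon map --------------------------------------------------------------

#' Read a taxon map from JSON
#'
#' The map has a mandatory `sides` object (major lineage -> `UNIKONT` or
#' `BIKONT`) and an optional `species` object (species -> `{lineage, status}`
#' with status one of `C` complete, `A` draft assembly, `P` ongoing).  When no
#' species entry exists for a taxon, the taxon is assumed to *be* a lineage
#' (lineage-level data).
#'
#' @param path path to a JSON file.
#' @return an object of class `taxon_map`: list with `sides` (named character)
#'   and `species` (data.frame or NULL).
#' @export
read_taxon_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$sides)) stop("taxon map lacks a 'sides' object: ", path)
  sides <- toupper(unlist(obj$sides))
  if (!all(sides %in% c("UNIKONT", "BIKONT")))
    stop("taxon map sides must be UNIKONT/BIKONT")
  species <- NULL
  if (!is.null(obj$species) && length(obj$species)) {
    species <- data.frame(
      species = names(obj$species),
      lineage = vapply(obj$species, function(s) as.character(s$lineage), ""),
      status = vapply(obj$species, function(s)
        if (is.null(s$status)) NA_character_ else toupper(as.character(s$status)), ""),
      stringsAsFactors = FALSE, row.names = NULL)
    bad <- !is.na(species$status) & !(species$status %in% c("C", "A", "P"))
    if (any(bad))
      stop("invalid genome status for: ",
           paste(species$species[bad], collapse = ", "), " (allowed: C, A, P)")
    unk <- setdiff(species$lineage, names(sides))
    if (length(unk))
      stop("species mapped to lineage(s) without a root side: ",
           paste(unk, collapse = ", "))
  }
  structure(list(sides = sides, species = species), class = "taxon_map")
}

#' Build a taxon map in code
#' @param sides named character vector, lineage -> UNIKONT/BIKONT.
#' @param species optional data.frame with columns species, lineage, status.
#' @export
taxon_map <- function(sides, species = NULL) {
  structure(list(sides = sides, species = species), class = "taxon_map")
}

#' Lineage of each taxon under a taxon map
#'
#' Species resolve through the species table; taxa without a species entry
#' must themselves be lineages named in `sides`.
#'
#' @param tm a `taxon_map`.
#' @param taxa character vector of taxon names.
#' @return character vector of lineages.
#' @export
lineage_of <- function(tm, taxa) {
  out <- rep(NA_character_, length(taxa))
  if (!is.null(tm$species)) {
    i <- match(taxa, tm$species$species)
    out[!is.na(i)] <- tm$species$lineage[i[!is.na(i)]]
  }
  miss <- is.na(out)
  out[miss & taxa %in% names(tm$sides)] <- taxa[miss & taxa %in% names(tm$sides)]
  if (anyNA(out))
    stop("taxa not mapped to any lineage: ",
         paste(taxa[is.na(out)], collapse = ", "))
  out
}

#' Genome status of each taxon (NA when unknown)
#' @inheritParams lineage_of
#' @export
status_of <- function(tm, taxa) {
  out <- rep(NA_character_, length(taxa))
  if (!is.null(tm$species)) {
    i <- match(taxa, tm$species$species)
    out[!is.na(i)] <- tm$species$status[i[!is.na(i)]]
  }
  stats::setNames(out, taxa)
}

# --- event reports ----------------------------------------------------------

#' Write event histories as a TSV report plus an annotated Newick tree
#'
#' The TSV has one row per component, sorted by component name, with the gain
#' edge, loss edges, root-ancestor status and tentative losses.  The Newick
#' output carries `[&&NHX:gains=..:losses=..]` comment tags on nodes with at
#' least one event (a gain is attached to the gain node, a loss to the child
#' node of the loss edge).  Output is byte-identical for identical input.
#'
#' @param reports a list of `event_history` objects (see [dollo_infer()]),
#'   optionally carrying `leca_status` and `tentative_losses` fields (see
#'   [classify_leca()], [map_events()]).
#' @param tree the `reference_tree` the histories live on.
#' @param tsv_path,nwk_path output paths.
#' @export
write_event_reports <- function(reports, tree, tsv_path, nwk_path) {
  for (h in reports) {
    nodes <- c(if (!is.na(h$gain_node)) h$gain_node, h$loss_edges)
    bad <- setdiff(nodes, tree$labels)
    if (length(bad))
      stop("event report for '", h$component, "' references node(s) not in tree: ",
           paste(bad, collapse = ", "))
  }
  ord <- order(vapply(reports, function(h) h$component, ""))
  reports <- reports[ord]
  fmt_edge <- function(node) {
    if (is.na(node)) return("NONE")
    p <- parent_of(tree, node)
    if (is.na(p)) "ROOT" else paste0(p, "->", node)
  }
  rows <- vapply(reports, function(h) {
    losses <- sort(h$loss_edges)
    paste(c(h$component, fmt_edge(h$gain_node),
            if (length(losses)) paste(vapply(losses, fmt_edge, ""), collapse = ";") else "NONE",
            length(losses),
            if (is.null(h$leca_status)) "NA" else h$leca_status,
            if (length(h$tentative_losses))
              paste(sort(h$tentative_losses), collapse = ";") else "NONE"),
          collapse = "\t")
  }, "")
  con <- file(tsv_path, open = "wb")
  writeLines(c(paste(c("component", "gain_edge", "loss_edges", "n_losses",
                       "leca_status", "tentative_losses"), collapse = "\t"),
               rows), con, sep = "\n")
  close(con)

  gains <- table(unlist(lapply(reports, function(h)
    if (is.na(h$gain_node)) character(0) else h$gain_node)))
  losses <- table(unlist(lapply(reports, function(h) h$loss_edges)))
  nodes <- sort(unique(c(names(gains), names(losses))))
  tags <- stats::setNames(vapply(nodes, function(nd) {
    g <- if (nd %in% names(gains)) gains[[nd]] else 0L
    l <- if (nd %in% names(losses)) losses[[nd]] else 0L
    paste(c(if (g > 0) paste0("gains=", g), if (l > 0) paste0("losses=", l)),
          collapse = ":")
  }, ""), nodes)
  con <- file(nwk_path, open = "wb")
  writeLines(.serialize_newick(tree, tags = tags), con, sep = "\n")
  close(con)
  invisible(tsv_path)
}

#' Read the 37-component inventory bundled with the package
#' @param path path to a component inventory TSV (component, class, group,
#'   table); defaults to the packaged one.
#' @export
read_components <- function(path = system.file("extdata", "components.tsv",
                                               package = "lecatrace")) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = "NA")
}
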