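#' Read per-component FASTA alignments
#'
#' @param paths named character vector of FASTA paths (names = component
#'   names; unnamed paths use the file basename without extension), or a
#'   single directory containing `.fa`/`.fasta` files.
#' @return named list of `Biostrings::AAStringSet`, each internally
#'   rectangular with unique, whitespace-normalized taxon names.
#' @export
read_alignments <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    paths <- sort(paths)
  }
  if (!length(paths)) stop("no alignment files found")
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("\\.(fa|fasta)$", "", basename(paths))
  out <- lapply(seq_along(paths), function(i) {
    aln <- Biostrings::readAAStringSet(paths[i])
    .validate_alignment(aln, names(paths)[i])
  })
  stats::setNames(out, names(paths))
}

.validate_alignment <- function(aln, name) {
  if (!length(aln)) stop("alignment '", name, "' is empty")
  nm <- trimws(sub("[[:space:]].*$", "", names(aln)))  # id up to first space
  if (anyDuplicated(nm))
    stop("duplicate taxon in alignment '", name, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(aln) <- nm
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("alignment '", name, "' is ragged (row lengths ",
         paste(sort(unique(w)), collapse = ", "), ")")
  aln
}

#' Concatenate per-component alignments into a partitioned supermatrix
#'
#' Taxa are the union across alignments, in order of first appearance.  A
#' taxon absent from a component has its whole block filled with `?`
#' (missing), distinct from within-sequence alignment gaps `-`.  Partition
#' coordinates are 1-based inclusive and tile the full length in input
#' component order.
#'
#' @param alignments named list of `AAStringSet` (or anything coercible via
#'   `as.character` to named equal-length strings per component).
#' @return an object of class `supermatrix`: list with `taxa`, `partitions`
#'   (data.frame component/start/end), `seqs` (named full-length strings) and
#'   `present` (logical taxa x partitions matrix).
#' @export
concatenate_alignments <- function(alignments) {
  if (!length(alignments) || is.null(names(alignments)))
    stop("need a named list of alignments")
  chr <- lapply(names(alignments), function(comp) {
    a <- alignments[[comp]]
    v <- if (inherits(a, "XStringSet")) {
      stats::setNames(as.character(a), names(a))
    } else if (is.character(a)) a else
      stats::setNames(as.character(a), names(a))
    if (is.null(names(v))) stop("alignment '", comp, "' has unnamed sequences")
    if (length(unique(nchar(v))) != 1L) stop("alignment '", comp, "' is ragged")
    if (anyDuplicated(names(v))) stop("duplicate taxon in alignment '", comp, "'")
    v
  })
  names(chr) <- names(alignments)
  taxa <- unique(unlist(lapply(chr, names), use.names = FALSE))
  lens <- vapply(chr, function(v) nchar(v[[1L]]), integer(1))
  end <- cumsum(lens)
  partitions <- data.frame(component = names(chr),
                           start = c(1L, utils::head(end, -1L) + 1L),
                           end = end, stringsAsFactors = FALSE,
                           row.names = NULL)
  present <- matrix(FALSE, length(taxa), length(chr),
                    dimnames = list(taxa, names(chr)))
  blocks <- matrix("", length(taxa), length(chr), dimnames = dimnames(present))
  for (j in seq_along(chr)) {
    filler <- strrep("?", lens[j])
    blocks[, j] <- filler
    blocks[names(chr[[j]]), j] <- unname(chr[[j]])
    present[names(chr[[j]]), j] <- TRUE
  }
  seqs <- stats::setNames(apply(blocks, 1L, paste, collapse = ""), taxa)
  structure(list(taxa = taxa, partitions = partitions, seqs = seqs,
                 present = present), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$taxa), "taxa x",
      x$partitions$end[nrow(x$partitions)], "columns in",
      nrow(x$partitions), "partition(s)\n")
  invisible(x)
}

#' Per-taxon missing-data fractions and per-partition occupancy
#'
#' By default the missing fraction of a taxon counts only columns of
#' partitions where the taxon has *no sequence at all* (whole-component
#' absence, the accounting behind a "> 60% missing data" taxon filter).  With
#' `gaps_as_missing = TRUE`, `-` and `?` characters inside present sequences
#' are counted too.
#'
#' @param sm a `supermatrix`.
#' @param gaps_as_missing logical flag (default FALSE).
#' @return list with `per_taxon` (data.frame taxon/missing_fraction) and
#'   `per_partition` (data.frame component/n_taxa).
#' @export
alignment_occupancy <- function(sm, gaps_as_missing = FALSE) {
  total <- sm$partitions$end[nrow(sm$partitions)]
  if (gaps_as_missing) {
    miss <- vapply(sm$seqs, function(s)
      sum(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("?", "-")), integer(1))
  } else {
    lens <- sm$partitions$end - sm$partitions$start + 1L
    miss <- as.vector((!sm$present) %*% lens)
  }
  list(per_taxon = data.frame(taxon = sm$taxa,
                              missing_fraction = unname(miss) / total,
                              stringsAsFactors = FALSE),
       per_partition = data.frame(component = sm$partitions$component,
                                  n_taxa = as.integer(unname(colSums(sm$present))),
                                  stringsAsFactors = FALSE))
}

#' Drop taxa exceeding a missing-data threshold
#'
#' Retains exactly the taxa whose missing fraction is `<= max_missing`;
#' partitions are never changed.  An explicit `exclude` list drops taxa
#' regardless of occupancy (e.g. species removed for multi-copy genes).
#'
#' @param sm a `supermatrix`.
#' @param max_missing fraction in \[0, 1\] (default 0.60: taxa with more than
#'   60\% missing data are discarded).
#' @param exclude character vector of taxa to drop unconditionally.
#' @inheritParams alignment_occupancy
#' @export
filter_taxa <- function(sm, max_missing = 0.60, exclude = character(0),
                        gaps_as_missing = FALSE) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0,1]")
  occ <- alignment_occupancy(sm, gaps_as_missing)
  keep <- occ$per_taxon$missing_fraction <= max_missing &
    !(sm$taxa %in% exclude)
  if (!any(keep)) {
    bad <- paste0(occ$per_taxon$taxon, " (",
                  round(occ$per_taxon$missing_fraction, 3), ")", collapse = ", ")
    stop("filter removes every taxon; occupancy report: ", bad)
  }
  sm$taxa <- sm$taxa[keep]
  sm$seqs <- sm$seqs[keep]
  sm$present <- sm$present[keep, , drop = FALSE]
  sm
}

#' Write a supermatrix (FASTA + partition table, optional NEXUS sets and
#' occupancy TSV)
#'
#' The partition file uses the RAxML convention `PROT, name = start-end`
#' with 1-based inclusive coordinates.
#'
#' @param sm a `supermatrix`.
#' @param fasta,partitions output paths (required).
#' @param nexus_sets optional path for a NEXUS `sets` block.
#' @param occupancy_tsv optional path for the per-taxon occupancy report.
#' @export
write_supermatrix <- function(sm, fasta, partitions, nexus_sets = NULL,
                              occupancy_tsv = NULL) {
  con <- file(fasta, open = "wb")
  for (tx in sm$taxa)
    writeLines(c(paste0(">", tx), sm$seqs[[tx]]), con, sep = "\n")
  close(con)
  con <- file(partitions, open = "wb")
  writeLines(sprintf("PROT, %s = %d-%d", sm$partitions$component,
                     sm$partitions$start, sm$partitions$end), con, sep = "\n")
  close(con)
  if (!is.null(nexus_sets)) {
    con <- file(nexus_sets, open = "wb")
    writeLines(c("#NEXUS", "begin sets;",
                 sprintf("  charset %s = %d-%d;",
                         gsub("[^A-Za-z0-9_]", "_", sm$partitions$component),
                         sm$partitions$start, sm$partitions$end),
                 "end;"), con, sep = "\n")
    close(con)
  }
  if (!is.null(occupancy_tsv)) {
    occ <- alignment_occupancy(sm)$per_taxon
    con <- file(occupancy_tsv, open = "wb")
    writeLines(c("taxon\tmissing_fraction",
                 sprintf("%s\t%s", occ$taxon,
                         format(occ$missing_fraction, digits = 15))),
               con, sep = "\n")
    close(con)
  }
  invisible(fasta)
}

#' Read back a supermatrix from FASTA + partition table
#' @param fasta,partitions paths written by [write_supermatrix()].
#' @return a `supermatrix`; a taxon is recorded absent from a partition iff
#'   its block is entirely `?`.
#' @export
read_supermatrix <- function(fasta, partitions) {
  # BStringSet: '?' missing markers are outside the amino-acid alphabet
  aln <- Biostrings::readBStringSet(fasta)
  seqs <- stats::setNames(as.character(aln), trimws(names(aln)))
  part <- utils::read.table(partitions, sep = ",", strip.white = TRUE,
                            col.names = c("model", "def"),
                            stringsAsFactors = FALSE)
  def <- strsplit(part$def, "=")
  parts <- data.frame(
    component = trimws(vapply(def, `[`, "", 1L)),
    start = as.integer(sub("-.*", "", trimws(vapply(def, `[`, "", 2L)))),
    end = as.integer(sub(".*-", "", trimws(vapply(def, `[`, "", 2L)))),
    stringsAsFactors = FALSE)
  taxa <- names(seqs)
  present <- matrix(FALSE, length(taxa), nrow(parts),
                    dimnames = list(taxa, parts$component))
  for (j in seq_len(nrow(parts))) {
    block <- substr(seqs, parts$start[j], parts$end[j])
    present[, j] <- block != strrep("?", parts$end[j] - parts$start[j] + 1L)
  }
  structure(list(taxa = taxa, partitions = parts, seqs = seqs,
                 present = present), class = "supermatrix")
}
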