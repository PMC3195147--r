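#' Collapse a species-level presence matrix to a categorical lineage profile
#'
#' For each major lineage with at least one sampled species, the presence
#' fraction f = (species with the component) / (species sampled) maps to a
#' category: f = 1 -> `ALL` ("100"), 0.5 <= f < 1 -> `GEQ_HALF` (">=50"),
#' 0 < f < 0.5 -> `LT_HALF` ("<50"), f = 0 -> `ABSENT` (blank).  The boundary
#' f = 0.5 belongs to `GEQ_HALF`: a 1-of-2 lineage prints as "Half"/"50" in
#' the source tables and supports downstream presence.  Lineages with zero
#' sampled species are omitted, not emitted as empty rows.
#'
#' @param mat a `presence_matrix` (species x components).
#' @param tm a `taxon_map` mapping every matrix taxon to a lineage.
#' @return a `lineage_profile` (lineages x components); lineage order follows
#'   first appearance in the matrix.
#' @export
summarize_lineages <- function(mat, tm) {
  lin <- lineage_of(tm, rownames(mat))
  lineages <- unique(lin)
  out <- matrix(NA_character_, length(lineages), ncol(mat),
                dimnames = list(lineages, colnames(mat)))
  for (L in lineages) {
    sub <- mat[lin == L, , drop = FALSE]
    f <- colSums(sub) / nrow(sub)
    out[L, ] <- ifelse(f == 0, "ABSENT",
                ifelse(f == 1, "ALL",
                ifelse(f >= 0.5, "GEQ_HALF", "LT_HALF")))
  }
  lineage_profile(out)
}

#' Binarize a categorical lineage profile
#'
#' Any printed category counts as presence: a lineage retaining a component
#' in even a minority of its species still witnesses that component for
#' ancestral inference (`ALL`, `GEQ_HALF`, `LT_HALF` -> 1; `ABSENT` -> 0).
#'
#' @param profile a `lineage_profile`.
#' @return a `presence_matrix` with lineages as taxa.
#' @export
binarize_profile <- function(profile) {
  m <- (unclass(profile) != "ABSENT") * 1L
  presence_matrix(m)
}
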