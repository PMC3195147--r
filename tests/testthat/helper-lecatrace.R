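fx <- function(name) {
  p <- system.file("extdata", name, package = "lecatrace")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

load_fig2 <- function() {
  tm <- read_taxon_map(fx("fig2_taxa.json"))
  list(tree = read_ref_tree(fx("fig2.nwk"), sides = tm), tm = tm)
}

# binarized Tables 1+2 profiles, plus the full 37-component inventory
fig2_binary <- function() {
  m <- cbind(binarize_profile(read_lineage_profile(fx("table1_profile.tsv"))),
             binarize_profile(read_lineage_profile(fx("table2_profile.tsv"))))
  presence_matrix(m)
}

random_ref_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  nch <- sum(phy$edge[, 1L] == length(phy$tip.label) + 1L)
  ref_tree(phy, rep(c("UNIKONT", "BIKONT"), length.out = nch))
}

random_presence <- function(tree, p = 0.5) {
  tips <- tree_tips(tree)
  stats::setNames(stats::rbinom(length(tips), 1L, p), tips)
}

# Independent MRCA oracle: intersect ancestor-or-self paths, pick the
# deepest member (max root distance).
mrca_by_path_intersection <- function(tree, tips) {
  paths <- lapply(tips, function(t) c(t, ancestors_of(tree, t)))
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(n) length(ancestors_of(tree, n)), integer(1))
  common[which.max(depth)]
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
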