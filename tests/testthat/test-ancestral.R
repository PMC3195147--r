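test_that("mrca_node: named ancestors, degenerate cases, oracle agreement", {
  f <- load_fig2()
  expect_identical(mrca_node(f$tree, c("Metazoa", "Dikarya")), "Opisthokonta")
  expect_identical(mrca_node(f$tree, tree_tips(f$tree)), "LECA")
  expect_identical(mrca_node(f$tree, "Metazoa"), "Metazoa")
  expect_identical(mrca_node(f$tree, c("Viridiplantae", "Rhodophyta")), "Plantae")
  expect_error(mrca_node(f$tree, character(0)), "empty")
  expect_error(mrca_node(f$tree, c("Metazoa", "Opisthokonta")), "tips")

  set.seed(7)
  for (draw in 1:200) {
    tr <- random_ref_tree(sample(4:20, 1), seed = 1000 + draw)
    tips <- sample(tree_tips(tr), sample(seq_len(tr$n_tips), 1))
    expect_identical(mrca_node(tr, tips), mrca_by_path_intersection(tr, tips))
  }
})

test_that("dollo_infer reproduces the stated example histories", {
  f <- load_fig2()
  tips <- tree_tips(f$tree)

  # present in a single lineage: gained on that terminal edge, zero losses
  apc16 <- stats::setNames(as.integer(tips == "Metazoa"), tips)
  h <- dollo_infer(f$tree, apc16, "Apc16")
  expect_identical(h$gain_node, "Metazoa")
  expect_identical(h$n_losses, 0L)
  expect_identical(classify_leca(h, f$tree), "ABSENT")

  # present everywhere: gain at root, zero losses
  h_all <- dollo_infer(f$tree, stats::setNames(rep(1L, 15), tips))
  expect_identical(h_all$gain_node, "LECA")
  expect_identical(h_all$n_losses, 0L)
  expect_identical(classify_leca(h_all, f$tree), "PRESENT")

  # six-tip worked example: gain at root, four terminal losses
  tr <- ref_tree(ape::read.tree(text = "(((A,B),C),((D,E),F));"),
                 sides = c("UNIKONT", "BIKONT"))
  pres <- stats::setNames(as.integer(tree_tips(tr) %in% c("A", "D")),
                          tree_tips(tr))
  h6 <- dollo_infer(tr, pres)
  expect_identical(h6$gain_node, tree_root(tr))
  expect_setequal(h6$loss_edges, c("B", "C", "E", "F"))
  orc <- dollo_oracle(tr, pres)
  expect_identical(orc$min_losses, 4L)
  expect_true(h6$gain_node %in% orc$gain_nodes)

  # all-absent input: no gain, no losses
  h0 <- dollo_infer(f$tree, stats::setNames(rep(0L, 15), tips))
  expect_true(is.na(h0$gain_node))
  expect_identical(h0$n_losses, 0L)
  expect_identical(classify_leca(h0, f$tree), "NO_DATA")

  expect_error(dollo_infer(f$tree, c(A = 1L)), "named by exactly")
})

test_that("dollo invariants hold on random instances (property sweep)", {
  set.seed(11)
  for (rep in 1:60) {
    tr <- random_ref_tree(sample(4:8, 1), seed = 2000 + rep)
    pres <- random_presence(tr, p = stats::runif(1, 0.2, 0.8))
    h <- dollo_infer(tr, pres)
    tips <- tree_tips(tr)

    # tip fidelity
    expect_identical(unname(h$node_states[tips] == "PRESENT"),
                     unname(pres == 1L))
    # single gain; gain=NONE iff all-absent
    expect_identical(is.na(h$gain_node), sum(pres) == 0L)
    if (!is.na(h$gain_node)) {
      # losses strictly inside the gain subtree, never the gain itself
      for (e in h$loss_edges) {
        expect_true(is_ancestor(tr, h$gain_node, e) && e != h$gain_node)
        expect_false(any(pres[subtree_tips(tr, e)] == 1L))
      }
      # maximality: no loss edge is an ancestor of another
      for (a in h$loss_edges) for (b in h$loss_edges)
        if (a != b) expect_false(is_ancestor(tr, a, b))
      # equivalence with the exhaustive oracle
      orc <- dollo_oracle(tr, pres)
      expect_identical(h$n_losses, orc$min_losses)
      expect_true(h$gain_node %in% orc$gain_nodes)
    }
  }
})

test_that("oracle dominance: presence confined to one subtree excludes the root", {
  tr <- ref_tree(ape::read.tree(text = "(((A,B),C),((D,E),F));"),
                 sides = c("UNIKONT", "BIKONT"))
  pres <- stats::setNames(as.integer(tree_tips(tr) %in% c("A", "B")),
                          tree_tips(tr))
  orc <- dollo_oracle(tr, pres)
  expect_false(tree_root(tr) %in% orc$gain_nodes)
  # all-present: zero losses, root among the optima
  all1 <- stats::setNames(rep(1L, 6), tree_tips(tr))
  orc1 <- dollo_oracle(tr, all1)
  expect_identical(orc1$min_losses, 0L)
  expect_true(tree_root(tr) %in% orc1$gain_nodes)
})

test_that("LECA rules reproduce the printed verdicts and nest correctly", {
  f <- load_fig2()
  b2 <- binarize_profile(read_lineage_profile(fx("table2_profile.tsv")))
  tips <- tree_tips(f$tree)

  scc4 <- dollo_infer(f$tree, stats::setNames(b2[tips, "Scc4"], tips), "Scc4")
  expect_identical(classify_leca(scc4, f$tree, leca_rule("MRCA")), "PRESENT")
  expect_identical(classify_leca(scc4, f$tree, leca_rule("CONSERVATIVE", 2)),
                   "ABSENT")

  securin <- dollo_infer(f$tree, stats::setNames(b2[tips, "Securin"], tips))
  expect_identical(classify_leca(securin, f$tree, leca_rule("MRCA")), "ABSENT")
  expect_identical(classify_leca(securin, f$tree, leca_rule("CONSERVATIVE", 2)),
                   "ABSENT")

  # nesting: CONSERVATIVE-PRESENT implies MRCA-PRESENT on every fixture column
  mat <- fig2_binary()
  res <- infer_origins(f$tree, mat)
  expect_true(all(res$table$leca_mrca[res$table$leca_conservative == "PRESENT"]
                  == "PRESENT"))
  # and with k = 1 the two modes coincide
  res1 <- infer_origins(f$tree, mat, k = 1L)
  expect_identical(res1$table$leca_conservative, res1$table$leca_mrca)
})

test_that("map_events tallies events with conservation and tentativeness", {
  f <- load_fig2()
  mat <- fig2_binary()
  res <- infer_origins(f$tree, mat)
  ev <- map_events(res$histories, f$tree)

  # total gains = components with >=1 presence; root gains = MRCA-PRESENT count
  expect_identical(sum(ev$gains), ncol(mat))
  expect_identical(ev$gains[ev$node == "LECA"],
                   sum(res$table$leca_mrca == "PRESENT"))
  # conservation of losses
  expect_identical(sum(ev$losses),
                   sum(vapply(res$histories, function(h) h$n_losses, integer(1))))

  # single all-present component: one root gain, zero losses anywhere
  tips <- tree_tips(f$tree)
  h_all <- dollo_infer(f$tree, stats::setNames(rep(1L, 15), tips))
  ev1 <- map_events(list(h_all), f$tree)
  expect_identical(ev1$gains[ev1$node == "LECA"], 1L)
  expect_identical(sum(ev1$gains), 1L)
  expect_identical(sum(ev1$losses), 0L)

  # a loss over an all-status-P subtree is tentative
  tr <- ref_tree(ape::read.tree(text = "((A,B),(C,D));"),
                 sides = c("UNIKONT", "BIKONT"))
  tm <- taxon_map(sides = c(A = "UNIKONT", B = "UNIKONT",
                            C = "BIKONT", D = "BIKONT"),
                  species = data.frame(species = c("a1", "b1", "c1", "d1"),
                                       lineage = c("A", "B", "C", "D"),
                                       status = c("P", "C", "C", "C")))
  pres <- c(A = 0L, B = 1L, C = 1L, D = 1L)
  h <- dollo_infer(tr, pres)
  ev2 <- map_events(list(h), tr, tm)
  expect_identical(ev2$tentative_losses[ev2$node == "A"], 1L)
  expect_identical(sum(ev2$tentative_losses), 1L)
  hf <- flag_tentative(h, tr, tm)
  expect_identical(hf$tentative_losses, "A")

  h_alien <- h; h_alien$loss_edges <- "Z"
  expect_error(map_events(list(h_alien), tr), "does not live on this tree")
})
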