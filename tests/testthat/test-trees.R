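# Tree I/O, rooting, pruning, covariance and consensus.

test_that("Newick parsing reads structure and branch lengths correctly", {
  tr <- parse_newick("(A:1,B:1);")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr3$tip.label), 3L)
  V <- vcv_matrix(tr3, c("A", "B", "C"))
  expect_equal(V["A", "B"], 1)   # A-B MRCA at depth 1 from the root
  expect_equal(unname(diag(V)), c(2, 2, 2))

  # quoted labels and scientific-notation lengths
  trq <- parse_newick("('sp one':1e-2,'it''s':2);")
  expect_setequal(trq$tip.label, c("sp one", "it's"))
  expect_equal(sort(trq$edge.length), c(0.01, 2))

  # missing semicolon tolerated; missing branch lengths stay absent
  trn <- parse_newick("(A,B)")
  expect_null(trn$edge.length)
})

test_that("malformed Newick is rejected with position information", {
  expect_error(parse_newick("((A:1,B:1):1,C:2;"), "unclosed")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
})

test_that("write_newick is canonical and round-trips with parse_newick", {
  expect_equal(write_newick(parse_newick("(A:1,B:1);")), "(A:1,B:1);")
  # children reordered by smallest descendant label
  expect_equal(write_newick(parse_newick("(B:1,A:1);")), "(A:1,B:1);")

  s <- "(A:1,(B:0.5,C:0.5):0.5);"
  expect_equal(write_newick(parse_newick(s)), s)

  # parse-write-parse identity on random trees
  for (seed in 1:20) {
    tr <- random_tree(sample(3:15, 1), seed = seed)
    s1 <- write_newick(tr)
    expect_equal(write_newick(parse_newick(s1)), s1)
  }
})

test_that("rooting on an outgroup places it as a child of the root", {
  tr <- parse_newick("(A:1,B:1,C:2);")   # trifurcation
  rt <- root_on_outgroup(tr, "C")
  root_kids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  expect_true(match("C", rt$tip.label) %in% root_kids)
  # idempotent on an already-rooted tree
  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(root_on_outgroup(tr2, "C"), tr2)
  expect_error(root_on_outgroup(tr2, "X"), "not a leaf")
})

test_that("pruning preserves path lengths and suppresses unary nodes", {
  tr <- parse_newick("((A:1,B:1):1,C:3);")
  expect_equal(prune_tree(tr, c("A", "B", "C")), tr)
  expect_equal(write_newick(prune_tree(tr, c("A", "B"))), "(A:1,B:1);")
  expect_equal(write_newick(prune_tree(tr, c("A", "C"))), "(A:2,C:3);")
  expect_error(prune_tree(tr, c("A", "X")), "not in tree")
  expect_error(prune_tree(tr, "A"), "at least 2")
})

test_that("vcv matrices are shared-path covariances, symmetric and PSD", {
  expect_equal(unname(vcv_matrix(parse_newick("(A:1,B:1);"))),
               diag(2), ignore_attr = TRUE)
  V <- vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"), c("A", "B", "C"))
  expect_equal(unname(V),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  expect_error(vcv_matrix(parse_newick("(A,B);")), "branch length")

  set.seed(99)
  for (i in 1:1000) {
    tr <- random_tree(sample(3:10, 1))
    V <- vcv_matrix(tr)
    expect_equal(V, t(V))
    expect_true(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
                >= -1e-9)
    # ultrametric Yule trees: equal diagonal
    expect_lt(diff(range(diag(V))) / max(diag(V)), 1e-9)
  }
})

test_that("pruning commutes with vcv (submatrix property)", {
  # The pruned tree is re-rooted at the kept leaves' MRCA (its stem is
  # discarded), so the pruned covariance equals the submatrix of the
  # full covariance shifted down by the MRCA's depth -- the smallest
  # shared path length among the kept leaves. When the MRCA is the
  # original root the shift is zero and the submatrix is recovered
  # exactly.
  for (seed in 1:25) {
    tr <- random_tree(8, seed = seed)
    keep <- sort(sample(tr$tip.label, 4))
    V_full <- vcv_matrix(tr)[keep, keep]
    V_sub <- vcv_matrix(prune_tree(tr, keep))[keep, keep]
    mrca_depth <- min(V_full[upper.tri(V_full)])
    expect_equal(V_sub, V_full - mrca_depth)
  }
  # keep sets spanning the root: exact submatrix selection
  tr <- parse_newick("(((A:1,B:2):1,C:3):1,(D:1,E:1):2);")
  keep <- c("A", "C", "D")
  expect_equal(vcv_matrix(prune_tree(tr, keep))[keep, keep],
               vcv_matrix(tr)[keep, keep])
})

test_that("burn-in discards the leading fraction and preserves order", {
  trees <- simulate_tree_sample(balanced4(), 100, 0, seed = 1)
  for (i in seq_along(trees)) trees[[i]]$gen <- i
  kept <- discard_burnin(trees, 0.25)
  expect_length(kept, 75)
  expect_equal(vapply(kept, `[[`, 0, "gen"), 26:100)
  expect_equal(discard_burnin(trees, 0), trees)
  expect_length(discard_burnin(trees[1:4], 0.5), 2)
  expect_error(discard_burnin(list(), 0.25), "empty")
})

test_that("majority-rule consensus keeps exactly the strict-majority clades", {
  t_ab <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t_ab2 <- parse_newick("((A:1,B:1):2,(C:1,D:1):1);")
  t_ac <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")

  # identical trees: same topology, all supports 1
  cons <- majority_rule_consensus(rep(list(t_ab), 10))
  expect_equal(tree_clades(cons), tree_clades(t_ab))
  expect_true(all(node_support(cons) == 1, na.rm = TRUE))

  # 2/3 split retained with support 0.667, and mean branch lengths
  cons2 <- majority_rule_consensus(list(t_ab, t_ab2, t_ac))
  expect_true("A,B" %in% tree_clades(cons2))
  expect_true(any(abs(node_support(cons2) - 2 / 3) < 1e-3, na.rm = TRUE))
  expect_match(write_newick(cons2), "0.667", fixed = TRUE)
  # mean of the A|B clade's stem over the two trees containing it: (1+2)/2
  ab_node <- ape::getMRCA(cons2, c("A", "B"))
  expect_equal(cons2$edge.length[cons2$edge[, 2] == ab_node], 1.5)

  # exact ties at 0.5 are excluded under the strict rule -> polytomy
  cons3 <- majority_rule_consensus(list(t_ab, t_ac))
  expect_length(tree_clades(cons3), 0)
  expect_equal(cons3$Nnode, 1L)

  expect_error(majority_rule_consensus(list()), "empty")
  t_bad <- parse_newick("((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(majority_rule_consensus(list(t_ab, t_bad)), "mismatched")
})

test_that("consensus clades match a brute-force frequency oracle", {
  set.seed(7)
  for (rep in 1:8) {
    base <- random_tree(sample(5:8, 1))
    trees <- simulate_tree_sample(base, 20, 0.3)
    freq <- clade_freq_oracle(trees)
    cons <- majority_rule_consensus(trees)
    got <- tree_clades(cons)
    want <- names(freq)[freq > 0.5]
    ntip <- length(base$tip.label)
    nontrivial <- lengths(strsplit(want, ",", fixed = TRUE)) < ntip &
      lengths(strsplit(want, ",", fixed = TRUE)) > 1
    expect_setequal(got, want[nontrivial])
    # supports equal oracle frequencies (prop.part lists clades in
    # internal-node order, root first)
    sup <- node_support(cons)
    pp <- ape::prop.part(cons)
    labs <- attr(pp, "labels")
    for (j in seq_along(pp)[-1]) {
      key <- paste(sort(labs[pp[[j]]]), collapse = ",")
      expect_equal(sup[j], round(unname(freq[key]), 3))
    }
  }
})

test_that("node_support normalizes percentage-scale labels", {
  tr <- parse_newick("((A:1,B:1)95:1,C:2);")
  expect_equal(node_support(tr), c(NA, 0.95))
  tr2 <- parse_newick("((A:1,B:1)0.5:1,C:2);")
  expect_equal(node_support(tr2), c(NA, 0.5))
})
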