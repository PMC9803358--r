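test_that("Newick parsing, branch enumeration and round-trip are stable", {
  tr <- fixture_tree
  expect_s3_class(tr, "master_tree")
  expect_equal(tr$n_tips, 62)
  # trifurcating root: one branch per non-root node = 2n - 3
  expect_equal(tr$n_branches, 2 * 62 - 3)
  expect_equal(anyDuplicated(tr$branch_names), 0L)

  # deterministic enumeration: parsing the same string twice is identical
  txt <- write_newick(tr)
  tr2 <- parse_newick(txt)
  expect_identical(tr2$branch_names, parse_newick(txt)$branch_names)

  # round-trip preserves topology and branch-length multiset
  expect_identical(tr$branch_names, tr2$branch_names)
  expect_equal(sort(unname(tr2$branch_lengths)), sort(unname(tr$branch_lengths)),
               tolerance = 1e-10)

  tiny <- parse_newick("(A:1,B:2);")
  expect_equal(tiny$n_tips, 2)
  expect_equal(unname(tiny$branch_lengths[c("A", "B")]), c(1, 2))

  expect_error(parse_newick("((A:1,B:2);"), "unclosed")
  expect_error(parse_newick("(A:1,B:2));"), "offset")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
})

test_that("foreground assignment reproduces the hairless configuration", {
  h <- fixture_hairless
  expect_equal(h$n_extant, 10)
  expect_equal(length(h$branch_index), 11)
  expect_equal(h$n_ancestral, 1)
  # the cetacean clade contributes orca, dolphin, and their ancestor
  cet <- c("orcOrc1", "turTru2", mrca_branch(fixture_tree, c("orcOrc1", "turTru2")))
  expect_length(intersect(h$branch_names, cet), 3)
  # the elephant-manatee ancestor stays background despite both tips foreground
  em <- mrca_branch(fixture_tree, c("loxAfr3", "triMan1"))
  expect_false(em %in% h$branch_names)

  expect_length(assign_foreground(fixture_tree, character())$branch_index, 0)
  expect_error(assign_foreground(fixture_tree, "notATip"), "notATip")
})

test_that("foreground assignment is monotone in the extant set", {
  set.seed(41)
  tips <- fixture_tree$phy$tip.label
  for (rep in 1:20) {
    base <- sample(tips, sample(2:20, 1))
    extra <- sample(setdiff(tips, base), 1)
    fg1 <- assign_foreground(fixture_tree, base)$branch_index
    fg2 <- assign_foreground(fixture_tree, c(base, extra))$branch_index
    expect_true(all(fg1 %in% fg2))
  }
})

test_that("Brownian motion simulation matches its analytic moments", {
  zero <- parse_newick("((A:0,B:0):0,C:0);")
  bm0 <- simulate_bm(zero, root_value = 3.5, rate = 1, seed = 1)
  expect_equal(unname(bm0$tip_values), rep(3.5, 3))

  # root-to-tip variance ~ rate * path length, sisters share the stem
  tr <- parse_newick("((A:0.1,B:0.05):0.15,C:0.25);")
  set.seed(99)
  reps <- 10000
  vals <- replicate(reps, simulate_bm(tr, 0, 1)$tip_values)
  expect_equal(var(vals["A", ]), 0.25, tolerance = 0.05)
  expect_equal(var(vals["C", ]), 0.25, tolerance = 0.05)
  expect_equal(cov(vals["A", ], vals["B", ]), 0.15, tolerance = 0.08)
  expect_equal(cov(vals["A", ], vals["C", ]), 0, tolerance = 0.01)

  expect_error(simulate_bm(tr, 0, rate = 0), "rate")
  # reproducible under a fixed seed
  expect_identical(simulate_bm(tr, 0, 1, seed = 7)$tip_values,
                   simulate_bm(tr, 0, 1, seed = 7)$tip_values)
})

test_that("ancestral reconstruction equals the brute-force BM likelihood maximizer", {
  # symmetric 2-tip case
  t2 <- parse_newick("(A:1,B:1);")
  a2 <- ancestral_states(t2, c(A = 2, B = 6))
  expect_equal(unname(a2$node_values["root"]), 4)

  # constant input reconstructs constant everywhere
  ac <- ancestral_states(fixture_tree,
                         setNames(rep(2.5, 62), fixture_tree$phy$tip.label))
  expect_equal(unname(ac$node_values), rep(2.5, length(ac$node_values)),
               tolerance = 1e-8)

  # random small trees against direct optimization of the BM log-likelihood
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    phy <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    tr <- master_tree(phy)
    y <- setNames(rnorm(n, 0, 2), tr$phy$tip.label)
    rec <- ancestral_states(tr, y)
    internal <- names(rec$node_values)
    negll <- function(vals) {
      node_val <- numeric(tr$n_tips + tr$phy$Nnode)
      node_val[seq_len(tr$n_tips)] <- y[tr$phy$tip.label]
      node_val[tr$n_tips + 1L] <- vals[1]
      int_b <- which(!tr$is_tip_branch)
      node_val[tr$branch_child[int_b]] <- vals[-1]
      d <- node_val[tr$branch_child] - node_val[tr$branch_parent]
      sum(d^2 / (2 * tr$branch_lengths))
    }
    opt <- optim(rep(mean(y), length(internal)), negll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(unname(rec$node_values), opt$par, tolerance = 1e-6)
  }

  expect_error(ancestral_states(t2, c(A = 1)), "missing tip")
})
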