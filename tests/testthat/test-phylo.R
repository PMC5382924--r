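# additive 4-leaf matrix from the tree ((A:1,B:2):3,C:4,D:5) by path sums
D4 <- matrix(c(0, 3, 8, 9,
               3, 0, 9, 10,
               8, 9, 0, 9,
               9, 10, 9, 0), 4, 4,
             dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))

test_that("NJ reconstructs a 4-leaf additive matrix exactly", {
  tr <- neighbor_joining(D4)
  truth <- ape::read.tree(text = "((A:1,B:2):3,C:4,D:5);")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(truth)), 0)
  expect_equal(cophenetic(tr)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-12)
})

test_that("3 leaves give the closed-form star branch lengths", {
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  # three-point formulas: a = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(2, 3, 5))
})

test_that("2 leaves become a single edge of total length D12", {
  D <- matrix(c(0, 4.2, 4.2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tr <- neighbor_joining(D)
  expect_equal(unname(cophenetic(tr)["a", "b"]), 4.2)
})

test_that("NJ recovers random additive trees (topology and path lengths)", {
  set.seed(404)
  for (trial in 1:30) {
    n <- sample(5:8, 1)
    truth <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- cophenetic(truth)
    tr <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(truth)), 0)
    expect_lt(max(abs(cophenetic(tr)[rownames(D), colnames(D)] - D)), 1e-9)
  }
})

test_that("NJ agrees with ape::nj on additive inputs", {
  set.seed(11)
  truth <- ape::rtree(7, br = function(k) runif(k, 0.2, 1.5))
  D <- cophenetic(truth)
  ours <- neighbor_joining(D)
  ref <- ape::nj(D)
  expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(ref)), 0)
})

test_that("matrix validation rejects asymmetry and NaN", {
  D <- D4; D[1, 2] <- 99
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- D4; D2[1, 3] <- D2[3, 1] <- NaN
  expect_error(neighbor_joining(D2), "non-finite|NA")
})

test_that("clade cutting spans the trivial and saturated cases", {
  tr <- neighbor_joining(D4)
  expect_equal(unname(cut_tree_clades(tr, 1)), rep(1L, 4))
  p4 <- cut_tree_clades(tr, 4)
  expect_equal(sort(unname(p4)), 1:4)
  # long internal edge splits {A,B} from {C,D}
  p2 <- cut_tree_clades(tr, 2)
  expect_equal(unname(p2["A"]), unname(p2["B"]))
  expect_equal(unname(p2["C"]), unname(p2["D"]))
  expect_false(unname(p2["A"]) == unname(p2["C"]))
})

test_that("purity and ARI behave on exact, perturbed and relabeled input", {
  part <- setNames(rep(1:2, each = 5), letters[1:10])
  groups <- setNames(rep(c("x", "y"), each = 5), letters[1:10])
  cc <- clade_concordance(part, groups)
  expect_equal(cc$purity, 1.0)
  expect_equal(cc$adjusted_rand, 1.0)

  groups2 <- groups
  groups2["a"] <- "y"  # one mislabeled leaf of 10
  expect_equal(clade_concordance(part, groups2)$purity, 0.9)

  # invariance to clade index relabeling
  part_relab <- setNames(ifelse(part == 1, 7L, 3L), names(part))
  expect_equal(clade_concordance(part_relab, groups2)$adjusted_rand,
               clade_concordance(part, groups2)$adjusted_rand)

  expect_error(clade_concordance(part, groups[1:8]), "leaf sets differ")
})

test_that("ARI matches mclust and is centered at zero under permutation", {
  set.seed(88)
  part <- setNames(sample(1:4, 50, replace = TRUE), paste0("L", 1:50))
  groups <- setNames(sample(c("g1", "g2", "g3"), 50, replace = TRUE),
                     names(part))
  ours <- clade_concordance(part, groups)$adjusted_rand
  ref <- mclust::adjustedRandIndex(part, groups[names(part)])
  expect_equal(ours, ref, tolerance = 1e-12)

  aris <- vapply(1:1000, function(i) {
    g <- setNames(sample(groups), names(groups))
    clade_concordance(part, g)$adjusted_rand
  }, 0)
  expect_lt(abs(mean(aris)), 0.05)
})
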