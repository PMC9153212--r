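# Clone-tree construction under the sum and crossing rules.

test_that("clone_tree validates its parent map", {
  expect_error(clone_tree(c(A = NA, B = "C", C = "B")), class = "mc_invalid_tree")   # cycle
  expect_error(clone_tree(c(A = NA, B = NA)), class = "mc_invalid_tree")             # two roots
  expect_error(clone_tree(c(A = NA, B = "Z")), class = "mc_invalid_tree")            # unknown parent
  tr <- clone_tree(c(A = NA, B = "A", C = "B"))
  expect_identical(tr$root, "A")
  expect_identical(tree_subtree(tr, "B"), c("B", "C"))
  expect_identical(tree_ancestors(tr, "C"), c("B", "A"))
})

test_that("pairwise relations follow dominance and crossing", {
  expect_identical(pairwise_relation(c(s1 = 0.9, s2 = 0.8), c(s1 = 0.5, s2 = 0.2)),
                   "a_can_contain_b")
  expect_identical(pairwise_relation(c(s1 = 0.6, s2 = 0.2), c(s1 = 0.2, s2 = 0.6)),
                   "branching")
  expect_identical(pairwise_relation(c(s1 = 0.5, s2 = 0.5), c(s1 = 0.48, s2 = 0.52)),
                   "ambiguous")
  expect_identical(pairwise_relation(c(s1 = 0.2, s2 = 0.2), c(s1 = 0.6, s2 = 0.7)),
                   "b_can_contain_a")
  expect_error(pairwise_relation(c(s1 = 0.5), c(s2 = 0.5)), class = "mc_incomparable")
})

worked_ccf <- function() {
  matrix(c(1, 1, 0.6, 0.1, 0.3, 0.7), nrow = 3, byrow = TRUE,
         dimnames = list(c("T", "X", "Y"), c("s1", "s2")))
}

test_that("the crossing rule forces siblings in the worked 3-cluster case", {
  # oracle: of the 3 arborescences rooted at T, X->Y and Y->X violate the
  # crossing rule, so X and Y must be siblings under T
  ccf <- worked_ccf()
  w <- c(s1 = 1, s2 = 1)
  feas <- oracle_tree_feasible(ccf, root = 1L, tol = 0.05)
  expect_length(feas, 1L)
  tr <- build_tree(ccf, w, tol = 0.05)
  expect_identical(tr$parent, c(T = NA_character_, X = "T", Y = "T"))
  expect_length(tr$ambiguous, 0L)
})

test_that("a single cluster yields a trunk-only tree", {
  ccf <- matrix(c(1, 1), 1, dimnames = list("T", c("s1", "s2")))
  tr <- build_tree(ccf, c(s1 = 1, s2 = 1))
  expect_identical(tr$parent, c(T = NA_character_))
})

test_that("an uncertain attachment is returned with its alternatives recorded", {
  # H fits under either of the branching clusters C and G (the sum rule
  # excludes the trunk); both ancestries must be recorded
  ccf <- matrix(c(1, 1, 0.6, 0.3, 0.3, 0.6, 0.25, 0.25), nrow = 4, byrow = TRUE,
                dimnames = list(c("T", "C", "G", "H"), c("s1", "s2")))
  w <- c(s1 = 1, s2 = 1)
  tr <- build_tree(ccf, w, tol = 0.05)
  expect_identical(tr$parent[["C"]], "T")
  expect_identical(tr$parent[["G"]], "T")
  expect_true(tr$parent[["H"]] %in% c("C", "G"))
  expect_setequal(c(tr$parent[["H"]], tr$ambiguous[["H"]]), c("C", "G"))
  # oracle agreement on the feasible set
  feas <- oracle_tree_feasible(ccf, root = 1L, tol = 0.05)
  h_parents <- sort(unique(vapply(feas, `[`, 0L, 4L)))
  expect_identical(h_parents, c(2L, 3L))
})

test_that("low-purity samples are excluded from construction", {
  ccf <- matrix(c(1, 1, 0.6, 0.9, 0.3, 0.8), nrow = 3, byrow = TRUE,
                dimnames = list(c("T", "X", "Y"), c("s1", "s2")))
  # with s2 (purity 0.03) included, X+Y would violate the sum rule at T
  tr <- build_tree(ccf, c(s1 = 0.8, s2 = 0.03), tol = 0.05)
  expect_identical(colnames(attr(tr, "ccf")), "s1")
})

test_that("infeasible cluster sets raise a typed report", {
  # X and Y cross, and each also crosses with Z so nothing can contain Z
  ccf <- matrix(c(1, 1, 0.9, 0.1, 0.1, 0.9, 0.55, 0.55), nrow = 4, byrow = TRUE,
                dimnames = list(c("T", "X", "Y", "Z"), c("s1", "s2")))
  # sum rule at T: X+Y+Z = 1.55 in both samples -> no arrangement works
  expect_error(build_tree(ccf, c(s1 = 1, s2 = 1), tol = 0.05),
               class = "mc_infeasible_phylogeny")
})

test_that("search equals brute-force enumeration on random instances", {
  # 120 random instances here; the acceptance suite runs 1,000
  for (r in 1:120) {
    inst <- oracle_random_instance(k = sample(3:6, 1), S = sample(2:4, 1), seed = 5000 + r)
    w <- stats::setNames(rep(1, ncol(inst$ccf)), colnames(inst$ccf))
    feas <- oracle_tree_feasible(inst$ccf, root = 1L, tol = 0.05)
    expect_gt(length(feas), 0L)
    pick <- oracle_tree_select(feas, inst$ccf, w)
    tr <- build_tree(inst$ccf, w, tol = 0.05, root_id = rownames(inst$ccf)[1L])
    ids <- rownames(inst$ccf)
    got <- vapply(ids, function(n) {
      p <- tr$parent[[n]]
      if (is.na(p)) 0L else match(p, ids)
    }, integer(1))
    expect_identical(unname(got), pick)
    expect_identical(attr(tr, "n_feasible"), length(feas))
  }
})
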