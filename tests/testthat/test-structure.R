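test_that("family BIC score matches its closed form", {
  x <- matrix(c(1L, 1L, 0L, 0L), 4, 1, dimnames = list(NULL, "v"))
  # LL = 4 ln(1/2); penalty = (ln 4)/2
  expect_equal(family_bic_score(x, "v"), 4 * log(0.5) - log(4) / 2,
               tolerance = 1e-12)
  expect_equal(family_bic_score(x, "v"), -3.46574, tolerance = 1e-5)
})

test_that("a constant parent leaves the likelihood unchanged and strictly lowers the score", {
  set.seed(2)
  x <- cbind(v = rbinom(50, 1, 0.5), k = rep(1L, 50))
  s0 <- family_bic_score(x, "v")
  s1 <- family_bic_score(x, "v", "k")
  # likelihood identical, penalty doubles: difference is exactly one extra
  # configuration worth of penalty
  expect_equal(s0 - s1, log(50) / 2, tolerance = 1e-12)
  expect_lt(s1, s0)
})

test_that("network score decomposes as the sum of family scores", {
  for (r in 1:10) {
    x <- random_binary_matrix(60, 4, seed = 100 + r)
    net <- random_bnet(4, seed = 200 + r)
    dag <- bn_dag(colnames(x),
                  setNames(lapply(net$dag$parents, function(p)
                    colnames(x)[match(p, net$dag$nodes)]), colnames(x)))
    total <- network_score(x, dag)
    by_family <- sum(vapply(dag$nodes, function(v)
      family_bic_score(x, v, dag$parents[[v]]), numeric(1)))
    expect_equal(total, by_family, tolerance = 1e-12)
  }
})

test_that("the score table enumerates exactly the right families", {
  x2 <- random_binary_matrix(40, 2, seed = 1)
  t2 <- compute_score_table(x2)
  expect_identical(sum(is.finite(t2$scores)), 4L)  # 2 nodes x 2 parent sets

  x4 <- random_binary_matrix(40, 4, seed = 2)
  t4 <- compute_score_table(x4)
  expect_identical(sum(is.finite(t4$scores)), 32L)  # n * 2^(n-1)

  # empty-parent entries agree with the reference implementation
  for (j in 1:4) {
    v <- colnames(x4)[j]
    expect_equal(t4$scores[1, j], family_bic_score(x4, v),
                 tolerance = 1e-10)
  }
  # and so does a non-trivial family
  expect_equal(t4$scores[1 + 2^1, 1],   # parents = {B}, node A
               family_bic_score(x4, "A", "B"), tolerance = 1e-10)
  # parent-set cap prunes the table
  t4c <- compute_score_table(x4, max_parents = 1)
  expect_identical(sum(is.finite(t4c$scores)), 4L * 4L)  # empty + 3 singletons
  df <- as.data.frame(t4)
  expect_identical(nrow(df), 32L)
})

test_that("exact search matches exhaustive enumeration over all DAGs", {
  set.seed(7)
  for (r in 1:30) {
    n <- sample(3:4, 1)
    x <- random_binary_matrix(sample(c(25, 60, 150), 1), n, seed = 300 + r)
    d <- learn_exact(x)
    e <- exhaustive_best_dag(x)
    expect_equal(attr(d, "score"), e$score, tolerance = 1e-9)
    expect_identical(e$n_dags, if (n == 3) 25L else 543L)
  }
})

test_that("degenerate inputs are handled: single variable, all-constant data", {
  x1 <- matrix(rbinom(20, 1, 0.5), dimnames = list(NULL, "only"))
  d1 <- learn_exact(x1)
  expect_identical(lengths(d1$parents), c(only = 0L))

  xc <- matrix(1L, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(dc <- learn_exact(xc), "constant")
  expect_true(all(lengths(dc$parents) == 0L))

  xbig <- matrix(0L, 5, 21, dimnames = list(NULL, paste0("v", 1:21)))
  expect_error(learn_exact(xbig), "20 variables")
})

test_that("a planted strong chain is recovered up to Markov equivalence", {
  dag <- bn_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  gtn <- bn_network(dag, list(X = 0.5, Y = c(0.1, 0.9), Z = c(0.1, 0.9)))
  cm <- sample_cohort(gtn, 5000, seed = 77)
  learned <- learn_exact(cm)
  skel <- moralize(learned)  # chain has no unshielded collider -> no fill-in
  expect_identical(nrow(skel$edges), 2L)
  expect_true(any(skel$edges[, 1] == "X" & skel$edges[, 2] == "Y"))
  expect_true(any(skel$edges[, 1] == "Y" & skel$edges[, 2] == "Z"))
  # no collider at Y: Y does not have both X and Z as parents
  expect_false(setequal(learned$parents[["Y"]], c("X", "Z")))
})

test_that("BIC is score-equivalent across Markov-equivalent 3-node DAGs", {
  x <- random_binary_matrix(120, 3, seed = 9)
  colnames(x) <- c("A", "B", "C")
  chain1 <- bn_dag(c("A", "B", "C"), list(B = "A", C = "B"))
  chain2 <- bn_dag(c("A", "B", "C"), list(A = "B", B = "C"))
  fork   <- bn_dag(c("A", "B", "C"), list(A = "B", C = "B"))
  collider <- bn_dag(c("A", "B", "C"), list(B = c("A", "C")))
  s <- vapply(list(chain1, chain2, fork), network_score, numeric(1),
              data = x)
  expect_equal(s[1], s[2], tolerance = 1e-10)
  expect_equal(s[1], s[3], tolerance = 1e-10)
  # the collider encodes different independencies; equality would be a fluke
  expect_false(isTRUE(all.equal(network_score(x, collider), s[1],
                                tolerance = 1e-10)))
})

test_that("learning is deterministic: same matrix in, same DAG out", {
  x <- random_binary_matrix(300, 5, seed = 41)
  d1 <- learn_exact(x)
  d2 <- learn_exact(x)
  expect_identical(d1$parents, d2$parents)
  expect_identical(attr(d1, "score"), attr(d2, "score"))
})

test_that("max_parents caps the learned in-degree", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 3000, seed = 55)
  d <- learn_exact(cm, max_parents = 1)
  expect_true(all(lengths(d$parents) <= 1L))
})

test_that("moralization marries co-parents and drops directions", {
  chain <- bn_dag(c("A", "B", "C"), list(B = "A", C = "B"))
  m <- moralize(chain)
  expect_identical(m$edges, matrix(c("A", "B", "B", "C"), 2, 2,
                                   byrow = TRUE,
                                   dimnames = list(NULL, c("a", "b"))))
  collider <- bn_dag(c("A", "B", "C"), list(C = c("A", "B")))
  mc <- moralize(collider)
  expect_identical(nrow(mc$edges), 3L)
  expect_true(any(mc$edges[, 1] == "A" & mc$edges[, 2] == "B"))  # married
  empty <- moralize(bn_dag(c("A", "B")))
  expect_identical(nrow(empty$edges), 0L)
})

test_that("cyclic parent structures are rejected", {
  expect_error(bn_dag(c("A", "B"), list(A = "B", B = "A")), "cycle")
  expect_error(bn_dag("A", list(A = "A")), "own parent")
})
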