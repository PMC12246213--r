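test_that("the PCGC-like scenario reproduces its calibration anchors by enumeration", {
  gtn <- pcgc_scenario()
  # overall damaging-genotype prevalence ~10.6%
  p_union <- 1 - bn_query(gtn, c(CHRMdGV = 0, CILIAdGV = 0))
  expect_equal(p_union, 0.1056, tolerance = 0.005)
  # genotype-outcome relative risks as calibrated
  expect_equal(true_relative_rr(gtn, c(MORT = 1), "CHRMdGV"), 1.8,
               tolerance = 0.02)
  expect_equal(true_relative_rr(gtn, c(ARREST = 1), "CHRMdGV"), 1.7,
               tolerance = 0.02)
  expect_equal(true_absolute_rr(gtn, "LVO", "CHRMdGV"), 1.61,
               tolerance = 0.02)
  expect_equal(true_absolute_rr(gtn, "HTX", "CILIAdGV"), 2.63,
               tolerance = 0.02)
  # planted ratios stay in the plausible clinical band
  a <- attr(gtn, "anchors")
  rrs <- unlist(a[grepl("^(abs|rel)_", names(a))])
  expect_true(all(rrs >= 1.3 & rrs <= 4.0))
})

test_that("phenotype nesting is deterministic: every HLHS patient has LVO", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 5000, seed = 12)
  expect_true(all(cm$x[cm$x[, "HLHS"] == 1, "LVO"] == 1))
  expect_equal(bn_query(gtn, c(HLHS = 1), c(LVO = 0)), 0)
})

test_that("ancestral sampling is seed-deterministic and handles n = 0", {
  gtn <- pcgc_scenario()
  a <- sample_cohort(gtn, 200, seed = 9)
  b <- sample_cohort(gtn, 200, seed = 9)
  expect_identical(a$x, b$x)
  e <- sample_cohort(gtn, 0, seed = 9)
  expect_identical(dim(e), c(0L, 10L))
})

test_that("sampled joint frequencies match the enumerated joint", {
  gtn <- pcgc_scenario()
  n <- 5e5
  cm <- sample_cohort(gtn, n, seed = 13)
  nodes <- gtn$dag$nodes
  cell <- as.vector(cm$x %*% 2^(seq_along(nodes) - 1))
  emp <- tabulate(cell + 1L, 2^length(nodes)) / n
  # enumerated joint via the independent brute-force oracle
  g <- all_assignments(nodes)
  truth <- vapply(seq_len(nrow(g)), function(i) brute_joint(gtn, g[i, ]),
                  numeric(1))
  idx <- as.vector(as.matrix(g) %*% 2^(seq_along(nodes) - 1)) + 1L
  truth <- truth[order(idx)]
  expect_equal(sum(truth), 1, tolerance = 1e-12)
  se <- sqrt(truth * (1 - truth) / n)
  within3 <- abs(emp - truth) <= 3 * se + 1e-12
  expect_gte(mean(within3), 0.99)   # ~0.3% of cells may exceed 3 SE by chance
})

test_that("marginal frequencies of a large sample match CPT enumeration", {
  gtn <- pcgc_scenario()
  n <- 1e5
  cm <- sample_cohort(gtn, n, seed = 14)
  f <- variable_frequencies(cm)
  for (v in gtn$dag$nodes) {
    p <- bn_query(gtn, setNames(1L, v))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(f$frequency[f$variable == v] - p), 3 * se + 1e-12)
  }
})

test_that("MCAR injection is calibrated, capped and identity at rate 0", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 1e4, seed = 15)
  expect_identical(inject_missingness(cm, 0), cm)
  holey <- inject_missingness(cm, 0.05, seed = 16)
  mfrac <- colMeans(is.na(holey$x))
  se <- sqrt(0.05 * 0.95 / nrow(cm$x))
  # 10 simultaneous binomial checks: the pooled rate must sit within 3 SE,
  # individual variables within 3 SE up to the expected multiplicity slack
  pooled_se <- se / sqrt(ncol(cm$x))
  expect_lt(abs(mean(is.na(holey$x)) - 0.05), 3 * pooled_se)
  expect_gte(sum(abs(mfrac - 0.05) <= 3 * se), ncol(cm$x) - 1L)
  expect_true(all(abs(mfrac - 0.05) <= 4.5 * se))
  expect_error(inject_missingness(cm, 0.2), "cap")
  expect_silent(inject_missingness(cm, 0.2, seed = 1, allow_excess = TRUE))
})

test_that("exact ratio oracles agree with hand enumeration", {
  dag <- bn_dag(c("C", "T"), list(T = "C"))
  net <- bn_network(dag, list(C = 0.1, T = c(0.05, 0.2)))
  # P(T) = 0.1*0.2 + 0.9*0.05 = 0.065
  expect_equal(true_absolute_rr(net, "T", "C"), 0.2 / 0.065,
               tolerance = 1e-12)
  # self-conditioning: 1 / P(T)
  expect_equal(true_absolute_rr(net, "T", "T"), 1 / 0.065,
               tolerance = 1e-12)
  # d-separated condition gives ratio 1
  dag2 <- bn_dag(c("A", "B"))
  net2 <- bn_network(dag2, list(A = 0.3, B = 0.6))
  expect_equal(true_absolute_rr(net2, "B", "A"), 1, tolerance = 1e-12)
  expect_equal(true_relative_rr(net2, c(B = 1), "A"), 1, tolerance = 1e-12)
  # zero-probability conditioning is an error, not NaN
  net3 <- bn_network(dag2, list(A = 0, B = 0.6))
  expect_error(true_absolute_rr(net3, "B", "A"), "impossible evidence")
})

test_that("phenotype-code cohorts are seed-deterministic and match their emissions", {
  fs <- fyler_scenario()
  a <- generate_fyler_cohort(fs, 500, seed = 3)
  b <- generate_fyler_cohort(fs, 500, seed = 3)
  expect_identical(a$codes, b$codes)
  expect_identical(a$labels, b$labels)

  big <- generate_fyler_cohort(fs, 1e5, seed = 4)
  for (cc in fs$categories) {
    sel <- big$labels == cc
    n_cc <- sum(sel)
    emp <- colMeans(big$codes[sel, , drop = FALSE])
    se <- sqrt(fs$emission[cc, ] * (1 - fs$emission[cc, ]) / n_cc)
    expect_gte(mean(abs(emp - fs$emission[cc, ]) <= 3 * se + 1e-12), 0.99)
  }
})

test_that("a mixing-free one-code-per-category scenario is perfectly separable", {
  fs <- fyler_scenario(codes_per_category = 1, shared_codes = 0,
                       emission_high = 1, emission_low = 0)
  d <- generate_fyler_cohort(fs, 200, seed = 5)
  # each patient carries exactly its category's code
  recovered <- fs$categories[apply(d$codes[, paste0("F_", fs$categories, "_01")],
                                   1, which.max)]
  expect_identical(recovered, as.character(d$labels))
  expect_true(all(rowSums(d$codes) == 1))
})
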