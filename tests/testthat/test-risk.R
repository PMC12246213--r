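test_that("absolute risk ratio matches hand enumeration and independence gives 1", {
  net <- bn_network(bn_dag(c("C", "T"), list(T = "C")),
                    list(C = 0.1, T = c(0.05, 0.2)))
  expect_equal(absolute_rr(net, "T", "C"), 0.2 / 0.065, tolerance = 1e-12)
  indep <- bn_network(bn_dag(c("C", "T")), list(C = 0.1, T = 0.3))
  expect_equal(absolute_rr(indep, "T", "C"), 1, tolerance = 1e-12)
  expect_equal(relative_rr(indep, c(T = 1), "C"), 1, tolerance = 1e-12)
})

test_that("relative risk ratio agrees with the enumeration oracle on a 3-node net", {
  dag <- bn_dag(c("G", "P", "M"), list(P = "G", M = c("G", "P")))
  net <- bn_network(dag, list(G = 0.1, P = c(0.2, 0.5),
                              M = c(0.05, 0.12, 0.15, 0.30)))
  got <- relative_rr(net, c(M = 1, P = 1), "G")
  want <- brute_query(net, c(M = 1, P = 1), c(G = 1)) /
    brute_query(net, c(M = 1, P = 1), c(G = 0))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(relative_rr(net, c(M = 1, G = 1), "G"), "not be among")
})

test_that("reciprocal coherence: RR_rel * P(T|F=0) equals P(T|F=1) exactly", {
  for (r in 1:10) {
    net <- random_bnet(4, seed = 500 + r)
    targets <- c(N3 = 1L, N4 = 1L)
    rr <- relative_rr(net, targets, "N1")
    p0 <- bn_query(net, targets, c(N1 = 0))
    p1 <- bn_query(net, targets, c(N1 = 1))
    expect_equal(rr * p0, p1, tolerance = 1e-12)
  }
})

test_that("a degenerate bootstrap reproduces the direct estimate", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 2000, seed = 19)
  vars <- c("CHRMdGV", "LVO", "HLHS", "STAT45")
  q <- risk_query("absolute", target = "LVO", condition = "CHRMdGV")
  est <- bootstrap_risk(cm, vars, q, B = 1, seed = 2, resample = FALSE)
  sub <- subset_variables(cm, vars)
  direct <- absolute_rr(bn_fit(sub, smoothing = 0.01), "LVO", "CHRMdGV")
  expect_equal(est$point, direct, tolerance = 1e-12)
})

test_that("bootstrap estimates are seed-deterministic end-to-end", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 800, seed = 20)
  q <- risk_query("relative", targets = c(MORT = 1), factor = "CHRMdGV")
  vars <- c("CHRMdGV", "STAT45", "MORT")
  a <- bootstrap_risk(cm, vars, q, B = 25, seed = 99)
  b <- bootstrap_risk(cm, vars, q, B = 25, seed = 99)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$point, b$point)
  c2 <- bootstrap_risk(cm, vars, q, B = 25, seed = 100)
  expect_false(identical(a$replicates, c2$replicates))
})

test_that("replicates with an impossible conditioning event are excluded and counted", {
  set.seed(33)
  # a very rare factor: resamples frequently contain no carrier at all
  x <- cbind(F = c(1L, rep(0L, 29)), T = rbinom(30, 1, 0.4))
  rownames(x) <- paste0("p", 1:30)
  q <- risk_query("relative", targets = c(T = 1), factor = "F")
  est <- bootstrap_risk(x, c("F", "T"), q, B = 60, seed = 3, smoothing = 0)
  expect_gt(est$n_undefined, 0)
  expect_identical(sum(!is.na(est$replicates)), 60L - est$n_undefined)
})

test_that("the two interval summaries implement their conventions", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 1200, seed = 21)
  q <- risk_query("absolute", target = "LVO", condition = "CHRMdGV")
  pm <- bootstrap_risk(cm, c("CHRMdGV", "LVO"), q, B = 40, seed = 4,
                       summary = "percentile_median")
  ok <- pm$replicates[!is.na(pm$replicates)]
  expect_equal(pm$point, median(ok))
  expect_equal(c(pm$ci_low, pm$ci_high),
               unname(quantile(ok, c(0.05, 0.95))))
  tm <- bootstrap_risk(cm, c("CHRMdGV", "LVO"), q, B = 40, seed = 4,
                       summary = "t_mean")
  ok <- tm$replicates[!is.na(tm$replicates)]
  half <- qt(0.975, length(ok) - 1) * sd(ok)
  expect_equal(tm$point, mean(ok))
  expect_equal(tm$ci_high - tm$point, half, tolerance = 1e-12)
  expect_equal(tm$point - tm$ci_low, half, tolerance = 1e-12)
})

test_that("feature screening keeps enriched pairs and drops protective ones", {
  # G raises T1 (RR 2), lowers T2 (RR < 1), independent of T3
  dag <- bn_dag(c("G", "T1", "T2", "T3"), list(T1 = "G", T2 = "G"))
  net <- bn_network(dag, list(G = 0.12, T1 = c(0.10, 0.24),
                              T2 = c(0.30, 0.12), T3 = 0.2))
  cm <- sample_cohort(net, 2253, seed = 22)
  sel <- screen_features(cm, candidates = "G",
                         targets = c("T1", "T2", "T3"), B = 60, seed = 5)
  expect_true(sel$selected[sel$target == "T1"])
  expect_false(sel$selected[sel$target == "T2"])
  expect_gt(sel$absolute_rr[sel$target == "T1"], 1.3)
})

test_that("a planted twofold enrichment is selected in nearly all cohorts", {
  dag <- bn_dag(c("G", "T"), list(T = "G"))
  # abs RR = p1 / (0.1 p1 + 0.9 p0); fix p1 = 0.2 and solve p0 for RR = 2
  p1 <- 0.20
  p0 <- (p1 / 2 - 0.1 * p1) / 0.9
  net <- bn_network(dag, list(G = 0.10, T = c(p0, p1)))
  expect_equal(true_absolute_rr(net, "T", "G"), 2, tolerance = 1e-12)
  hits <- 0
  for (r in 1:40) {
    cm <- sample_cohort(net, 2253, seed = 600 + r)
    sel <- screen_features(cm, "G", "T", B = 30, seed = r)
    hits <- hits + sel$selected
  }
  expect_gte(hits / 40, 0.95)
})

test_that("the enrichment table dashes empty pathways and recovers a planted signal", {
  dag <- bn_dag(c("PW1", "PW2", "PH1", "PH2"), list(PH1 = "PW1"))
  net <- bn_network(dag, list(PW1 = 0.08, PW2 = 0.05,
                              PH1 = c(0.15, 0.45), PH2 = 0.25))
  cm <- sample_cohort(net, 4000, seed = 23)
  x <- as.matrix(cm)
  x[, "PW2"] <- 0L  # no carriers at all
  tab <- pathway_enrichment_table(x, c("PW1", "PW2"), c("PH1", "PH2"),
                                  B = 60, seed = 6)
  expect_identical(unname(tab$n_carriers["PW2"]), 0)
  expect_true(all(is.na(tab$point["PW2", ])))
  # only the planted cell's interval excludes 1
  expect_gt(tab$ci_low["PW1", "PH1"], 1)
  expect_lt(tab$ci_low["PW1", "PH2"], 1)
})

test_that("risk reports round-trip through the TSV dialect", {
  gtn <- pcgc_scenario()
  cm <- sample_cohort(gtn, 600, seed = 24)
  ests <- list(
    bootstrap_risk(cm, c("CHRMdGV", "LVO"),
                   risk_query("absolute", target = "LVO",
                              condition = "CHRMdGV"), B = 10, seed = 7),
    bootstrap_risk(cm, c("CHRMdGV", "MORT", "STAT45"),
                   risk_query("relative", targets = c(MORT = 1),
                              factor = "CHRMdGV"), B = 10, seed = 8))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_risk_report(ests, tmp)
  back <- read_risk_report(tmp)
  expect_identical(nrow(back), 2L)
  expect_identical(sort(back$kind), c("absolute", "relative"))
  expect_true(all(c("n_undefined_replicates", "seed") %in% names(back)))
  # empty report still carries the schema
  write_risk_report(list(), tmp)
  empty <- read_risk_report(tmp)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(back))
})
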