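test_that("pairedT matches the closed form and flags degenerate input", {
  # identical pairs: zero difference, degenerate, p = 1
  r0 <- pairedT(rep(100, 4), rep(100, 4))
  expect_equal(r0$status, "degenerate")
  expect_equal(r0$diff, 0)
  expect_equal(r0$p_raw, 1)

  # constant nonzero shift: zero variance with positive mean difference
  r1 <- pairedT(c(102, 98, 101, 99), c(52, 48, 51, 49))
  expect_equal(r1$status, "degenerate")
  expect_equal(r1$diff, 50)
  expect_equal(r1$p_raw, 0)
  expect_equal(r1$t_stat, Inf)

  # generic case against the closed form
  r2 <- pairedT(c(110, 95, 105, 100, 90, 100), c(60, 55, 70, 50, 45, 60))
  o2 <- oraclePairedT(c(110, 95, 105, 100, 90, 100),
                      c(60, 55, 70, 50, 45, 60))
  expect_equal(r2$t_stat, o2$t, tolerance = 1e-12)
  expect_equal(r2$p_raw, o2$p, tolerance = 1e-12)

  expect_equal(pairedT(1, 2)$status, "insufficient")
})

test_that("pairedT agrees with oracles on 1000 random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:15, 1)
    c_ <- rnorm(n, 100, 12); t_ <- rnorm(n, 100, 12)
    r <- pairedT(c_, t_)
    o <- oraclePairedT(c_, t_)
    expect_equal(r$t_stat, o$t, tolerance = 1e-12)
    expect_equal(r$p_raw, o$p, tolerance = 1e-12)
  }
  # spot-check a batch against stats::t.test as a second, library oracle
  set.seed(102)
  for (i in 1:50) {
    c_ <- rnorm(8, 100, 10); t_ <- rnorm(8, 95, 10)
    tt <- stats::t.test(c_, t_, paired = TRUE)
    r <- pairedT(c_, t_)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p_raw, tt$p.value, tolerance = 1e-12)
  }
})

test_that("fisherCombine matches the df=4 closed-form survival", {
  r <- fisherCombine(c(1, 1))
  expect_equal(r$X2, 0)
  expect_equal(r$p_combined, 1)

  r2 <- fisherCombine(c(0.05, 0.05))
  X2 <- -4 * log(0.05)
  expect_equal(r2$X2, X2, tolerance = 1e-12)
  expect_equal(r2$p_combined, exp(-X2 / 2) * (1 + X2 / 2),
               tolerance = 1e-12)

  # single p passes through
  expect_equal(fisherCombine(0.123)$p_combined, 0.123)

  set.seed(7)
  for (i in 1:1000) {
    p <- runif(2)
    x <- -2 * sum(log(p))
    expect_equal(fisherCombine(p)$p_combined,
                 exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  }
  expect_warning(r3 <- fisherCombine(c(0, 0.5)), "clamped")
  expect_lt(r3$p_combined, 1e-100)
})

test_that("BH adjustment is the step-up procedure and monotone", {
  expect_equal(adjustP(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjustP(0.37), 0.37)
  expect_true(all(adjustP(rep(0.5, 10)) >= 0.5))
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    # independent step-up oracle: min over j >= i of m p_(j) / j
    m <- length(p); o <- order(p)
    adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
    expected <- pmin(1, adj)[order(o)]
    expect_equal(adjustP(p), expected, tolerance = 1e-12)
    expect_true(all(adjustP(p) >= p - 1e-15))
  }
})

test_that("hit calling enforces all three conditions and the linkage veto", {
  base <- S4Vectors::DataFrame(
    gene = sprintf("g%d", 1:5),
    n_pairs = 12L, mean_control = 100,
    mean_test = c(70, 70, 70, 130, 99),
    diff = c(30, 30, 100, -30, 1),
    t_stat = c(5, 5, 2, -5, 0.1),
    sign_consistent = TRUE,
    p_combined = c(0.0001, 0.0001, 0.5, 0.0001, 0.9),
    status = "ok", linked = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    p_adjusted = NA_real_, call = "none")
  out <- callHits(base)
  expect_equal(out$call,
               c("sick",   # significant, large positive diff
                 "none",   # linkage veto despite significance
                 "none",   # fails alpha despite huge diff
                 "rescue", # significant negative diff
                 "none"))  # neither
  expect_true(is.na(out$p_adjusted[2]))  # linked gene outside universe

  # inconsistent sign across experiments is never called
  base$sign_consistent <- FALSE
  expect_true(all(callHits(base)$call == "none"))
})

test_that("scoreScreen pairs spots by replicate and recovers planted effects", {
  cfg <- SimulationConfig(nGenes = 96, replicatesPerGene = 4,
                          nExperiments = 2, plateEffectSd = 0.1,
                          noiseCv = 0.08, sickFraction = 0.05,
                          rescueFraction = 0.02, missingRate = 0,
                          seed = 21)
  sim <- simulateScreen(cfg)
  norm <- normalizePlates(sim$screen)
  res <- callHits(scoreScreen(norm$screen))
  truth <- sim$truth
  sick <- truth$gene[truth$class == "sick"]
  rescue <- truth$gene[truth$class == "rescue"]
  expect_setequal(res$gene[res$call == "sick"], sick)
  expect_setequal(res$gene[res$call == "rescue"], rescue)
  # diff is on normalized units: planted 0.5x effect -> diff near +50
  expect_equal(mean(res$diff[res$gene %in% sick]), 50, tolerance = 0.15)
})

test_that("increasing planted effect never decreases |t| without noise", {
  # noise-free screens: stronger effects give larger |diff| at zero sd,
  # so t is +Inf (degenerate) for all planted genes; compare |diff| and
  # check monotonicity of |t| on lightly-noised screens instead
  effects <- c(0.9, 0.7, 0.5, 0.3)
  tstats <- vapply(effects, function(ef) {
    cfg <- SimulationConfig(nGenes = 50, replicatesPerGene = 4,
                            nExperiments = 1, plateEffectSd = 0,
                            edgeBoost = 1, noiseCv = 0.05,
                            sickFraction = 0.02, rescueFraction = 0,
                            sickEffect = ef, missingRate = 0, seed = 33)
    sim <- simulateScreen(cfg)
    norm <- normalizePlates(sim$screen)
    res <- scoreScreen(norm$screen)
    g <- sim$truth$gene[sim$truth$class == "sick"]
    res$t_stat[res$gene == g]
  }, numeric(1))
  expect_true(all(diff(abs(tstats)) > 0))
})

test_that("two screens sharing planted sick genes are recovered by intersection", {
  cfg <- function(s) SimulationConfig(nGenes = 200, replicatesPerGene = 12,
                                      nExperiments = 2, sickFraction = 0.05,
                                      rescueFraction = 0, seed = s)
  score <- function(config, truth = NULL) {
    sim <- simulateScreen(config, truth = truth)
    res <- callHits(scoreScreen(normalizePlates(sim$screen)$screen))
    list(res = res, truth = sim$truth)
  }
  a <- score(cfg(301))
  b <- score(cfg(302), truth = a$truth)   # same library, same true hits
  shared <- intersectScreens(a$res, b$res)
  sick <- a$truth$gene[a$truth$class == "sick"]
  expect_length(sick, 10L)
  expect_gte(length(intersect(shared$gene, sick)), 9L)
})

test_that("intersectScreens keeps genes called in both screens", {
  mk <- function(genes, calls) S4Vectors::DataFrame(
    gene = genes, n_pairs = 4L, mean_control = 100, mean_test = 60,
    diff = 40, t_stat = 5, p_combined = 0.001, p_adjusted = 0.01,
    status = "ok", linked = FALSE, sign_consistent = TRUE, call = calls)
  a <- mk(c("g1", "g2", "g3"), c("sick", "sick", "none"))
  b <- mk(c("g2", "g3", "g4"), c("sick", "sick", "sick"))
  out <- intersectScreens(a, b)
  expect_equal(out$gene, "g2")
  expect_equal(out$diff_a, 40)

  empty <- intersectScreens(mk("g1", "sick"), mk("g1", "none"))
  expect_equal(nrow(empty), 0L)
  expect_warning(intersectScreens(mk("g1", "sick"), mk("zz", "sick")),
                 "disjoint")
})
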