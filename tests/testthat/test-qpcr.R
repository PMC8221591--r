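test_that("replicate aggregation returns means with a replicate-SD QC column", {
  df <- data.frame(gene = "Arc", sample = "s1", group = "sleep",
                   replicate = 1:3, ct = c(20.0, 20.2, 20.1))
  agg <- aggregateReplicates(df)
  expect_equal(agg$ct, 20.1)
  expect_equal(agg$ct_sd, sd(c(20.0, 20.2, 20.1)))
  expect_equal(agg$n_replicates, 3L)
  one <- aggregateReplicates(data.frame(gene = "Arc", sample = "s1",
                                        replicate = 1, ct = 21.3))
  expect_equal(one$ct, 21.3)
  expect_true(is.na(one$ct_sd))
})

test_that("model-based stability matches the brute-force decomposition oracle", {
  set.seed(42)
  genes <- paste0("g", 1:4)
  samples <- paste0("s", 1:8)
  Y <- matrix(rnorm(32, mean = 20, sd = 1), 4, 8,
              dimnames = list(genes, samples))
  group <- rep(c("sleep", "SD"), each = 4)
  tab <- ctTableFromMatrix(Y, group)
  got <- stabilityModelBased(tab, genes, groups = c("sleep", "SD"))
  want <- oracleModelStability(Y, group)
  expect_equal(got$stability, want$stability, tolerance = 1e-9)
  expect_equal(got$intergroup_diff, want$intergroup_diff, tolerance = 1e-9)
})

test_that("a noiseless, undrifted gene has stability zero and rank one", {
  genes <- paste0("g", 1:4)
  base <- c(20, 22, 24, 26)
  drift <- c(0, 0.2, -0.2, 0)        # candidate drifts cancel around genes 1 and 4
  Y <- outer(base, rep(1, 8)) + outer(drift, c(rep(0, 4), rep(1, 4)))
  dimnames(Y) <- list(genes, paste0("s", 1:8))
  tab <- ctTableFromMatrix(Y, rep(c("sleep", "SD"), each = 4))
  st <- stabilityModelBased(tab, genes, groups = c("sleep", "SD"))
  expect_equal(st$stability[1], 0)
  expect_equal(which.min(st$stability), 1L)
  expect_error(stabilityModelBased(tab, genes[1:2]), ">= 3")
})

test_that("adding noise to one gene raises its stability value", {
  genes <- paste0("g", 1:5)
  worse <- replicate(40, {
    seedY <- matrix(20 + rnorm(40, 0, 0.05), 5, 8,
                    dimnames = list(genes, paste0("s", 1:8)))
    noisy <- seedY
    noisy["g3", ] <- noisy["g3", ] + rnorm(8, 0, 0.5)
    grp <- rep(c("sleep", "SD"), each = 4)
    a <- stabilityModelBased(ctTableFromMatrix(seedY, grp), genes)
    b <- stabilityModelBased(ctTableFromMatrix(noisy, grp), genes)
    b$stability[3] - a$stability[3]
  })
  expect_gt(mean(worse > 0), 0.9)
})

test_that("pairwise M matches hand arithmetic and its invariances", {
  genes <- c("a", "b", "c")
  Y <- rbind(a = c(20.0, 20.5, 21.0, 20.2),
             b = c(18.1, 18.4, 19.2, 18.2),
             c = c(25.0, 24.8, 26.1, 25.3))
  colnames(Y) <- paste0("s", 1:4)
  tab <- ctTableFromMatrix(Y, rep(c("sleep", "SD"), 2))
  m <- stabilityPairwiseM(tab, genes)
  hand <- c(mean(c(sd(Y[1, ] - Y[2, ]), sd(Y[1, ] - Y[3, ]))),
            mean(c(sd(Y[2, ] - Y[1, ]), sd(Y[2, ] - Y[3, ]))),
            mean(c(sd(Y[3, ] - Y[1, ]), sd(Y[3, ] - Y[2, ]))))
  expect_equal(m$M, hand)

  ## two genes at a constant offset: M = 0 for both
  two <- ctTableFromMatrix(rbind(a = c(20, 21, 22, 23),
                                 b = c(18, 19, 20, 21)) |>
                             (\(x) {colnames(x) <- paste0("s", 1:4); x})(),
                           rep(c("sleep", "SD"), 2))
  expect_equal(stabilityPairwiseM(two, c("a", "b"))$M, c(0, 0))

  ## shifting one gene by a constant changes nothing
  Y2 <- Y; Y2["b", ] <- Y2["b", ] + 5
  m2 <- stabilityPairwiseM(ctTableFromMatrix(Y2, rep(c("sleep", "SD"), 2)), genes)
  expect_equal(m2$M, m$M)
  ## the comparative delta-Ct measure shares the same values
  cd <- stabilityCompDeltaCt(tab, genes)
  expect_equal(cd$mean_pairwise_sd, m$M)
  expect_error(stabilityPairwiseM(tab, "a"), ">= 2")
})

test_that("rank aggregation is a geometric mean with model-based tie-break", {
  rk <- data.frame(gene = c("a", "b", "c"),
                   model_based = c(1, 2, 3), pairwise_M = c(1, 2, 3))
  agg <- stabilityAggregate(rk)
  expect_equal(agg$rank_aggregate, c(1L, 2L, 3L))

  ## geomean tie (1,4) vs (2,2): broken by the first method
  tie <- data.frame(gene = c("x", "y"), model_based = c(1, 2),
                    pairwise_M = c(4, 2))
  at <- stabilityAggregate(tie)
  expect_equal(at$rank_geomean, c(2, 2))
  expect_equal(at$rank_aggregate, c(1L, 2L))

  ## permuting gene order permutes but does not change aggregated ranks
  perm <- rk[c(3, 1, 2), ]
  ap <- stabilityAggregate(perm)
  expect_equal(ap$rank_aggregate[match(rk$gene, ap$gene)], agg$rank_aggregate)
})

test_that("stability ranking is invariant to relabeling and per-gene shifts", {
  sim <- simulateCtTable(seed = 77)
  rep1 <- stabilityReport(sim$table, hkCandidates, c("sleep", "SD"))
  ## per-gene constant shift
  shifted <- sim$table
  for (i in seq_along(hkCandidates)) {
    sel <- shifted$gene == hkCandidates[i]
    shifted$ct[sel] <- shifted$ct[sel] + i * 3
  }
  rep2 <- stabilityReport(shifted, hkCandidates, c("sleep", "SD"))
  t1 <- stabilityTable(rep1); t2 <- stabilityTable(rep2)
  expect_equal(t2$rank_aggregate[match(t1$gene, t2$gene)], t1$rank_aggregate)
  ## gene relabeling (permuted candidate order)
  rep3 <- stabilityReport(sim$table, rev(hkCandidates), c("sleep", "SD"))
  t3 <- stabilityTable(rep3)
  expect_equal(t3$rank_aggregate[match(t1$gene, t3$gene)], t1$rank_aggregate)
  expect_setequal(selectedPair(rep3), selectedPair(rep1))
})

test_that("pair selection minimizes the countervailing sum with stability tie-break", {
  pg <- data.frame(gene = c("a", "b", "c"),
                   intergroup_diff = c(0.3, -0.3, 0.5),
                   stability = c(0.2, 0.25, 0.1),
                   rank_aggregate = c(1, 2, 3))
  expect_setequal(selectPair(pg, top_k = 4), c("a", "b"))

  ## all d equal: the two lowest stability values win
  eq <- data.frame(gene = c("a", "b", "c", "d"),
                   intergroup_diff = rep(0.2, 4),
                   stability = c(0.4, 0.1, 0.3, 0.2),
                   rank_aggregate = 1:4)
  expect_setequal(selectPair(eq, top_k = 4), c("b", "d"))
  expect_error(selectPair(pg[1, ], top_k = 4), "fewer than 2")
})

test_that("the designed countervailing pair is recovered from simulated panels", {
  hits <- vapply(1:25, function(s) {
    sim <- simulateCtTable(seed = s, sigma_rep = 0.1)
    setequal(selectedPair(stabilityReport(sim$table, hkCandidates,
                                          c("sleep", "SD"))),
             c("Actg1", "Hprt1"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pair group ratios convert CT shifts into the report convention", {
  ## identical groups: ratio and fold change are exactly 1
  Y <- rbind(h1 = rep(20, 6), h2 = rep(22, 6))
  colnames(Y) <- paste0("s", 1:6)
  tab <- ctTableFromMatrix(Y, rep(c("sleep", "SD"), each = 3))
  pr <- pairGroupRatio(tab, c("h1", "h2"), c("sleep", "SD"))
  expect_equal(pr$ratio, 1)
  expect_equal(pr$fold_change, 1)

  ## pair-mean CT lower by 0.2 cycles in sleep: ratio 2^-0.2, fold -1.15
  Y2 <- Y; Y2[, 4:6] <- Y2[, 4:6] + 0.2
  pr2 <- pairGroupRatio(ctTableFromMatrix(Y2, rep(c("sleep", "SD"), each = 3)),
                        c("h1", "h2"), c("sleep", "SD"))
  expect_equal(pr2$ratio, 2^-0.2, tolerance = 1e-12)
  expect_equal(pr2$fold_change, -1.15)

  ## a sample missing one pair gene is dropped with a warning
  miss <- tab[!(tab$sample == "s2" & tab$gene == "h2"), ]
  expect_warning(pm <- pairGroupRatio(miss, c("h1", "h2"), c("sleep", "SD")),
                 "s2")
  expect_equal(nrow(pm$per_sample), 5)
})

test_that("ratio-to-fold-change conversion matches the published convention", {
  expect_equal(foldChangeConvert(0.98), -1.02)
  expect_equal(foldChangeConvert(1.02), 1.02)
  expect_equal(foldChangeConvert(1.00), 1.00)
  ## a printed ratio of 0.92 converts to -1.09 under the stated convention
  ## (-1/0.92 = -1.0869...); see the acceptance suite for the full table
  expect_equal(foldChangeConvert(0.92), -1.09)
  expect_error(foldChangeConvert(0), "positive")
  expect_error(foldChangeConvert(-2), "positive")
  ## antisymmetry away from 1
  for (r in c(0.2, 0.5, 0.87, 1.3, 2.5)) {
    expect_equal(foldChangeConvert(1 / r, digits = NULL),
                 -foldChangeConvert(r, digits = NULL))
  }
})

test_that("delta CT normalization is exact and shift-invariant", {
  tab <- data.frame(gene = c("Arc", "h1", "h2"), sample = "s1",
                    ct = c(25, 20, 22))
  expect_equal(deltaCt(tab, c("h1", "h2"))$delta_ct, 4)
  tab$ct <- c(21, 20, 22)
  expect_equal(deltaCt(tab, c("h1", "h2"))$delta_ct, 0)
  ## adding a constant to every CT of a sample leaves delta CT unchanged
  two <- rbind(tab, transform(tab, sample = "s2", ct = ct + 3.7))
  d <- deltaCt(two, c("h1", "h2"))
  expect_equal(d$delta_ct[d$sample == "s1"], d$delta_ct[d$sample == "s2"])
  ## missing housekeeping: sample dropped with warning
  miss <- two[!(two$sample == "s2" & two$gene == "h2"), ]
  expect_warning(dm <- deltaCt(miss, c("h1", "h2")), "s2")
  expect_equal(dm$sample, "s1")
})

test_that("delta-delta-CT fold changes propagate error as root-sum-square", {
  same <- ddctFoldChange(c(5, 5.2, 4.8), c(5, 5.2, 4.8))
  expect_equal(same$ddct, 0)
  expect_equal(same$log2_fc, 0)
  expect_equal(same$fold_change, 1)

  ## group means 5.16 and 3.90 with SEMs 0.37 and 0.19
  r <- ddctFromSummary(5.16, 0.37, 4, 3.90, 0.19, 5)
  expect_equal(r$ddct, -1.26)
  expect_equal(r$log2_fc, 1.26)
  expect_equal(r$ratio, 2^1.26)
  expect_equal(r$se_ddct, sqrt(0.37^2 + 0.19^2))
  expect_equal(round(r$se_ddct, 3), 0.416)

  expect_error(ddctFoldChange(1, c(1, 2)), "2 samples")
  ## the bootstrap SE agrees with the propagated SE in order of magnitude
  set.seed(1)
  x <- rnorm(6, 5, 0.4); y <- rnorm(6, 4, 0.4)
  fb <- ddctFoldChange(x, y, bootstrap = 400, seed = 2)
  expect_lt(abs(fb$se_boot - fb$se_ddct) / fb$se_ddct, 0.5)
})

test_that("delta-delta-CT is invariant to per-sample constants", {
  sim <- simulateCtTable(seed = 15, sigma_sample = 0)
  d0 <- deltaCt(sim$table, c("Actg1", "Hprt1"))
  shifted <- sim$table
  offs <- setNames(seq_along(unique(shifted$sample)), unique(shifted$sample))
  shifted$ct <- shifted$ct + offs[shifted$sample]
  d1 <- deltaCt(shifted, c("Actg1", "Hprt1"))
  expect_equal(d1$delta_ct, d0$delta_ct, tolerance = 1e-12)
})

test_that("marker enrichment against input uses a one-sample t with conventions", {
  ip <- setNames(c(19, 18.8, 19.2, 19.0), paste0("m", 1:4))
  inp <- setNames(c(20, 20, 20, 20), paste0("m", 1:4))
  e <- enrichmentVsInput(ip, inp)
  expect_equal(e$per_sample$enrichment_log2, c(1.0, 1.2, 0.8, 1.0))
  expect_equal(e$mean, 1)
  expect_equal(e$se, sd(c(1, 1.2, 0.8, 1)) / 2)
  expect_equal(e$df, 3)
  expect_equal(e$t, 1 / e$se, tolerance = 1e-12)
  expect_equal(round(e$t, 2), 12.25)

  ## sign flip: t flips, p unchanged
  ef <- enrichmentVsInput(setNames(2 * inp[paste0("m", 1:4)] - ip, paste0("m", 1:4)), inp)
  expect_equal(ef$t, -e$t, tolerance = 1e-12)
  expect_equal(ef$p, e$p, tolerance = 1e-12)

  ## all-zero enrichment: t = 0, p = 1 by convention
  z <- enrichmentVsInput(inp, inp)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)

  ## unpaired samples are dropped with a warning
  expect_warning(w <- enrichmentVsInput(ip, inp[1:3]), "m4")
  expect_equal(w$df, 2)
})

test_that("the Welch group test separates shifted groups and handles degeneracy", {
  expect_equal(groupTest(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_equal(groupTest(c(1, 1, 1), c(2, 2, 2))$p, 0)
  set.seed(8)
  x <- rnorm(6); y <- rnorm(6) + 10
  expect_lt(groupTest(x, y)$p, 1e-6)
  expect_error(groupTest(1, c(1, 2)), "2 values")
})

test_that("step-down Sidak adjustment matches its closed form and is monotone", {
  expect_equal(holmSidak(0.2)$p_adj, 0.2)
  hs <- holmSidak(c(0.01, 0.04))
  expect_equal(hs$p_adj, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holmSidak(c(0, 0, 0))$p_adj, c(0, 0, 0))
  expect_error(holmSidak(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(20)
  out <- holmSidak(p)
  expect_true(all(out$p_adj >= p - 1e-12))
  expect_true(all(diff(out$p_adj[order(out$p)]) >= -1e-12))
  expect_true(all(out$p_adj <= 1))
})
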