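test_that("vector-sum OSI/DSI match hand-computed complex sums", {
  expect_equal(osi_dsi(rep(2, 8)), list(osi = 0, dsi = 0))
  one <- c(0, 0, 5, 0, 0, 0, 0, 0)
  expect_equal(osi_dsi(one), list(osi = 1, dsi = 1))
  ## r = (2,1,0,1,2,1,0,1): |sum r e^{2i theta}| = 4, sum r = 8, z1 = 0
  r <- c(2, 1, 0, 1, 2, 1, 0, 1)
  res <- osi_dsi(r)
  expect_equal(res$osi, 0.5, tolerance = 1e-12)
  expect_equal(res$dsi, 0, tolerance = 1e-12)
  expect_true(is.na(osi_dsi(rep(0, 8))$osi))
})

test_that("preferred direction disambiguates and is rotation-equivariant", {
  r <- rep(0, 8); r[3] <- 4   # only 90 degrees
  expect_equal(preferred_direction(r), 90)
  ## equal peaks at 0 and 180: z1 = 0, the >= branch keeps the orientation
  r2 <- c(3, 0, 0, 0, 3, 0, 0, 0)
  expect_equal(preferred_direction(r2), 0)
  ## rotating the response vector by one slot rotates the PD by 45 degrees
  r3 <- c(4, 2.5, 1, 0.5, 0.8, 0.5, 1, 2.5)
  pd <- preferred_direction(r3)
  for (k in 1:7) {
    rk <- r3[((seq_len(8) - 1 - k) %% 8) + 1]
    expect_equal(preferred_direction(rk), (pd + 45 * k) %% 360,
                 tolerance = 1e-9)
  }
  ## below the 1 Hz peak-rate threshold the PD is undefined
  expect_true(is.na(preferred_direction(rep(0.05, 8))))
})

test_that("response sparsity has its boundary and worked values", {
  expect_equal(selectivity(rep(3, 118)), 0)
  one <- rep(0, 118); one[40] <- 7
  expect_equal(selectivity(one), 1)
  expect_equal(selectivity(c(3, 1)), (1 - 4 / 5) / (1 / 2))
  expect_true(is.na(selectivity(rep(0, 10))))
  ## scale invariance
  set.seed(1)
  r <- runif(50)
  expect_equal(selectivity(r), selectivity(3 * r))
})

test_that("participation ratio reports the busiest-bin active fraction", {
  expect_equal(participation_ratio(matrix(0L, 10, 100)), 0)
  all_at_once <- matrix(0L, 10, 100); all_at_once[, 7] <- 1L
  expect_equal(participation_ratio(all_at_once), 1)
  half <- matrix(0L, 10, 100); half[1:5, 33] <- 1L
  expect_equal(participation_ratio(half), 0.5)
})

test_that("oracle correlation is 1 for reliable, ~0 for noise responses", {
  set.seed(2)
  sig <- runif(30, 0, 10)
  reliable <- matrix(sig, 30, 8)
  expect_equal(oracle_correlation(reliable), 1)
  noise <- matrix(rnorm(100 * 10), 100, 10)
  expect_lt(abs(oracle_correlation(noise)), 0.1)
  ## scale invariance
  expect_equal(oracle_correlation(noise * 2 + 0),
               oracle_correlation(noise), tolerance = 1e-12)
  expect_true(is.na(oracle_correlation(matrix(1, 5, 4))))
})

test_that("similarity score is the complemented KS statistic", {
  x <- rnorm(200)
  expect_equal(similarity_score(x, x), 1)
  expect_equal(similarity_score(1:100, 201:300), 0)
  ## invariance under a common monotone transform
  set.seed(3)
  a <- rgamma(150, 2); b <- rgamma(180, 3)
  expect_equal(similarity_score(a, b), similarity_score(log(a), log(b)),
               tolerance = 1e-12)
})

test_that("response-correlation weight deltas follow the sign convention", {
  w <- c(rep(1, 10), rep(1, 10), rep(1, 10))
  cc <- c(runif(10, 0.6, 0.9), runif(10, -0.2, 0.2), runif(10, -0.9, -0.6))
  res <- response_correlation_deltas(w, cc)
  expect_equal(res$delta_like, 0)
  expect_equal(res$delta_anti, 0)
  ## mu_like = 1.2 vs mu_unc = 1.0 -> Delta_like = 0.2
  w2 <- c(rep(1.2, 10), rep(1, 10), rep(0.9, 10))
  res2 <- response_correlation_deltas(w2, cc)
  expect_equal(res2$delta_like, 0.2, tolerance = 1e-12)
  expect_equal(res2$delta_anti, 0.1, tolerance = 1e-12)
  ## inhibitory: stronger inhibition for correlated pairs is like-to-like
  w3 <- -w2
  res3 <- response_correlation_deltas(w3, cc)
  expect_equal(res3$delta_like, 0.2, tolerance = 1e-12)
  expect_equal(res3$delta_anti, 0.1, tolerance = 1e-12)
  ## degenerate baseline flagged as undefined
  res4 <- response_correlation_deltas(c(1, 0, -1) * 1e-20,
                                      c(0.7, 0, -0.7))
  expect_true(is.na(res4$delta_like))
})

test_that("cosine-series PD-difference fit recovers exact and noisy effects", {
  d <- seq(0, 180, by = 5)
  fit0 <- pd_difference_fit(rep(2, length(d)), d)
  expect_equal(fit0$a, 0, tolerance = 1e-10)
  expect_equal(fit0$b, 0, tolerance = 1e-10)
  ## exact data w = 2 + cos(d): a = 1, b = 0, c = 2, a/c = 0.5
  w <- 2 + cos(d * pi / 180)
  fit1 <- pd_difference_fit(w, d)
  expect_equal(fit1$a, 1, tolerance = 1e-9)
  expect_equal(fit1$b, 0, tolerance = 1e-9)
  expect_equal(fit1$c, 2, tolerance = 1e-9)
  expect_equal(fit1$a_over_c, 0.5, tolerance = 1e-9)
  ## folding: differences beyond 180 are reflected
  expect_equal(pd_difference_fit(w, 360 - d)$a, fit1$a, tolerance = 1e-9)
  ## simulated noisy direction effect: recovered within 3 SE, significant
  set.seed(4)
  dd <- runif(1e4, 0, 180)
  ww <- 2 + 0.5 * cos(dd * pi / 180) + rnorm(1e4, 0, 0.5)
  fit2 <- pd_difference_fit(ww, dd)
  expect_lt(abs(fit2$a - 0.5), 3 * fit2$se[1])
  expect_lt(fit2$p[1], 0.001)
  expect_error(pd_difference_fit(1:3, c(0, 60, 120)), "at least 4")
})

test_that("cohort split makes per-type core tertiles with target fractions", {
  net <- net_mid()
  cs <- cohort_split(net)
  asg <- cs$assignment
  ## only core sources are assigned
  expect_true(all(net$neurons$core[asg$id]))
  ## per type, tertiles within one of each other
  for (tt in unique(asg$type)) {
    tab <- table(asg$cohort[asg$type == tt])
    expect_lte(diff(range(tab)), 1)
  }
  ## target fractions sum to one per (type, cohort)
  fr <- cs$target_fractions
  sums <- tapply(fr$fraction, paste(fr$type, fr$cohort), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  ## an inhibitory cohort holds ~ (inh core count / 3) neurons: the
  ## fraction-of-network arithmetic is consistent with the composition
  pv_core <- sum(net$neurons$type == "PV" & net$neurons$core)
  pv_cohort <- sum(asg$type == "PV" & asg$cohort == "high")
  expect_lte(abs(pv_cohort - pv_core / 3), 1)
  ## 9 distinct totals -> 3/3/3
  toy <- net
  toy$neurons <- data.frame(id = 1:9, type = "T", x = 0, y = 0, z = 0,
                            tuning_angle = 0, indegree_target = 10,
                            model_id = 1L, core = TRUE)
  toy$edges_rec <- data.frame(src = 1:9, dst = c(2:9, 1),
                              weight = 1:9, delay = 1L, family = 1L)
  toy$config <- net$config
  toy$config$cell_types$T <- toy$config$cell_types$L4_Exc
  toy$config$cell_types$T$name <- "T"
  asg9 <- cohort_split(toy)$assignment
  expect_equal(as.numeric(table(asg9$cohort)), c(3, 3, 3))
  expect_equal(asg9$cohort[order(asg9$total_out)],
               rep(c("low", "mid", "high"), each = 3))
})

test_that("silencing suppresses targets and propagates downstream", {
  ## hand-built 3-neuron chain: LGN -> n1 -> n2 -> n3, strong excitation
  g <- glif_param_set(-70, -50, 0.2, 20, c(0, 0), c(0.1, 0.1), 2)
  kin <- list(tau_f = 1.5, tau_s = 6, lam = 0.4)
  u <- calibrate_unitary_psp(g, kin)
  base <- one_neuron_net(g, kin)
  cfg <- base$config
  net <- base
  net$neurons <- data.frame(id = 1:3, type = "L4_Exc", x = 0, y = 400, z = 0,
                            tuning_angle = 0, indegree_target = 100,
                            model_id = 1L, core = TRUE)
  net$glif <- glif_vectors(list(g), rep(1L, 3))
  fam_ee <- base$edges_rec$family %||% NULL
  fams <- net$family_kinetics
  fee <- fams$family[fams$src_eff == "L4_Exc" & fams$dst_eff == "L4_Exc"]
  fex <- fams$family[fams$src_eff == "ExtExc" & fams$dst_eff == "L4_Exc"]
  w_str <- 25 / u
  net$edges_rec <- data.frame(src = c(1L, 2L), dst = c(2L, 3L),
                              weight = w_str, delay = 1L, family = fee)
  net$edges_lgn <- data.frame(src = 1L, dst = 1L, weight = w_str,
                              delay = 1L, family = fex)
  net$edges_bkg <- data.frame(src = 1L, dst = 1L, weight = 0,
                              delay = 1L, family = fex)[0, ]
  net$lgn_units$baseline <- 80   # brisk drive to the chain head
  ## empty cohort is a no-op
  res0 <- silence_and_compare(net, integer(0), seed = 5, n_trials = 1L,
                              duration = 150L)
  expect_true(all(res0$summary$pct_rate == 0 | is.na(res0$summary$pct_rate)))
  ## silencing the driver collapses downstream rates
  res1 <- silence_and_compare(net, 1L, seed = 5, n_trials = 1L,
                              duration = 300L)
  expect_gt(mean(res1$baseline$rate), 0)
  expect_lt(res1$summary$pct_rate, 0)
  ## silenced neuron excluded from reports
  expect_false(1L %in% res1$baseline$id)
})

test_that("the contrast sweep aggregates rates and selectivity per type", {
  res <- contrast_sweep(net_small(), contrasts = c(0.1, 0.8),
                        directions = c(0, 90), n_trials = 1L,
                        duration = 150L, seed = 3)
  expect_setequal(unique(res$contrast), c(0.1, 0.8))
  expect_setequal(unique(res$type), unique(net_small()$neurons$type[
    net_small()$neurons$core]))
  expect_true(all(res$rate >= 0))
  expect_true(all(is.na(res$osi) | (res$osi >= 0 & res$osi <= 1)))
})

test_that("matched resampling returns the requested p-value distribution", {
  set.seed(6)
  df <- data.frame(x = rnorm(400), y = rnorm(400))
  statfun <- function(d) {
    ct <- suppressWarnings(cor.test(d$x, d$y))
    list(stat = unname(ct$estimate), p = ct$p.value)
  }
  res <- matched_resample_pvalues(df, 50, statfun, reps = 100, seed = 7)
  expect_equal(nrow(res), 100)
  ## using every pair gives a degenerate distribution at the full-sample p
  res_all <- matched_resample_pvalues(df, 400, statfun, reps = 5, seed = 8)
  expect_equal(length(unique(res_all$p)), 1)
  expect_equal(res_all$p[1], statfun(df)$p)
  ## under the null the p-values are approximately uniform; the pool must
  ## dwarf the subsample so rep-to-rep overlap and the pool's own sample
  ## correlation do not distort the marginal distribution
  set.seed(10)
  big <- data.frame(x = rnorm(4000), y = rnorm(4000))
  res_null <- matched_resample_pvalues(big, 50, statfun, reps = 1000, seed = 9)
  ks <- suppressWarnings(ks.test(res_null$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
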