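test_that("neuron placement respects geometry, counts and distributions", {
  cfg <- toy_build_config(n_neurons = 400)
  neurons <- place_neurons(cfg, seed = 42)
  ## counts per type = round(density * layer volume)
  vol <- pi * (cfg$column_radius / 1000)^2 *
    diff(cfg$cell_types[[1]]$depth_range) / 1000
  for (ct in cfg$cell_types) {
    expect_equal(sum(neurons$type == ct$name),
                 unname(round(ct$density * vol)))
  }
  ## all lateral radii within the column
  expect_true(all(sqrt(neurons$x^2 + neurons$z^2) <= cfg$column_radius))
  ## depths within laminar ranges
  expect_true(all(neurons$y >= 350 & neurons$y <= 450))
  expect_true(all(neurons$indegree_target > 0))
})

test_that("tuning angles are circularly uniform (Rayleigh test)", {
  cfg <- toy_build_config(n_neurons = 80)
  cfg$cell_types$L4_Exc$density <- cfg$cell_types$L4_Exc$density * 160
  neurons <- place_neurons(cfg, seed = 1)
  th <- neurons$tuning_angle[neurons$type == "L4_Exc"] * pi / 180
  n <- length(th)
  expect_gt(n, 9000)
  rbar <- Mod(sum(exp(1i * th))) / n
  p_rayleigh <- exp(-n * rbar^2)
  expect_gt(p_rayleigh, 0.01)
})

test_that("in-degree draws recover the log-normal shape by MLE refit", {
  cfg <- toy_build_config(n_neurons = 80)
  cfg$cell_types$L4_Exc$density <- cfg$cell_types$L4_Exc$density * 160
  cfg$cell_types$L4_Exc$indegree_lognormal <- list(sdlog = 0.5, scale = 1000)
  neurons <- place_neurons(cfg, seed = 2)
  x <- neurons$indegree_target[neurons$type == "L4_Exc"]
  ## MLE of sdlog for a log-normal is the sd of the logs
  expect_lt(abs(sd(log(x)) - 0.5), 0.05)
})

test_that("negative density is rejected and zero-count types warn", {
  cfg <- toy_build_config(n_neurons = 300)
  cfg$cell_types$SST$density <- -1
  expect_error(place_neurons(cfg, 1), "negative density")
  cfg$cell_types$SST$density <- 1e-9
  expect_warning(place_neurons(cfg, 1), "zero neurons")
})

test_that("connection probability follows the displaced anisotropic profile", {
  ## at the centroid the probability equals p_max (exponent zero)
  th <- 30
  mu_inh <- 50 * c(cos(th * pi / 180), sin(th * pi / 180))
  expect_equal(unname(connection_probability(rbind(mu_inh), th, 0.3, 100,
                                             "inhibitory", TRUE)), 0.3)
  mu_exc <- -mu_inh
  expect_equal(unname(connection_probability(rbind(mu_exc), th, 0.3, 100,
                                             "excitatory", TRUE)), 0.3)
  ## excitatory, theta = 0: centroid at (-dR, 0)
  expect_equal(connection_probability(rbind(c(-50, 0)), 0, 0.2, 80,
                                      "excitatory", TRUE), 0.2)
  ## inhibitory outside the displacement region: centred isotropic Gaussian
  p <- connection_probability(rbind(c(100, 0)), 77, 0.4, 100,
                              "inhibitory", FALSE)
  expect_equal(p, 0.4 * exp(-0.5), tolerance = 1e-12)
  ## excitatory anisotropy: tighter along the orientation axis than across
  ## (80 um from the displaced centroid in each direction)
  p_along <- connection_probability(rbind(c(-50 + 80, 0)), 0, 0.2, 80,
                                    "excitatory", TRUE)
  p_across <- connection_probability(rbind(c(-50, 80)), 0, 0.2, 80,
                                     "excitatory", TRUE)
  expect_equal(p_along, 0.2 * exp(-0.5 * (80 / (80 / 1.5))^2), tolerance = 1e-12)
  expect_equal(p_across, 0.2 * exp(-0.5 * (80 / (80 * 1.5))^2), tolerance = 1e-12)
  expect_lt(p_along, p_across)
})

test_that("like-to-like factor matches its closed forms and averages to one", {
  expect_equal(like_to_like_factor(c(0, 30, 90), 1), c(1, 1, 1))
  expect_equal(like_to_like_factor(0, 0.6), 1.25)
  expect_equal(like_to_like_factor(90, 0.6), 0.75)
  ## folding: 150 deg folds to 30 deg
  expect_equal(like_to_like_factor(150, 0.6), like_to_like_factor(30, 0.6))
  ## mean over uniform offsets equals 1 (trapezoid quadrature)
  for (beta in c(0.2, 0.6, 0.95)) {
    x <- seq(0, 90, length.out = 20001)
    f <- like_to_like_factor(x, beta)
    m <- sum((f[-1] + f[-length(f)]) / 2) * diff(x)[1] / 90
    expect_lt(abs(m - 1), 1e-6)
  }
  expect_error(like_to_like_factor(10, 0), "beta")
})

test_that("in-degree factor is the plain ratio", {
  expect_equal(indegree_factor(2000, 2000), 1)
  expect_equal(indegree_factor(4000, 2000), 2)
  expect_equal(indegree_factor(500, 2000), 0.25)
  expect_error(indegree_factor(-1, 10), "positive")
})

test_that("log-normal quotient weight rule has the stated moments", {
  ## sigma_W = sqrt(sigma_PSP^2 - sigma_N^2)
  set.seed(1)
  w <- sample_connection_weight(list(meanlog = 0, sdlog = 0.9),
                                list(sdlog = 0.5, scale = 1000),
                                n_mean = 1000, n_target = rep(1000, 2e4),
                                unitary_psp = 1)
  expect_lt(abs(sd(log(w)) - sqrt(0.9^2 - 0.5^2)), 0.02)
  expect_lt(abs(sqrt(0.56) - 0.7483), 1e-4)  # closed form of the example pair
  ## degenerate case collapses to the floor
  set.seed(2)
  w2 <- sample_connection_weight(list(meanlog = 0, sdlog = 0.5),
                                 list(sdlog = 0.5, scale = 1000),
                                 1000, rep(1000, 2e4), 1)
  expect_lt(abs(sd(log(w2)) - 0.01), 0.002)
  expect_error(sample_connection_weight(list(meanlog = 0, sdlog = 0.9),
                                        list(sdlog = 0.5, scale = 1000),
                                        1000, 1000, unitary_psp = 0),
               "unitary")
})

test_that("quotient closure recovers the population PSP distribution", {
  ## drawing the in-degree per connection and rescaling, the final weights
  ## are log-normal with exactly the experimental PSP parameters
  set.seed(3)
  mu_psp <- log(0.4); s_psp <- 0.9; s_n <- 0.5; scale_n <- 1000
  n <- 1e5
  n_t <- pmax(1, round(rlnorm(n, log(scale_n), s_n)))
  w <- sample_connection_weight(list(meanlog = mu_psp, sdlog = s_psp),
                                list(sdlog = s_n, scale = scale_n),
                                n_mean = scale_n, n_target = n_t,
                                unitary_psp = 1)
  ks <- suppressWarnings(ks.test(w, plnorm, meanlog = mu_psp, sdlog = s_psp))
  expect_gt(ks$p.value, 0.01)
})

test_that("unitary PSP calibration is linear and kinetics-sensitive", {
  g <- glif_param_set(-70, -50, 0.2, 20, c(0, 0), c(0.1, 0.1), 4)
  kin0 <- list(tau_f = 1.5, tau_s = 6, lam = 0)
  kin1 <- list(tau_f = 1.5, tau_s = 6, lam = 0.5)
  u0 <- calibrate_unitary_psp(g, kin0)
  u1 <- calibrate_unitary_psp(g, kin1)
  expect_gt(u1, u0)   # added slow charge strictly increases the peak
  ## doubling membrane resistance doubles the deflection (linearity)
  g2 <- glif_param_set(-70, -50, 0.4, 20, c(0, 0), c(0.1, 0.1), 4)
  expect_equal(calibrate_unitary_psp(g2, kin1), 2 * u1, tolerance = 1e-12)
  ## weight conversion: desired 1 mV at unitary 0.5 mV -> weight 2
  expect_equal(1 / 0.5, 2)
  ## a threshold crossing during calibration is rejected
  g3 <- glif_param_set(-70, -69.99, 10, 20, c(0, 0), c(0.1, 0.1), 4)
  expect_error(calibrate_unitary_psp(g3, kin1), "threshold")
})

test_that("Yule-Simon pmf, normalization and sampler agree", {
  expect_equal(yule_simon_pmf(1, 2), 2 / 3, tolerance = 1e-12)
  k <- 1:50
  expect_equal(yule_simon_pmf(k, 1), 1 / (k * (k + 1)), tolerance = 1e-12)
  expect_lt(abs(sum(yule_simon_pmf(1:1e6, 2)) - 1), 1e-4)
  expect_error(yule_simon_pmf(1, 0), "rho")
  set.seed(4)
  s <- yule_simon_sample(2e5, 2.5)
  expect_true(all(s >= 1))
  expect_lt(abs(mean(s) - yule_simon_mean(2.5)), 0.02)
  ## sampler matches the pmf head
  emp <- tabulate(s, 6) / length(s)
  expect_equal(emp, yule_simon_pmf(1:6, 2.5), tolerance = 0.01)
})

test_that("recurrent wiring matches analytic edge-count expectation", {
  ## single-class isotropic config with degenerate in-degree spread
  cfg <- toy_build_config(n_neurons = 500)
  cfg$cell_types <- cfg$cell_types["L4_Exc"]
  cfg$cell_types$L4_Exc$density <- cfg$cell_types$L4_Exc$density / 0.8
  cfg$cell_types$L4_Exc$indegree_lognormal <- list(sdlog = 0, scale = 250)
  cfg$connections <- Filter(function(s)
    s$src_type == "L4_Exc" && s$dst_type == "L4_Exc", cfg$connections)
  cfg$connections[[1]]$p_max <- 0.1
  cfg$connections[[1]]$sigma <- 100
  cfg$connections[[1]]$beta <- NULL
  neurons <- place_neurons(cfg, seed = 5)
  fams <- build_family_kinetics(cfg)
  unitary <- unitary_psp_table(cfg, fams)
  edges <- wire_recurrent(neurons, cfg, seed = 6, unitary = unitary)
  ## analytic expectation: sum over ordered pairs of the spatial rule
  disp_r <- cfg$displacement_region_factor * cfg$core_radius
  in_region <- sqrt(neurons$x^2 + neurons$z^2) <= disp_r
  exp_edges <- 0; var_edges <- 0
  for (j in seq_len(nrow(neurons))) {
    dr <- cbind(neurons$x - neurons$x[j], neurons$z - neurons$z[j])
    p <- connection_probability(dr, neurons$tuning_angle[j], 0.1, 100,
                                "excitatory", rep(in_region[j], nrow(dr)))
    p[j] <- 0
    exp_edges <- exp_edges + sum(p)
    var_edges <- var_edges + sum(p * (1 - p))
  }
  expect_lt(abs(nrow(edges) - exp_edges), 3 * sqrt(var_edges))
  ## no autapses, Dale sign (excitatory source -> positive)
  expect_true(all(edges$src != edges$dst))
  expect_true(all(edges$weight > 0))
})

test_that("degenerate recurrent wiring cases", {
  cfg <- toy_build_config(n_neurons = 120)
  for (i in seq_along(cfg$connections)) cfg$connections[[i]]$p_max <- 0
  neurons <- place_neurons(cfg, seed = 1)
  fams <- build_family_kinetics(cfg)
  unitary <- unitary_psp_table(cfg, fams)
  expect_equal(nrow(wire_recurrent(neurons, cfg, 2, unitary)), 0)
  ## two co-located neurons outside the displacement region, p_max = 1:
  ## both directed edges must be realized
  cfg2 <- toy_build_config(n_neurons = 120)
  cfg2$connections <- Filter(function(s)
    s$src_type == "L4_Exc" && s$dst_type == "L4_Exc", cfg2$connections)
  cfg2$connections[[1]]$p_max <- 1
  cfg2$connections[[1]]$beta <- NULL
  two <- data.frame(id = 1:2, type = "L4_Exc", x = c(350, 350), y = 400,
                    z = 0, tuning_angle = c(10, 200), indegree_target = 250,
                    model_id = 1L, core = FALSE)
  fams2 <- build_family_kinetics(cfg2)
  unitary2 <- unitary_psp_table(cfg2, fams2)
  e2 <- wire_recurrent(two, cfg2, 3, unitary2)
  expect_equal(nrow(e2), 2)
  expect_setequal(paste(e2$src, e2$dst), c("1 2", "2 1"))
})

test_that("network edges respect Dale's law and delay rounding", {
  net <- net_small()
  cfg <- net$config
  src_class <- vapply(net$neurons$type[net$edges_rec$src],
                      function(tt) type_class(cfg, tt), "")
  expect_true(all(sign(net$edges_rec$weight) ==
                    ifelse(src_class == "excitatory", 1, -1)))
  expect_true(all(net$edges_rec$delay >= 1))
  expect_true(all(net$edges_rec$delay == round(net$edges_rec$delay)))
  ## LGN delay 1.7 ms rounds to 2 steps; background delay 1 ms stays 1
  expect_true(all(net$edges_lgn$delay == 2L))
  expect_true(all(net$edges_bkg$delay == 1L))
  expect_true(all(net$edges_lgn$weight > 0))
  expect_true(all(net$edges_bkg$weight > 0))
})

test_that("LGN wiring follows the Yule-Simon connection-count rule", {
  cfg <- toy_build_config(n_neurons = 120, n_lgn_units = 200L)
  cfg$cell_types$L4_Exc$lgn_rho <- 2
  cfg$cell_types$L4_Exc$lgn_fraction <- 0.2
  one <- data.frame(id = 1L, type = "L4_Exc", x = 0, y = 400, z = 0,
                    tuning_angle = 0, indegree_target = 500L,
                    model_id = 1L, core = TRUE)
  units <- make_lgn_units(cfg, seed = 8, n_units = 200L)
  fams <- build_family_kinetics(cfg)
  unitary <- unitary_psp_table(cfg, fams)
  edges <- wire_lgn(one, units, cfg, seed = 9, unitary = unitary)
  ## N_syn = 0.2 * 500 = 100; N_conn = 100 * (2 - 1) / 2 = 50
  expect_equal(nrow(edges), 50)
  expect_true(all(edges$n_syn >= 1))
  ## weight proportional to synapse count
  expect_equal(order(edges$weight), order(edges$n_syn))
  ## distinct sources
  expect_equal(anyDuplicated(edges$src), 0)
  ## rho <= 1 rejected
  cfg$cell_types$L4_Exc$lgn_rho <- 1
  expect_error(wire_lgn(one, units, cfg, 9, unitary = unitary), "rho")
})

test_that("LGN synapse counts have the Yule-Simon mean", {
  net <- net_small()
  rho <- net$config$cell_types$L4_Exc$lgn_rho
  counts <- net$lgn_n_syn
  expect_gt(length(counts), 1000)
  expect_lt(abs(mean(counts) - yule_simon_mean(rho)),
            3 * sd(counts) / sqrt(length(counts)) + 0.05)
})

test_that("background wiring gives exactly 4 distinct units per neuron", {
  net <- net_small()
  by_dst <- split(net$edges_bkg$src, net$edges_bkg$dst)
  expect_true(all(vapply(by_dst, length, 0L) == 4L))
  expect_true(all(vapply(by_dst, anyDuplicated, 0L) == 0L))
  cfg <- net$config
  cfg$background$n_units <- 3L
  expect_error(wire_background(net$neurons, cfg, 1), "fewer")
})

test_that("the 19-type composition yields 11 effective types and 121 families", {
  cts <- full_cell_type_table()
  expect_length(cts, 19L)
  eff <- effective_types(cts)
  expect_length(eff, 11L)
  expect_true("ExtExc" %in% eff)
  fams <- receptor_families(cts)
  expect_equal(nrow(fams), 121L)
  expect_equal(anyDuplicated(fams[, c("src_eff", "dst_eff")]), 0L)
})

test_that("seeded builds are bit-reproducible", {
  cfg <- toy_build_config(n_neurons = 120)
  a <- build_network(cfg, seed = 31, calibrate_background = FALSE)
  b <- build_network(cfg, seed = 31, calibrate_background = FALSE)
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$edges_rec, b$edges_rec)
  expect_identical(a$edges_lgn, b$edges_lgn)
  expect_identical(a$edges_bkg, b$edges_bkg)
})
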