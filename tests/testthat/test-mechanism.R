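# Mechanism dissection: variant toggles, MINC, RINC, R-ratio

test_that("minc reproduces the worked stoichiometric chain", {
  y <- minc_yields()
  # 25 mM lactate -> 31.87 mM sulfate demand -> 27.56 mM nitrate demand
  expect_equal(25 * y$sulfate_per_lactate, 31.87, tolerance = 0.05 / 31.87)
  expect_equal(minc(25), 27.56, tolerance = 0.05 / 27.56)
  expect_equal(y$sulfide_per_nitrate_total, 1.1564,
               tolerance = 0.01 / 1.16)
  expect_equal(minc(0), 0)
  # exact linearity in the donor concentration
  expect_equal(minc(50), 2 * minc(25))
  for (lac in c(1, 7.3, 100)) {
    expect_equal(minc(lac), lac * minc(1))
  }
  expect_error(minc(25, yield_sulfate_per_lactate = 0), "positive")
})

test_that("inhibition toggle is exactly the factor removal", {
  net <- reaction_network("A")
  kin <- fix_truth_kinetics()
  off <- sim_variant(net, kin, inhibition_on = FALSE)
  expect_true(is.infinite(off$kinetics$SRB$I))
  # inhibition-off rate at saturating nitrite equals inhibition-on rate
  # at zero nitrite
  p_on <- kin$SRB; p_off <- off$kinetics$SRB
  X <- 1e-3
  expect_equal(monod_rate(p_off, X, 1, 1, C_inhibitor = 10),
               monod_rate(p_on, X, 1, 1, C_inhibitor = 0),
               tolerance = 1e-12)
  # output invariant to the inhibitor trajectory once removed
  init_hi <- batch_design()[["no3_1000"]]
  out1 <- run_variant(off, "batch", initial = init_hi,
                      t_grid = fix_times())
  init_lo <- init_hi; init_lo["nitrate"] <- 0
  out2 <- run_variant(off, "batch", initial = init_lo,
                      t_grid = fix_times())
  # sulfate path identical up to the (tiny) donor competition difference
  expect_equal(out1$sulfate, out2$sulfate, tolerance = 0.02)
})

test_that("variant validation", {
  net <- reaction_network("A")
  kin <- fix_truth_kinetics()
  expect_error(sim_variant(net, kin, drop = "NRSOB1"), "not in the model")
  # dropping every nitrate reducer with no nitrate in the feed matches
  # the SRB-only base model
  v <- sim_variant(net, kin, drop = c("NRB1", "NRB2"))
  expect_identical(v$network$communities, "SRB")
})

test_that("SIM toggles: inhibition dominates, biocompetition is minor", {
  # noisy data generated from the full model (inhibition on); the
  # inhibition-free variant (SIM2-like) and the SRB-only variant
  # (SIM3-like) fail almost identically, and much worse than the base
  syn <- make_batch_set("A", noise_sd = 0.05, times = fix_times(),
                        seed = 42)
  truth <- fix_truth_kinetics()
  net <- reaction_network("A")
  score <- function(variant) {
    traj <- lapply(syn$experiments, function(init) {
      simulate_batch(variant$network, variant$kinetics, init, syn$times)
    })
    sse_score(traj, syn$data, species = c("sulfate", "sulfide"))$sse
  }
  sse1 <- score(sim_variant(net, truth))
  sse2 <- score(sim_variant(net, truth, inhibition_on = FALSE))
  sse3 <- score(sim_variant(net, truth, drop = c("NRB1", "NRB2")))
  expect_equal(sse2, sse3, tolerance = 0.1)
  expect_gt(sse2, 10 * sse1)
  expect_gt(sse3, 10 * sse1)
})

test_that("souring develops faster at higher nitrite-reduction rate R", {
  net <- reaction_network("A")
  truth <- fix_truth_kinetics()
  init <- batch_design()[["no3_700"]]
  tg <- seq(0, 48 * 3600, length.out = 49)
  tth <- vapply(c(0.25, 0.75, 1.5, 2.75), function(R) {
    kin <- set_r_ratio(net, truth, R, "NRB1", "NRB2")$kinetics
    time_to_half_max(simulate_batch(net, kin, init, tg), "sulfide")
  }, 0)
  expect_true(all(diff(tth) < 0))
})

test_that("set_r_ratio rescales the nitrite-step rate linearly", {
  net <- reaction_network("A")
  kin <- fix_truth_kinetics()
  r1 <- set_r_ratio(net, kin, 1, "NRB1", "NRB2")
  expect_equal(r1$achieved_R, 1)
  r2 <- set_r_ratio(net, kin, 2, "NRB1", "NRB2")
  expect_equal(r2$kinetics$NRB2$mu_max, 2 * r1$kinetics$NRB2$mu_max)
  expect_error(set_r_ratio(net, kin, 0, "NRB1", "NRB2"), "positive")
  kin0 <- kin; kin0$NRB1$mu_max <- 0
  expect_error(set_r_ratio(net, kin0, 1, "NRB1", "NRB2"), "zero")
})

test_that("quasi-steady sulfide is non-increasing in the nitrate dose", {
  grid <- fix_column_grid()
  net <- reaction_network("B")
  kin <- fix_column_kinetics()
  qs <- vapply(c(0, 5, 10, 20), function(dose) {
    as.numeric(quasi_steady_sulfide(
      dose, grid, net, kin, fix_column_initial, fix_column_influent,
      flow_ml_h = 6, distance_cm = 62, t_end_d = 10,
      steady_window_d = 3, dt_d = 0.02, startup = FALSE,
      warn_unsteady = FALSE))
  }, 0)
  expect_true(all(diff(qs) <= 1e-9))
  expect_gt(qs[1], 1)          # untreated column sours
  expect_lt(qs[4], 0.1)        # high dose suppresses it
})

test_that("RINC is zero without SRB and rises with distance", {
  grid <- column_grid(length_cm = 200, n_cells = 50, diameter_cm = 1)
  net <- reaction_network("B")
  kin <- default_kinetics(net$communities)
  kin$SRB$X0 <- 500;    kin$SRB$b <- 1e-7
  kin$NRSOB1$X0 <- 300; kin$NRSOB1$b <- 1e-7; kin$NRSOB1$mu_max <- 5e-6
  kin$NRSOB2$X0 <- 300; kin$NRSOB2$b <- 1e-7; kin$NRSOB2$mu_max <- 5e-6
  # no SRB: nothing to inhibit, the search returns the lower bracket
  no_srb <- sim_variant(net, kin, drop = "SRB")
  r0 <- rinc_search(lo = 0, hi = 10, tol_mM = 0.5,
                    grid = fix_column_grid(), network = no_srb$network,
                    kinetics = no_srb$kinetics,
                    initial = fix_column_initial,
                    influent_mM = fix_column_influent, flow_ml_h = 6,
                    distance_cm = 62, t_end_d = 4, steady_window_d = 2,
                    dt_d = 0.02, startup = FALSE, warn_unsteady = FALSE)
  expect_equal(as.numeric(r0), 0)
  # farther observation points need at least as much nitrate
  rinc <- vapply(c(6.5, 50.5, 199.5), function(d) {
    as.numeric(rinc_search(
      lo = 0, hi = 30, tol_mM = 0.5, grid = grid, network = net,
      kinetics = kin, initial = fix_column_initial,
      influent_mM = fix_column_influent, flow_ml_h = 6,
      distance_cm = d, t_end_d = 10, steady_window_d = 3, dt_d = 0.02,
      startup = FALSE, warn_unsteady = FALSE))
  }, 0)
  expect_true(all(diff(rinc) >= 0))
  expect_gt(rinc[3], rinc[1])
  # non-bracketing upper bound raises a search error
  expect_error(rinc_search(
    lo = 0, hi = 0.01, tol_mM = 0.5, grid = fix_column_grid(),
    network = net, kinetics = kin, initial = fix_column_initial,
    influent_mM = fix_column_influent, flow_ml_h = 6, distance_cm = 62,
    t_end_d = 4, steady_window_d = 2, dt_d = 0.02, startup = FALSE,
    warn_unsteady = FALSE), "does not suppress")
})

test_that("without nitrite inhibition the RINC collapses to the MINC", {
  # fast kinetics and frozen biomass give complete conversion within the
  # residence time, so the only remaining control is stoichiometric:
  # the bisection lands on the 27.56 mM nitrate demand of 25 mM lactate
  grid <- fix_column_grid()
  net <- reaction_network("B")
  kin <- default_kinetics(net$communities)
  kin$SRB    <- kinetic_params(2e-5, 2e-4, 2e-4, I = Inf, b = 0,
                               X0 = 2000)
  kin$NRSOB1 <- kinetic_params(2e-5, 2e-4, 2e-4, b = 0, X0 = 1000)
  kin$NRSOB2 <- kinetic_params(2e-5, 2e-4, 2e-4, b = 0, X0 = 1000)
  r <- rinc_search(lo = 20, hi = 30, tol_mM = 0.25,
                   grid = grid, network = net, kinetics = kin,
                   initial = fix_column_initial,
                   influent_mM = fix_column_influent, flow_ml_h = 3,
                   distance_cm = 62, t_end_d = 8, steady_window_d = 3,
                   dt_d = 0.02, startup = FALSE, frozen_biomass = TRUE,
                   warn_unsteady = FALSE)
  expect_equal(as.numeric(r), minc(25), tolerance = 0.5 / 27.56)
})

test_that("time_to_half_max handles flat and rising trajectories", {
  flat <- data.frame(time = 0:10, sulfide = rep(0, 11))
  expect_true(is.na(time_to_half_max(flat)))
  rise <- data.frame(time = 0:10, sulfide = 0:10)
  expect_equal(time_to_half_max(rise), 5)
})
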