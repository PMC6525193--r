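# 1D finite-volume reactive transport: transport, splitting, mass balance

test_that("no flow and no dispersion leaves the state unchanged", {
  grid <- column_grid(n_cells = 8, Dm_cm2_s = 0)
  conc <- matrix(runif(16), 2, 8, dimnames = list(c("sulfate", "sulfide"),
                                                  NULL))
  out <- transport_step(conc, grid, q_cm_s = 0,
                        c_in = c(sulfate = 1, sulfide = 0), dt_s = 100)
  expect_identical(out$conc, conc)
  expect_equal(sum(out$influx), 0)
})

test_that("tracer transport conserves mass to 1e-10 relative", {
  grid <- fix_column_grid(n_cells = 32)
  conc <- matrix(0, 1, 32, dimnames = list("sulfate", NULL))
  conc[1, 10:15] <- 2e-3                       # interior pulse
  vol_l <- grid$area_cm2 * grid$dx_cm * grid$porosity / 1000
  q <- 9 / 3600 / grid$area_cm2
  m0 <- sum(conc) * vol_l
  influx <- outflux <- 0
  for (i in 1:40) {
    st <- transport_step(conc, grid, q, c(sulfate = 1e-3), dt_s = 600)
    conc <- st$conc
    influx <- influx + st$influx
    outflux <- outflux + st$outflux
  }
  m1 <- sum(conc) * vol_l
  expect_equal(m1, m0 + unname(influx) - unname(outflux),
               tolerance = 1e-10)
  expect_true(all(conc >= 0))
})

test_that("inter-port travel time at 9 ml/h matches advection", {
  # pore velocity = Q / (A phi); 56 cm between ports 1 and 5
  grid <- column_grid()                        # full 64-cell geometry
  v_cm_d <- 9 * 24 / (grid$area_cm2 * grid$porosity)
  t_analytic <- 56 / v_cm_d
  expect_equal(t_analytic, 1.55, tolerance = 0.02)

  net <- reaction_network("SRB")
  kin <- default_kinetics("SRB"); kin$SRB$X0 <- 0
  sched <- column_schedule(0, 9, sulfate = 10)
  run <- run_column(grid, sched, net, kin, c(sulfate = 0), t_end_d = 4,
                    dt_d = 0.005, sample_every_d = 0.01, startup = FALSE)
  tt <- midrise_time(run$ports, "port5") - midrise_time(run$ports, "port1")
  expect_equal(tt, 1.55, tolerance = 0.02)
})

test_that("grid refinement moves breakthrough time by < 2%", {
  kin <- default_kinetics("SRB"); kin$SRB$X0 <- 0
  net <- reaction_network("SRB")
  sched <- column_schedule(0, 9, sulfate = 10)
  bt <- vapply(c(64, 128), function(nc) {
    grid <- column_grid(n_cells = nc)
    run <- run_column(grid, sched, net, kin, c(sulfate = 0), t_end_d = 4,
                      dt_d = 0.005, sample_every_d = 0.01,
                      startup = FALSE,
                      ports = list(port5 = cells_at(grid, 62, 2)))
    midrise_time(run$ports, "port5")
  }, 0)
  expect_lt(abs(bt[2] - bt[1]) / bt[1], 0.02)
})

test_that("a zero-dt or biomass-free reaction step is the identity", {
  net <- reaction_network("B")
  kin <- fix_column_kinetics()
  conc <- matrix(1e-3, length(net$species), 4,
                 dimnames = list(net$species, NULL))
  X <- matrix(1e-3, length(net$communities), 4)
  out <- reaction_step(conc, X, net, kin, dt_s = 0)
  expect_identical(out$conc, conc)
  out2 <- reaction_step(conc, 0 * X, net, kin, dt_s = 3600)
  expect_identical(out2$conc, conc)
})

test_that("single-cell reaction step equals simulate_batch", {
  net <- reaction_network("A")
  kin <- default_kinetics(net$communities)
  init <- batch_design()[["no3_500"]]
  dt <- 2 * 3600
  batch <- simulate_batch(net, kin, init, c(0, dt),
                          frozen_biomass = FALSE, rtol = 1e-10,
                          atol = 1e-14)
  conc0 <- stats::setNames(numeric(length(net$species)), net$species)
  conc0[names(init)] <- init
  X0 <- vapply(net$communities,
               function(cm) to_molar(kin[[cm]]$X0, "biomass", "mg/l"), 0)
  st <- reaction_step(matrix(conc0, ncol = 1,
                             dimnames = list(net$species, NULL)),
                      matrix(X0, ncol = 1), net, kin, dt,
                      rtol = 1e-10, atol = 1e-14)
  expect_equal(drop(st$conc), unlist(batch[2, net$species]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reaction step conserves sulfur cell by cell", {
  net <- reaction_network("B")
  kin <- fix_column_kinetics()
  set.seed(3)
  conc <- matrix(abs(rnorm(length(net$species) * 6, 2e-3, 1e-3)),
                 length(net$species), 6,
                 dimnames = list(net$species, NULL))
  X <- matrix(abs(rnorm(length(net$communities) * 6, 2e-3, 1e-3)),
              length(net$communities), 6)
  st <- reaction_step(conc, X, net, kin, dt_s = 6 * 3600)
  s_before <- colSums(conc[c("sulfate", "sulfide", "s0"), ])
  s_after <- colSums(st$conc[c("sulfate", "sulfide", "s0"), ])
  expect_equal(s_after, s_before, tolerance = 1e-9)
})

test_that("global elemental sulfur balance closes over a reactive run", {
  grid <- fix_column_grid()
  net <- reaction_network("B")
  kin <- fix_column_kinetics()
  sched <- do.call(column_schedule,
                   c(list(time_d = 0, flow_ml_h = 6, nitrate = 5),
                     as.list(fix_column_influent)))
  run <- run_column(grid, sched, net, kin, fix_column_initial,
                    t_end_d = 3, dt_d = 0.02, sample_every_d = 0.5,
                    startup = FALSE, track_balance = TRUE)
  b <- run$balance
  s_species <- c("sulfate", "sulfide", "s0")
  s_in <- sum(b$influx[s_species])
  s_out <- sum(b$outflux[s_species])
  s_acc <- sum(b$final[s_species]) - sum(b$initial[s_species])
  expect_equal(s_in - s_out, s_acc, tolerance = 1e-6 * max(s_in, 1e-12))
})

test_that("biomass never advects: it changes only by growth and decay", {
  grid <- fix_column_grid()
  net <- reaction_network("SRB")
  kin <- default_kinetics("SRB"); kin$SRB$b <- 0
  sched <- column_schedule(0, 9, sulfate = 10, lactate = 25, ammonium = 5)
  run0 <- run_column(grid, sched, net, kin,
                     c(sulfate = 0, lactate = 0), t_end_d = 1,
                     dt_d = 0.02, startup = FALSE, frozen_biomass = TRUE,
                     track_balance = TRUE)
  # frozen biomass, pure flushing: column biomass exactly constant
  expect_equal(sum(run0$state$X), sum(run0$balance$initial_X) /
                 (grid$area_cm2 * grid$dx_cm * grid$porosity / 1000),
               tolerance = 1e-12)
  # growth on: biomass only increases via growth (no export)
  run1 <- run_column(grid, sched, net, kin, fix_column_initial,
                     t_end_d = 1, dt_d = 0.02, startup = FALSE,
                     track_balance = TRUE)
  expect_gt(sum(run1$balance$final_X), sum(run1$balance$initial_X))
})

test_that("halving the splitting step changes port series by < 0.5%", {
  grid <- fix_column_grid()
  net <- reaction_network("B")
  kin <- fix_column_kinetics()
  sched <- do.call(column_schedule,
                   c(list(time_d = 0, flow_ml_h = 6, nitrate = 2.5),
                     as.list(fix_column_influent)))
  runs <- lapply(c(0.02, 0.01), function(dt) {
    run_column(grid, sched, net, kin, fix_column_initial, t_end_d = 2,
               dt_d = dt, sample_every_d = 0.5, startup = FALSE)
  })
  a <- runs[[1]]$ports; b <- runs[[2]]$ports
  m <- merge(a, b, by = c("time_d", "port", "species"))
  scale <- max(m$value_mM.x)
  expect_lt(max(abs(m$value_mM.x - m$value_mM.y)) / scale, 0.005)
})

test_that("strang splitting agrees with sequential at small dt", {
  grid <- fix_column_grid(n_cells = 8)
  net <- reaction_network("SRB")
  kin <- default_kinetics("SRB"); kin$SRB$X0 <- 300; kin$SRB$b <- 0
  sched <- column_schedule(0, 6, sulfate = 10, lactate = 25, ammonium = 5)
  runs <- lapply(c("sequential", "strang"), function(spl) {
    run_column(grid, sched, net, kin, fix_column_initial, t_end_d = 1,
               dt_d = 0.01, sample_every_d = 0.25, startup = FALSE,
               splitting = spl)
  })
  m <- merge(runs[[1]]$ports, runs[[2]]$ports,
             by = c("time_d", "port", "species"))
  expect_lt(max(abs(m$value_mM.x - m$value_mM.y)) / max(m$value_mM.x),
            0.005)
})

test_that("startup phase runs the column batchwise to 0.1 mM sulfate", {
  grid <- fix_column_grid(n_cells = 8)
  net <- reaction_network("SRB")
  kin <- default_kinetics("SRB"); kin$SRB$X0 <- 2000
  sched <- column_schedule(0, 0.5, sulfate = 10, lactate = 25,
                           ammonium = 5)
  run <- run_column(grid, sched, net, kin, fix_column_initial,
                    t_end_d = 0.25, dt_d = 0.05)
  expect_gt(run$startup_days, 0)
  # at the end of startup every cell is at (or below) the threshold
  first <- run$ports[run$ports$time_d == 0 &
                     run$ports$species == "sulfate", ]
  expect_true(all(first$value_mM <= 0.1 + 1e-6))
})

test_that("with no reactions the effluent reaches the influent", {
  grid <- fix_column_grid(n_cells = 8)
  net <- reaction_network("SRB")
  kin <- default_kinetics("SRB"); kin$SRB$X0 <- 0
  sched <- column_schedule(0, 9, sulfate = 10)
  run <- run_column(grid, sched, net, kin, c(sulfate = 0), t_end_d = 3,
                    dt_d = 0.01, startup = FALSE,
                    ports = list(out = grid$n_cells))
  last <- run$ports[run$ports$species == "sulfate", ]
  expect_equal(last$value_mM[which.max(last$time_d)], 10,
               tolerance = 1e-3)
})

test_that("estimate_influent_sulfate averages sulfate + sulfide", {
  mk <- function(t, so4, hs) {
    rbind(data.frame(time_d = t, port = "port1", species = "sulfate",
                     value_mM = so4),
          data.frame(time_d = t, port = "port1", species = "sulfide",
                     value_mM = hs))
  }
  d <- mk(1:10, 3, 7)
  expect_equal(estimate_influent_sulfate(d), 10)
  d2 <- mk(1:10, seq(2, 4, length.out = 10), 0)
  expect_equal(estimate_influent_sulfate(d2), 3)
  set.seed(9)
  n <- 50
  noise <- rnorm(n, 0, 0.1)
  d3 <- mk(seq_len(n), 3 + noise / 2, 7 + noise / 2)
  expect_lt(abs(estimate_influent_sulfate(d3) - 10), 3 * 0.1 / sqrt(n))
  expect_error(estimate_influent_sulfate(d[d$time_d == 1, ]),
               "at least two")
})

test_that("schedule validation and lookup", {
  expect_error(column_schedule(c(1, 2), 1), "start at time 0")
  expect_error(column_schedule(c(0, 0), 1), "strictly increasing")
  expect_error(column_schedule(0, -1), ">= 0")
  expect_error(column_schedule(0, 1, kryptonite = 1), "unknown species")
  sched <- column_schedule(c(0, 10), c(1, 2), nitrate = c(0, 5))
  expect_equal(soursim:::schedule_at(sched, 3)$flow_ml_h, 1)
  expect_equal(soursim:::schedule_at(sched, 10.5)$nitrate_mM, 5)
})
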