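# Shared fixtures: small, fast model settings used across the suite.
# Everything is generated in code; no stored data.

# coarse observation grid over the batch horizon
fix_times <- function(n = 13) seq(0, 12 * 3600, length.out = n)

# ground-truth kinetics for the scenario-A batch fixture
fix_truth_kinetics <- function() default_kinetics(c("SRB", "NRB1", "NRB2"))

# noiseless scenario-A synthetic batch set (memoized per session)
fix_batch_clean <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_batch_set("A", noise_sd = 0, times = fix_times(),
                               species = c("sulfate", "sulfide", "nitrate",
                                           "nitrite", "ammonium",
                                           "lactate"),
                               seed = 42)
    }
    cache
  }
})

# small column fixture: 16-cell, 1 cm diameter -> short residence time
fix_column_grid <- function(length_cm = 64, n_cells = 16)
  column_grid(length_cm = length_cm, n_cells = n_cells, diameter_cm = 1)

# group B + SRB kinetics for column fixtures: growth on, light decay
fix_column_kinetics <- function() {
  kin <- default_kinetics(c("SRB", "NRSOB1", "NRSOB2"))
  kin$SRB$X0 <- 500; kin$SRB$b <- 1e-7
  kin$NRSOB1$X0 <- 200; kin$NRSOB1$b <- 1e-7
  kin$NRSOB2$X0 <- 200; kin$NRSOB2$b <- 1e-7
  kin
}

fix_column_influent <- c(sulfate = 10, lactate = 25, ammonium = 5)

fix_column_initial <- c(sulfate = 10e-3, lactate = 25e-3, ammonium = 5e-3)

# mid-rise time of a monotone breakthrough curve at a port, by
# interpolation on the rising limb
midrise_time <- function(ports_df, port, species = "sulfate",
                         level = NULL) {
  s <- ports_df[ports_df$port == port & ports_df$species == species, ]
  s <- s[order(s$time_d), ]
  if (is.null(level)) level <- max(s$value_mM) / 2
  i <- which(s$value_mM >= level)[1]
  stopifnot(!is.na(i), i > 1)
  t1 <- s$time_d[i - 1]; t2 <- s$time_d[i]
  v1 <- s$value_mM[i - 1]; v2 <- s$value_mM[i]
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}
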