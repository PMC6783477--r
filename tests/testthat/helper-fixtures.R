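# Shared fixtures, built in code.

# semidiurnal tide table spanning a few days from a fixed origin
fixture_tides <- function(n_days = 4) {
  simulate_tide_table(as.POSIXct("2016-05-01 00:00:00", tz = "UTC"), n_days)
}

# a small simulation design for fast end-to-end tests
small_design <- function(seed = 1, ...) {
  simulation_design(n_per_estuary = c(Vasseide = 6, Vinnesvag = 6,
                                      Torvesund = 6, Stolmen = 6),
                    seed = seed, ...)
}

# a bearing_track holding a fixed lab-frame heading
fixed_track <- function(heading, test_start, eel_id = "e1",
                        estuary = "Vasseide", condition = 0, n = 600) {
  bearing_track(eel_id, estuary, condition, test_start,
                bearings = rep(heading, n))
}

# a time guaranteed to be in an ebb (high -> low) window of fixture_tides()
ebb_time <- function(tides = fixture_tides()) {
  i <- which(tides$type == "high")[1]
  tides$time[i] + diff(as.numeric(tides$time[i + 0:1])) / 2
}

flood_time <- function(tides = fixture_tides()) {
  i <- which(tides$type == "low")[1]
  tides$time[i] + diff(as.numeric(tides$time[i + 0:1])) / 2
}

# independent brute-force circular mean: accumulate unit vectors one by one
oracle_circ_mean <- function(deg) {
  cx <- 0; sx <- 0
  for (d in deg) {
    cx <- cx + cospi(d / 180)
    sx <- sx + sinpi(d / 180)
  }
  r <- sqrt(cx^2 + sx^2) / length(deg)
  mu <- (atan2(sx, cx) * 180 / pi) %% 360
  list(mu = mu, r = r)
}

# run the CLI without echoing its log to the test output
run_cli_quiet <- function(args) suppressMessages(run_cli(args))
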