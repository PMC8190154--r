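# Small, fast scene configurations used across the suite.

tiny_config <- function(...) {
  defaults <- list(grid_shape = c(16L, 16L),
                   season_start = "2019-05-01",
                   season_end = "2019-06-30",
                   n_patches = 1L,
                   patch_radius = 3L,
                   noise_sd = 0,
                   closure_gap_fraction = 0.15,
                   seed = 11L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Hourly records data frame from bare vectors (hourly spacing from t0).
make_records <- function(Rn, LE = NA_real_, Ta = 20, RH = 0.5, G = 0, H = 0,
                         P = 0, t0 = as.POSIXct("2019-06-01 00:00:00",
                                                tz = "UTC")) {
  n <- max(length(Rn), length(LE), length(Ta), length(RH))
  Rn <- rep_len(Rn, n)
  data.frame(timestamp = t0 + 3600 * (seq_len(n) - 1L),
             Ta = rep_len(Ta, n), RH = rep_len(RH, n), Rn = Rn,
             G = rep_len(G, n), H = rep_len(H, n),
             LE = rep_len(LE, n), P = rep_len(P, n))
}

# Independent two-pass implementation of the evaluation statistics
# (population moments), kept deliberately naive.
stats_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  covxy <- sum((x - mx) * (y - my)) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  list(r2 = (covxy / (sy * sx))^2,
       bias = sum(y - x) / n,
       mae = sum(abs(y - x)) / n)
}
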