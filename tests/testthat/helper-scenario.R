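# Small shared fixtures, generated in code.

# two-week early-season scenario: fast, covers the water-deficit phase
tiny_scenario <- function(...) {
  greenhouse_scenario("2019", start = as.Date("2019-03-12"),
                      end = as.Date("2019-03-25"), ...)
}

tiny_inputs <- function(seed = 42) {
  generate_scenario(tiny_scenario(), seed = seed)
}

# minimal hand-built hourly met table (no generator involved)
toy_met <- function(n = 48, start = "2019-05-01") {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = "hour", length.out = n)
  hr <- as.integer(format(ts, "%H"))
  shape <- pmax(0, sin(pi * (hr - 6) / 13))
  data.frame(timestamp = ts, Rn = 400 * shape - 5 * (shape == 0),
             Ta = 20 + 6 * shape, RH = 70 - 20 * shape,
             u2 = 0.1 + 0.05 * shape)
}

toy_crop <- function(dates, lai = 2) {
  data.frame(date = as.Date(dates), lai = lai)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
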