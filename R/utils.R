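# Internal helpers shared across modules.

# Pixel edge length (m) and area (ha) for all synthetic rasters.
PIXEL_M <- 30
PIXEL_HA <- 0.09
DAYS_PER_YEAR <- 365.25


# Deterministic substream seed so each generator can be re-run independently
# from one master seed. Kept below 2^31 - 1 for R's 32-bit integer seeds.
substream_seed <- function(seed, component) {
  offsets <- c(
    landscape = 1L, reflectance = 2L, occurrences = 3L, counts = 4L,
    background = 5L, split = 6L, routes = 7L, mcmc = 8L, misc = 9L
  )
  off <- offsets[[component]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483587)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Day-of-epoch (days since the first simulated year's Jan 1) of mid-year.
year_mid_t <- function(year, year0) {
  (year - year0) * DAYS_PER_YEAR + DAYS_PER_YEAR / 2
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "birdhab_config_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "birdhab_validation_error")
}
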