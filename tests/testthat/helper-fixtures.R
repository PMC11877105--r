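# small deterministic fixtures shared across test files

# straight-line track: n points stepping (dx, dy) um every `interval` s
line_track <- function(n = 37, dx = 0, dy = 1, interval = 20,
                       id = "line") {
  k <- seq_len(n) - 1
  track(id, t = k * interval, x = k * dx, y = k * dy,
        frame_interval = interval)
}

# closed square loop returning exactly to the start (side length `side`)
loop_track <- function(side = 3, interval = 20, id = "loop") {
  x <- c(0, side, side, 0, 0)
  y <- c(0, 0, side, side, 0)
  track(id, t = (0:4) * interval, x = x, y = y, frame_interval = interval)
}

random_track <- function(n = 12, id = "rand", interval = 20) {
  ang <- stats::runif(n - 1, -pi, pi)
  len <- stats::rgamma(n - 1, 2, 2)
  track(id, t = (seq_len(n) - 1) * interval,
        x = c(0, cumsum(len * cos(ang))),
        y = c(0, cumsum(len * sin(ang))),
        frame_interval = interval)
}

# independent per-step chemotactic index: explicit loop, no vectorisation
brute_ci <- function(track, g) {
  g <- g / sqrt(sum(g^2))
  total <- 0; used <- 0L
  for (i in seq_len(length(track$t) - 1L)) {
    dx <- track$x[i + 1] - track$x[i]
    dy <- track$y[i + 1] - track$y[i]
    len <- sqrt(dx^2 + dy^2)
    if (len > 0) {
      total <- total + (dx * g[1] + dy * g[2]) / len
      used <- used + 1L
    }
  }
  if (used == 0L) NA_real_ else total / used
}

# two-sided Fisher p by full enumeration over tables with fixed margins,
# probability-mass ordering
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# standard glycolysis schedule used in handcrafted flux fixtures
glyco_schedule <- function(pma = 18, oligo = 54, dg = 78) {
  injection_schedule(c("PMA", "oligomycin", "2DG"), c(pma, oligo, dg),
                     assay = "glycolysis")
}
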