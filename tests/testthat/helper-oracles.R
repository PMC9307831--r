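# Independent brute-force oracles used by the diagnostic and solver tests.
# These re-derive expected values from first principles (grid scans,
# run-length loops, per-group averaging) without calling the package
# internals they check.

# Exhaustive residual scan of the leaf energy balance on a 0.001 K grid.
oracle_leaf_temperature <- function(absorbed, T_air, RH, r_a, open,
                                    pressure) {
  r_s <- if (open) 200 else 5000
  e_air <- RH / 100 * 0.6108 * exp(17.27 * (T_air - 273.15) /
                                     (T_air - 273.15 + 237.3))
  gamma <- 0.000665 * pressure
  Tg <- seq(T_air - 40, T_air + 40, by = 0.001)
  es <- 0.6108 * exp(17.27 * (Tg - 273.15) / (Tg - 273.15 + 237.3))
  resid <- absorbed -
    1.2 * 1005 * (Tg - T_air) / r_a -
    1.2 * 1005 / gamma * (es - e_air) / (r_a + r_s) -
    0.97 * 5.670374419e-8 * (Tg^4 - T_air^4)
  Tg[which.min(abs(resid))]
}

# Run-length episode detection by explicit loop.
oracle_episodes <- function(inverted) {
  out <- list()
  i <- 1L
  n <- length(inverted)
  while (i <= n) {
    if (inverted[i]) {
      j <- i
      while (j < n && inverted[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Daily means by explicit per-day loop.
oracle_daily_means <- function(dates, values) {
  ud <- sort(unique(dates))
  vapply(ud, function(d) mean(values[dates == d]), 0)
}

# Per-bin means by explicit double loop over bin edges (data must lie
# strictly inside the outer edges).
oracle_bin_means <- function(x, y, values, xbreaks, ybreaks) {
  out <- list()
  for (i in seq_len(length(xbreaks) - 1)) {
    for (j in seq_len(length(ybreaks) - 1)) {
      sel <- x > xbreaks[i] & x <= xbreaks[i + 1] &
        y > ybreaks[j] & y <= ybreaks[j + 1]
      if (any(sel))
        out[[length(out) + 1L]] <- data.frame(
          xi = i, yj = j, n = sum(sel), mean = mean(values[sel]))
    }
  }
  do.call(rbind, out)
}
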