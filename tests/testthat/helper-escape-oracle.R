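# Brute-force fine-time-step escape oracle, independent of the event-driven
# implementation: the unbound molecule performs an explicit random walk with
# dt = tau_on_mean / 100; at each step a binding attempt fires with
# probability 1 - exp(-dt / tau_on_mean); on an attempt the molecule snaps
# to the nearest lattice site and rebinds if the site is on the cluster,
# otherwise it has escaped.
escape_oracle <- function(cfg, n_iter, seed) {
  a <- cfg$lattice_a; side <- cfg$side
  dt <- cfg$tau_on_mean / 100
  p_bind <- 1 - exp(-dt / cfg$tau_on_mean)
  sd_dt <- sqrt(2 * cfg$d_slb * dt)
  withr::with_seed(seed, {
    tau_esc <- n_reb <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      repeat {
        ix <- sample.int(side, 1L) - 1L
        iy <- sample.int(side, 1L) - 1L
        if (cfg$active[iy * side + ix + 1L]) break
      }
      x <- ix * a; y <- iy * a
      total <- stats::rexp(1L, 1 / cfg$tau_off_mean)
      n <- 0L
      repeat {
        # walk until a binding attempt fires
        hop_t <- 0
        repeat {
          x <- x + stats::rnorm(1L, 0, sd_dt)
          y <- y + stats::rnorm(1L, 0, sd_dt)
          hop_t <- hop_t + dt
          if (stats::runif(1L) < p_bind) break
        }
        total <- total + hop_t
        jx <- round(x / a); jy <- round(y / a)
        on_cluster <- jx >= 0 && jx < side && jy >= 0 && jy < side &&
          cfg$active[jy * side + jx + 1L]
        if (!on_cluster) break
        n <- n + 1L
        x <- jx * a; y <- jy * a
        total <- total + stats::rexp(1L, 1 / cfg$tau_off_mean)
      }
      tau_esc[it] <- total
      n_reb[it] <- n
    }
    list(ratio = mean(tau_esc) / cfg$tau_off_mean,
         n_rebinds_mean = mean(n_reb))
  })
}

# Brute-force optimal assignment by permutation enumeration (n <= 7).
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = best, cost = best_cost)
}
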