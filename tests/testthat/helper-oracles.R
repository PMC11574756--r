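# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation (explicit loops, direct
# formulas) kept separate from the implementation paths it checks.

# random rigid motion of a trajectory/ring tibble (columns x, y, z)
apply_rigid_motion <- function(df, angles, shift) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  m <- rx(angles[1]) %*% rz(angles[2]) %*% rx(angles[3])
  p <- as.matrix(df[, c("x", "y", "z")]) %*% t(m)
  df$x <- p[, 1] + shift[1]
  df$y <- p[, 2] + shift[2]
  df$z <- p[, 3] + shift[3]
  df
}

# brute-force Cremer-Pople sums, explicit j = 1..6 loop on raw coordinates
cp_oracle <- function(ring) {
  pos <- as.matrix(ring[match(c("O5", "C1", "C2", "C3", "C4", "C5"), ring$atom),
                        c("x", "y", "z")])
  pos <- sweep(pos, 2, colMeans(pos))
  rp <- c(0, 0, 0); rpp <- c(0, 0, 0)
  for (j in 1:6) {
    rp <- rp + pos[j, ] * sin(2 * pi * (j - 1) / 6)
    rpp <- rpp + pos[j, ] * cos(2 * pi * (j - 1) / 6)
  }
  n <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
         rp[3] * rpp[1] - rp[1] * rpp[3],
         rp[1] * rpp[2] - rp[2] * rpp[1])
  n <- n / sqrt(sum(n^2))
  z <- numeric(6)
  for (j in 1:6) z[j] <- sum(pos[j, ] * n)
  q2c <- 0; q2s <- 0; q3 <- 0
  for (j in 1:6) {
    q2c <- q2c + sqrt(1 / 3) * z[j] * cos(2 * pi * 2 * (j - 1) / 6)
    q2s <- q2s - sqrt(1 / 3) * z[j] * sin(2 * pi * 2 * (j - 1) / 6)
    q3 <- q3 + sqrt(1 / 6) * z[j] * (-1)^(j - 1)
  }
  q2 <- sqrt(q2c^2 + q2s^2)
  list(Q = sqrt(q2^2 + q3^2),
       theta = atan2(q2, q3) * 180 / pi,
       phi = (atan2(q2s, q2c) * 180 / pi) %% 360)
}

# naive double-loop bias summation oracle
bias_oracle <- function(hills, points, upto_time = Inf) {
  cv <- cv_names(hills)
  pts <- glycofel:::as_points_matrix(points, cv)
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    acc <- 0
    for (h in seq_len(nrow(hills))) {
      if (hills$time[h] > upto_time) next
      e <- 0
      for (i in seq_along(cv)) {
        e <- e + (pts[p, i] - hills[[cv[i]]][h])^2 /
          (2 * hills[[paste0("sigma_", cv[i])]][h]^2)
      }
      acc <- acc + hills$height[h] * exp(-e)
    }
    out[p] <- acc
  }
  out
}

# independent recrossing labeller: mid-basin threshold crossings with dwell
# confirmation, written as a plain scan rather than an rle state machine
recross_oracle <- function(time, x, r_range, p_range, min_dwell) {
  in_basin <- function(v, rng) v >= rng[1] & v <= rng[2]
  state <- "none"; cycles <- 0L
  enter_t <- NA; current <- "out"; confirmed_start <- NA
  starts <- c()
  i <- 1
  confirmed <- function(i0, rng) {
    # basin visit confirmed if it persists min_dwell from entry
    t0 <- time[i0]; j <- i0
    while (j <= length(x) && in_basin(x[j], rng)) {
      if (time[j] - t0 >= min_dwell) return(TRUE)
      j <- j + 1
    }
    FALSE
  }
  phase <- 0
  for (i in seq_along(x)) {
    entering_r <- in_basin(x[i], r_range) && (i == 1 || !in_basin(x[i - 1], r_range))
    entering_p <- in_basin(x[i], p_range) && (i == 1 || !in_basin(x[i - 1], p_range))
    if (entering_r && confirmed(i, r_range)) {
      if (phase == 2) cycles <- cycles + 1L
      phase <- 1
    } else if (entering_p && phase == 1 && confirmed(i, p_range)) {
      phase <- 2
    }
  }
  cycles
}

# quick double-well toy run used by several tests (cheap: < 1 s)
toy_double_well_run <- function(seed = 7, n_hills = 3000, stop_recross = 2) {
  run_toy_metadynamics(
    toy_potential("double_well", barrier = 5), x0 = -1,
    n_hills = n_hills, width = 0.06, seed = seed,
    stop_recross = stop_recross
  )
}
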