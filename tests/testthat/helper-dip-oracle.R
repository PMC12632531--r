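# Definitional oracle for the dip statistic.
#
# dip(x) = min over unimodal CDFs G of sup |F_n - G|.  For a trial band
# half-width d, a unimodal G inside the band exists iff for some mode
# position (data point or gap midpoint) there are values v_l <= v_r such
# that a convex nondecreasing function fits the band left of the mode
# ending at v_l, and a concave nondecreasing function fits the band right
# of the mode starting at v_r (the jump v_l -> v_r is the mode atom).
# Pinned-end feasibility is monotone in the pinned value, so the attainable
# end-value intervals are found by inner bisection; every claimed-feasible
# d is additionally VERIFIED by assembling the witness G and directly
# measuring sup |F_n - G| against the step ECDF.  The dip is the outer
# bisection limit.

oracle_dip_machinery <- function(x, tol = 1e-9) {
  x <- sort(as.numeric(x))
  n <- length(x)
  u <- unique(x)
  cc <- cumsum(tabulate(match(x, u)))
  m <- length(u)
  if (m == 1) return(function(d) TRUE)
  rng <- diff(range(u))
  mids <- (u[-m] + u[-1]) / 2
  pL <- u[1] - 3 * rng - 1
  pR <- u[m] + 3 * rng + 1
  grid <- sort(c(pL, u, mids, pR))
  M <- length(grid)
  is_data <- grid %in% u
  cum_at <- function(p) if (any(u <= p)) cc[max(which(u <= p))] else 0
  Fp <- vapply(grid, cum_at, numeric(1)) / n          # F(p)
  Fm <- vapply(seq_len(M), function(i) {              # F(p^-)
    if (is_data[i]) {
      j <- match(grid[i], u)
      if (j == 1) 0 else cc[j - 1] / n
    } else Fp[i]
  }, numeric(1))

  # lower convex hull values at each point via all-pairs chords
  lower_env <- function(p, v) {
    k <- length(p)
    if (k <= 2) return(v)
    env <- v
    for (i in 2:(k - 1)) {
      a <- 1:(i - 1); b <- (i + 1):k
      ch <- outer(a, b, function(ai, bi)
        v[ai] + (v[bi] - v[ai]) * (p[i] - p[ai]) / (p[bi] - p[ai]))
      env[i] <- min(v[i], ch)
    }
    env
  }

  feasible <- function(d, give_witness = FALSE) {
    lo <- pmax(Fp - d, 0)
    hi <- pmin(Fm + d, 1)
    hi_r <- pmin(Fp + d, 1)   # upper bound for the right-piece start value
    for (jm in seq_len(M)) {
      li <- 1:jm; ri <- jm:M
      # left tube: points (pL has box [0, d]-ish already), pinned end value v
      left_env <- function(v) {
        vv <- hi[li]; vv[jm] <- v
        env <- lower_env(grid[li], vv)
        rev(cummin(rev(env)))  # largest NONDECREASING convex fit under vv
      }
      right_env <- function(w) {
        vv <- lo[ri]; vv[1] <- w
        env <- -lower_env(grid[ri], -vv)
        cummax(env)            # smallest nondecreasing concave fit over vv
      }
      left_ok <- function(v) {
        env <- left_env(v)
        all(env[-jm] >= lo[li][-jm] - tol) && env[jm] <= v + tol
      }
      right_ok <- function(w) {
        env <- right_env(w)
        all(env[-1] <= hi[ri][-1] + tol) && env[1] >= w - tol
      }
      if (!left_ok(hi[jm])) next
      if (!right_ok(lo[ri][1])) next
      # smallest feasible left end value
      a <- 0; b <- hi[jm]
      if (left_ok(0)) b <- 0 else for (it in 1:30) {
        mid <- (a + b) / 2
        if (left_ok(mid)) b <- mid else a <- mid
      }
      lmin <- b
      # largest feasible right start value (capped by the right-limit band)
      a <- lo[ri][1]; b <- hi_r[jm]
      if (right_ok(b)) a <- b else for (it in 1:30) {
        mid <- (a + b) / 2
        if (right_ok(mid)) a <- mid else b <- mid
      }
      rmax <- a
      if (lmin > rmax + tol) next
      # assemble witness: v_l = lmin, v_r = clamp
      v_l <- lmin
      v_r <- min(max(lo[ri][1], v_l), rmax)
      gl <- pmin(pmax(left_env(v_l), 0), 1)
      gr <- pmin(pmax(right_env(v_r), 0), 1)
      if (any(diff(gl) < -1e-9) || any(diff(gr) < -1e-9) || gl[jm] > gr[1] + 1e-9) next
      sd <- sup_dist(jm, gl, gr)
      if (sd <= d + 1e-7) {
        if (give_witness) return(list(jm = jm, gl = gl, gr = gr, sup = sd))
        return(TRUE)
      }
    }
    FALSE
  }

  sup_dist <- function(jm, gl, gr) {
    G_at <- function(p, from_left = FALSE) {
      mode_p <- grid[jm]
      if (p < mode_p || (p == mode_p && from_left)) {
        if (p <= grid[1]) return(gl[1])
        i <- findInterval(p, grid[1:jm])
        if (i >= jm) return(gl[jm])
        gl[i] + (gl[i + 1] - gl[i]) * (p - grid[i]) / (grid[i + 1] - grid[i])
      } else {
        if (p >= grid[M]) return(gr[M - jm + 1])
        i <- findInterval(p, grid[jm:M])
        g1 <- gr[i]; g2 <- gr[i + 1]
        p1 <- grid[jm + i - 1]; p2 <- grid[jm + i]
        g1 + (g2 - g1) * (p - p1) / (p2 - p1)
      }
    }
    dmax <- 0
    for (i in seq_len(M)) {
      dmax <- max(dmax,
                  abs(Fp[i] - G_at(grid[i])),
                  abs(Fm[i] - G_at(grid[i], from_left = TRUE)))
    }
    dmax
  }

  feasible
}

oracle_dip <- function(x, iters = 30) {
  feasible <- oracle_dip_machinery(x)
  blo <- 0; bhi <- 0.26
  for (it in seq_len(iters)) {
    mid <- (blo + bhi) / 2
    if (feasible(mid)) bhi <- mid else blo <- mid
  }
  (blo + bhi) / 2
}

oracle_dip_confirms <- function(x, d, eps = 2e-6) {
  feasible <- oracle_dip_machinery(x)
  feasible(d + eps) && (d - eps <= 0 || !feasible(d - eps))
}
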