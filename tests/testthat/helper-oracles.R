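# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, direct definitions) so they cannot
# share a defect with the vectorized implementations they check.

# Symmetric normalized co-occurrence matrix by explicit pair enumeration.
glcm_oracle <- function(levels, ng, offset) {
  P <- matrix(0, ng, ng)
  nr <- nrow(levels)
  nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]
      c2 <- c + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- levels[r, c]
      b <- levels[r2, c2]
      if (a == 0 || b == 0) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

# Run-length matrix by walking each line pixel by pixel.
glrlm_oracle <- function(levels, ng, direction) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  starts <- list()
  dr <- direction[1]
  dc <- direction[2]
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pr <- r - dr
      pc <- c - dc
      inside <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc
      if (!inside) starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]
    c <- s[2]
    cur <- 0L
    len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (v == cur && v != 0L) {
        len <- len + 1L
      } else {
        if (cur != 0L) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v
        len <- if (v != 0L) 1L else 0L
      }
      r <- r + dr
      c <- c + dc
    }
    if (cur != 0L) runs[[length(runs) + 1]] <- c(cur, len)
  }
  lmax <- max(1L, max(vapply(runs, `[`, integer(1), 2), 1L))
  R <- matrix(0, ng, lmax)
  for (rn in runs) R[rn[1], rn[2]] <- R[rn[1], rn[2]] + 1
  R
}

# Harrell's C by explicit O(n^2) pair enumeration.
cindex_oracle <- function(pred, times, events) {
  num <- 0
  den <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- times[i]; tj <- times[j]
      if (ti == tj) {
        # tied follow-up: usable only when exactly one member fails (the
        # censored one is known to survive longer)
        if (events[i] + events[j] != 1) next
        short <- if (events[i] == 1) i else j
        long <- if (events[i] == 1) j else i
      } else {
        short <- if (ti < tj) i else j
        long <- if (ti < tj) j else i
        if (events[short] != 1) next
      }
      den <- den + 1
      if (pred[short] > pred[long]) num <- num + 1
      else if (pred[short] == pred[long]) num <- num + 0.5
    }
  }
  num / den
}

# Random masked toy image with at least one in-mask pixel.
random_toy_image <- function(nr, nc, p_mask = 0.7) {
  px <- matrix(stats::rnorm(nr * nc), nr, nc)
  mk <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
  if (!any(mk)) mk[sample(nr * nc, 1)] <- TRUE
  roi_image(px, mk, id = "toy")
}

# Quick two-class exponential survival sample.
expo_sample <- function(n, hr = 2, base_rate = 0.02, censor_at = Inf) {
  g <- rep(0:1, length.out = n)
  t <- stats::rexp(n, base_rate * hr^g)
  e <- as.integer(t <= censor_at)
  list(times = pmin(t, censor_at), events = e, group = g)
}
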