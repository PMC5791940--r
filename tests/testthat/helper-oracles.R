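# Independent brute-force oracles: naive nested-loop enumerations, written
# without reference to the package's vectorized implementations.

offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
})

in_grid <- function(v, dm) all(v >= 1) && all(v <= dm)

# wrap an integer level array (0 = outside mask) as a quantized_volume
as_quantized <- function(lev, L = max(lev)) {
  structure(list(levels = lev, L = as.integer(L), vmin = 0, vmax = 1,
                 spacing = c(1, 1, 1)),
            class = "quantized_volume")
}

# random quantized blob on a small grid
random_blob <- function(seed, dm = c(5L, 5L, 5L), L = 4L, p_mask = 0.7) {
  set.seed(seed)
  lev <- array(0L, dim = dm)
  inm <- array(stats::runif(prod(dm)) < p_mask, dim = dm)
  lev[inm] <- sample.int(L, sum(inm), replace = TRUE)
  lev
}

glcm_oracle <- function(lev, distance = 1L) {
  dm <- dim(lev)
  L <- max(lev)
  counts <- matrix(0, L, L)
  vox <- which(lev > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    for (k in seq_len(nrow(offsets26))) {
      u <- v + offsets26[k, ] * distance
      if (in_grid(u, dm) && lev[u[1], u[2], u[3]] > 0L)
        counts[lev[v[1], v[2], v[3]], lev[u[1], u[2], u[3]]] <-
          counts[lev[v[1], v[2], v[3]], lev[u[1], u[2], u[3]]] + 1
    }
  }
  counts
}

nid_oracle <- function(lev) {
  dm <- dim(lev)
  L <- max(lev)
  vox <- which(lev > 0L, arr.ind = TRUE)
  s <- numeric(L)
  n_i <- numeric(L)
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    nb <- c()
    for (k in seq_len(nrow(offsets26))) {
      u <- v + offsets26[k, ]
      if (in_grid(u, dm) && lev[u[1], u[2], u[3]] > 0L)
        nb <- c(nb, lev[u[1], u[2], u[3]])
    }
    if (length(nb) == 0) next
    g <- lev[v[1], v[2], v[3]]
    s[g] <- s[g] + abs(g - mean(nb))
    n_i[g] <- n_i[g] + 1
  }
  N <- sum(n_i)
  p <- n_i / N
  present <- which(p > 0)
  den_b <- 0
  for (i in present) for (j in present)
    if (i != j) den_b <- den_b + abs(i * p[i] - j * p[j])
  busy <- if (den_b > 0) sum(p[present] * s[present]) / den_b else 0
  ngp <- length(present)
  contrast <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in present) for (j in present) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (ngp * (ngp - 1)) * sum(s) / N
  }
  list(p = p, s = s, n_voxels = N, busyness = busy, contrast = contrast)
}

# runs of equal level along the 13 unique directions: returns data frame
runs_oracle <- function(lev) {
  dm <- dim(lev)
  dirs <- offsets26[apply(offsets26, 1, function(v) {
    nz <- v[v != 0]; nz[1] > 0
  }), , drop = FALSE]
  out <- list()
  vox <- which(lev > 0L, arr.ind = TRUE)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    for (i in seq_len(nrow(vox))) {
      v <- vox[i, ]
      g <- lev[v[1], v[2], v[3]]
      prev <- v - d
      if (in_grid(prev, dm) && lev[prev[1], prev[2], prev[3]] == g) next
      len <- 1L
      nxt <- v + d
      while (in_grid(nxt, dm) && lev[nxt[1], nxt[2], nxt[3]] == g) {
        len <- len + 1L
        nxt <- nxt + d
      }
      out[[length(out) + 1L]] <- c(g, len)
    }
  }
  m <- do.call(rbind, out)
  data.frame(level = m[, 1], length = m[, 2])
}

# zone list via stack-based flood fill, 26-connectivity, equal level
zones_oracle <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dim = dm)
  zones <- list()
  vox <- which(lev > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    if (seen[v[1], v[2], v[3]]) next
    g <- lev[v[1], v[2], v[3]]
    stack <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0L
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(offsets26))) {
        w <- u + offsets26[k, ]
        if (in_grid(w, dm) && !seen[w[1], w[2], w[3]] &&
            lev[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  m <- do.call(rbind, zones)
  data.frame(level = m[, 1], size = m[, 2])
}

# exhaustive pair-counting concordance (event-anchored, risk ties = 1/2)
harrell_oracle <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# hand product-limit estimator at each distinct event time
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ts, surv = out)
}

# quick uniform-volume helper
uniform_volume <- function(suv, dm = c(3L, 3L, 3L), spacing = c(4, 4, 4)) {
  pet_volume(array(suv, dim = dm), spacing = spacing)
}
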