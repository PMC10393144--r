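# Independent oracles used across the suite.

# Brute-force TFCE: per threshold, label suprathreshold components with
# igraph and accumulate extent^E * h^H * dh (independent of the package's
# compiled kernel).
tfce_oracle_signed <- function(map, adj, E = 0.5, H = 2, dh = 0.1) {
  one_sided <- function(v) {
    out <- numeric(length(v))
    vmax <- max(v)
    if (vmax <= 0) return(out)
    for (h in dh * seq_len(floor(vmax / dh + 1e-9))) {
      sup <- which(v >= h)
      if (length(sup) == 0) next
      g <- igraph::graph_from_adjacency_matrix(
        adj[sup, sup, drop = FALSE], mode = "undirected")
      cm <- igraph::components(g)
      for (i in seq_along(sup)) {
        out[sup[i]] <- out[sup[i]] + cm$csize[cm$membership[i]]^E * h^H * dh
      }
    }
    out
  }
  one_sided(pmax(map, 0)) - one_sided(pmax(-map, 0))
}

# adjacency matrix of a 1-D or 2-D lattice, built by explicit loops
lattice_adj_matrix <- function(dims) {
  if (length(dims) == 1) {
    n <- dims
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    return(adj)
  }
  nr <- dims[1]; nc <- dims[2]
  n <- nr * nc
  adj <- matrix(FALSE, n, n)
  id <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) adj[id(r, c), id(r + 1, c)] <- adj[id(r + 1, c), id(r, c)] <- TRUE
    if (c < nc) adj[id(r, c), id(r, c + 1)] <- adj[id(r, c + 1), id(r, c)] <- TRUE
  }
  adj
}

# 10x-oversampled cumulative-integration oracle for the 50% fractional-area
# latency of a non-negative bump inside its window (dense linear
# interpolation + trapezoid cumulative sum)
frac_area_oracle <- function(x, times, window, oversample = 10) {
  win <- times >= window[1] & times <= window[2]
  tv <- times[win]; xv <- pmax(x[win], 0)
  td <- seq(tv[1], tv[length(tv)], length.out = oversample * length(tv))
  xd <- approx(tv, xv, xout = td)$y
  seg <- diff(td) * (xd[-length(xd)] + xd[-1]) / 2
  cs <- cumsum(seg)
  half <- cs[length(cs)] / 2
  i <- which(cs >= half)[1]
  td[i + 1]
}

# exhaustive two-sided permutation p for the Welch statistic
perm_welch_oracle <- function(a, b) {
  z <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(z), n1)
  tobs <- abs(welch_t(a, b)$t)
  ts <- apply(idx, 2, function(i) abs(welch_t(z[i], z[-i])$t))
  mean(ts >= tobs - 1e-10)
}

# brute-force two-sided Mann-Whitney p by enumerating group assignments
mw_oracle <- function(a, b) {
  z <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  uobs <- u_of(a, b)
  m <- n1 * length(b) / 2
  idx <- utils::combn(length(z), n1)
  us <- apply(idx, 2, function(i) u_of(z[i], z[-i]))
  mean(abs(us - m) >= abs(uobs - m) - 1e-12)
}

# tiny two-group epoch set for pipeline-level tests
tiny_epochs <- function(paradigm = "MT", n = 2, seed = 42, noise = 2,
                        alpha = 1, sd_scale = 0.1, targets_only = TRUE) {
  simulate_epochs(
    sim_config(n_subjects_per_group = n, noise_amplitude = noise,
               alpha_amplitude = alpha, seed = seed),
    paradigm,
    scale_profile_sds(default_group_profiles(), sd_scale),
    targets_only = targets_only)
}
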