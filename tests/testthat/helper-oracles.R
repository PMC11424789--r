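# Independent oracles used across the test suite. Deliberately naive
# implementations (enumeration, closed forms, direct linear algebra) kept
# separate from the package's own code paths.

# --- stationary covariance of an MVAR(1): solve Sigma = A Sigma A' + Q ---
lyapunov_cov <- function(A, Q) {
  n <- nrow(A)
  matrix(solve(diag(n^2) - A %x% A, as.vector(Q)), n, n)
}

# --- OLS multichannel AR(p) fit oracle -------------------------------------
ols_mvar_fit <- function(x, order) {
  x <- x - rowMeans(x)
  n <- nrow(x); N <- ncol(x)
  Y <- x[, (order + 1):N, drop = FALSE]
  X <- do.call(rbind, lapply(seq_len(order), function(r)
    x[, (order + 1 - r):(N - r), drop = FALSE]))
  B <- Y %*% t(X) %*% solve(X %*% t(X))   # n x (n*order)
  array(B, c(n, n, order))
}

# --- exact Mann-Whitney two-sided p by full label enumeration --------------
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# --- brute-force graph metrics for small graphs ----------------------------
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all simple paths s -> t by DFS (tiny graphs only)
all_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] > 0))
      if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  paths
}

brute_node_metrics <- function(adj) {
  n <- nrow(adj)
  D <- floyd_warshall(adj)
  deg <- rowSums(adj)
  clu <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0); k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, 0)
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0); k <- length(nb)
    if (k < 2) return(0)
    Ds <- floyd_warshall(adj[nb, nb, drop = FALSE])
    mean(1 / Ds[upper.tri(Ds)])
  }, 0)
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- all_simple_paths(adj, s, t)
    lens <- vapply(paths, length, 0L) - 1L
    short <- paths[lens == D[s, t]]
    sigma <- length(short)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(p) v %in% p[-c(1, length(p))],
                            TRUE))
      btw[v] <- btw[v] + through / sigma
    }
  }
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
  Dx <- D
  diag(Dx) <- Inf
  apl <- apply(Dx, 1, function(v) {
    f <- is.finite(v)
    if (!any(f)) NA_real_ else mean(v[f])
  })
  data.frame(degree = as.integer(deg), cost = deg / (n - 1),
             clustering = clu, local_efficiency = leff, betweenness = btw,
             avg_path_length = apl)
}

# adjacency matrix from an edge bitmask over upper-triangle pairs
adj_from_bits <- function(n, bits) {
  adj <- matrix(0L, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- which(bitwAnd(bits, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0)
  adj[pairs[on, , drop = FALSE]] <- 1L
  adj + t(adj)
}

# random stable MVAR model (couplings scaled to the requested radius)
random_stable_mvar <- function(n, p, seed, radius = 0.9) {
  withr::with_seed(seed, {
    A <- array(stats::rnorm(n * n * p, 0, 0.3), c(n, n, p))
    m <- restflow::mvar_model(A, check = FALSE)
    r <- restflow::spectral_radius(m)
    if (r >= radius) m$coeffs <- A * (radius / r)^(1 / 1)
    while (restflow::spectral_radius(m) >= 0.99) m$coeffs <- m$coeffs * 0.9
    restflow::mvar_model(m$coeffs)
  })
}
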