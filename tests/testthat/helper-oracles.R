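# Independent brute-force oracles used to validate the analytic
# implementations; all are literal transcriptions of the defining
# formulas, kept free of any shared code with the package internals.

rand_graph <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

rand_partition <- function(n, kmax = 4) {
  repeat {
    k <- sample(2:kmax, 1)
    memb <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(memb)) >= 2) break  # keep between-module pairs defined
  }
  ## relabel contiguously from 1
  as.integer(factor(memb))
}

# Eq.-style modularity by explicit per-module edge enumeration
naive_modularity <- function(a, memb) {
  deg <- rowSums(a)
  L <- sum(a) / 2
  q <- 0
  for (mod in unique(memb)) {
    l_i <- 0
    idx <- which(memb == mod)
    for (i in idx) for (j in idx) if (j > i) l_i <- l_i + a[i, j]
    d_i <- sum(deg[idx])
    q <- q + l_i / L - (d_i / (2 * L))^2
  }
  q
}

naive_intra_density <- function(a, memb) {
  labs <- sort(unique(memb))
  out <- numeric(length(labs))
  for (k in seq_along(labs)) {
    idx <- which(memb == labs[k])
    ns <- length(idx)
    if (ns < 2) next
    e <- 0
    for (i in idx) for (j in idx) if (j > i) e <- e + a[i, j]
    out[k] <- 2 * e / (ns * (ns - 1))
  }
  stats::setNames(out, labs)
}

naive_inter_density <- function(a, memb) {
  labs <- sort(unique(memb))
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (s in seq_along(labs)) for (t in seq_along(labs)) {
    if (s >= t) next
    e <- 0
    for (i in which(memb == labs[s])) for (j in which(memb == labs[t]))
      e <- e + a[i, j]
    m[s, t] <- m[t, s] <- e / (sum(memb == labs[s]) * sum(memb == labs[t]))
  }
  m
}

naive_wd <- function(a, memb) {
  n <- nrow(a)
  e <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j != i && memb[j] == memb[i]) e[i] <- e[i] + a[i, j]
  wd <- numeric(n)
  for (s in unique(memb)) {
    idx <- which(memb == s)
    mu <- mean(e[idx])
    sigma <- sqrt(sum((e[idx] - mu)^2) / length(idx))
    wd[idx] <- if (sigma > 0) (e[idx] - mu) / sigma else 0
  }
  wd
}

naive_pc <- function(a, memb) {
  n <- nrow(a)
  labs <- sort(unique(memb))
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(a[i, ])
    if (k_i == 0) next
    acc <- 0
    for (s in labs) {
      k_is <- sum(a[i, memb == s])
      acc <- acc + (k_is / k_i)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# literal BH step-up: largest i with p_(i) <= (i/m) q, tests 1..i significant
bh_stepup_oracle <- function(pvalues, q_level) {
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  cut <- 0
  for (i in seq_len(m)) if (ps[i] <= (i / m) * q_level) cut <- i
  sig <- logical(m)
  if (cut > 0) sig[ord[seq_len(cut)]] <- TRUE
  sig
}

# exhaustive maximum-modularity partition by enumerating all set
# partitions (restricted growth strings); feasible up to ~10 nodes
exhaustive_best_q <- function(a) {
  n <- nrow(a)
  deg <- rowSums(a)
  L <- sum(a) / 2
  ut <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  ei <- ut[, 1]; ej <- ut[, 2]
  best_q <- -Inf
  best_m <- NULL
  memb <- integer(n)
  rec <- function(k, maxlab) {
    if (k > n) {
      q <- sum(memb[ei] == memb[ej]) / L - sum(rowsum(deg, memb)^2) / (4 * L^2)
      if (q > best_q) {
        best_q <<- q
        best_m <<- memb
      }
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      memb[k] <<- lab
      rec(k + 1L, max(maxlab, lab))
    }
  }
  rec(1L, 0L)
  list(q = best_q, membership = best_m)
}

# named fixture graphs for detection tests
two_cliques_bridge <- function(k = 5) {
  n <- 2 * k
  a <- matrix(0, n, n)
  a[1:k, 1:k] <- 1
  a[(k + 1):n, (k + 1):n] <- 1
  diag(a) <- 0
  a[k, k + 1] <- a[k + 1, k] <- 1
  a
}

clique_ring <- function(n_cliques = 4, clique_size = 8) {
  n <- n_cliques * clique_size
  a <- matrix(0, n, n)
  for (c in seq_len(n_cliques)) {
    idx <- ((c - 1) * clique_size + 1):(c * clique_size)
    a[idx, idx] <- 1
    nxt <- if (c == n_cliques) 1 else idx[clique_size] + 1
    a[idx[1], nxt] <- a[nxt, idx[1]] <- 1
  }
  diag(a) <- 0
  a
}

# same-group co-membership matrix, for label-free partition comparison
comembership <- function(memb) outer(memb, memb, "==")
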