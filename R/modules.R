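#' Modularity Q of a partition on a binary network
#'
#' Newman modularity of a hard partition:
#' \deqn{Q = \sum_{i=1}^{N_m} \left[ l_i/L - (d_i/2L)^2 \right]}
#' where \eqn{L} is the total edge count, \eqn{l_i} the number of edges
#' inside module \eqn{i}, and \eqn{d_i} the summed degree of its nodes.
#'
#' @param net a `binary_network` or a symmetric 0/1 adjacency matrix with
#'   zero diagonal.
#' @param partition a `module_partition`, or an integer vector assigning
#'   each node to a module; must cover every node.
#' @return the scalar Q, in \eqn{[-1, 1]}.
#' @export
modularity_q <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  deg <- rowSums(a)
  L <- sum(deg) / 2
  if (L < 1) stop("modularity is undefined on an edgeless network")
  q <- 0
  for (mod in unique(memb)) {
    idx <- which(memb == mod)
    l_i <- sum(a[idx, idx]) / 2
    d_i <- sum(deg[idx])
    q <- q + l_i / L - (d_i / (2 * L))^2
  }
  q
}

## internal: accept a module_partition or raw membership vector
as_membership <- function(partition, n_nodes) {
  memb <- if (inherits(partition, "module_partition")) partition$assignment else partition
  memb <- as.integer(memb)
  if (length(memb) != n_nodes || anyNA(memb))
    stop("partition must assign every node to a module")
  memb
}

## internal: relabel a membership vector canonically:
## labels 1..N_m ordered by decreasing module size, ties by smallest node index
canonical_labels <- function(memb) {
  sizes <- table(memb)
  firsts <- vapply(names(sizes), function(l) min(which(memb == as.integer(l))), 0L)
  ord <- order(-as.integer(sizes), firsts)
  new <- integer(length(sizes))
  new[ord] <- seq_along(ord)
  names(new) <- names(sizes)
  unname(new[as.character(memb)])
}

new_module_partition <- function(memb, net) {
  memb <- canonical_labels(memb)
  structure(list(assignment = stats::setNames(memb, colnames(as_adjacency(net))),
                 q = modularity_q(net, memb),
                 n_modules = length(unique(memb))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.4f\n",
              x$n_modules, length(x$assignment), x$q))
  cat("module sizes:", paste(table(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

## internal: connected components of an adjacency matrix (BFS)
graph_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(a[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## internal: Kernighan-Lin style refinement of a bipartition sign vector.
## One pass moves every node exactly once in best-gain order, tracking the
## cumulative Q change and keeping the best intermediate state; passes
## repeat while they still improve Q, and only strictly improving pass
## results are accepted. Intermediate moves may decrease Q, which lets the
## pass escape single-flip local optima.
kl_refine <- function(b_sub, s, L) {
  n <- length(s)
  repeat {
    s_work <- s
    moved <- rep(FALSE, n)
    bs <- as.numeric(b_sub %*% s_work)
    cum <- 0
    best_cum <- 0
    best_state <- s
    for (step in seq_len(n)) {
      gains <- (diag(b_sub) - s_work * bs) / L
      gains[moved] <- -Inf
      i <- which.max(gains)
      cum <- cum + gains[i]
      s_work[i] <- -s_work[i]
      moved[i] <- TRUE
      bs <- bs + 2 * s_work[i] * b_sub[, i]
      if (cum > best_cum + 1e-12) {
        best_cum <- cum
        best_state <- s_work
      }
    }
    if (best_cum > 1e-12) s <- best_state else break
  }
  s
}

## internal: attempt a spectral bipartition of the node subset `idx`
## using the generalized modularity matrix; returns NULL when indivisible.
## Candidate bipartitions are every contiguous cut of the nodes ordered by
## the leading eigenvector (vector partitioning; the plain sign split is
## the cut at zero), each refined by Kernighan-Lin passes; the candidate
## with the largest refined Q gain wins, ties by the earliest cut.
spectral_split <- function(B, idx, L) {
  b_sub <- B[idx, idx, drop = FALSE]
  diag(b_sub) <- diag(b_sub) - rowSums(b_sub)
  es <- eigen(b_sub, symmetric = TRUE)
  lead <- es$values[1]
  if (lead <= 1e-10) return(NULL)
  v <- es$vectors[, 1]
  ## deterministic orientation: first component of magnitude > 1e-12 positive
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  n <- length(idx)
  ## subsets of <= 12 nodes: score every bipartition directly (at most
  ## 2^11 - 1 candidates, one vectorized quadratic form each) and hand the
  ## best few to the caller's beam; spectral machinery is reserved for
  ## subproblems where enumeration stops being free
  if (n <= 12) {
    masks <- seq_len(2^(n - 1) - 1)
    S <- vapply(masks, function(k) {
      s <- rep(1, n)
      s[which(as.logical(intToBits(k)[seq_len(n - 1)]))] <- -1
      s
    }, numeric(n))
    dq_all <- colSums(S * (b_sub %*% S)) / (4 * L)
    ok <- which(dq_all > 1e-12)
    if (!length(ok)) return(NULL)
    ok <- ok[order(-dq_all[ok])]
    return(lapply(ok[seq_len(min(8, length(ok)))], function(j)
      list(left = idx[S[, j] > 0], right = idx[S[, j] < 0])))
  }
  cands <- list()
  dqs <- numeric(0)
  ## sweep cuts along the top eigenvectors with positive eigenvalue (the
  ## leading one always; on mid-size subproblems the next two add escape
  ## routes from first-cut local optima)
  n_vec <- if (n <= 24) max(1, min(3, sum(es$values > 1e-10))) else 1
  for (iv in seq_len(n_vec)) {
    vv <- es$vectors[, iv]
    nz <- which(abs(vv) > 1e-12)
    if (length(nz) && vv[nz[1]] < 0) vv <- -vv
    ord <- order(vv, idx)        # eigenvector order, index tie-break
    for (cut in seq_len(n - 1)) {
      s <- rep(1, n)
      s[ord[seq_len(cut)]] <- -1
      s <- kl_refine(b_sub, s, L)
      if (all(s == s[1])) next
      dq <- as.numeric(t(s) %*% b_sub %*% s) / (4 * L)
      if (dq <= 1e-12) next
      key <- paste(sort(idx[s < 0]), collapse = ",")
      key2 <- paste(sort(idx[s > 0]), collapse = ",")
      if (key2 < key) key <- key2   # orientation-free identity
      if (key %in% names(cands)) next
      cands[[key]] <- list(left = idx[s > 0], right = idx[s < 0])
      dqs[key] <- dq
    }
  }
  if (!length(cands)) return(NULL)
  ## on small subproblems return the best few distinct candidates and let
  ## the caller complete each (beam search over splits); larger subproblems
  ## keep only the top-gain candidate, plus any exact ties with it
  if (n <= 24) {
    ord_dq <- order(-dqs)
    return(unname(cands[ord_dq[seq_len(min(8, length(cands)))]]))
  }
  keep <- dqs >= max(dqs) - 1e-12
  unname(cands[keep])
}

#' Detect modules by Newman spectral optimization
#'
#' Recursive leading-eigenvector bipartitioning of the modularity matrix
#' `B = A - k k' / (2L)` (generalized form on subgraphs), with each split
#' refined by Kernighan-Lin style single-node-move passes whose results are
#' accepted only when they strictly increase Q. Recursion stops when the
#' generalized modularity matrix is `<= 1e-10` or the refined split does not
#' increase Q. Disconnected components are partitioned independently. Final
#' labels are canonical: 1..N_m by decreasing module size, ties broken by
#' smallest node index. The eigenvector sign ambiguity is resolved by
#' forcing its first non-negligible component positive, so the result is
#' deterministic across eigensolvers.
#'
#' @param net a `binary_network` or symmetric 0/1 adjacency matrix with at
#'   least one edge.
#' @return a `module_partition`: list with `assignment` (named integer
#'   vector), `q`, and `n_modules`.
#' @export
detect_modules <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  deg <- rowSums(a)
  L <- sum(deg) / 2
  if (L < 1) stop("cannot detect modules on an edgeless network")
  B <- a - outer(deg, deg) / (2 * L)

  ## modularity contribution of a completed set of modules
  subset_q <- function(mods) {
    sum(vapply(mods, function(m)
      sum(a[m, m]) / (2 * L) - (sum(deg[m]) / (2 * L))^2, 0))
  }
  ## recursively partition a node subset; when several candidate splits tie
  ## on refined gain, each is completed and the best final Q wins
  partition_subset <- function(idx) {
    sps <- if (length(idx) > 1) spectral_split(B, idx, L) else NULL
    if (is.null(sps)) return(list(idx))
    if (length(sps) > 8) sps <- sps[seq_len(8)]   # cap tie branching
    best_mods <- NULL
    best_q <- -Inf
    for (sp in sps) {
      mods <- c(partition_subset(sp$left), partition_subset(sp$right))
      q <- subset_q(mods)
      if (q > best_q + 1e-15) {
        best_q <- q
        best_mods <- mods
      }
    }
    best_mods
  }

  memb <- integer(n)
  next_label <- 0L
  comp <- graph_components(a)
  for (cc in unique(comp)) {
    for (mod in partition_subset(which(comp == cc))) {
      next_label <- next_label + 1L
      memb[mod] <- next_label
    }
  }
  memb <- global_refine(a, memb, deg, L)
  new_module_partition(memb, net)
}

## internal: final Kernighan-Lin refinement over the complete partition.
## Each pass tentatively relocates every node exactly once, in best-gain
## order, to its best alternative module (including a fresh singleton);
## intermediate moves may lower Q, the best intermediate partition is kept,
## and a pass result is accepted only if it strictly increases Q. Catches
## multi-way structure the recursive bipartitioning cannot reach.
global_refine <- function(a, memb, deg, L) {
  n <- length(memb)
  repeat {
    work <- memb
    moved <- rep(FALSE, n)
    cum <- 0
    best_cum <- 0
    best_state <- memb
    for (step in seq_len(n)) {
      labs <- sort(unique(work))
      k <- length(labs)
      ind <- matrix(0, n, k)
      ind[cbind(seq_len(n), match(work, labs))] <- 1
      k_vs <- a %*% ind                      # edges from each node into each module
      d_s <- as.numeric(crossprod(ind, deg)) # summed degree per module
      cur <- match(work, labs)
      k_own <- k_vs[cbind(seq_len(n), cur)]
      ## gain of moving node v from module r to module t:
      ## (k_vt - k_vr)/L - k_v (d_t - d_r + k_v) / (2 L^2)
      gain <- (k_vs - k_own) / L -
        (deg * (rep(d_s, each = n) - d_s[cur] + deg)) / (2 * L^2)
      dim(gain) <- c(n, k)
      ## extra column: move to a brand-new singleton module
      gain <- cbind(gain, -k_own / L - deg * (deg - d_s[cur]) / (2 * L^2))
      gain[cbind(seq_len(n), cur)] <- -Inf
      gain[tabulate(cur, k)[cur] == 1, k + 1] <- -Inf  # singleton to new = no-op
      gain[moved, ] <- -Inf
      pick <- which.max(gain)
      v <- (pick - 1) %% n + 1
      t <- (pick - 1) %/% n + 1
      if (!is.finite(gain[pick])) break
      cum <- cum + gain[pick]
      work[v] <- if (t > k) max(work) + 1L else labs[t]
      moved[v] <- TRUE
      if (cum > best_cum + 1e-12) {
        best_cum <- cum
        best_state <- work
      }
    }
    if (best_cum > 1e-12) memb <- best_state else break
  }
  memb
}

#' Relabel a partition to best match a reference partition
#'
#' Modules of `partition` are relabeled by a maximum-overlap one-to-one
#' assignment to the reference labels (computed on the confusion matrix;
#' exact optimal assignment by exhaustive permutation search when the
#' smaller side has at most 8 modules, greedy largest-overlap otherwise).
#' Surplus modules with no reference counterpart receive fresh labels above
#' the reference maximum, in decreasing size order. The grouping itself
#' (node co-membership) is never changed, only labels.
#'
#' @param partition,reference `module_partition`s (or membership vectors)
#'   over the same node set.
#' @param net the network `partition` was computed on (used to recompute Q
#'   bookkeeping; Q is label-invariant, so it is unchanged).
#' @return a `module_partition` with relabeled assignment.
#' @export
match_to_reference <- function(partition, reference, net) {
  a <- as_adjacency(net)
  p <- as_membership(partition, nrow(a))
  r <- as_membership(reference, nrow(a))
  pn <- names_of(partition); rn <- names_of(reference)
  if (!is.null(pn) && !is.null(rn) && !identical(sort(pn), sort(rn)))
    stop("partition and reference cover different node sets")

  p_labels <- sort(unique(p)); r_labels <- sort(unique(r))
  conf <- matrix(0L, length(p_labels), length(r_labels),
                 dimnames = list(p_labels, r_labels))
  for (i in seq_along(p)) {
    conf[as.character(p[i]), as.character(r[i])] <-
      conf[as.character(p[i]), as.character(r[i])] + 1L
  }
  assign_to <- best_assignment(conf)

  new_memb <- integer(length(p))
  fresh <- max(r_labels)
  ## surplus modules: fresh labels in decreasing size order
  surplus <- p_labels[is.na(assign_to)]
  if (length(surplus)) {
    sz <- vapply(surplus, function(l) sum(p == l), 0L)
    surplus <- surplus[order(-sz)]
  }
  for (l in surplus) {
    fresh <- fresh + 1L
    assign_to[as.character(l)] <- fresh
  }
  for (i in seq_along(p)) new_memb[i] <- assign_to[as.character(p[i])]

  structure(list(assignment = stats::setNames(new_memb, colnames(a)),
                 q = modularity_q(a, new_memb),
                 n_modules = length(unique(new_memb))),
            class = "module_partition")
}

names_of <- function(partition) {
  if (inherits(partition, "module_partition")) names(partition$assignment)
  else names(partition)
}

## internal: one-to-one assignment of rows (partition modules) to columns
## (reference labels) maximizing total overlap. Exact for <= 8 modules on
## the smaller side; greedy otherwise. Returns a named vector mapping row
## label -> reference label (NA = unassigned surplus).
best_assignment <- function(conf) {
  nr <- nrow(conf); nc <- ncol(conf)
  out <- stats::setNames(rep(NA_integer_, nr), rownames(conf))
  if (min(nr, nc) <= 8) {
    if (nr <= nc) {
      perms <- permutations_of(seq_len(nc), nr)
      scores <- vapply(perms, function(pm) sum(conf[cbind(seq_len(nr), pm)]), 0)
      best <- perms[[which.max(scores)]]
      out[] <- as.integer(colnames(conf))[best]
    } else {
      perms <- permutations_of(seq_len(nr), nc)
      scores <- vapply(perms, function(pm) sum(conf[cbind(pm, seq_len(nc))]), 0)
      best <- perms[[which.max(scores)]]
      out[best] <- as.integer(colnames(conf))
    }
  } else {
    ## greedy: repeatedly take the largest remaining overlap cell
    cf <- conf
    repeat {
      if (all(cf < 0)) break
      ij <- which(cf == max(cf), arr.ind = TRUE)[1, ]
      if (cf[ij[1], ij[2]] < 0) break
      out[rownames(conf)[ij[1]]] <- as.integer(colnames(conf)[ij[2]])
      cf[ij[1], ] <- -1L
      cf[, ij[2]] <- -1L
      if (all(!is.na(out)) || all(cf < 0)) break
    }
  }
  out
}

## internal: all ordered selections of `k` elements from `v`
permutations_of <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i], k - 1)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Modularity across a range of sparsity thresholds
#'
#' Thresholds a connectivity matrix at each sparsity in turn, detects
#' modules, and records `(sparsity, q, n_modules)`. The conventional grid
#' is 0.10 to 0.30 in steps of 0.01 (21 points).
#'
#' @param z symmetric Fisher-z connectivity matrix.
#' @param sparsities strictly increasing vector of sparsities in (0, 1].
#' @return data.frame with columns `sparsity`, `q`, `n_modules`.
#' @export
sparsity_sweep <- function(z, sparsities = seq(0.10, 0.30, by = 0.01)) {
  stopifnot(length(sparsities) >= 1, all(sparsities > 0), all(sparsities <= 1),
            all(diff(sparsities) > 0))
  rows <- lapply(sparsities, function(s) {
    p <- tryCatch(detect_modules(threshold_sparsity(z, s)),
                  error = function(e) stop(sprintf("at sparsity %.3f: %s", s, conditionMessage(e)),
                                           call. = FALSE))
    data.frame(sparsity = s, q = p$q, n_modules = p$n_modules)
  })
  do.call(rbind, rows)
}

#' Merge undersized modules into their best-connected neighbor
#'
#' Post-hoc reporting aid: detection itself imposes no minimum module size,
#' but group-level summaries are conventionally reported over a few large
#' modules. Repeatedly takes the smallest module below `min_size` and
#' merges it into the module to which it has the greatest number of edges
#' (ties broken by smaller module label), then relabels canonically.
#'
#' @param net the network the partition lives on.
#' @param partition a `module_partition` or membership vector.
#' @param min_size smallest module size kept as its own module (default 5).
#' @return a `module_partition`.
#' @export
merge_small_modules <- function(net, partition, min_size = 5) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  repeat {
    sizes <- table(memb)
    if (length(sizes) <= 1) break
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    victim <- as.integer(small[which.min(sizes[small])])
    vi <- which(memb == victim)
    others <- setdiff(unique(memb), victim)
    conn <- vapply(others, function(m) sum(a[vi, memb == m, drop = FALSE]), 0)
    target <- others[order(-conn, others)][1]
    memb[vi] <- target
  }
  new_module_partition(memb, net)
}
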