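#' Intramodule connectivity density
#'
#' For each module s with \eqn{N_s} nodes, the realized fraction of possible
#' internal edges:
#' \deqn{D_s = 2 \sum_{i,j \in s} \varepsilon_{i,j} / (N_s (N_s - 1))}
#' Singleton modules have no internal pairs and return 0 by convention.
#'
#' @param net a `binary_network` or 0/1 adjacency matrix.
#' @param partition module assignment covering every node.
#' @return named numeric vector of densities, one per module label.
#' @export
intramodule_density <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  labs <- sort(unique(memb))
  out <- vapply(labs, function(s) {
    idx <- which(memb == s)
    ns <- length(idx)
    if (ns < 2) return(0)
    sum(a[idx, idx]) / (ns * (ns - 1))   # == 2 * edges / (ns (ns-1))
  }, 0)
  stats::setNames(out, labs)
}

#' Intermodule connectivity density
#'
#' For each module pair (s, t), the realized fraction of possible between
#' edges \eqn{D_{s,t} = \sum_{i \in s, j \in t} \varepsilon_{i,j} / (N_s N_t)}.
#' The diagonal of the returned matrix is filled with the intramodule
#' densities for convenient reporting.
#'
#' @inheritParams intramodule_density
#' @return symmetric numeric matrix indexed by module label; off-diagonal
#'   entries are between-module densities, diagonal entries intramodule
#'   densities.
#' @export
intermodule_density <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  labs <- sort(unique(memb))
  if (length(labs) < 2)
    stop("intermodule density requires at least two modules")
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j) next
      si <- which(memb == labs[i]); sj <- which(memb == labs[j])
      m[i, j] <- m[j, i] <- sum(a[si, sj]) / (length(si) * length(sj))
    }
  }
  diag(m) <- intramodule_density(a, memb)
  m
}

#' Within-module degree z-score
#'
#' For node i in module s, \eqn{WD_i = (e_i - \bar e_s) / \sigma_s}, where
#' \eqn{e_i} counts only neighbors inside s and \eqn{\bar e_s, \sigma_s} are
#' the mean and population (divide-by-\eqn{N_s}) standard deviation of those
#' within-degrees over s. Modules in which every node has the same
#' within-degree (\eqn{\sigma_s = 0}) return 0 for all their nodes, so
#' cohort tables never contain structurally missing cells.
#'
#' @inheritParams intramodule_density
#' @return numeric vector of WD values, one per node (named after nodes
#'   when the network carries labels).
#' @export
within_module_degree <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  wd <- numeric(nrow(a))
  for (s in unique(memb)) {
    idx <- which(memb == s)
    e <- rowSums(a[idx, idx, drop = FALSE])
    sigma <- sqrt(mean((e - mean(e))^2))
    wd[idx] <- if (sigma > 0) (e - mean(e)) / sigma else 0
  }
  stats::setNames(wd, colnames(a))
}

#' Participation coefficient
#'
#' For node i with total degree \eqn{k_i} and \eqn{k_{i,s}} edges into each
#' module s, \eqn{PC_i = 1 - \sum_{s=1}^{N_m} (k_{i,s}/k_i)^2}, the sum
#' running over all modules including the node's own. Isolated nodes
#' (\eqn{k_i = 0}) return 0 by convention.
#'
#' @inheritParams intramodule_density
#' @return numeric vector of PC values in \eqn{[0, 1 - 1/N_m]}, one per node.
#' @export
participation_coefficient <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- as_membership(partition, nrow(a))
  labs <- sort(unique(memb))
  k_is <- vapply(labs, function(s) rowSums(a[, memb == s, drop = FALSE]), numeric(nrow(a)))
  k_is <- matrix(k_is, nrow = nrow(a))
  k <- rowSums(k_is)
  pc <- ifelse(k > 0, 1 - rowSums((k_is / pmax(k, 1))^2), 0)
  stats::setNames(pc, colnames(a))
}

#' Long-format nodal/module metric table for one subject's network
#'
#' Convenience wrapper computing all four module/nodal metrics under a
#' fixed reference partition and returning them in long format, ready to be
#' stacked across subjects for group inference.
#'
#' @param net a `binary_network` for one subject.
#' @param partition the fixed reference partition (never per-subject).
#' @param subject_id identifier recorded in the output.
#' @return data.frame with columns `subject_id`, `metric`
#'   (`intra_density`, `inter_density`, `wd`, `pc`), `unit` (module label,
#'   "s:t" module pair, or node id), and `value`.
#' @export
subject_metrics <- function(net, partition, subject_id = "subj") {
  a <- as_adjacency(net)
  ds <- intramodule_density(a, as_membership(partition, nrow(a)))
  dst <- intermodule_density(a, as_membership(partition, nrow(a)))
  wd <- within_module_degree(a, partition)
  pc <- participation_coefficient(a, partition)
  labs <- rownames(dst)
  pairs <- which(upper.tri(dst), arr.ind = TRUE)
  rbind(
    data.frame(subject_id = subject_id, metric = "intra_density",
               unit = names(ds), value = unname(ds)),
    data.frame(subject_id = subject_id, metric = "inter_density",
               unit = paste0(labs[pairs[, 1]], ":", labs[pairs[, 2]]),
               value = dst[upper.tri(dst)]),
    data.frame(subject_id = subject_id, metric = "wd",
               unit = if (is.null(names(wd))) paste0("n", seq_along(wd)) else names(wd),
               value = unname(wd)),
    data.frame(subject_id = subject_id, metric = "pc",
               unit = if (is.null(names(pc))) paste0("n", seq_along(pc)) else names(pc),
               value = unname(pc))
  )
}
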