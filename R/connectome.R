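#' Clean ROI time series: detrend, band-pass filter, nuisance regression
#'
#' Applies, per column, the signal-cleaning chain used on extracted ROI
#' series: (1) removal of a least-squares linear trend (intercept + time),
#' (2) a zero-phase frequency-domain band-pass that retains Fourier
#' components with `band[1] <= f <= band[2]` Hz (inclusive at both edges),
#' (3) least-squares regression of the supplied nuisance columns, returning
#' the residuals. Filtering precedes nuisance regression. Motion expansions,
#' tissue signals and the global signal are all represented simply as
#' nuisance columns supplied by the caller.
#'
#' @param ts numeric matrix, timepoints x regions; all values finite.
#' @param nuisance optional numeric matrix, timepoints x K, of confound
#'   regressors. Rank-deficient sets are reduced to a linearly independent
#'   subset with a warning naming the dropped columns.
#' @param band length-2 numeric, pass band in Hz; must satisfy
#'   `0 <= band[1] < band[2] < 1/(2*tr)` (Nyquist).
#' @param tr repetition time in seconds (sampling interval).
#' @return matrix of cleaned residual series, same dimensions as `ts`.
#' @examples
#' x <- matrix(rnorm(220 * 4), 220, 4)
#' y <- clean_timeseries(x, band = c(0.01, 0.08), tr = 2)
#' @export
clean_timeseries <- function(ts, nuisance = NULL, band = c(0.01, 0.08), tr = 2) {
  ts <- as.matrix(ts)
  stopifnot(is.numeric(ts), nrow(ts) >= 2, all(is.finite(ts)))
  nyquist <- 1 / (2 * tr)
  if (!(length(band) == 2 && band[1] >= 0 && band[1] < band[2]))
    stop("band must satisfy 0 <= low < high")
  if (band[2] >= nyquist)
    stop(sprintf("band upper edge %.4f Hz is at or above Nyquist %.4f Hz", band[2], nyquist))
  n <- nrow(ts)

  ## 1. detrend: residuals of column ~ intercept + time
  X <- cbind(1, seq_len(n))
  ts <- qr.resid(qr(X), ts)

  ## 2. zero-phase ideal band-pass in the frequency domain
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)     # two-sided frequency axis
  keep <- freq >= band[1] & freq <= band[2]
  f <- stats::mvfft(ts)
  f[!keep, ] <- 0
  ts <- Re(stats::mvfft(f, inverse = TRUE)) / n

  ## 3. nuisance regression
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n)
      stop("nuisance must have one row per retained timepoint")
    qn <- qr(cbind(1, nuisance))
    if (qn$rank < ncol(qn$qr)) {
      dropped <- qn$pivot[seq.int(qn$rank + 1L, ncol(qn$qr))] - 1L
      dropped <- dropped[dropped > 0L]
      nm <- colnames(nuisance)
      if (is.null(nm)) nm <- paste0("nuisance", seq_len(ncol(nuisance)))
      warning("rank-deficient nuisance set; dropping dependent column(s): ",
              paste(nm[dropped], collapse = ", "))
    }
    ts <- qr.resid(qn, ts)
  }
  ts
}

#' Fisher-z connectivity matrix from ROI time series
#'
#' Pearson correlation between every pair of columns, clipped to
#' `+/-(1 - 1e-7)` and transformed by Fisher's r-to-z (`atanh`). The
#' diagonal is fixed at 0. Negative correlations are retained in the matrix;
#' they are only excluded later, at sparsity thresholding.
#'
#' @param ts numeric matrix, timepoints x regions, at least 3 timepoints.
#'   Columns with zero variance are rejected with an error naming the node.
#' @return symmetric numeric matrix of z values with zero diagonal; node
#'   labels are carried over from `colnames(ts)` when present.
#' @export
connectivity_from_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  stopifnot(nrow(ts) >= 3, all(is.finite(ts)))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(ts)
    if (is.null(nm)) nm <- paste0("n", seq_len(ncol(ts)))
    stop("zero-variance column(s): ", paste(nm[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts)
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Threshold a connectivity matrix at a fixed sparsity
#'
#' Keeps the `K = round(sparsity * N * (N - 1) / 2)` positive-z pairs with
#' the largest z as edges of a binary undirected network. Only strictly
#' positive z values are candidates (negative correlations are excluded from
#' the ranking, not zeroed in the source matrix). Ties at the cutoff are
#' broken by ascending (row, column) index so that the edge set is a pure
#' function of the matrix. If fewer than `K` positive candidates exist, all
#' of them become edges and the `insufficient` flag is set.
#'
#' @param z symmetric numeric connectivity matrix (Fisher z), zero diagonal.
#' @param sparsity target edge fraction in (0, 1].
#' @return an object of class `binary_network`: a list with elements
#'   `adjacency` (0/1 symmetric matrix, zero diagonal), `sparsity`,
#'   `n_edges`, `insufficient`, and `node_ids`.
#' @export
threshold_sparsity <- function(z, sparsity) {
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(n == ncol(z), n >= 2, is.numeric(sparsity),
            length(sparsity) == 1, sparsity > 0, sparsity <= 1)
  k_target <- round(sparsity * n * (n - 1) / 2)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  zv <- z[upper.tri(z)]
  pos <- zv > 0
  ri <- ut[pos, 1]; ci <- ut[pos, 2]; zp <- zv[pos]
  ord <- order(-zp, ri, ci)
  n_keep <- min(k_target, length(zp))
  adj <- matrix(0, n, n)
  if (n_keep > 0) {
    sel <- ord[seq_len(n_keep)]
    adj[cbind(ri[sel], ci[sel])] <- 1
    adj <- adj + t(adj)
  }
  ids <- colnames(z)
  if (is.null(ids)) ids <- paste0("n", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj,
                 sparsity = sparsity,
                 n_edges = n_keep,
                 insufficient = length(zp) < k_target,
                 node_ids = ids),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (target sparsity %.3f%s)\n",
              length(x$node_ids), x$n_edges, x$sparsity,
              if (x$insufficient) ", insufficient positive candidates" else ""))
  invisible(x)
}

#' Element-wise mean of connectivity matrices
#'
#' Group-averaged connectivity: the element-wise mean of per-subject
#' Fisher-z matrices. Module detection is performed on these averages, not
#' on individual subjects.
#'
#' @param matrices non-empty list of equally sized connectivity matrices
#'   with identical node labels (when labelled).
#' @return the mean connectivity matrix.
#' @export
group_average <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0)
    stop("need a non-empty list of connectivity matrices")
  ref <- as.matrix(matrices[[1]])
  for (m in matrices) {
    m <- as.matrix(m)
    if (!all(dim(m) == dim(ref)))
      stop("matrices differ in dimension")
    if (!is.null(colnames(m)) && !is.null(colnames(ref)) &&
        !identical(colnames(m), colnames(ref)))
      stop("matrices have mismatched node labels")
  }
  Reduce(`+`, lapply(matrices, as.matrix)) / length(matrices)
}

## internal: adjacency extraction shared by metric/module code
as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) return(net$adjacency)
  a <- as.matrix(net)
  stopifnot(nrow(a) == ncol(a), all(a %in% c(0, 1)),
            isTRUE(all.equal(a, t(a))), all(diag(a) == 0))
  a
}
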