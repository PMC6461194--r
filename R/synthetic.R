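#' Configuration for the synthetic SVD-style cohort generator
#'
#' Bundles every tunable of the generator. The defaults emulate the study
#' conditions the pipeline is designed for: four groups
#' (`HC-low`, `HC-high`, `SVD-NCI`, `SVD-MCI`) with the published group
#' sizes, 128-node networks with four equal planted modules, 220 retained
#' volumes at TR = 2 s, heterogeneous planted correlations (within-module
#' pairs drawn uniformly from `within_weight_range`, between-module pairs
#' from `between_weight_range` — overlapping ranges keep a mixed edge set
#' at realistic sparsities), and group effects that reproduce the expected
#' reorganization pattern: executive-control (module 2) internal coupling
#' raised in `HC-high` and lowered in `SVD-MCI`, default-mode (module 1)
#' internal coupling raised in `SVD-MCI`, and module 1-2 coupling raised in
#' `HC-high`.
#'
#' @param n_subjects_per_group named integer vector of subjects per group.
#' @param n_nodes number of network nodes (default 128).
#' @param n_timepoints retained volumes per subject (default 220, i.e. 230
#'   acquired minus 10 discarded).
#' @param tr repetition time in seconds.
#' @param planted_partition integer vector of module labels, contiguous
#'   from 1, one per node; default four equal modules.
#' @param within_weight_range,between_weight_range length-2 numeric bounds
#'   in (-1, 1) for planted within/between-module correlations.
#' @param group_effects named list (by group) of lists with elements
#'   `within` (named numeric: module label -> additive shift of the within
#'   weight mean) and `between` (3-column matrix: module s, module t, shift).
#' @param mediation_params list with `a`, `b`, `c_prime` (standardized path
#'   coefficients of the planted burden -> mediator -> cognition pathway)
#'   and `noise_sd_m`, `noise_sd_y`.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   bit-for-bit.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_group = c("HC-low" = 17, "HC-high" = 19,
                                                  "SVD-NCI" = 25, "SVD-MCI" = 24),
                         n_nodes = 128,
                         n_timepoints = 220,
                         tr = 2,
                         planted_partition = rep(seq_len(4), each = n_nodes / 4),
                         within_weight_range = c(0.15, 0.45),
                         between_weight_range = c(0.05, 0.30),
                         group_effects = default_group_effects(),
                         mediation_params = list(a = -0.5, b = 0.4, c_prime = -0.5,
                                                 noise_sd_m = 0.8, noise_sd_y = 0.8),
                         seed = 1L) {
  stopifnot(length(n_subjects_per_group) >= 1, !is.null(names(n_subjects_per_group)),
            all(n_subjects_per_group >= 1),
            n_nodes >= 2, n_timepoints >= 2, tr > 0,
            length(planted_partition) == n_nodes)
  labs <- sort(unique(as.integer(planted_partition)))
  if (!identical(labs, seq_along(labs)))
    stop("planted module labels must be contiguous from 1")
  for (rg in list(within_weight_range, between_weight_range)) {
    if (!(length(rg) == 2 && rg[1] <= rg[2] && rg[1] > -1 && rg[2] < 1))
      stop("weight ranges must satisfy -1 < low <= high < 1")
  }
  bad <- setdiff(names(group_effects), names(n_subjects_per_group))
  if (length(bad))
    stop("group_effects refer to unknown group(s): ", paste(bad, collapse = ", "))
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 n_nodes = as.integer(n_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 tr = tr,
                 planted_partition = as.integer(planted_partition),
                 within_weight_range = within_weight_range,
                 between_weight_range = between_weight_range,
                 group_effects = group_effects,
                 mediation_params = mediation_params,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted group effects
#'
#' Additive shifts of the planted weight means, per group, encoding the
#' expected reorganization: module 2 (executive-control analogue) gains
#' +0.10 internal coupling in `HC-high` and loses 0.10 in `SVD-MCI`;
#' module 1 (default-mode analogue) gains +0.10 in `SVD-MCI`; the module
#' 1-2 coupling gains +0.06 in `HC-high`. `HC-low` is the unshifted
#' reference; `SVD-NCI` sits at baseline connectivity.
#'
#' @return named list of per-group effect specifications.
#' @export
default_group_effects <- function() {
  list("HC-low"  = list(),
       "HC-high" = list(within = c("2" = 0.10),
                        between = matrix(c(1, 2, 0.06), nrow = 1)),
       "SVD-NCI" = list(),
       "SVD-MCI" = list(within = c("1" = 0.10, "2" = -0.10)))
}

#' Planted correlation-weight matrix for one group
#'
#' Draws a symmetric zero-diagonal matrix of target correlations:
#' within-module pairs i.i.d. uniform on `within_weight_range`,
#' between-module pairs on `between_weight_range`, each plus the group's
#' configured additive shift for that module or module pair, clipped to
#' (-0.99, 0.99). Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param config a `synth_config`.
#' @param group one of the configured group labels.
#' @return `n_nodes` x `n_nodes` symmetric numeric matrix, zero diagonal.
#' @export
planted_weight_matrix <- function(config, group) {
  stopifnot(inherits(config, "synth_config"))
  if (!group %in% names(config$n_subjects_per_group))
    stop("unknown group label: ", group)
  part <- config$planted_partition
  n <- config$n_nodes
  eff <- config$group_effects[[group]]

  w <- matrix(0, n, n)
  iu <- which(upper.tri(w), arr.ind = TRUE)
  mi <- part[iu[, 1]]; mj <- part[iu[, 2]]
  same <- mi == mj
  lo <- ifelse(same, config$within_weight_range[1], config$between_weight_range[1])
  hi <- ifelse(same, config$within_weight_range[2], config$between_weight_range[2])
  vals <- stats::runif(nrow(iu), lo, hi)

  if (!is.null(eff$within)) {
    for (m in names(eff$within)) {
      sel <- same & mi == as.integer(m)
      vals[sel] <- vals[sel] + eff$within[[m]]
    }
  }
  if (!is.null(eff$between)) {
    for (r in seq_len(nrow(eff$between))) {
      s <- eff$between[r, 1]; t <- eff$between[r, 2]; shift <- eff$between[r, 3]
      sel <- (!same) & ((mi == s & mj == t) | (mi == t & mj == s))
      vals[sel] <- vals[sel] + shift
    }
  }
  vals <- pmin(pmax(vals, -0.99), 0.99)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  w
}

#' Sample a multivariate-normal ROI time series with a target correlation
#'
#' The target correlation matrix is the positive-semidefinite repair of
#' `I + weights`: eigenvalues clipped at 1e-6, the matrix reconstructed and
#' rescaled to unit diagonal. `n_timepoints` independent multivariate-normal
#' rows are then drawn with that correlation. Uses the current RNG state.
#'
#' @param weights symmetric matrix of target correlations, zero diagonal,
#'   entries in (-1, 1).
#' @param n_timepoints number of rows to draw.
#' @return `n_timepoints` x `n_nodes` numeric matrix; column names carried
#'   over from `weights`.
#' @export
sample_timeseries <- function(weights, n_timepoints) {
  weights <- as.matrix(weights)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("weights must be symmetric")
  stopifnot(n_timepoints >= 2, all(abs(weights[upper.tri(weights)]) < 1))
  rt <- chol_of_repaired(weights)
  x <- matrix(stats::rnorm(n_timepoints * ncol(weights)), n_timepoints) %*% rt
  colnames(x) <- colnames(weights)
  x
}

## internal: upper Cholesky factor of the PSD-repaired correlation target;
## cached per weight matrix by callers that draw many subjects per group.
chol_of_repaired <- function(weights) {
  s <- weights
  diag(s) <- 1
  es <- eigen(s, symmetric = TRUE)
  ev <- pmax(es$values, 1e-6)
  s2 <- es$vectors %*% (ev * t(es$vectors))
  s2 <- stats::cov2cor(s2)
  ## tiny asymmetry from floating point: symmetrize before chol
  chol((s2 + t(s2)) / 2)
}

#' Cognitive status from education-adjusted MoCA cutoffs
#'
#' Beijing-version MoCA cutoffs stratified by education: with no formal
#' education the cutoff is 13/14 (MCI iff score <= 13); with 1-6 years it is
#' 19/20 (MCI iff <= 19); with 7+ years it is 24/25 (MCI iff <= 24).
#'
#' @param education_years non-negative years of education (vectorized).
#' @param moca MoCA score in \[0, 30\] (vectorized).
#' @return character vector, `"MCI"` or `"NCI"`.
#' @examples
#' assign_cognitive_status(c(0, 5, 10), c(14, 19, 25))
#' @export
assign_cognitive_status <- function(education_years, moca) {
  stopifnot(all(education_years >= 0))
  if (any(moca < 0 | moca > 30))
    stop("moca scores must lie in [0, 30]")
  cutoff <- ifelse(education_years == 0, 13, ifelse(education_years <= 6, 19, 24))
  ifelse(moca <= cutoff, "MCI", "NCI")
}

#' Generate a mediation triplet with known path coefficients
#'
#' Simulates the structural model X -> M -> Y with a direct path:
#' `M = a*X + covariate terms + eps_M`, `Y = c_prime*X + b*M + covariate
#' terms + eps_Y`, X standardized. Covariates, when requested, are i.i.d.
#' standard normal columns entering both equations with the given
#' coefficients. Uses the current RNG state.
#'
#' @param n number of subjects (>= 10).
#' @param a,b,c_prime true standardized path coefficients.
#' @param covariate_effects optional list with named numeric vectors `m`
#'   and `y`: coefficients of shared covariates in each equation.
#' @param noise_sds length-2 numeric `(sd_M, sd_Y)`, both >= 0.
#' @return list with `x`, `m`, `y`, `covariates` (data.frame or NULL), and
#'   `truth` (the coefficients used).
#' @export
generate_mediation_triplet <- function(n, a = 0.5, b = 0.4, c_prime = 0.3,
                                       covariate_effects = NULL,
                                       noise_sds = c(1, 1)) {
  stopifnot(n >= 10, all(noise_sds >= 0))
  x <- as.numeric(scale(stats::rnorm(n)))
  covs <- NULL
  cm <- cy <- 0
  if (!is.null(covariate_effects)) {
    nm <- union(names(covariate_effects$m), names(covariate_effects$y))
    covs <- as.data.frame(matrix(stats::rnorm(n * length(nm)), n,
                                 dimnames = list(NULL, nm)))
    get_term <- function(coefs) {
      if (is.null(coefs)) return(0)
      as.matrix(covs[, names(coefs), drop = FALSE]) %*% coefs
    }
    cm <- get_term(covariate_effects$m)
    cy <- get_term(covariate_effects$y)
  }
  m <- a * x + cm + stats::rnorm(n, sd = noise_sds[1])
  y <- c_prime * x + b * m + cy + stats::rnorm(n, sd = noise_sds[2])
  list(x = x, m = as.numeric(m), y = as.numeric(y), covariates = covs,
       truth = list(a = a, b = b, c_prime = c_prime))
}

## Table-1-style distribution parameters used by generate_cohort;
## means follow the published cohort, dispersions are plausible SDs
## (the printed dispersion entries behave like standard errors).
cohort_demographics <- function() {
  list(
    age       = list("HC-low" = c(55.5, 4.2), "HC-high" = c(68.2, 5.3),
                     "SVD-NCI" = c(64.5, 10.7), "SVD-MCI" = c(65.9, 9.1)),
    male_prob = c("HC-low" = 7 / 17, "HC-high" = 14 / 19,
                  "SVD-NCI" = 12 / 25, "SVD-MCI" = 11 / 24),
    education = list("HC-low" = c(11.5, 4.1), "HC-high" = c(11.8, 3.6),
                     "SVD-NCI" = c(11.2, 4.1), "SVD-MCI" = c(12.7, 3.4)),
    gm_volume = c(540, 50),
    wmh_meanlog = c("HC-low" = log(470), "HC-high" = log(719),
                    "SVD-NCI" = log(2978), "SVD-MCI" = log(4826)),
    wmh_sdlog = 0.9,
    pwmh_frac = c(8, 3),              # Beta shape: PWMH share of total WMH
    lacune_prob = c("HC-low" = 0, "HC-high" = 0,
                    "SVD-NCI" = 0.28, "SVD-MCI" = 0.54),
    moca = list("HC-low" = c(25.5, 2.0), "HC-high" = c(25.7, 2.0),
                "SVD-NCI" = c(26.1, 2.0), "SVD-MCI" = c(21.4, 2.5)),
    domain_means = list(
      "HC-low"  = c(episodic_memory = 0.60, visuospatial = 0.18,
                    processing_speed = 0.36, language = 0.26, executive = 0.31),
      "HC-high" = c(episodic_memory = -0.10, visuospatial = 0.14,
                    processing_speed = 0.09, language = 0.12, executive = 0.36),
      "SVD-NCI" = c(episodic_memory = 0.11, visuospatial = 0.26,
                    processing_speed = 0.18, language = 0.12, executive = -0.12),
      "SVD-MCI" = c(episodic_memory = -0.53, visuospatial = -0.50,
                    processing_speed = -0.51, language = -0.40, executive = -0.38)),
    domain_sd = 0.6
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws, deterministically from `config$seed`: per-group planted weight
#' matrices, per-subject ROI time series sampled from the group target
#' correlation, demographic and lesion covariates loosely matched to the
#' emulated cohort, MoCA scores consistent with each SVD subject's
#' NCI/MCI label under the education-adjusted cutoffs, cognitive domain
#' scores, and a planted mediation pathway: standardized log-PWMH burden
#' (X) drives a mediator variable `mediator_pc` (M, standing for a nodal
#' participation-coefficient readout) which drives the visuospatial score
#' (Y), with the configured (a, b, c') and covariate-free noise.
#'
#' @param config a `synth_config`.
#' @return an object of class `cohort_bundle`: list with `records`
#'   (data.frame manifest), `timeseries` (named list of timepoint x node
#'   matrices), and `truth` (planted partition, per-group weight matrices,
#'   mediation coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  demo <- cohort_demographics()
  groups <- names(config$n_subjects_per_group)

  group_weights <- list()
  chol_cache <- list()
  for (g in groups) {
    group_weights[[g]] <- planted_weight_matrix(config, g)
    chol_cache[[g]] <- chol_of_repaired(group_weights[[g]])
  }

  records <- list()
  timeseries <- list()
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(config$n_subjects_per_group[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      dpar <- function(tab) if (is.list(tab)) tab[[g]] else tab
      age <- min(max(stats::rnorm(1, dpar(demo$age)[1], dpar(demo$age)[2]), 50), 80)
      sex <- if (stats::runif(1) < demo$male_prob[[g]] %||% 0.5) "male" else "female"
      edu <- max(0L, round(stats::rnorm(1, dpar(demo$education)[1], dpar(demo$education)[2])))
      gmv <- stats::rnorm(1, demo$gm_volume[1], demo$gm_volume[2])
      wmh <- stats::rlnorm(1, demo$wmh_meanlog[[g]], demo$wmh_sdlog)
      pfrac <- stats::rbeta(1, demo$pwmh_frac[1], demo$pwmh_frac[2])
      pwmh <- wmh * pfrac
      dwmh <- wmh - pwmh
      lac <- if (stats::runif(1) < (demo$lacune_prob[[g]] %||% 0))
        1L + stats::rpois(1, 1) else 0L
      moca <- draw_consistent_moca(g, edu, dpar(demo$moca))

      x <- matrix(stats::rnorm(config$n_timepoints * config$n_nodes),
                  config$n_timepoints) %*% chol_cache[[g]]
      colnames(x) <- colnames(group_weights[[g]])
      timeseries[[sid]] <- x

      dm <- demo$domain_means[[g]]
      doms <- stats::rnorm(length(dm), dm, demo$domain_sd)
      names(doms) <- names(dm)
      records[[idx]] <- data.frame(
        subject_id = sid, group = g, age = age, sex = sex,
        education_years = edu, gm_volume = gmv,
        wmh = wmh, pwmh = pwmh, dwmh = dwmh, lacunes = lac, moca = moca,
        t(doms))
    }
  }
  records <- do.call(rbind, records)

  ## planted mediation pathway: X = standardized log-PWMH burden
  mp <- config$mediation_params
  x <- as.numeric(scale(log(records$pwmh)))
  m <- mp$a * x + stats::rnorm(nrow(records), sd = mp$noise_sd_m)
  y <- mp$c_prime * x + mp$b * m + stats::rnorm(nrow(records), sd = mp$noise_sd_y)
  records$mediator_pc <- m
  records$visuospatial <- y    # mediated cognitive score overwrites the draw

  structure(list(records = records,
                 timeseries = timeseries,
                 truth = list(partition = config$planted_partition,
                              group_weights = group_weights,
                              mediation = mp[c("a", "b", "c_prime")]),
                 config = config),
            class = "cohort_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: MoCA draw kept consistent with the group's NCI/MCI label
## (SVD-NCI subjects must fall above their education cutoff, SVD-MCI at or
## below it; HC draws are truncated above the cutoff)
draw_consistent_moca <- function(group, education, pars) {
  want_mci <- group == "SVD-MCI"
  force_nci <- group != "SVD-MCI"
  for (try in 1:200) {
    m <- min(30, max(0, round(stats::rnorm(1, pars[1], pars[2]))))
    st <- assign_cognitive_status(education, m)
    if ((want_mci && st == "MCI") || (force_nci && st == "NCI")) return(m)
  }
  cutoff <- ifelse(education == 0, 13, ifelse(education <= 6, 19, 24))
  if (want_mci) cutoff else min(30, cutoff + 1)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d subjects, %d nodes, %d timepoints\n",
              nrow(x$records), x$config$n_nodes, x$config$n_timepoints))
  print(table(x$records$group))
  invisible(x)
}

#' Write a cohort bundle to disk in plain-text formats
#'
#' Writes the manifest (`manifest.csv`, one row per subject with a
#' `timeseries_path` column), per-subject time series
#' (`timeseries/<id>.tsv`, header row of node ids, one row per timepoint),
#' the planted partition (`truth_partition.tsv`: node_id, module_id,
#' 1-based), and the true generator parameters (`truth_params.txt`,
#' key=value lines).
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  rec <- bundle$records
  rec$timeseries_path <- file.path("timeseries", paste0(rec$subject_id, ".tsv"))
  utils::write.csv(rec, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (sid in names(bundle$timeseries))
    write_timeseries_tsv(bundle$timeseries[[sid]],
                         file.path(dir, "timeseries", paste0(sid, ".tsv")))
  write_partition_tsv(bundle$truth$partition, file.path(dir, "truth_partition.tsv"))
  mp <- bundle$truth$mediation
  writeLines(c(paste0("seed=", bundle$config$seed),
               paste0("a=", mp$a), paste0("b=", mp$b),
               paste0("c_prime=", mp$c_prime)),
             file.path(dir, "truth_params.txt"))
  invisible(dir)
}
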