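#' Random rooted binary topology
#'
#' Plumbing for the simulators: a random rooted binary tree with leaf labels
#' `t1..tn`, reproducible under `seed`. Branch lengths are not assigned (ages
#' come from the samplers).
#'
#' @param n number of leaves (>= 2).
#' @param seed optional integer seed.
#' @return a rooted `phylo` with `n - 1` internal nodes and no branch lengths.
#' @export
yule_topology <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 2)
    abort_hgt("need at least 2 leaves", "hgtclock_value_error")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}

#' Specification for sampling node ages under a calibrated prior
#'
#' Declares the fixed topology, the root prior, hard calibration bounds, and
#' sampler settings. Joint satisfiability of the bounds is verified by
#' interval propagation at construction: minimum bounds propagate rootward,
#' maximum bounds tipward, and any node whose feasible interval is empty
#' makes the spec infeasible.
#'
#' @param phy rooted `phylo` topology.
#' @param prior a [root_prior].
#' @param calibrations list of [calibration] objects.
#' @param n number of samples to emit.
#' @param thin emit every `thin`-th sweep (default 5).
#' @param seed integer seed (mandatory, recorded in the output).
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(phy, prior, calibrations = list(), n = 1000L,
                       thin = 5L, seed) {
  stopifnot(inherits(phy, "phylo"), inherits(prior, "root_prior"))
  if (missing(seed) || !is.numeric(seed))
    abort_hgt("a numeric seed is mandatory in a prior spec",
              "hgtclock_value_error")
  if (n < 1L) abort_hgt("n must be >= 1", "hgtclock_value_error")
  spec <- structure(list(phy = phy, prior = prior,
                         calibrations = calibrations,
                         n = as.integer(n), thin = as.integer(thin),
                         seed = as.integer(seed)),
                    class = "prior_spec")
  prior_bounds(spec)   # errors if infeasible
  spec
}

# Resolve calibrations to node ids and propagate bounds; errors on
# infeasibility. Returns per-node min/max vectors and the feasible root range.
prior_bounds <- function(spec) {
  phy <- spec$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- root_node(phy)
  min_b <- rep(0, nn); max_b <- rep(Inf, nn)
  base <- new_chronogram(phy, rep(0, nn), check = FALSE)  # for resolve only
  for (cal in spec$calibrations) {
    v <- resolve_node(base, cal$clade, strict = FALSE)
    if (v <= ntip)
      abort_hgt(sprintf("calibration '%s' resolves to a leaf", cal$label),
                "hgtclock_infeasible")
    if (!is.na(cal$min_age)) min_b[v] <- max(min_b[v], cal$min_age)
    if (!is.na(cal$max_age)) max_b[v] <- min(max_b[v], cal$max_age)
  }
  if (spec$prior$shape == "flat") {
    min_b[root] <- max(min_b[root], spec$prior$younger)
    max_b[root] <- min(max_b[root], spec$prior$older)
  }
  # rootward propagation of minima
  lo <- min_b
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    lo[p] <- max(lo[p], lo[po$edge[i, 2L]])
  }
  # tipward propagation of maxima
  hi <- max_b
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    ch <- pre[i, 2L]
    hi[ch] <- min(hi[ch], hi[pre[i, 1L]])
  }
  internal <- (ntip + 1L):nn
  bad <- internal[lo[internal] >= hi[internal]]
  if (length(bad) > 0L)
    abort_hgt(sprintf(
      "calibration bounds are jointly unsatisfiable at node %d (feasible interval [%.6g, %.6g] Ma is empty)",
      bad[1L], lo[bad[1L]], hi[bad[1L]]), "hgtclock_infeasible")
  list(min_b = min_b, max_b = max_b, lo = lo, hi = hi)
}

root_log_density <- function(prior, x) {
  switch(prior$shape,
         flat = 0,
         gamma = stats::dgamma(x, shape = prior$mean^2 / prior$sd^2,
                               scale = prior$sd^2 / prior$mean, log = TRUE),
         normal = stats::dnorm(x, prior$mean, prior$sd, log = TRUE))
}

#' Sample chronograms under a calibrated prior
#'
#' MCMC whose stationary law is: root age distributed per the root prior
#' (gamma parameterized by mean and SD, normal, or flat between hard bounds);
#' conditional on the root, uncalibrated internal node ages uniform subject
#' to parent-older-than-child ordering; hard calibration bounds enforced
#' exactly. Non-root nodes are updated by exact conditional draws (uniform on
#' the interval between the oldest child and the youngest of parent age and
#' maximum bound). The root is updated by a Gaussian random walk whose
#' acceptance combines the root prior density, the ordering/bound
#' indicators, and an order-polytope volume correction
#' `(age_old / age_new)^m` (m = number of uncalibrated non-root internal
#' nodes) that keeps the root marginal equal to the prior rather than its
#' volume-size-biased version; with internal calibrations the correction is
#' approximate, but bounds remain exact. Every `thin`-th sweep is emitted
#' after discarding the first 10% of sweeps.
#'
#' @param spec a [prior_spec].
#' @return a [chronogram_trace] (marked burn-in-applied), with the emitted
#'   age matrix attached as `attr(, "age_matrix")` (samples x nodes).
#' @export
sample_prior <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  phy <- spec$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- root_node(phy)
  b <- prior_bounds(spec)
  set.seed(spec$seed)

  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]],
                                     phy$edge[i, 2L])
  internal <- (ntip + 1L):nn
  nonroot <- setdiff(internal, root)
  m_free <- sum(b$min_b[nonroot] == 0 & !is.finite(b$max_b[nonroot]))

  prior <- spec$prior
  root_hi <- if (is.finite(b$hi[root])) b$hi[root] else
    prior$mean + 6 * prior$sd
  root_lo <- b$lo[root]
  step <- if (prior$shape == "flat") (prior$older - prior$younger) / 6 else
    prior$sd

  # initialize: root mid-range, then tipward uniform draws in feasible gaps
  ages <- numeric(nn)
  ages[root] <- root_lo + 0.5 * (root_hi - root_lo)
  depth_order <- nonroot[order(ape::node.depth.edgelength(
    compute_unit_lengths(phy))[nonroot])]
  for (v in depth_order) {
    cap <- min(b$max_b[v], ages[parent[v]])
    ages[v] <- stats::runif(1, b$lo[v], cap)
  }

  n_emit <- spec$n
  total <- ceiling(n_emit * spec$thin / 0.9)
  burn <- total - n_emit * spec$thin
  emit_at <- burn + spec$thin * seq_len(n_emit)
  out <- matrix(0, nrow = n_emit, ncol = nn)
  ei <- 1L
  for (sweep in seq_len(total)) {
    for (v in internal[sample.int(length(internal))]) {
      kid_max <- max(ages[children[[v]]])
      if (v == root) {
        prop <- ages[root] + stats::rnorm(1, 0, step)
        ok <- prop > max(kid_max, b$min_b[root]) && prop < b$max_b[root] &&
          (prior$shape != "flat" ||
             (prop >= prior$younger && prop <= prior$older))
        if (ok) {
          la <- root_log_density(prior, prop) -
            root_log_density(prior, ages[root]) +
            m_free * (log(ages[root]) - log(prop))
          if (log(stats::runif(1)) < la) ages[root] <- prop
        }
      } else {
        lo <- max(kid_max, b$min_b[v])
        hi <- min(ages[parent[v]], b$max_b[v])
        ages[v] <- stats::runif(1, lo, hi)
      }
    }
    if (ei <= n_emit && sweep == emit_at[ei]) {
      out[ei, ] <- ages
      ei <- ei + 1L
    }
  }
  samples <- lapply(seq_len(n_emit), function(i)
    new_chronogram(phy, out[i, ], check = FALSE))
  tr <- chronogram_trace(samples,
                         source = sprintf("sample_prior(seed = %d)", spec$seed),
                         burnin_applied = TRUE, burnin_fraction = 0.1)
  attr(tr, "age_matrix") <- out
  tr
}

# unit branch lengths so node.depth.edgelength orders nodes by topology depth
compute_unit_lengths <- function(phy) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

#' Simulate a pseudo-posterior trace by jittering a true chronogram
#'
#' A stand-in for dating-software output used throughout the test suite: each
#' sample redraws node ages root-down from normals centered on the true ages,
#' truncated to `(0, parent age)` so parent-older-than-child ordering and
#' non-negativity hold by construction. The per-sample, per-node age ledger
#' is returned so downstream results can be checked against generator
#' bookkeeping.
#'
#' @param truth a [chronogram] holding the true node ages.
#' @param sd jitter standard deviation in Ma (>= 0; 0 reproduces the truth).
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return list with `trace` (a [chronogram_trace]), `age_matrix`
#'   (n x nodes), and `truth` (the input ages).
#' @export
simulate_posterior_trace <- function(truth, sd = 10, n = 100L, seed = NULL) {
  stopifnot(inherits(truth, "chronogram"))
  if (sd < 0) abort_hgt("jitter SD must be >= 0", "hgtclock_value_error")
  if (n < 1) abort_hgt("sample count must be >= 1", "hgtclock_value_error")
  if (!is.null(seed)) set.seed(seed)
  phy <- truth$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- root_node(phy)
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  internal <- (ntip + 1L):nn
  ord <- internal[order(ape::node.depth.edgelength(
    compute_unit_lengths(phy))[internal])]

  ages <- matrix(0, nrow = n, ncol = nn)
  for (v in ord) {
    mu <- truth$ages[v]
    if (sd == 0) {
      ages[, v] <- mu
      next
    }
    hi <- if (v == root) rep(Inf, n) else ages[, parent[v]]
    plo <- stats::pnorm(0, mu, sd)
    phi <- stats::pnorm(hi, mu, sd)
    u <- stats::runif(n, plo, phi)
    ages[, v] <- stats::qnorm(u, mu, sd)
  }
  samples <- lapply(seq_len(n), function(i)
    new_chronogram(phy, ages[i, ], check = FALSE))
  trace <- chronogram_trace(samples,
                            source = sprintf("simulate_posterior_trace(sd = %g, seed = %s)",
                                             sd, seed %||% "NULL"),
                            burnin_applied = TRUE, burnin_fraction = 0)
  list(trace = trace, age_matrix = ages, truth = truth$ages)
}

#' Jointly Gaussian paired age samples
#'
#' Analytic test harness for [prob_older()]: two age traces with the
#' requested normal marginals and correlation.
#'
#' @param mean_a,sd_a,mean_b,sd_b marginal parameters (Ma).
#' @param correlation in `[-1, 1]`.
#' @param n number of pairs.
#' @param seed integer seed.
#' @return list with `age_trace` elements `a` and `b`.
#' @export
paired_age_generator <- function(mean_a, sd_a, mean_b, sd_b,
                                 correlation = 0, n, seed = NULL) {
  if (!is.numeric(correlation) || abs(correlation) > 1)
    abort_hgt("correlation must lie in [-1, 1]", "hgtclock_value_error")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  a <- mean_a + sd_a * z1
  b <- mean_b + sd_b * (correlation * z1 + sqrt(1 - correlation^2) * z2)
  list(a = age_trace("A", pmax(a, 0)), b = age_trace("B", pmax(b, 0)))
}
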