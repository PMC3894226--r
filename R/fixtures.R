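#' Canonical fixture networks
#'
#' Six parameter families mirroring the scenarios the theory addresses. All
#' numeric values are package defaults chosen to put the networks in the
#' inhibition-dominated balanced regime at a plausible working activity; they
#' are documented conventions, not literature values.
#'
#' \describe{
#'   \item{three_population}{homogeneous connectivity (weights depend only on
#'     the source type), N_E = N_I = 2000, fixed in-degree K = 100 from each
#'     population, J_E = J_X = 0.1, J_I = -0.6, external population of
#'     N_X = 400 sources at rate m_X = 0.1; thresholds place the working
#'     point at m = 0.2. The N_X sweep (including N_X = K_X and dc mode)
#'     runs on this family.}
#'   \item{homogeneous_small}{the same structure at 400 neurons per
#'     population with the in-degrees and weights kept (K = 100), so the
#'     working point and feedback strength match the full-size family;
#'     for quick checks.}
#'   \item{inhomogeneous}{target-dependent weights (invertible structural
#'     coupling matrix), same sizes as three_population.}
#'   \item{heterogeneous}{the inhomogeneous family with binomially
#'     distributed in-degrees (p = 0.05).}
#'   \item{purely_inhibitory}{a single inhibitory population of 1000 neurons
#'     (K = 100, J = -1) with no external variance source; neurons are
#'     intrinsically active through a negative threshold. The E population is
#'     a disconnected singleton so the general solver reduces to the scalar
#'     closed form.}
#'   \item{structural_base}{homogeneous 1000+1000 network with dc external
#'     drive used as the base of the structural (eigenvalue) sweeps.}
#' }
#'
#' @param name fixture name.
#' @param N_X optional external-population size override (three_population
#'   family).
#' @param external_mode optional external-mode override.
#' @return a \code{network_spec}.
#' @export
fixture_spec <- function(name = c("three_population", "homogeneous_small",
                                  "inhomogeneous", "heterogeneous",
                                  "purely_inhibitory", "structural_base"),
                         N_X = NULL, external_mode = NULL) {
  name <- match.arg(name)
  mk <- function(N, K, J, m_target, m_X = 0.1, mode = "stochastic",
                 rule = "fixed") {
    sp <- network_spec(N = N, K = K, J = J, theta = c(E = 0, I = 0),
                       m_X = m_X, external_mode = mode, indegree_rule = rule)
    rebalance_threshold(sp, m_target)
  }
  row2 <- function(e, i, x) matrix(rep(c(e, i, x), each = 2), 2, 3)
  spec <- switch(name,
    three_population = mk(
      N = c(E = 2000, I = 2000, X = 400),
      K = row2(100, 100, 100), J = row2(0.1, -0.6, 0.1), m_target = 0.2),
    homogeneous_small = mk(
      N = c(E = 400, I = 400, X = 400),
      K = row2(100, 100, 100), J = row2(0.1, -0.6, 0.1), m_target = 0.2),
    inhomogeneous = mk(
      N = c(E = 2000, I = 2000, X = 2000),
      K = row2(100, 100, 100),
      J = matrix(c(0.1, 0.2, -0.6, -0.8, 0.15, 0.1), 2, 3),
      m_target = 0.2),
    heterogeneous = mk(
      N = c(E = 2000, I = 2000, X = 2000),
      K = row2(100, 100, 100),
      J = matrix(c(0.1, 0.2, -0.6, -0.8, 0.15, 0.1), 2, 3),
      m_target = 0.2, rule = "binomial"),
    purely_inhibitory = {
      sp <- network_spec(
        N = c(E = 1, I = 1000, X = 100),
        K = matrix(c(0, 0, 0, 0, 100, 0), 2, 3, byrow = TRUE),
        J = matrix(c(0, 0, 0, 0, -1, 0), 2, 3, byrow = TRUE),
        theta = c(E = 1, I = 0), m_X = 0.1, external_mode = "dc")
      m <- c(E = 0, I = 0.2)
      mu <- mean_input(sp, m)
      sig <- sqrt(pmax(input_variance(sp, m), 0))
      sp$theta["I"] <- mu["I"] - sig["I"] * stats::qnorm(0.2)
      sp
    },
    structural_base = mk(
      N = c(E = 1000, I = 1000, X = 1000),
      K = row2(100, 100, 100), J = row2(0.2, -0.8, 0.2),
      m_target = 0.5, mode = "dc"))
  if (!is.null(N_X)) {
    spec$N["X"] <- N_X
    validate_spec(spec)
  }
  if (!is.null(external_mode)) spec$external_mode <- external_mode
  spec
}

#' Names of all canonical fixture families
#' @return character vector.
#' @export
fixture_names <- function() {
  c("three_population", "homogeneous_small", "inhomogeneous",
    "heterogeneous", "purely_inhibitory", "structural_base")
}

#' Write the canonical fixture configurations to disk
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(fixture_names(), function(nm) {
    p <- file.path(dir, paste0(nm, ".json"))
    save_config(fixture_spec(nm), p)
    p
  }, character(1))
  invisible(paths)
}

#' Serialize a network specification (and optional simulator settings)
#'
#' @param spec a \code{network_spec}.
#' @param path output JSON path.
#' @param sim optional \code{simulator_config}.
#' @return invisibly, the path.
#' @export
save_config <- function(spec, path, sim = NULL) {
  obj <- list(
    network = list(
      N = as.list(spec$N), K = apply(spec$K, 1, as.list, simplify = FALSE),
      J = apply(spec$J, 1, as.list, simplify = FALSE),
      theta = as.list(spec$theta), tau = spec$tau, m_X = spec$m_X,
      external_mode = spec$external_mode, indegree_rule = spec$indegree_rule,
      p = apply(spec$p, 1, as.list, simplify = FALSE)))
  if (!is.null(sim)) obj$simulator <- sim[!vapply(sim, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a network specification from a configuration file
#'
#' Parses and validates a JSON configuration written by
#' \code{\link{save_config}}. Validation failures carry an itemized message
#' naming the offending keys.
#'
#' @param path JSON path.
#' @return list with the \code{spec} and, if present, the \code{sim}
#'   configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nw <- obj$network
  if (is.null(nw)) stop("config has no 'network' entry")
  as_mat <- function(x) {
    m <- rbind(E = unlist(x$E), I = unlist(x$I))
    m[, c("E", "I", "X"), drop = FALSE]
  }
  spec <- network_spec(
    N = unlist(nw$N), K = as_mat(nw$K), J = as_mat(nw$J),
    theta = unlist(nw$theta), tau = nw$tau, m_X = nw$m_X,
    external_mode = nw$external_mode, indegree_rule = nw$indegree_rule,
    p = if (!is.null(nw$p)) as_mat(nw$p) else NULL)
  sim <- NULL
  if (!is.null(obj$simulator)) {
    sm <- obj$simulator
    sim <- simulator_config(
      duration = sm$duration, resolution = sm$resolution,
      delay = if (is.null(sm$delay)) 1L else sm$delay,
      measurement_interval = sm$measurement_interval,
      seed = if (is.null(sm$seed)) 1L else sm$seed,
      transient = sm$transient)
  }
  list(spec = spec, sim = sim)
}

#' Reproducibility manifest for a run
#'
#' Records the three independent seed streams (connectivity, dynamics, pair
#' sampling), a content hash of the specification, and package/version
#' metadata; a stochastic result is reproducible from the manifest alone.
#'
#' @param spec a \code{network_spec}.
#' @param network_seed,simulation_seed,pair_seed the three seed streams.
#' @param outputs optional named output paths.
#' @return list of class \code{run_manifest}.
#' @export
run_manifest <- function(spec, network_seed, simulation_seed, pair_seed,
                         outputs = list()) {
  structure(list(
    config_hash = spec_hash(spec),
    seeds = list(network = network_seed, simulation = simulation_seed,
                 pairs = pair_seed),
    package_version = as.character(utils::packageVersion("binnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = outputs), class = "run_manifest")
}

# polynomial rolling checksum over the serialized spec (exact in doubles)
spec_hash <- function(spec) {
  bytes <- as.integer(serialize(spec, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Theory-versus-simulation comparison table
#'
#' Runs \code{n_seeds} independent simulations of a specification (fresh
#' connectivity, dynamics and pair-sampling seeds per run), pools the
#' per-pair covariance estimates, and tabulates them against the analytical
#' prediction: one row per statistic with the theory value, simulation mean,
#' pooled standard error, and z-score.
#'
#' @param spec a \code{network_spec}.
#' @param config a \code{simulator_config} (its seed field seeds the whole
#'   registry).
#' @param n_seeds number of independent runs.
#' @param n_pairs pairs per label per run.
#' @param iterate use the iterative finite-size-corrected theory.
#' @return data.frame with attributes \code{manifest} (list of per-run
#'   manifests) and \code{activity} (pooled mean activities).
#' @export
compare_theory_simulation <- function(spec, config, n_seeds = 5,
                                      n_pairs = 1000, iterate = TRUE) {
  th <- if (iterate) iterate_self_consistent(spec)
        else { mf <- solve_mean_field(spec); list(mf = mf, cs = solve_correlations(spec, mf)) }
  cth <- covariance_vector(th$cs)
  per_label <- list(); acts <- NULL; manifests <- list()
  for (s in seq_len(n_seeds)) {
    seeds <- config$seed * 100 + s * 3 + c(net = 0, dyn = 1, pair = 2)
    real <- build_realization(spec, seeds["net"])
    pairs <- sample_pairs(spec, n_pairs, seeds["pair"])
    cfg <- config; cfg$seed <- seeds["dyn"]
    rec <- simulate_network(real, cfg, pairs = pairs, init = th$mf$m)
    est <- pairwise_covariances(rec)
    pc <- est$per_pair
    for (lb in unique(pc$label))
      per_label[[lb]] <- c(per_label[[lb]], pc$cov[pc$label == lb])
    acts <- rbind(acts, activity_means(rec)[c("E", "I")])
    manifests[[s]] <- run_manifest(spec, seeds["net"], seeds["dyn"], seeds["pair"])
  }
  labs <- names(per_label)
  out <- data.frame(
    statistic = paste0("c_", labs),
    theory = unname(cth[labs]),
    simulation = vapply(per_label, mean, numeric(1)),
    se = vapply(per_label, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(per_label, length, numeric(1)), row.names = NULL)
  out$z <- (out$simulation - out$theory) / out$se
  # mean activities with across-seed errors
  act <- data.frame(
    statistic = c("m_E", "m_I"),
    theory = unname(th$mf$m[c("E", "I")]),
    simulation = colMeans(acts),
    se = if (n_seeds > 1) apply(acts, 2, stats::sd) / sqrt(n_seeds) + 1e-12
         else rep(NA_real_, 2),
    n = n_seeds, row.names = NULL)
  act$z <- (act$simulation - act$theory) / act$se
  out <- rbind(act, out)
  attr(out, "manifest") <- manifests
  attr(out, "theory") <- th
  out
}
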