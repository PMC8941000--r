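# Synthetic-data twin of the in vitro workflow: a 12-strain batch-dilution
# community with known growth parameters, resource-depletion sets, pairwise
# interaction coefficients and observation noise, so every analysis stage
# has a parameter-recovery test.

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Fixed-step RK4 for dN/dt = f(N). Steps with dt, shortening the final step
# of each recording interval so the requested times are hit exactly.
.rk4 <- function(f, n0, record_times, dt = 0.01, guard = Inf) {
  n <- n0
  out <- matrix(NA_real_, length(record_times), length(n0))
  t_now <- record_times[1]
  out[1, ] <- n
  for (k in seq_along(record_times)[-1]) {
    target <- record_times[k]
    while (t_now < target - 1e-12) {
      h <- min(dt, target - t_now)
      k1 <- f(n)
      k2 <- f(n + h / 2 * k1)
      k3 <- f(n + h / 2 * k2)
      k4 <- f(n + h * k3)
      n <- pmax(n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
      t_now <- t_now + h
      if (any(n > guard))
        stop("trajectory divergence: abundance exceeded the stability guard; ",
             "unstable design")
    }
    out[k, ] <- n
  }
  out
}

#' Integrate generalized Lotka-Volterra dynamics
#'
#' `dN_i/dt = N_i (mu_i + sum_j A[i,j] N_j)`, fixed-step RK4 (default step
#' 0.01 h). States are clipped at zero; abundances exceeding 1e6 times the
#' largest self-limited capacity abort as an unstable design.
#'
#' @param n0 Initial abundances (OD units).
#' @param mu Intrinsic growth rates (1/h).
#' @param A Interaction matrix (per-capita effect of column j on row i);
#'   diagonal must be negative (self-limitation).
#' @param record_times Increasing times (h) at which to record the state;
#'   must start at 0.
#' @param dt Step size in hours.
#' @return Matrix `length(record_times)` x `length(n0)` of abundances.
#' @export
glv_integrate <- function(n0, mu, A, record_times, dt = 0.01) {
  A <- as.matrix(A)
  stopifnot(length(mu) == length(n0), nrow(A) == length(n0),
            all(diag(A) < 0), record_times[1] == 0)
  caps <- -mu / diag(A)
  guard <- 1e6 * max(caps)
  f <- function(n) n * (mu + drop(A %*% n))
  .rk4(f, n0, record_times, dt = dt, guard = guard)
}

#' Integrate gLV dynamics under serial batch dilution
#'
#' Runs [glv_integrate()] in cycles of `period_h` hours; between cycles all
#' abundances are multiplied by the dilution factor (instantaneous transfer
#' into fresh medium).
#'
#' @inheritParams glv_integrate
#' @param cycles Number of growth cycles.
#' @param period_h Cycle length in hours.
#' @param dilution_factor Transfer fraction in (0, 1).
#' @return Matrix `(cycles + 1)` x `length(n0)`: the inoculum (row 1) and
#'   the end-of-cycle states before each dilution.
#' @export
glv_passage <- function(n0, mu, A, cycles, period_h = 24,
                        dilution_factor = 0.01, dt = 0.01) {
  stopifnot(dilution_factor > 0, dilution_factor < 1, cycles >= 1)
  out <- matrix(NA_real_, cycles + 1L, length(n0))
  out[1, ] <- n0
  n <- n0
  for (cy in seq_len(cycles)) {
    traj <- glv_integrate(n, mu, A, record_times = c(0, period_h), dt = dt)
    n <- traj[2, ]
    out[cy + 1L, ] <- n
    n <- n * dilution_factor
  }
  out
}

#' Construct a synthetic community design
#'
#' Bundles ground-truth parameters for the in silico twin: per-strain
#' growth parameters, the dimensionless interaction couplings, bacteriocin
#' kill rates, the strain x feature resource-usage/depletion profile, noise
#' levels and the batch-dilution schedule. Couplings `c[i, j]` are the
#' per-capita effect of strain j (at its capacity) on strain i's effective
#' growth, so the gLV matrix is `A[i, j] = c[i, j] * mu_i / K_j` off the
#' diagonal and `A[i, i] = -mu_i / K_i`.
#'
#' @param strains data.frame with columns `strain_id`, `mu` (1/h), `K`
#'   (OD), `od0` (inoculum OD), `acid_coef` (pH drop per OD of biomass),
#'   `copies_per_od` (16S copies per OD unit), `phylum`.
#' @param coupling S x S dimensionless coupling matrix (diagonal ignored).
#' @param kill S x S dimensionless bacteriocin kill couplings (effect of
#'   column j on row i; non-negative), converted like `coupling` but always
#'   subtracted.
#' @param resource_usage S x F binary usage matrix.
#' @param depletion_depth S x F depletion depths in \[0, 1\].
#' @param production S x F binary production matrix.
#' @param tree_newick Newick string for the strains' phylogeny.
#' @param noise List with `od_sd`, `intensity_cv`, `cq_sd`, `abundance_cv`.
#' @param dilution List with `factor` in (0,1) and `period_h`.
#' @param production_fold Fold-increase of produced features.
#' @param baseline_log_mean,baseline_log_sd Log-normal feature baseline
#'   parameters.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(strains, coupling, kill = NULL,
                             resource_usage = NULL, depletion_depth = NULL,
                             production = NULL, tree_newick = NULL,
                             noise = list(od_sd = 0.005, intensity_cv = 0.10,
                                          cq_sd = 0.1, abundance_cv = 0.2),
                             dilution = list(factor = 0.01, period_h = 24),
                             production_fold = 5,
                             baseline_log_mean = log(1000),
                             baseline_log_sd = 0.5) {
  S <- nrow(strains)
  stopifnot(all(c("strain_id", "mu", "K", "od0") %in% names(strains)),
            all(strains$mu > 0), all(strains$K > 0), all(strains$od0 > 0))
  coupling <- as.matrix(coupling)
  stopifnot(dim(coupling) == c(S, S))
  if (is.null(kill)) kill <- matrix(0, S, S)
  kill <- as.matrix(kill)
  stopifnot(dim(kill) == c(S, S), all(kill >= 0))
  stopifnot(dilution$factor > 0, dilution$factor < 1,
            all(unlist(noise) >= 0))
  if (!is.null(resource_usage)) {
    stopifnot(nrow(resource_usage) == S,
              all(resource_usage %in% c(0, 1)))
    if (is.null(depletion_depth))
      depletion_depth <- resource_usage * 0.85
    stopifnot(dim(depletion_depth) == dim(resource_usage),
              all(depletion_depth >= 0), all(depletion_depth <= 1))
  }
  ids <- as.character(strains$strain_id)
  mu <- strains$mu; K <- strains$K
  A <- (coupling - kill) * (mu / rep(K, each = S))
  diag(A) <- -mu / K
  dimnames(A) <- dimnames(coupling) <- dimnames(kill) <- list(ids, ids)
  structure(list(strains = strains, coupling = coupling, kill = kill, A = A,
                 resource_usage = resource_usage,
                 depletion_depth = depletion_depth,
                 production = production, tree_newick = tree_newick,
                 noise = noise, dilution = dilution,
                 production_fold = production_fold,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("<synthetic_design> %d strains, %s features, dilution 1:%d / %g h\n",
              nrow(x$strains),
              if (is.null(x$resource_usage)) "no" else ncol(x$resource_usage),
              round(1 / x$dilution$factor), x$dilution$period_h))
  invisible(x)
}

#' Ground-truth interaction signs of a design
#'
#' @param design A [synthetic_design()].
#' @return S x S character matrix: sign of the designed effect of the
#'   column strain on the row strain (`"+"`, `"0"`, `"-"`); diagonal `"0"`.
#' @export
truth_signs <- function(design) {
  cp <- design$coupling
  k <- design$kill
  s <- matrix("0", nrow(cp), ncol(cp), dimnames = dimnames(cp))
  s[cp > 0 & k == 0] <- "+"
  s[cp < 0 | k > 0] <- "-"
  diag(s) <- "0"
  s
}

#' The default 12-strain community design
#'
#' A desk-scale in silico stand-in for a 12-member gut community: growth
#' rates spanning 0.5-2.0 /h (4 fast, 5 intermediate, 3 slow strains), one
#' bacteriocin producer, a pairwise interaction census of 46 amensal, 7
#' competitive, 11 neutral, 1 commensal and 1 predatory pair (no
#' mutualism), and niche-structured resource-depletion sets along a
#' phylogeny so that related strains share substrates.
#'
#' @param n_features Size of the metabolomic feature universe (>= 392).
#' @return A [synthetic_design()].
#' @export
default_design <- function(n_features = 400) {
  stopifnot(n_features >= 392)
  ids <- sprintf("s%02d", 1:12)
  strains <- data.frame(
    strain_id = ids,
    mu = c(1.8, 1.7, 1.6, 1.55, 1.3, 1.2, 1.1, 1.05, 1.02, 0.9, 0.7, 0.5),
    K = c(1.2, 0.8, 1.0, 0.9, 0.7, 1.1, 0.6, 0.8, 0.9, 1.0, 0.5, 0.4),
    od0 = 0.01,
    acid_coef = c(0.9, 0.7, 0.2, 0.6, 0.1, 0.8, -0.1, 0.1, 0.2, 0.7, -0.2, 0.0),
    copies_per_od = c(2.1e9, 1.4e9, 1.8e9, 1.6e9, 1.2e9, 2.4e9,
                      0.9e9, 1.5e9, 1.7e9, 2.0e9, 0.8e9, 0.6e9),
    phylum = c("PhylumA", "PhylumB", "PhylumA", "PhylumA", "PhylumA",
               "PhylumC", "PhylumA", "PhylumA", "PhylumA", "PhylumC",
               "PhylumD", "PhylumE"),
    stringsAsFactors = FALSE)
  S <- 12L
  cp <- matrix(0, S, S)
  kill <- matrix(0, S, S)
  # predation: s01 benefits from s05 (cross-feeding), s05 is killed back by
  # s01's bacteriocin; calibrated to endpoint ratios ~4 and ~0.25
  cp[1, 5] <- 12
  kill[5, 1] <- 0.1875
  # commensalism: s02 benefits from s06
  cp[2, 6] <- 3
  # competition: mutual moderate couplings (stable coexistence requires < 1)
  comp <- list(c(3, 4), c(3, 7), c(3, 8), c(4, 7), c(4, 8), c(7, 8), c(9, 10))
  for (p in comp) {
    cp[p[1], p[2]] <- -0.9
    cp[p[2], p[1]] <- -0.9
  }
  # neutral pairs (slow strains largely decoupled)
  neutral <- list(c(11, 12), c(10, 12), c(10, 11), c(9, 12), c(9, 11),
                  c(8, 12), c(8, 11), c(7, 12), c(7, 11), c(6, 12), c(6, 11))
  # s01's remaining harm is bacteriocin-mediated (it is the producer);
  # all other unassigned pairs: the faster strain suppresses the slower
  assigned <- c(list(c(1, 5), c(2, 6)), comp, neutral)
  akey <- vapply(assigned, function(p) paste(sort(p), collapse = "-"), "")
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    if (paste(i, j, sep = "-") %in% akey) next
    if (i == 1) kill[j, 1] <- 0.75 else cp[j, i] <- -0.75
  }
  # niche-structured resource profile along the phylogeny
  tree_newick <- paste0(
    "(((s01:0.05,s05:0.05):0.10,((s03:0.04,s04:0.04):0.06,",
    "(s07:0.05,(s08:0.03,s09:0.03):0.02):0.05):0.05):0.15,",
    "((s06:0.10,s10:0.10):0.20,(s02:0.25,(s11:0.22,s12:0.22):0.03):0.05):0.10);")
  dmat <- patristic_distances(parse_newick(tree_newick))
  pos <- stats::cmdscale(dmat$d[ids, ids], k = 1)[, 1]
  centers <- (pos - min(pos)) / (max(pos) - min(pos))  # niche centre in [0,1]
  widths <- c(0.30, 0.10, 0.22, 0.20, 0.12, 0.25, 0.10,
              0.15, 0.18, 0.24, 0.06, 0.04)
  n_niche <- 320L
  xf <- seq(0, 1, length.out = n_niche)
  usage <- matrix(0L, S, n_features)
  for (i in seq_len(S))
    usage[i, seq_len(n_niche)] <- as.integer(abs(xf - centers[i]) <= widths[i])
  production <- matrix(0L, S, n_features)
  for (i in seq_len(S))
    production[i, n_niche + (i - 1L) * 6L + 1:6] <- 1L
  feature_ids <- c(sprintf("pos_F%04d", seq_len(n_features %/% 2)),
                   sprintf("neg_F%04d", seq_len(n_features - n_features %/% 2)))
  colnames(usage) <- colnames(production) <- feature_ids
  synthetic_design(strains = strains, coupling = cp, kill = kill,
                   resource_usage = usage,
                   depletion_depth = usage * 0.85,
                   production = production,
                   tree_newick = tree_newick)
}

# fraction of a consumer's resources already removed from a producer's
# spent medium (weighted by depletion depth); 0 for a consumer using nothing
.depletion_fraction <- function(design, producer, consumer) {
  u <- design$resource_usage
  if (is.null(u)) return(0)
  ids <- design$strains$strain_id
  p <- match(producer, ids); cns <- match(consumer, ids)
  uc <- u[cns, ]
  if (sum(uc) == 0) return(0)
  sum(uc * design$depletion_depth[p, ]) / sum(uc)
}

#' Simulate one monoculture growth curve
#'
#' Logistic growth `dN/dt = mu N (1 - N/K_eff)` integrated with fixed-step
#' RK4, sampled every 10 min over 20 h, with Gaussian OD noise. In a spent
#' medium the effective capacity is the fresh capacity reduced by the
#' fraction of the strain's resources already depleted, and the growth rate
#' carries the bacteriocin penalty.
#'
#' @param design A [synthetic_design()].
#' @param strain Strain id.
#' @param medium_state List with `depletion_frac` in \[0, 1\] and
#'   `kill_coupling` (>= 0, dimensionless); defaults describe fresh medium.
#' @param seed Integer seed (NULL for no noise reseeding).
#' @param replicate Replicate index recorded on the curve.
#' @param medium_id Medium label recorded on the curve.
#' @return A [growth_curve()].
#' @export
simulate_monoculture <- function(design, strain,
                                 medium_state = list(depletion_frac = 0,
                                                     kill_coupling = 0),
                                 seed = NULL, replicate = 1L,
                                 medium_id = "fresh") {
  st <- design$strains[design$strains$strain_id == strain, ]
  if (nrow(st) != 1L) stop("unknown strain: ", strain)
  if (st$mu <= 0 || st$K <= 0) stop("non-positive growth parameters")
  K_eff <- max(st$K * (1 - medium_state$depletion_frac), 1e-4)
  mu_eff <- max(st$mu * (1 - medium_state$kill_coupling), 0.01)
  times <- seq(0, 20, by = 1 / 6)
  traj <- glv_integrate(st$od0, mu_eff, matrix(-mu_eff / K_eff, 1, 1), times)
  od <- traj[, 1]
  od <- .with_seed(seed, od + stats::rnorm(length(od), 0, design$noise$od_sd))
  growth_curve(strain, medium_id, replicate, times, pmax(od, 0))
}

#' Simulate the full spent-media experiment
#'
#' Grows every strain in fresh medium and in the spent medium of every
#' producer (including its own), in `n_reps` noisy replicates, and returns
#' the designed (noiseless) d_AUC per producer/consumer pair as ground
#' truth.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed.
#' @param n_reps Replicates per condition.
#' @return List with `curves` (list of [growth_curve()]; media are
#'   `"fresh"` or `"SM_<producer>"`) and `truth` (data.frame `producer`,
#'   `consumer`, `expected_d_auc`).
#' @export
simulate_spent_media_experiment <- function(design, seed = 1L, n_reps = 3L) {
  ids <- design$strains$strain_id
  S <- length(ids)
  curves <- list()
  truth <- NULL
  auc_fresh <- numeric(S)
  .with_seed(seed, {
    noiseless <- lapply(ids, function(s)
      simulate_monoculture(design, s, seed = NULL, medium_id = "fresh"))
    for (i in seq_len(S)) auc_fresh[i] <- compute_auc(noiseless[[i]])
    for (s in seq_len(S)) for (r in seq_len(n_reps))
      curves[[length(curves) + 1L]] <-
        simulate_monoculture(design, ids[s], seed = NULL, replicate = r,
                             medium_id = "fresh")
    for (p in seq_len(S)) {
      for (cns in seq_len(S)) {
        ms <- list(
          depletion_frac = .depletion_fraction(design, ids[p], ids[cns]),
          kill_coupling = design$kill[cns, p])
        nl <- simulate_monoculture(design, ids[cns], ms, seed = NULL,
                                   medium_id = paste0("SM_", ids[p]))
        truth <- rbind(truth, data.frame(
          producer = ids[p], consumer = ids[cns],
          expected_d_auc = (compute_auc(nl) - auc_fresh[cns]) / auc_fresh[cns],
          stringsAsFactors = FALSE))
        for (r in seq_len(n_reps))
          curves[[length(curves) + 1L]] <-
            simulate_monoculture(design, ids[cns], ms, seed = NULL,
                                 replicate = r,
                                 medium_id = paste0("SM_", ids[p]))
      }
    }
  })
  list(curves = curves, truth = truth)
}

# The noise above relies on .with_seed wrapping the whole block; inner
# simulate_monoculture calls draw from that stream (seed = NULL).

#' Simulate an untargeted-metabolomics feature table
#'
#' Fresh-medium replicates scatter log-normally around per-feature
#' baselines; each strain's spent-medium replicates have the strain's used
#' features reduced by the designed depletion depth and its produced
#' features elevated by the production fold.
#'
#' @param design A [synthetic_design()] with a resource profile.
#' @param seed Integer seed.
#' @param n_reps Replicates per condition.
#' @return A [feature_table()].
#' @export
simulate_feature_table <- function(design, seed = 1L, n_reps = 3L) {
  if (is.null(design$resource_usage))
    stop("design has no resource profile")
  ids <- design$strains$strain_id
  fids <- colnames(design$resource_usage)
  Fn <- length(fids)
  cv <- design$noise$intensity_cv
  sdlog <- sqrt(log(1 + cv^2))
  .with_seed(seed, {
    baseline <- stats::rlnorm(Fn, design$baseline_log_mean, design$baseline_log_sd)
    conds <- c("fresh", ids)
    cols <- list(); meta <- NULL
    for (cond in conds) {
      expect <- baseline
      if (cond != "fresh") {
        i <- match(cond, ids)
        expect <- expect * (1 - design$depletion_depth[i, ])
        prod <- design[["production"]]  # exact match: production_fold exists
        if (!is.null(prod))
          expect <- expect * ifelse(prod[i, ] == 1, design$production_fold, 1)
      }
      for (r in seq_len(n_reps)) {
        sid <- paste(cond, r, sep = "_")
        cols[[sid]] <- expect * stats::rlnorm(Fn, -sdlog^2 / 2, sdlog)
        meta <- rbind(meta, data.frame(sample_id = sid, condition = cond,
                                       replicate = r, mode = "mixed",
                                       stringsAsFactors = FALSE))
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- fids
    feature_table(mat, meta)
  })
}

#' Noiseless co-culture/monoculture endpoint truth
#'
#' Integrates the design's gLV dynamics for all monocultures and all
#' unordered pairs under the batch-dilution schedule (3 cycles for a 72 h
#' endpoint by default) and returns true abundances (OD units) at every
#' cycle boundary. Pairs are inoculated 1:1 at the monoculture total, i.e.
#' each member starts at half its monoculture inoculum. Deterministic: all
#' pairs are integrated as one block-diagonal system.
#'
#' @param design A [synthetic_design()].
#' @param cycles Number of dilution cycles.
#' @return data.frame `strain`, `culture_type` (`"mono"`/`"pair"`),
#'   `partner`, `timepoint_h`, `true_od`.
#' @export
coculture_truth <- function(design, cycles = 3L) {
  ids <- design$strains$strain_id
  S <- length(ids)
  mu <- design$strains$mu; K <- design$strains$K; od0 <- design$strains$od0
  A <- design$A
  dil <- design$dilution
  # monocultures: decoupled, one diagonal system
  mono <- glv_passage(od0, mu, diag(diag(A)), cycles,
                      period_h = dil$period_h, dilution_factor = dil$factor)
  combos <- utils::combn(S, 2)
  P <- ncol(combos)
  idx_a <- combos[1, ]; idx_b <- combos[2, ]
  state_i <- c(rbind(idx_a, idx_b))         # strain index per state slot
  partner_slot <- c(rbind(seq(2, 2 * P, 2), seq(1, 2 * P, 2)))
  mu_v <- mu[state_i]
  self_v <- diag(A)[state_i]
  cross_v <- A[cbind(state_i, state_i[partner_slot])]
  n0 <- od0[state_i] / 2
  guard <- 1e6 * max(K)
  f <- function(n) n * (mu_v + self_v * n + cross_v * n[partner_slot])
  n <- n0
  states <- matrix(NA_real_, cycles + 1L, 2 * P)
  states[1, ] <- n
  for (cy in seq_len(cycles)) {
    traj <- .rk4(f, n, c(0, dil$period_h), dt = 0.01, guard = guard)
    n <- traj[2, ]
    states[cy + 1L, ] <- n
    n <- n * dil$factor
  }
  tps <- seq(0, cycles) * dil$period_h
  mono_df <- data.frame(
    strain = rep(ids, each = length(tps)),
    culture_type = "mono", partner = NA_character_,
    timepoint_h = rep(tps, S),
    true_od = as.vector(mono),
    stringsAsFactors = FALSE)
  pair_df <- data.frame(
    strain = rep(ids[state_i], each = length(tps)),
    culture_type = "pair",
    partner = rep(ids[state_i[partner_slot]], each = length(tps)),
    timepoint_h = rep(tps, 2 * P),
    true_od = as.vector(states),  # column-major: one state slot at a time
    stringsAsFactors = FALSE)
  rbind(mono_df, pair_df)
}

#' Simulate endpoint qPCR abundance records for mono- and co-cultures
#'
#' Observation layer over [coculture_truth()]: converts true OD to 16S
#' copies with the design's per-strain copy yield and draws `n_reps`
#' log-normal replicate observations at the design's abundance CV.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed.
#' @param n_reps Replicate experiments.
#' @param truth Optional precomputed [coculture_truth()] (avoids
#'   re-integrating identical dynamics across seeds).
#' @return data.frame `strain`, `culture_id`, `culture_type`, `partner`,
#'   `timepoint_h`, `replicate`, `copies`.
#' @export
simulate_cocultures <- function(design, seed = 1L, n_reps = 3L, truth = NULL) {
  if (is.null(truth)) truth <- coculture_truth(design)
  cv <- design$noise$abundance_cv
  sdlog <- sqrt(log(1 + cv^2))
  yield <- stats::setNames(design$strains$copies_per_od, design$strains$strain_id)
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      df <- truth
      df$replicate <- r
      df$copies <- df$true_od * yield[df$strain] *
        stats::rlnorm(nrow(df), -sdlog^2 / 2, sdlog)
      df
    }))
    out$culture_id <- ifelse(out$culture_type == "mono",
                             paste0("mono_", out$strain),
                             paste0("pair_", pmin(out$strain, out$partner),
                                    "_", pmax(out$strain, out$partner)))
    out$true_od <- NULL
    rownames(out) <- NULL
    out[, c("strain", "culture_id", "culture_type", "partner",
            "timepoint_h", "replicate", "copies")]
  })
}

#' Simulate serial-passage community dynamics
#'
#' Inoculates all strains (or all minus a dropout) equally and integrates
#' the full gLV system with daily dilution for `days` cycles, returning
#' noisy replicate copy numbers per strain and day.
#'
#' @param design A [synthetic_design()].
#' @param days Number of daily cycles (>= 1).
#' @param dropout Optional strain id to omit.
#' @param seed Integer seed.
#' @param n_reps Replicate communities.
#' @return data.frame `strain`, `community` (`"full"` or
#'   `"dropout_<strain>"`), `day`, `replicate`, `copies`, `true_od`.
#' @export
simulate_community <- function(design, days = 10L, dropout = NULL,
                               seed = 1L, n_reps = 3L) {
  stopifnot(days >= 1)
  ids <- design$strains$strain_id
  keep <- if (is.null(dropout)) seq_along(ids)
          else which(ids != dropout)
  if (length(keep) == length(ids) && !is.null(dropout))
    stop("unknown dropout strain: ", dropout)
  mu <- design$strains$mu[keep]
  A <- design$A[keep, keep, drop = FALSE]
  n0 <- rep(design$strains$od0[1] / length(keep), length(keep))
  traj <- glv_passage(n0, mu, A, cycles = days,
                      period_h = design$dilution$period_h,
                      dilution_factor = design$dilution$factor)
  label <- if (is.null(dropout)) "full" else paste0("dropout_", dropout)
  cv <- design$noise$abundance_cv
  sdlog <- sqrt(log(1 + cv^2))
  yield <- design$strains$copies_per_od[keep]
  .with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      do.call(rbind, lapply(seq_len(days + 1L) - 1L, function(d) {
        od <- traj[d + 1L, ]
        data.frame(strain = ids[keep], community = label, day = d,
                   replicate = r,
                   copies = od * yield * stats::rlnorm(length(od), -sdlog^2 / 2, sdlog),
                   true_od = od, stringsAsFactors = FALSE)
      }))
    }))
  })
}

#' Default qPCR standard curves for a design
#'
#' @param design A [synthetic_design()].
#' @return Named list of [standard_curve()]s, slopes between -3.6 and -3.2.
#' @export
default_standard_curves <- function(design) {
  ids <- design$strains$strain_id
  slopes <- seq(-3.6, -3.2, length.out = length(ids))
  intercepts <- seq(36, 39, length.out = length(ids))
  stats::setNames(
    lapply(seq_along(ids), function(i)
      standard_curve(ids[i], slopes[i], intercepts[i], cq_range = c(5, 35))),
    ids)
}

#' Simulate qPCR Cq readouts from abundances
#'
#' `Cq = intercept + slope * log10(copies)` plus Gaussian noise; zero
#' abundances are censored at the maximum cycle with `detected = FALSE`.
#'
#' @param abundances data.frame with columns `strain` and `copies` (e.g.
#'   from [simulate_cocultures()]).
#' @param curves Named list of [standard_curve()]s covering every strain.
#' @param cq_sd Gaussian Cq noise standard deviation.
#' @param seed Integer seed.
#' @param max_cycle Censoring value for undetected strains.
#' @return The input with added `cq` and `detected` columns.
#' @export
simulate_qpcr <- function(abundances, curves, cq_sd = 0.1, seed = 1L,
                          max_cycle = 40) {
  missing_curves <- setdiff(unique(abundances$strain), names(curves))
  if (length(missing_curves))
    stop("no standard curve for: ", paste(missing_curves, collapse = ", "))
  .with_seed(seed, {
    out <- abundances
    slope <- vapply(curves, `[[`, numeric(1), "slope")[out$strain]
    intercept <- vapply(curves, `[[`, numeric(1), "intercept")[out$strain]
    detected <- out$copies > 0
    cq <- rep(max_cycle, nrow(out))
    cq[detected] <- intercept[detected] +
      slope[detected] * log10(out$copies[detected]) +
      stats::rnorm(sum(detected), 0, cq_sd)
    out$cq <- cq
    out$detected <- detected
    out
  })
}
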