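test_that("generators are bit-reproducible given a seed and leave the RNG alone", {
  d <- tiny_design(noise = list(od_sd = 0.005, intensity_cv = 0.1,
                                cq_sd = 0.1, abundance_cv = 0.2))
  a <- simulate_monoculture(d, "t1", seed = 42)
  b <- simulate_monoculture(d, "t1", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$od, simulate_monoculture(d, "t1", seed = 43)$od))
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_feature_table(d, seed = 7)); after <- runif(1)
  expect_identical(before, after)
  ft1 <- simulate_feature_table(d, seed = 7)
  ft2 <- simulate_feature_table(d, seed = 7)
  expect_identical(ft1$intensities, ft2$intensities)
})

test_that("noiseless monocultures saturate at the designed capacity", {
  d <- tiny_design()
  cv <- simulate_monoculture(d, "t1")
  expect_equal(max(cv$od), 1.0, tolerance = 0.01)
  expect_equal(length(cv$times), 121)  # 10-min sampling over 20 h
  # halved capacity halves late growth and lowers the AUC
  half <- simulate_monoculture(d, "t1", medium_state = list(depletion_frac = 0.5,
                                                            kill_coupling = 0))
  expect_lt(compute_auc(half), compute_auc(cv))
  expect_equal(max(half$od), 0.5, tolerance = 0.01)
  expect_error(simulate_monoculture(d, "zz"), "unknown strain")
})

test_that("the growth-rate estimator recovers the designed rate from logistic curves", {
  d <- tiny_design()
  d$strains$mu[1] <- 1.2
  cv <- simulate_monoculture(d, "t1")
  expect_equal(estimate_growth_rate(cv), 1.2, tolerance = 0.05)
})

test_that("fixed-step gLV agrees with a tiny-step reference and lsoda", {
  mu <- c(1.2, 0.9, 0.6)
  A <- rbind(c(-1.2, -0.3, 0), c(-0.2, -1.1, -0.1), c(0, -0.4, -0.8))
  n0 <- c(0.01, 0.02, 0.015)
  tt <- c(0, 6, 12, 24)
  coarse <- glv_integrate(n0, mu, A, tt, dt = 0.01)
  fine <- glv_integrate(n0, mu, A, tt, dt = 0.0005)
  expect_lt(max(abs(coarse[-1, ] - fine[-1, ]) / fine[-1, ]), 1e-4)
  # independent adaptive integrator
  library(deSolve)
  rhs <- function(t, n, p) list(n * (mu + as.vector(A %*% n)))
  ref <- ode(n0, tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)[, -1]
  expect_lt(max(abs(coarse[-1, ] - ref[-1, ]) / ref[-1, ]), 1e-4)
})

test_that("divergent designs are rejected by the stability guard", {
  expect_error(
    glv_integrate(c(0.1, 0.1), c(1, 1),
                  rbind(c(-0.001, 5), c(5, -0.001)), c(0, 48)),
    "divergence")
})

test_that("spent-media outcomes reflect designed resource overlap", {
  d <- tiny_design()
  sm <- simulate_spent_media_experiment(d, seed = 3)
  tru <- sm$truth
  get <- function(p, cns) tru$expected_d_auc[tru$producer == p & tru$consumer == cns]
  # disjoint resources, no bacteriocin: no inhibition
  expect_lt(abs(get("t3", "t1")), 0.1)
  expect_lt(abs(get("t1", "t4")), 0.1)
  # t2's resources nested in t1's: strong inhibition in t1's spent medium
  expect_lt(get("t1", "t2"), -0.5)
  # every strain is strongly inhibited in its own spent medium
  for (s in d$strains$strain_id) expect_lt(get(s, s), -0.5)
  # analysis path recovers the designed d_AUC from the noisy curves
  cs <- do.call(rbind, lapply(sm$curves, summarise_growth))
  smv <- cs$auc[cs$strain_id == "t2" & cs$medium_id == "SM_t1"]
  fr <- cs$auc[cs$strain_id == "t2" & cs$medium_id == "fresh"]
  expect_equal(compute_inhibition_factor(smv, fr)$d_auc, get("t1", "t2"),
               tolerance = 0.05)
})

test_that("designed depletion sets are recovered from simulated feature tables", {
  d <- tiny_design()
  ft <- simulate_feature_table(d, seed = 11)
  profs <- call_feature_changes(ft, alpha = 0.05)
  for (i in 1:4) {
    sid <- d$strains$strain_id[i]
    designed <- colnames(d$resource_usage)[d$resource_usage[i, ] == 1]
    recovered <- length(intersect(profs[[sid]]$depleted, designed)) / length(designed)
    expect_gte(recovered, 0.95)
  }
  # produced features are found in the produced sets, not the depleted ones
  expect_false(any(profs$t1$produced %in%
                     colnames(d$resource_usage)[d$resource_usage[1, ] == 1]))
})

test_that("zero-depth designs give false-positive rates near alpha", {
  d <- tiny_design()
  d$depletion_depth <- d$resource_usage * 0
  d$production <- NULL
  ft <- simulate_feature_table(d, seed = 12)
  profs <- call_feature_changes(ft, alpha = 0.05)
  fp <- mean(sapply(profs, function(p) length(c(p$depleted, p$produced)) / 40))
  expect_lte(fp, 0.12)  # 40 features per strain: coarse binomial check
})

test_that("decoupled co-cultures give r_bm near 1 and designed couplings their signs", {
  base <- tiny_design(noise = list(od_sd = 0, intensity_cv = 0.1,
                                   cq_sd = 0, abundance_cv = 0))
  neutral <- synthetic_design(base$strains, matrix(0, 4, 4),
                              noise = base$noise)
  tr <- coculture_truth(neutral)
  end <- tr[tr$timepoint_h == 72, ]
  mono <- setNames(end$true_od[end$culture_type == "mono"],
                   end$strain[end$culture_type == "mono"])
  pr <- end[end$culture_type == "pair", ]
  expect_true(all(abs(pr$true_od / mono[pr$strain] - 1) < 0.05))
  # designed amensalism and competition come back with the right sign pairs
  ab <- simulate_cocultures(base, seed = 2)
  # noise-free ratios trigger the degenerate direction rule (tested in
  # test-network); its warnings are expected here
  net <- suppressWarnings(build_interaction_network(ab))
  e <- net$edges
  expect_equal(e$type[e$strain_a == "t1" & e$strain_b == "t2"], "amensalism")
  expect_equal(e$sign_b[e$strain_a == "t1" & e$strain_b == "t2"], "-")
  expect_equal(e$type[e$strain_a == "t3" & e$strain_b == "t4"], "competition")
})

test_that("serial passage exhibits the dilution washout threshold", {
  mu_star <- log(100) / 24
  persists <- function(mu) {
    tr <- glv_passage(1e-4, mu, matrix(-mu, 1, 1), cycles = 10,
                      period_h = 24, dilution_factor = 0.01)
    tr[11, 1] > tr[2, 1]
  }
  expect_false(persists(0.98 * mu_star))
  expect_true(persists(1.02 * mu_star))
})

test_that("community dropout of a designed killer releases its targets", {
  strains <- data.frame(
    strain_id = c("k", "v1", "v2", "n"),
    mu = c(1.5, 1.2, 1.1, 1.0),
    K = c(1.0, 0.8, 0.9, 0.7),
    od0 = 0.01, acid_coef = 0,
    copies_per_od = c(2e9, 1.5e9, 1e9, 0.8e9),
    phylum = "P", stringsAsFactors = FALSE)
  kill <- matrix(0, 4, 4)
  kill[2, 1] <- kill[3, 1] <- 0.6   # k suppresses v1 and v2
  des <- synthetic_design(strains, matrix(0, 4, 4), kill = kill,
                          noise = list(od_sd = 0, intensity_cv = 0.1,
                                       cq_sd = 0, abundance_cv = 0.05))
  full <- simulate_community(des, days = 10, seed = 4, n_reps = 4)
  drop <- simulate_community(des, days = 10, dropout = "k", seed = 5, n_reps = 4)
  to_mat <- function(df) {
    d10 <- df[df$day == 10, ]
    t(sapply(split(d10$copies, d10$strain), identity))
  }
  res <- compare_dropout(to_mat(full), to_mat(drop), "k")
  expect_equal(res$direction[res$strain == "v1"], "increase")
  expect_equal(res$direction[res$strain == "v2"], "increase")
  expect_equal(res$direction[res$strain == "n"], "unchanged")
  # a neutral community equilibrates near even composition
  des0 <- synthetic_design(strains, matrix(0, 4, 4),
                           noise = des$noise)
  cm <- simulate_community(des0, days = 10, seed = 6, n_reps = 1)
  fin <- cm[cm$day == 10, ]
  rel <- fin$true_od / sum(fin$true_od)
  expect_true(all(rel > 0.1))  # nobody washes out or dominates
})

test_that("qPCR simulation round-trips through quantification", {
  d <- tiny_design()
  curves <- default_standard_curves(d)
  ab <- data.frame(strain = c("t1", "t2", "t3"), copies = c(1e6, 1e4, 0))
  q <- simulate_qpcr(ab, curves, cq_sd = 0, seed = 1)
  back <- as.numeric(quantify_from_cq(q$cq[1], curves$t1))
  expect_equal(back, 1e6, tolerance = 1e-9)
  expect_false(q$detected[3])
  expect_equal(q$cq[3], 40)
  # direct evaluation: copies=1e4, slope=-3.5, intercept=38 -> cq=24
  cu <- standard_curve("z", -3.5, 38)
  qz <- simulate_qpcr(data.frame(strain = "z", copies = 1e4),
                      list(z = cu), cq_sd = 0, seed = 1)
  expect_equal(qz$cq, 24)
})
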