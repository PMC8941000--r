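make_table <- function(fresh, strain, ids = sprintf("f%02d", seq_len(nrow(fresh)))) {
  mat <- cbind(fresh, strain)
  rownames(mat) <- ids
  colnames(mat) <- c(paste0("fr", seq_len(ncol(fresh))),
                     paste0("st", seq_len(ncol(strain))))
  meta <- data.frame(
    sample_id = colnames(mat),
    condition = rep(c("fresh", "sA"), c(ncol(fresh), ncol(strain))),
    replicate = c(seq_len(ncol(fresh)), seq_len(ncol(strain))))
  feature_table(mat, meta)
}

test_that("feature calls agree with the per-feature Welch t-test oracle", {
  fresh <- rbind(c(1000, 1010, 990), c(500, 501, 499), c(100, 110, 90))
  strain <- rbind(c(100, 110, 90), c(500.2, 500.9, 499.3), c(1000, 1010, 990))
  tab <- make_table(fresh, strain)
  prof <- call_feature_changes(tab, alpha = 0.05)[["sA"]]
  expect_equal(prof$depleted, "f01")
  expect_equal(prof$produced, "f03")
  # p-values equal t.test's, feature by feature
  for (i in 1:3)
    expect_equal(prof$stats$p_value[i],
                 t.test(strain[i, ], fresh[i, ])$p.value, tolerance = 1e-12)
  # pooled-variance option matches the Student oracle
  prof_s <- call_feature_changes(tab, var_equal = TRUE)[["sA"]]
  expect_equal(prof_s$stats$p_value[1],
               t.test(strain[1, ], fresh[1, ], var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("zero-variance features are skipped with a warning, not mis-called", {
  fresh <- rbind(c(500, 500, 500), c(1000, 1010, 990))
  strain <- rbind(c(500, 500, 500), c(100, 110, 90))
  tab <- make_table(fresh, strain)
  expect_warning(prof <- call_feature_changes(tab), "zero-variance")
  expect_false("f01" %in% c(prof$sA$depleted, prof$sA$produced))
  expect_equal(prof$sA$depleted, "f02")
})

test_that("Benjamini-Hochberg adjustment is available and more conservative", {
  set.seed(31)
  fresh <- matrix(rnorm(60 * 3, 1000, 50), 60)
  strain <- fresh * matrix(runif(60 * 3, 0.8, 1.0), 60)
  tab <- make_table(fresh, strain)
  raw <- call_feature_changes(tab)[["sA"]]
  bh <- call_feature_changes(tab, adjust = "BH")[["sA"]]
  expect_lte(length(bh$depleted), length(raw$depleted))
})

test_that("replicate requirements are enforced by the table constructor", {
  mat <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     condition = c("fresh", "fresh", "sA"), replicate = c(1, 2, 1))
  expect_error(feature_table(mat, meta), "< 2 replicates")
})

test_that("altered fraction depends only on the union of altered sets", {
  pA <- depletion_profile("A", sprintf("f%04d", 1:1600), sprintf("f%04d", 2001:2387))
  pB <- depletion_profile("B", sprintf("f%04d", 1500:2000))
  expect_equal(fraction_altered(list(pA, pB), 3092), 77.20)
  expect_equal(fraction_altered(list(depletion_profile("A", character())), 100), 0)
  expect_equal(fraction_altered(list(depletion_profile("A", letters)), 26), 100)
  # invariance to repartitioning the same union
  pc <- depletion_profile("C", sprintf("f%04d", 1:1000))
  pd <- depletion_profile("D", sprintf("f%04d", 1001:2387))
  expect_equal(fraction_altered(list(pc, pd), 3092), 77.20)
  expect_error(fraction_altered(list(pA), 0), "positive")
})

test_that("overlap percentages reproduce the asymmetric worked example", {
  shared <- sprintf("s%03d", 1:33)
  pA <- depletion_profile("A", c(shared, sprintf("a%03d", 1:337)))  # 370 total
  pB <- depletion_profile("B", c(shared, sprintf("b%03d", 1:95)))   # 128 total
  ov <- overlap_matrix(list(pA, pB))
  expect_equal(ov$counts["A", "B"], 33)
  expect_equal(round_half_up(ov$percent["A", "B"], 1), 8.9)
  expect_equal(round_half_up(ov$percent["B", "A"], 1), 25.8)
  # disjoint and subset cases
  pC <- depletion_profile("C", sprintf("c%03d", 1:10))
  expect_equal(overlap_matrix(list(pA, pC))$percent["A", "C"], 0)
  pSub <- depletion_profile("S", shared[1:10])
  expect_equal(overlap_matrix(list(pSub, pB))$percent["S", "B"], 100)
})

test_that("overlap cross-identity holds on random sets and empty sets warn", {
  set.seed(7)
  for (i in 1:15) {
    uni <- sprintf("u%03d", 1:200)
    profs <- lapply(1:4, function(k)
      depletion_profile(paste0("s", k), sample(uni, rpois(1, 60) + 1)))
    ov <- overlap_matrix(profs)
    for (a in 1:4) for (b in 1:4) {
      expect_equal(ov$percent[a, b] * ov$set_sizes[[a]],
                   ov$percent[b, a] * ov$set_sizes[[b]])
      expect_gte(ov$percent[a, b], 0)
      expect_lte(ov$percent[a, b], 100)
    }
    expect_true(all(diag(ov$percent)[ov$set_sizes > 0] == 100))
    expect_true(isSymmetric(ov$counts))
  }
  expect_warning(
    ov0 <- overlap_matrix(list(depletion_profile("E", character()),
                               depletion_profile("B", c("x", "y")))),
    "empty")
  expect_true(all(ov0$percent["E", ] == 0))
})

test_that("phylum partition enumerates exclusive regions that conserve the union", {
  p1 <- depletion_profile("a", sprintf("f%02d", 1:40))
  part <- phylum_partition(list(p1), c(a = "P1"))
  expect_equal(unname(part$region_sizes["P1"]), 40L)
  # two disjoint phyla
  p2 <- depletion_profile("b", sprintf("g%02d", 1:20))
  part2 <- phylum_partition(list(p1, p2), c(a = "P1", b = "P2"))
  expect_equal(unname(part2$region_sizes[c("P1", "P2")]), c(40L, 20L))
  expect_false("P1+P2" %in% names(part2$region_sizes))
  # three phyla with designed sharing, checked by brute-force membership
  u <- sprintf("h%02d", 1:60)
  sets <- list(x = u[1:30], y = u[21:45], z = u[c(21:25, 40:60)])
  profs <- Map(depletion_profile, names(sets), sets)
  part3 <- phylum_partition(profs, c(x = "PX", y = "PY", z = "PZ"))
  member <- sapply(sets, function(s) u %in% s)
  want <- table(apply(member, 1, function(m)
    paste(sort(c("PX", "PY", "PZ")[m]), collapse = "+")))
  want <- want[names(want) != ""]
  expect_equal(sort(part3$region_sizes), sort(setNames(as.integer(want), names(want))))
  expect_equal(sum(part3$region_sizes), part3$union_size)
  expect_error(phylum_partition(profs, c(x = "PX", y = "PY")), "without a phylum")
})

test_that("designed niche structure yields overlap decaying with tree distance", {
  d <- default_design()
  profs <- lapply(seq_len(nrow(d$strains)), function(i)
    depletion_profile(d$strains$strain_id[i],
                      colnames(d$resource_usage)[d$resource_usage[i, ] == 1]))
  ov <- overlap_matrix(profs)
  dm <- patristic_distances(parse_newick(d$tree_newick))
  res <- shared_count_vs_distance(ov, dm)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n, 66)
})

test_that("pairwise correlations reject degenerate inputs", {
  pA <- depletion_profile("A", c("f1", "f2"))
  pB <- depletion_profile("B", c("f1", "f3"))
  ov2 <- overlap_matrix(list(pA, pB))
  dm2 <- patristic_distances(parse_newick("(A:1,B:1);"))
  expect_error(shared_count_vs_distance(ov2, dm2), "at least 3")
  # all-zero d_AUC: zero variance in the inhibition values
  pC <- depletion_profile("C", c("f2", "f4"))
  ov <- overlap_matrix(list(pA, pB, pC))
  ids <- c("A", "B", "C")
  recs <- do.call(rbind, lapply(ids, function(p)
    do.call(rbind, lapply(ids, function(cns)
      compute_inhibition_factor(c(4, 4), c(4, 4), p, cns)))))
  im <- build_inhibition_matrix(recs, ids)
  expect_error(overlap_vs_inhibition(ov, im), "variance")
})
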