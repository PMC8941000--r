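# Shared fixtures and independent oracles used across the suite.

# Brute-force patristic distances: breadth-first path enumeration over the
# tree's edge list, independent of any cophenetic code path.
brute_force_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (src in seq_len(n_tip)) {
    dist <- rep(NA_real_, nodes)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(dist[nb])) {
          dist[nb] <- dist[v] + w
          queue <- c(queue, nb)
        }
      }
    }
    d[src, ] <- dist[seq_len(n_tip)]
  }
  d
}

# Direct eigendecomposition PCA oracle: scores of column-centred data from
# the covariance eigenvectors.
eigen_pca_oracle <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(xc), symmetric = TRUE)
  list(scores = xc %*% e$vectors[, seq_len(k), drop = FALSE],
       explained_variance = (e$values / sum(e$values))[seq_len(k)])
}

# A small 4-strain design: s1 harms s2 (strong one-sided), s3 and s4
# mutually compete, everything else neutral; disjoint-vs-nested resource
# blocks exercise the spent-media overlap logic.
tiny_design <- function(noise = list(od_sd = 0, intensity_cv = 0.1,
                                     cq_sd = 0, abundance_cv = 0.2)) {
  strains <- data.frame(
    strain_id = c("t1", "t2", "t3", "t4"),
    mu = c(1.6, 1.2, 1.0, 0.8),
    K = c(1.0, 0.8, 0.9, 0.7),
    od0 = 0.01,
    acid_coef = c(0.5, 0.2, 0.1, 0),
    copies_per_od = c(2e9, 1.5e9, 1e9, 0.8e9),
    phylum = c("P1", "P1", "P2", "P2"),
    stringsAsFactors = FALSE)
  cp <- matrix(0, 4, 4)
  cp[2, 1] <- -0.75          # s1 -> s2 amensal
  cp[3, 4] <- cp[4, 3] <- -0.9  # competition
  usage <- matrix(0L, 4, 40)
  usage[1, 1:20] <- 1L       # t1 uses features 1-20
  usage[2, 11:20] <- 1L      # t2's set nested inside t1's
  usage[3, 21:30] <- 1L      # t3 disjoint from t1/t2
  usage[4, 31:40] <- 1L      # t4 disjoint from everyone
  colnames(usage) <- sprintf("pos_F%03d", 1:40)
  synthetic_design(strains, cp, resource_usage = usage,
                   depletion_depth = usage * 0.9,
                   noise = noise,
                   tree_newick = "((t1:0.1,t2:0.1):0.2,(t3:0.15,t4:0.15):0.15);")
}

# Endpoint abundance records with exact designed ratios and no noise:
# 12 strains, every pair present, copies chosen directly (no dynamics).
exact_abundance_records <- function(ratios = NULL, n_strains = 12,
                                    n_reps = 3, mono_copies = 1e6) {
  ids <- sprintf("x%02d", seq_len(n_strains))
  mono <- expand.grid(strain = ids, replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  mono$culture_type <- "mono"
  mono$partner <- NA_character_
  mono$copies <- mono_copies
  combos <- combn(ids, 2)
  pair <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    ra <- if (is.null(ratios)) 1 else ratios(a, b)
    rb <- if (is.null(ratios)) 1 else ratios(b, a)
    expand.grid(strain = c(a, b), replicate = seq_len(n_reps),
                stringsAsFactors = FALSE) |>
      transform(culture_type = "pair",
                partner = ifelse(strain == a, b, a),
                copies = mono_copies * ifelse(strain == a, ra, rb))
  }))
  out <- rbind(mono, pair)
  out$timepoint_h <- 72
  out$culture_id <- paste(out$culture_type, out$strain, out$partner, sep = "_")
  out
}
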