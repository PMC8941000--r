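#' Construct a metabolomic feature table
#'
#' Integrated peak areas for untargeted-MS features across spent-medium and
#' fresh-medium samples. Positive- and negative-ionization features live in
#' one universe; ids are expected to be mode-prefixed upstream (e.g.
#' `pos_F0001`) so they cannot collide.
#'
#' @param intensities Numeric feature x sample matrix (non-negative), with
#'   rownames = feature ids and colnames = sample ids.
#' @param sample_meta data.frame with columns `sample_id`, `condition`
#'   (`"fresh"` or a strain id), `replicate`, and optionally `mode`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_meta) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("'intensities' needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate feature ids")
  if (!all(c("sample_id", "condition", "replicate") %in% names(sample_meta)))
    stop("'sample_meta' needs columns sample_id, condition, replicate")
  if (!setequal(sample_meta$sample_id, colnames(intensities)))
    stop("sample ids in metadata and matrix disagree")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  sample_meta <- sample_meta[match(colnames(intensities), sample_meta$sample_id), ]
  reps <- table(sample_meta$condition)
  if (any(reps < 2))
    stop("conditions with < 2 replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  if (!"fresh" %in% sample_meta$condition)
    stop("a 'fresh' (fresh-medium) condition is required")
  structure(list(intensities = intensities, sample_meta = sample_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d conditions)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$sample_meta$condition))))
  invisible(x)
}

# Vectorised Welch / Student two-sample t-test across features.
# Returns two-sided p-values; features where both groups have zero variance
# get NA (undefined statistic).
.row_t_test <- function(xm, ym, var_equal = FALSE) {
  n1 <- ncol(xm); n2 <- ncol(ym)
  m1 <- rowMeans(xm); m2 <- rowMeans(ym)
  v1 <- rowSums((xm - m1)^2) / (n1 - 1)
  v2 <- rowSums((ym - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- NA_real_
  list(p = p, mean_x = m1, mean_y = m2)
}

#' Call per-strain depleted and produced features
#'
#' For every strain condition, each feature's replicate intensities are
#' compared to the fresh-medium replicates with a two-sided two-sample
#' t-test (Welch by default). A feature is *depleted* if `p < alpha` and its
#' strain mean is below the fresh mean, *produced* if `p < alpha` and above.
#' No multiple-testing correction is applied by default; `adjust = "BH"`
#' switches to Benjamini-Hochberg adjusted p-values, which is more
#' conservative and will call fewer features.
#'
#' @param table A [feature_table()].
#' @param alpha Per-feature significance level in (0, 1).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param log10_transform Test `log10(intensity + 1)` instead of the raw scale.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Named list (one per strain) of `depletion_profile` objects: each
#'   holds `strain_id`, character sets `depleted` and `produced`, and a
#'   per-feature `stats` data.frame (`feature_id`, `mean_fresh`,
#'   `mean_strain`, `p_value`). Features with an undefined statistic (zero
#'   variance in both groups) are skipped with a warning. The feature
#'   universe is attached as `attr(, "feature_ids")`.
#' @export
call_feature_changes <- function(table, alpha = 0.05, var_equal = FALSE,
                                 log10_transform = FALSE, adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"), alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  mat <- table$intensities
  if (log10_transform) mat <- log10(mat + 1)
  meta <- table$sample_meta
  fresh <- mat[, meta$condition == "fresh", drop = FALSE]
  strains <- setdiff(unique(meta$condition), "fresh")
  res <- lapply(strains, function(s) {
    sm <- mat[, meta$condition == s, drop = FALSE]
    tt <- .row_t_test(sm, fresh, var_equal = var_equal)
    p <- tt$p
    if (anyNA(p))
      warning(sum(is.na(p)), " zero-variance feature(s) skipped for strain ", s)
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    sig <- !is.na(p) & p < alpha
    ids <- rownames(mat)
    structure(
      list(strain_id = s,
           depleted = ids[sig & tt$mean_x < tt$mean_y],
           produced = ids[sig & tt$mean_x > tt$mean_y],
           stats = data.frame(feature_id = ids, mean_fresh = tt$mean_y,
                              mean_strain = tt$mean_x, p_value = p,
                              row.names = NULL, stringsAsFactors = FALSE)),
      class = "depletion_profile")
  })
  names(res) <- strains
  attr(res, "feature_ids") <- rownames(mat)
  res
}

#' Build a depletion profile directly from feature sets
#'
#' Convenience constructor used when the significantly depleted/produced
#' sets are already known (e.g. from a published figure legend or a
#' simulation's ground truth).
#'
#' @param strain_id Strain identifier.
#' @param depleted,produced Disjoint character vectors of feature ids.
#' @return A `depletion_profile`.
#' @export
depletion_profile <- function(strain_id, depleted, produced = character()) {
  depleted <- unique(as.character(depleted))
  produced <- unique(as.character(produced))
  if (length(intersect(depleted, produced)))
    stop("'depleted' and 'produced' must be disjoint")
  structure(list(strain_id = as.character(strain_id), depleted = depleted,
                 produced = produced, stats = NULL),
            class = "depletion_profile")
}

#' @export
print.depletion_profile <- function(x, ...) {
  cat(sprintf("<depletion_profile> %s: %d depleted, %d produced\n",
              x$strain_id, length(x$depleted), length(x$produced)))
  invisible(x)
}

#' Fraction of the feature universe altered by at least one strain
#'
#' @param profiles List of `depletion_profile`s.
#' @param total_features Size of the detected feature universe (>= union of
#'   altered sets).
#' @return Percentage (0-100), rounded to two decimals.
#' @export
fraction_altered <- function(profiles, total_features) {
  if (total_features <= 0) stop("'total_features' must be positive")
  altered <- unique(unlist(lapply(profiles, function(p) c(p$depleted, p$produced))))
  if (length(altered) > total_features)
    stop("union of altered features exceeds 'total_features'")
  round(100 * length(altered) / total_features, 2)
}

#' Asymmetric substrate-depletion overlap matrix
#'
#' `percent[i, j] = 100 * |D_i intersect D_j| / |D_i|`: the share of strain
#' i's depleted features that strain j also depletes. Counts are symmetric;
#' percentages are not (each row is normalised by that strain's own set
#' size). Full precision is retained; round only in reports.
#'
#' @param profiles List of `depletion_profile`s (named or carrying
#'   `strain_id`s).
#' @return An `overlap_matrix`: list with `strains`, `percent`, `counts`,
#'   `set_sizes`. Strains with an empty depleted set get a zero percent row
#'   (with a warning) rather than 0/0.
#' @export
overlap_matrix <- function(profiles) {
  strains <- vapply(profiles, function(p) p$strain_id, character(1))
  sets <- lapply(profiles, function(p) p$depleted)
  names(sets) <- strains
  S <- length(strains)
  counts <- matrix(0L, S, S, dimnames = list(strains, strains))
  for (i in seq_len(S))
    for (j in seq_len(S))
      counts[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  sizes <- lengths(sets)
  if (any(sizes == 0))
    warning("empty depleted set(s): ",
            paste(strains[sizes == 0], collapse = ", "),
            "; their percent rows are set to 0")
  denom <- ifelse(sizes == 0, 1, sizes)
  percent <- 100 * counts / denom
  percent[sizes == 0, ] <- 0
  structure(list(strains = strains, percent = percent, counts = counts,
                 set_sizes = sizes),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d strains, set sizes %d-%d\n",
              length(x$strains), min(x$set_sizes), max(x$set_sizes)))
  invisible(x)
}

#' Exclusive-region partition of depleted features by phylum
#'
#' Groups strain depletion sets into phylum-level unions and counts, for
#' every non-empty subset of phyla, the features depleted by exactly that
#' subset (the regions of an Euler diagram). Regions are disjoint and sum
#' to the size of the overall union.
#'
#' @param profiles List of `depletion_profile`s.
#' @param taxonomy Named character vector mapping strain id -> phylum; every
#'   strain must be labelled.
#' @return A list with `groups` (phylum -> union of member sets),
#'   `region_sizes` (named integer vector; names are `+`-joined sorted
#'   phylum subsets) and `union_size`.
#' @export
phylum_partition <- function(profiles, taxonomy) {
  strains <- vapply(profiles, function(p) p$strain_id, character(1))
  missing_tax <- setdiff(strains, names(taxonomy))
  if (length(missing_tax))
    stop("strains without a phylum label: ", paste(missing_tax, collapse = ", "))
  phyla <- sort(unique(unname(taxonomy[strains])))
  groups <- lapply(phyla, function(ph) {
    unique(unlist(lapply(profiles[taxonomy[strains] == ph],
                         function(p) p$depleted)))
  })
  names(groups) <- phyla
  universe <- unique(unlist(groups))
  membership <- vapply(groups, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, phyla))
  sig <- apply(membership, 1L, function(m) paste(phyla[m], collapse = "+"))
  region_sizes <- table(sig)
  out <- stats::setNames(as.integer(region_sizes), names(region_sizes))
  list(groups = groups, region_sizes = out, union_size = length(universe))
}

# Flatten the upper triangle of a square matrix into the unordered-pair
# vector used by the pairwise correlations.
.upper_pairs <- function(m) m[upper.tri(m)]

#' Shared depleted features versus phylogenetic distance
#'
#' Correlates pairwise shared-feature counts with pairwise patristic
#' distances over the S(S-1)/2 unordered strain pairs; phylogenetically
#' close strains depleting similar substrate sets shows up as a negative
#' correlation.
#'
#' @param overlap An [overlap_matrix()].
#' @param distances A `distance_matrix` from [patristic_distances()].
#' @param method Passed to [correlate()].
#' @return A [correlate()] result.
#' @export
shared_count_vs_distance <- function(overlap, distances, method = "pearson") {
  if (!setequal(overlap$strains, distances$strains))
    stop("overlap and distance matrices cover different strains")
  ord <- match(overlap$strains, distances$strains)
  d <- distances$d[ord, ord]
  correlate(.upper_pairs(overlap$counts), .upper_pairs(d), method = method)
}

#' Substrate overlap versus spent-medium growth inhibition
#'
#' For every ordered (producer, consumer) pair (self-pairs excluded), pairs
#' the consumer's depletion overlap with the producer
#' (`percent[consumer, producer]`, the share of the consumer's substrates
#' the producer also depletes) with the consumer's d_AUC in that producer's
#' spent medium. Exploitative competition predicts a negative correlation.
#'
#' @param overlap An [overlap_matrix()].
#' @param inhibition An [build_inhibition_matrix()] result.
#' @param method Passed to [correlate()].
#' @return A [correlate()] result.
#' @export
overlap_vs_inhibition <- function(overlap, inhibition, method = "pearson") {
  if (!setequal(overlap$strains, inhibition$strains))
    stop("overlap and inhibition matrices cover different strains")
  strains <- inhibition$strains
  ord <- match(strains, overlap$strains)
  pct <- overlap$percent[ord, ord]
  pairs <- expand.grid(producer = seq_along(strains),
                       consumer = seq_along(strains))
  pairs <- pairs[pairs$producer != pairs$consumer, ]
  x <- pct[cbind(pairs$consumer, pairs$producer)]
  y <- inhibition$d_auc[cbind(pairs$producer, pairs$consumer)]
  correlate(x, y, method = method)
}
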