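#' Relative abundances with detection flags
#'
#' Converts per-strain absolute copy numbers in one sample into fractions of
#' the sample total. Strains whose fraction falls below the detection limit
#' (or whose copies fall below an absolute limit, if given) are flagged as
#' not detected; the flag is explicit rather than an imputed zero.
#'
#' @param copies Named non-negative copy numbers, one per strain.
#' @param detection_limit Relative-abundance detection limit (default 1e-4).
#' @param absolute_limit Optional absolute-copies detection limit overriding
#'   the relative one.
#' @return data.frame with `strain`, `copies`, `rel_abundance`, `detected`.
#' @export
relative_abundance <- function(copies, detection_limit = 1e-4,
                               absolute_limit = NULL) {
  if (is.null(names(copies))) stop("'copies' must be named by strain")
  if (any(copies < 0)) stop("'copies' must be non-negative")
  total <- sum(copies)
  if (total <= 0) stop("all strains below detection; no composition defined")
  rel <- copies / total
  detected <- if (is.null(absolute_limit)) rel >= detection_limit
              else copies >= absolute_limit
  if (!any(detected)) stop("all strains below detection; no composition defined")
  data.frame(strain = names(copies), copies = unname(copies),
             rel_abundance = unname(rel), detected = unname(detected),
             stringsAsFactors = FALSE)
}

#' Compare a dropout community with the full community
#'
#' Per shared strain, fold-change of mean absolute abundance in the dropout
#' arm relative to the full arm, a two-sided two-sample (Welch) t-test, and
#' a direction label at `alpha`. Identifies which strains profit from (or
#' suffer under) the removal of one member.
#'
#' @param full,dropout Matrices (or data.frames) strains x replicates of
#'   absolute abundances; `dropout` lacks the removed strain's row.
#' @param removed_strain Identifier of the removed strain; must be present
#'   in `full` and absent from `dropout`.
#' @param alpha Significance level.
#' @return data.frame with `strain`, `mean_full`, `mean_dropout`,
#'   `fold_change`, `p_value`, `direction` in
#'   `c("increase", "decrease", "unchanged")`. Strains with zero abundance
#'   in both arms are excluded with a note in `attr(, "excluded")`.
#' @export
compare_dropout <- function(full, dropout, removed_strain, alpha = 0.05) {
  full <- as.matrix(full); dropout <- as.matrix(dropout)
  if (!removed_strain %in% rownames(full))
    stop("'removed_strain' not found in the full community")
  if (removed_strain %in% rownames(dropout))
    stop("'", removed_strain, "' must be absent from the dropout community")
  shared <- setdiff(rownames(full), removed_strain)
  if (!setequal(shared, rownames(dropout)))
    stop("strain sets differ beyond the removed strain: ",
         paste(union(setdiff(shared, rownames(dropout)),
                     setdiff(rownames(dropout), shared)), collapse = ", "))
  if (ncol(full) < 2L || ncol(dropout) < 2L)
    stop("need >= 2 replicates per arm")
  excluded <- character()
  rows <- lapply(shared, function(s) {
    xf <- full[s, ]; xd <- dropout[s, ]
    if (all(xf == 0) && all(xd == 0)) {
      excluded <<- c(excluded, s)
      return(NULL)
    }
    p <- tryCatch(stats::t.test(xd, xf)$p.value, error = function(e) NA_real_)
    fc <- mean(xd) / mean(xf)
    dir <- if (is.na(p) || p >= alpha) "unchanged"
           else if (fc > 1) "increase" else "decrease"
    data.frame(strain = s, mean_full = mean(xf), mean_dropout = mean(xd),
               fold_change = fc, p_value = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Per-strain z-score scaling across conditions
#'
#' Scales each strain's abundances to mean 0 and unit standard deviation
#' across conditions, revealing trends independent of the strain's absolute
#' abundance level. Constant rows become all-zero with a warning.
#'
#' @param mat Numeric strains x conditions matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
scale_by_strain <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 conditions per strain")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0))
    warning("constant row(s) scaled to zero: ",
            paste(rownames(mat)[sds == 0], collapse = ", "))
  out <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  out[sds == 0, ] <- 0
  out
}

#' Principal component ordination of community compositions
#'
#' Column-centred PCA of a samples x strains relative-abundance matrix.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making scores reproducible across linear-algebra
#' backends. Components beyond the matrix rank carry zero variance.
#'
#' @param compositions Numeric samples x strains matrix.
#' @param n_components Number of components, `< min(dim(compositions))`.
#' @return List with `scores` (samples x components), `loadings`
#'   (strains x components) and `explained_variance` (fractions, summing
#'   to <= 1, non-increasing).
#' @export
ordinate <- function(compositions, n_components = 2L) {
  x <- as.matrix(compositions)
  if (nrow(x) < 3L) stop("need >= 3 samples")
  if (n_components >= min(dim(x)))
    stop("'n_components' must be < min(samples, strains)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  # fix the sign convention
  for (j in k) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ev <- ev[k]
  ev[ev < .Machine$double.eps * 100] <- 0
  list(scores = scores, loadings = loadings, explained_variance = ev)
}
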