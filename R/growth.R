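#' Construct a growth curve
#'
#' A single blank-corrected OD600 time series for one strain in one medium
#' (fresh medium or the spent medium of another strain).
#'
#' @param strain_id Strain identifier.
#' @param medium_id Medium identifier, e.g. `"fresh"` or `"SM_<strain>"`.
#' @param replicate Positive integer replicate index.
#' @param times Numeric vector of timepoints in hours, strictly increasing,
#'   at least 3 points.
#' @param od Numeric vector of OD600 readings, same length as `times`.
#'   Negative readings (possible after blank correction upstream) are
#'   clipped to zero.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(strain_id, medium_id, replicate, times, od) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) < 3L)
    stop("a growth curve needs at least 3 timepoints, got ", length(times))
  if (length(od) != length(times))
    stop("'times' and 'od' must have the same length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(od)))
    stop("'od' must be finite")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("'replicate' must be a positive integer")
  structure(
    list(strain_id = as.character(strain_id),
         medium_id = as.character(medium_id),
         replicate = replicate,
         times = times,
         od = pmax(od, 0)),
    class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s in %s (rep %d): %d points, %.1f-%.1f h, max OD %.3f\n",
              x$strain_id, x$medium_id, x$replicate, length(x$times),
              min(x$times), max(x$times), max(x$od)))
  invisible(x)
}

#' Blank-correct a growth curve
#'
#' Subtracts a blank OD value from every reading and clips at zero.
#'
#' @param curve A [growth_curve()].
#' @param blank_value Finite blank OD600 to subtract.
#' @return The corrected `growth_curve`; metadata unchanged.
#' @export
blank_correct <- function(curve, blank_value) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(blank_value) || length(blank_value) != 1L || !is.finite(blank_value))
    stop("'blank_value' must be a single finite number")
  curve$od <- pmax(curve$od - blank_value, 0)
  curve
}

#' Area under a growth curve
#'
#' Trapezoidal integral of OD600 over the recorded interval, in OD.h.
#'
#' @param curve A [growth_curve()] (or any list with `times`/`od`).
#' @return Non-negative area in OD.h.
#' @export
compute_auc <- function(curve) {
  t <- curve$times
  y <- curve$od
  if (length(t) < 2L) stop("AUC needs at least 2 points")
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Maximum specific growth rate from a growth curve
#'
#' Sliding-window log-linear regression: the maximum slope of `ln(OD)` versus
#' time over all contiguous windows of `window_points` readings whose OD all
#' exceed `min_od`. The conventional batch-culture estimator of the maximum
#' specific growth rate.
#'
#' @param curve A [growth_curve()].
#' @param window_points Window width in points (>= 3).
#' @param min_od Only readings above this OD enter a window (> 0); keeps the
#'   estimate off the noise floor.
#' @return Rate in 1/h; 0 (with a warning) if no eligible window exists or
#'   the best slope is negative.
#' @export
estimate_growth_rate <- function(curve, window_points = 5L, min_od = 0.02) {
  stopifnot(window_points >= 3L, min_od > 0)
  t <- curve$times
  y <- curve$od
  ok <- y > min_od
  n <- length(t)
  if (n < window_points || !any(ok)) {
    warning("no readings above min_od; returning growth rate 0")
    return(0)
  }
  best <- 0
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    if (!all(ok[idx])) next
    tw <- t[idx]
    lw <- log(y[idx])
    # closed-form simple-regression slope
    slope <- stats::cov(tw, lw) / stats::var(tw)
    if (slope > best) best <- slope
  }
  if (best == 0 && !all(ok))
    best <- 0  # flat or declining curve
  best
}

#' Classify a growth rate
#'
#' Rate classes for defined-community strains: fast (> 1.5/h),
#' intermediate (> 1/h), slow (<= 1/h). Boundaries follow the strict ">"
#' convention of the upper classes, so exactly 1.0 is slow and exactly 1.5
#' is intermediate.
#'
#' @param rate Non-negative growth rate in 1/h (vectorised).
#' @return Character vector in `c("fast", "intermediate", "slow")`.
#' @export
classify_growth_rate <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("'rate' must be finite and non-negative")
  ifelse(rate > 1.5, "fast", ifelse(rate > 1, "intermediate", "slow"))
}

#' Normalized spent-medium inhibition factor (d_AUC)
#'
#' `d_AUC = (mean(AUC_SM) - mean(AUC_fresh)) / mean(AUC_fresh)`: the growth
#' of a consumer strain in a producer's spent medium relative to fresh
#' medium, averaged over replicate experiments. Values below -0.5 are
#' flagged as strong inhibition (strict inequality).
#'
#' @param auc_sm Replicate AUCs (OD.h) of the consumer in the spent medium.
#' @param auc_fresh Replicate AUCs of the same strain in fresh medium;
#'   mean must be positive.
#' @param producer_strain,consumer_strain Optional identifiers carried into
#'   the record.
#' @param per_replicate Also keep per-replicate d_AUC values (paired by
#'   position, recycled mean otherwise) for uncertainty estimates.
#' @return One-row data.frame with columns `producer_strain`,
#'   `consumer_strain`, `auc_sm_mean`, `auc_fresh_mean`, `d_auc`,
#'   `strong_inhibition`.
#' @export
compute_inhibition_factor <- function(auc_sm, auc_fresh,
                                      producer_strain = NA_character_,
                                      consumer_strain = NA_character_,
                                      per_replicate = FALSE) {
  if (!length(auc_sm) || !length(auc_fresh))
    stop("replicate AUC lists must be non-empty")
  m_sm <- mean(auc_sm)
  m_fr <- mean(auc_fresh)
  if (!is.finite(m_fr) || m_fr <= 0)
    stop("mean fresh-medium AUC must be positive (got ", m_fr, ")")
  d <- (m_sm - m_fr) / m_fr
  rec <- data.frame(producer_strain = as.character(producer_strain),
                    consumer_strain = as.character(consumer_strain),
                    auc_sm_mean = m_sm, auc_fresh_mean = m_fr,
                    d_auc = d, strong_inhibition = d < -0.5,
                    stringsAsFactors = FALSE)
  if (per_replicate)
    attr(rec, "d_auc_replicates") <- (auc_sm - m_fr) / m_fr
  rec
}

#' Assemble the producer x consumer inhibition matrix
#'
#' @param records data.frame of inhibition records
#'   ([compute_inhibition_factor()] rows bound together) covering every
#'   ordered (producer, consumer) pair including self-pairs.
#' @param strains Ordered strain identifiers defining rows and columns.
#' @return An `inhibition_matrix`: list with `strains`, `d_auc` (rows = SM
#'   producer, columns = growing strain), `strong` (logical matrix),
#'   `per_producer_strong_counts` (strong inhibitions of *other* strains per
#'   producer) and `strongly_inhibiting_producers` (number of producers whose
#'   SM strongly inhibits at least one other strain).
#' @export
build_inhibition_matrix <- function(records, strains) {
  strains <- as.character(strains)
  need <- expand.grid(producer = strains, consumer = strains,
                      stringsAsFactors = FALSE)
  key <- paste(records$producer_strain, records$consumer_strain, sep = "\r")
  want <- paste(need$producer, need$consumer, sep = "\r")
  miss <- setdiff(want, key)
  if (length(miss))
    stop("missing (producer, consumer) pairs: ",
         paste(gsub("\r", " -> ", miss), collapse = ", "))
  S <- length(strains)
  d <- matrix(NA_real_, S, S, dimnames = list(producer = strains, consumer = strains))
  idx <- match(want, key)
  d[cbind(match(need$producer, strains), match(need$consumer, strains))] <-
    records$d_auc[idx]
  strong <- d < -0.5
  other <- strong
  diag(other) <- FALSE
  counts <- rowSums(other)
  structure(
    list(strains = strains, d_auc = d, strong = strong,
         per_producer_strong_counts = counts,
         strongly_inhibiting_producers = sum(counts > 0)),
    class = "inhibition_matrix")
}

#' @export
print.inhibition_matrix <- function(x, ...) {
  cat(sprintf("<inhibition_matrix> %d strains; %d producers strongly inhibit >=1 other strain\n",
              length(x$strains), x$strongly_inhibiting_producers))
  invisible(x)
}

#' Spent/double-spent medium pH accounting
#'
#' Decomposes medium acidification into the shift caused by the producer
#' (`delta_ph_sm = ph_sm - ph_fresh`) and the further shift caused by the
#' consumer growing in the spent medium
#' (`delta_ph_dsm = ph_dsm - ph_sm`), so that
#' `ph_fresh + delta_ph_sm + delta_ph_dsm = ph_dsm`.
#'
#' @param ph_fresh,ph_sm,ph_dsm pH values in \[0, 14\]; `ph_dsm` may be `NA`
#'   when no double-spent measurement exists.
#' @param strain_id,medium_id Optional identifiers.
#' @return One-row data.frame with the pH values and both deltas.
#' @export
compute_delta_ph <- function(ph_fresh, ph_sm, ph_dsm = NA_real_,
                             strain_id = NA_character_, medium_id = NA_character_) {
  vals <- c(ph_fresh, ph_sm, ph_dsm)
  vals <- vals[!is.na(vals)]
  if (any(vals < 0 | vals > 14))
    stop("pH values must lie in [0, 14]")
  data.frame(strain_id = as.character(strain_id),
             medium_id = as.character(medium_id),
             ph_fresh = ph_fresh, ph_sm = ph_sm, ph_dsm = ph_dsm,
             delta_ph_sm = ph_sm - ph_fresh,
             delta_ph_dsm = ph_dsm - ph_sm,
             stringsAsFactors = FALSE)
}

#' Correlation with significance
#'
#' Pearson (default; two-sided p from the t-distribution with n - 2 df) or
#' Spearman rank correlation, with explicit guards for the degenerate cases
#' the plain `cor.test` would silently produce `NA` for.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with `r`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 pairs (got ", length(x), ")")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0) stop("zero variance in 'x'; correlation undefined")
  if (stats::var(y) == 0) stop("zero variance in 'y'; correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  data.frame(r = unname(ct$estimate), p_value = ct$p.value,
             n = length(x), method = method, stringsAsFactors = FALSE)
}

#' Summarise one growth curve
#'
#' @param curve A [growth_curve()].
#' @param window_points,min_od Passed to [estimate_growth_rate()].
#' @return One-row data.frame with `strain_id`, `medium_id`, `replicate`,
#'   `auc`, `growth_rate`, `max_od`, `rate_class`.
#' @export
summarise_growth <- function(curve, window_points = 5L, min_od = 0.02) {
  gr <- suppressWarnings(estimate_growth_rate(curve, window_points, min_od))
  data.frame(strain_id = curve$strain_id, medium_id = curve$medium_id,
             replicate = curve$replicate,
             auc = compute_auc(curve), growth_rate = gr,
             max_od = max(curve$od),
             rate_class = classify_growth_rate(gr),
             stringsAsFactors = FALSE)
}
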