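#' qPCR standard curve
#'
#' Strain-specific calibration `Cq = intercept + slope * log10(copies)`.
#' The amplification efficiency implied by the slope,
#' `10^(-1/slope) - 1`, must be positive and at most 1.2 (a perfect
#' doubling per cycle gives slope -3.3219 and efficiency 1).
#'
#' @param strain_id Strain identifier.
#' @param slope Cq per log10(copies); must be negative.
#' @param intercept Cq at 1 copy.
#' @param cq_range Optional calibration range `c(min_cq, max_cq)`; values
#'   quantified outside it are flagged.
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(strain_id, slope, intercept, cq_range = NULL) {
  if (!is.finite(slope) || slope >= 0) stop("'slope' must be negative")
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.2)
    stop(sprintf("implied efficiency %.3f outside (0, 1.2]; check the slope", eff))
  if (!is.null(cq_range)) stopifnot(length(cq_range) == 2L, diff(cq_range) > 0)
  structure(list(strain_id = as.character(strain_id), slope = slope,
                 intercept = intercept, efficiency = eff, cq_range = cq_range),
            class = "standard_curve")
}

#' Absolute quantification from a Cq value
#'
#' `copies = dilution_factor * 10^((cq - intercept) / slope)`; monotone
#' decreasing in Cq. If the curve carries a calibration range and the Cq
#' falls outside it, the value is still returned but carries an
#' `out_of_range` attribute.
#'
#' @param cq Finite quantification-cycle value(s); vectorised.
#' @param curve A [standard_curve()].
#' @param dilution_factor Positive scale factor back to the original sample.
#' @return Copy number(s), with attribute `out_of_range` (logical vector).
#' @export
quantify_from_cq <- function(cq, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"), dilution_factor > 0)
  if (any(!is.finite(cq))) stop("'cq' must be finite")
  copies <- dilution_factor * 10^((cq - curve$intercept) / curve$slope)
  oor <- if (is.null(curve$cq_range)) rep(FALSE, length(cq))
         else cq < curve$cq_range[1] | cq > curve$cq_range[2]
  attr(copies, "out_of_range") <- oor
  copies
}

#' Co-culture to monoculture abundance ratio (r_bm)
#'
#' Per independent experiment, the focal strain's absolute abundance at the
#' 72 h endpoint in co-culture divided by its abundance in monoculture
#' (paired by experiment index), then averaged across experiments.
#'
#' @param co,mono Equal-length replicate copy numbers at the endpoint,
#'   paired by position (experiment).
#' @param strain_id,partner_id Optional identifiers.
#' @return An `rbm_result`: list with `strain_id`, `partner_id`,
#'   `per_replicate_ratios`, `mean_ratio`. Replicates with zero monoculture
#'   copies are excluded with a warning; all excluded is an error.
#' @export
compute_rbm <- function(co, mono, strain_id = NA_character_,
                        partner_id = NA_character_) {
  if (length(co) != length(mono))
    stop("'co' and 'mono' must be paired by experiment (equal lengths)")
  usable <- mono > 0
  if (!all(usable))
    warning(sum(!usable), " replicate(s) with zero monoculture copies excluded")
  if (!any(usable)) stop("no usable replicates: all monoculture copies are zero")
  ratios <- co[usable] / mono[usable]
  structure(list(strain_id = as.character(strain_id),
                 partner_id = as.character(partner_id),
                 per_replicate_ratios = ratios,
                 mean_ratio = mean(ratios)),
            class = "rbm_result")
}

#' Classify a strain's co-culture effect sign
#'
#' Two-sided one-sample t-test of the replicate ratios against 1 (or of the
#' log-ratios against 0 with `log_ratio = TRUE`). Significant and mean > 1
#' is `+`, significant and mean < 1 is `-`, otherwise `0`. Degenerate
#' zero-variance replicate sets are signed by direction with a warning.
#'
#' @param result An [compute_rbm()] result.
#' @param alpha Significance level.
#' @param log_ratio Test `log(ratio)` against 0 instead of the raw ratios
#'   against 1 (ratio distributions are skewed; this variant is symmetric).
#' @return The `rbm_result` augmented with `p_value` and
#'   `sign` in `c("+", "0", "-")`.
#' @export
classify_effect <- function(result, alpha = 0.05, log_ratio = FALSE) {
  stopifnot(inherits(result, "rbm_result"))
  r <- result$per_replicate_ratios
  if (length(r) < 2L) stop("need >= 2 usable replicate ratios")
  x <- if (log_ratio) log(r) else r
  mu0 <- if (log_ratio) 0 else 1
  if (stats::var(x) == 0) {
    if (mean(x) == mu0) {
      result$p_value <- 1
      result$sign <- "0"
    } else {
      warning("zero variance in replicate ratios; sign assigned by direction")
      result$p_value <- 0
      result$sign <- if (mean(x) > mu0) "+" else "-"
    }
    return(result)
  }
  tt <- stats::t.test(x, mu = mu0, alternative = "two.sided")
  result$p_value <- tt$p.value
  result$sign <- if (tt$p.value >= alpha) "0"
                 else if (mean(x) > mu0) "+" else "-"
  result
}

#' Ecological interaction type from a sign pair
#'
#' Maps the unordered pair of per-strain effect signs onto the six classical
#' pairwise interaction types: (+,+) mutualism; (+,0) commensalism;
#' (0,0) neutralism; (0,-) amensalism; (-,-) competition; (+,-) predation.
#'
#' @param sign_a,sign_b Signs in `c("+", "0", "-")` (vectorised).
#' @return Character vector of type labels.
#' @export
interaction_type <- function(sign_a, sign_b) {
  valid <- c("+", "0", "-")
  if (!all(sign_a %in% valid) || !all(sign_b %in% valid))
    stop("signs must be one of '+', '0', '-'")
  # canonicalise the unordered pair with an explicit sign order
  # (locale-independent, unlike character pmin/pmax)
  ord <- c("+" = 1L, "0" = 2L, "-" = 3L)
  a <- ord[sign_a]; b <- ord[sign_b]
  key <- paste(pmin(a, b), pmax(a, b))
  map <- c("1 1" = "mutualism",
           "1 2" = "commensalism",
           "2 2" = "neutralism",
           "2 3" = "amensalism",
           "3 3" = "competition",
           "1 3" = "predation")
  unname(map[key])
}

#' Build the pairwise interaction network
#'
#' From endpoint qPCR abundances of all monocultures and all pairwise
#' co-cultures, computes r_bm for both members of every unordered pair,
#' classifies each side's sign, assigns the interaction type, and tallies
#' the census.
#'
#' @param abundances data.frame with columns `strain`, `culture_type`
#'   (`"mono"` or `"pair"`), `partner` (`NA` for monocultures), `timepoint_h`,
#'   `replicate`, `copies`.
#' @param alpha Significance level for the sign tests.
#' @param endpoint_h Endpoint timepoint (default 72).
#' @param log_ratio Passed to [classify_effect()].
#' @return An `interaction_network`: list with `edges` (data.frame:
#'   `strain_a`, `strain_b`, `mean_rbm_a`, `mean_rbm_b`, `p_a`, `p_b`,
#'   `sign_a`, `sign_b`, `type`), `census` (named counts over the six
#'   types), `negative_out_counts` (per strain, number of partners it
#'   affects negatively) and `strains`.
#' @export
build_interaction_network <- function(abundances, alpha = 0.05,
                                      endpoint_h = 72, log_ratio = FALSE) {
  need <- c("strain", "culture_type", "partner", "timepoint_h", "replicate", "copies")
  if (!all(need %in% names(abundances)))
    stop("abundances must have columns: ", paste(need, collapse = ", "))
  ab <- abundances[abundances$timepoint_h == endpoint_h, ]
  mono <- ab[ab$culture_type == "mono", ]
  pair <- ab[ab$culture_type == "pair", ]
  strains <- sort(unique(mono$strain))
  S <- length(strains)
  combos <- utils::combn(strains, 2)
  # completeness check
  gaps <- character()
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    if (!any(pair$strain == a & pair$partner == b) ||
        !any(pair$strain == b & pair$partner == a))
      gaps <- c(gaps, paste(a, b, sep = "~"))
  }
  miss_mono <- setdiff(unique(pair$strain), strains)
  if (length(gaps) || length(miss_mono))
    stop("incomplete design; missing pairs: ",
         paste(gaps, collapse = ", "),
         if (length(miss_mono)) paste0("; missing monocultures: ",
                                       paste(miss_mono, collapse = ", ")))
  mono_copies <- function(s) {
    x <- mono[mono$strain == s, ]
    x$copies[order(x$replicate)]
  }
  side <- function(focal, partner) {
    x <- pair[pair$strain == focal & pair$partner == partner, ]
    co <- x$copies[order(x$replicate)]
    classify_effect(compute_rbm(co, mono_copies(focal), focal, partner),
                    alpha = alpha, log_ratio = log_ratio)
  }
  edges <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    ra <- side(a, b); rb <- side(b, a)
    data.frame(strain_a = a, strain_b = b,
               mean_rbm_a = ra$mean_ratio, mean_rbm_b = rb$mean_ratio,
               p_a = ra$p_value, p_b = rb$p_value,
               sign_a = ra$sign, sign_b = rb$sign,
               type = interaction_type(ra$sign, rb$sign),
               stringsAsFactors = FALSE)
  }))
  types <- c("mutualism", "commensalism", "neutralism", "amensalism",
             "competition", "predation")
  census <- stats::setNames(integer(length(types)), types)
  tab <- table(edges$type)
  census[names(tab)] <- as.integer(tab)
  neg_out <- stats::setNames(integer(S), strains)
  for (i in seq_len(nrow(edges))) {
    if (edges$sign_b[i] == "-") neg_out[edges$strain_a[i]] <- neg_out[edges$strain_a[i]] + 1L
    if (edges$sign_a[i] == "-") neg_out[edges$strain_b[i]] <- neg_out[edges$strain_b[i]] + 1L
  }
  structure(list(strains = strains, edges = edges, census = census,
                 negative_out_counts = neg_out),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d strains, %d edges\n",
              length(x$strains), nrow(x$edges)))
  print(x$census)
  invisible(x)
}

#' r_bm matrix (focal strain x partner)
#'
#' @param network An [build_interaction_network()] result.
#' @return Numeric matrix, rows = focal strain, columns = partner; `NA` on
#'   the diagonal.
#' @export
rbm_matrix <- function(network) {
  s <- network$strains
  m <- matrix(NA_real_, length(s), length(s), dimnames = list(focal = s, partner = s))
  e <- network$edges
  m[cbind(match(e$strain_a, s), match(e$strain_b, s))] <- e$mean_rbm_a
  m[cbind(match(e$strain_b, s), match(e$strain_a, s))] <- e$mean_rbm_b
  m
}
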