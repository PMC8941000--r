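# Readers and writers for the plain-text interchange formats the pipeline
# uses. All CSV is UTF-8, header required, decimal point.

#' Read long-format OD600 growth curves
#'
#' Expects columns `strain,medium,replicate,time_h,od600`.
#'
#' @param path CSV file path.
#' @param blank Blank OD to subtract from every reading (default 0).
#' @return List of [growth_curve()]s, one per (strain, medium, replicate).
#' @export
read_od_csv <- function(path, blank = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "medium", "replicate", "time_h", "od600")
  if (!all(need %in% names(df)))
    stop("OD CSV must have columns: ", paste(need, collapse = ", "))
  keys <- unique(df[, c("strain", "medium", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$strain == keys$strain[i] & df$medium == keys$medium[i] &
                df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$time_h), ]
    blank_correct(growth_curve(keys$strain[i], keys$medium[i],
                               keys$replicate[i], sub$time_h, sub$od600),
                  blank)
  })
}

#' Write growth curves to long-format CSV
#'
#' @param curves List of [growth_curve()]s.
#' @param path Output CSV path.
#' @export
write_od_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(strain = cu$strain_id, medium = cu$medium_id,
               replicate = cu$replicate, time_h = cu$times, od600 = cu$od,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pH table
#'
#' Expects columns `strain,medium,ph_fresh,ph_sm,ph_dsm`.
#'
#' @param path CSV file path.
#' @return data.frame of [compute_delta_ph()] records.
#' @export
read_ph_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "medium", "ph_fresh", "ph_sm", "ph_dsm")
  if (!all(need %in% names(df)))
    stop("pH CSV must have columns: ", paste(need, collapse = ", "))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    compute_delta_ph(df$ph_fresh[i], df$ph_sm[i], df$ph_dsm[i],
                     strain_id = df$strain[i], medium_id = df$medium[i])))
}

#' Read a metabolomic feature table and its sample metadata
#'
#' The TSV's first column is `feature_id`; remaining columns are sample
#' ids. The metadata CSV has columns `sample_id,condition,replicate,mode`.
#'
#' @param table_path Feature-intensity TSV path.
#' @param meta_path Sample-metadata CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(table_path, meta_path) {
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "feature_id")
    stop("first column of the feature TSV must be 'feature_id'")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$feature_id
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  feature_table(mat, meta)
}

#' Write a feature table to TSV + metadata CSV
#'
#' @param table A [feature_table()].
#' @param table_path,meta_path Output paths.
#' @export
write_feature_table <- function(table, table_path, meta_path) {
  df <- data.frame(feature_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(table$sample_meta, meta_path, row.names = FALSE)
  invisible(table_path)
}

#' Read a qPCR table
#'
#' Expects columns `strain,culture_id,culture_type,partner,timepoint_h,
#' replicate` plus either `cq` (converted through the standard curves) or
#' `copies`.
#'
#' @param path qPCR CSV path.
#' @param standards Optional named list of [standard_curve()]s (required
#'   when only `cq` is present) or a path to a standards CSV with columns
#'   `strain,slope,intercept`.
#' @param dilution_factor Passed to [quantify_from_cq()].
#' @return data.frame with a `copies` column, ready for
#'   [build_interaction_network()].
#' @export
read_qpcr_csv <- function(path, standards = NULL, dilution_factor = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "culture_id", "culture_type", "partner",
            "timepoint_h", "replicate")
  if (!all(need %in% names(df)))
    stop("qPCR CSV must have columns: ", paste(need, collapse = ", "))
  if (!"copies" %in% names(df)) {
    if (!"cq" %in% names(df)) stop("qPCR CSV needs a 'cq' or 'copies' column")
    if (is.null(standards))
      stop("standard curves are required to convert Cq to copies")
    if (is.character(standards)) standards <- read_standards_csv(standards)
    df$copies <- vapply(seq_len(nrow(df)), function(i) {
      cu <- standards[[df$strain[i]]]
      if (is.null(cu)) stop("no standard curve for strain ", df$strain[i])
      as.numeric(quantify_from_cq(df$cq[i], cu, dilution_factor))
    }, numeric(1))
  }
  df
}

#' Read qPCR standard curves
#'
#' Expects columns `strain,slope,intercept`.
#'
#' @param path Standards CSV path.
#' @return Named list of [standard_curve()]s.
#' @export
read_standards_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "slope", "intercept")
  if (!all(need %in% names(df)))
    stop("standards CSV must have columns: ", paste(need, collapse = ", "))
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i)
      standard_curve(df$strain[i], df$slope[i], df$intercept[i])),
    df$strain)
}

#' Write an inhibition matrix and its summary
#'
#' The CSV notes the orientation (rows = spent-medium producer, columns =
#' growing strain) in a leading comment line; the JSON summary carries the
#' per-producer strong-inhibition counts.
#'
#' @param x An [build_inhibition_matrix()] result.
#' @param csv_path,json_path Output paths.
#' @export
write_inhibition_matrix <- function(x, csv_path, json_path = NULL) {
  con <- file(csv_path, "w")
  writeLines("# rows = SM producer, columns = growing strain (d_AUC)", con)
  utils::write.csv(as.data.frame(x$d_auc), con)
  close(con)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(per_producer_strong_counts = as.list(x$per_producer_strong_counts),
           strongly_inhibiting_producers = x$strongly_inhibiting_producers),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}

#' Write an overlap matrix (percent and counts)
#'
#' Percentages are rounded half-up to one decimal in the report; the
#' counts CSV keeps exact integers.
#'
#' @param x An [overlap_matrix()] result.
#' @param percent_path,counts_path Output paths.
#' @export
write_overlap_matrix <- function(x, percent_path, counts_path = NULL) {
  con <- file(percent_path, "w")
  writeLines("# percent[i,j] = 100*|D_i & D_j|/|D_i|; rows = i", con)
  utils::write.csv(as.data.frame(round_half_up(x$percent, 1)), con)
  close(con)
  if (!is.null(counts_path))
    utils::write.csv(as.data.frame(x$counts), counts_path)
  invisible(percent_path)
}

#' Round half away from zero
#'
#' Plain decimal rounding (0.05 -> 0.1) as used in printed percentage
#' reports, rather than the banker's rounding of [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write an interaction-network edge list and census
#'
#' @param network An [build_interaction_network()] result.
#' @param edges_path Edge-list CSV path.
#' @param census_path Optional census JSON path.
#' @param rbm_path Optional r_bm matrix CSV path (rows = focal strain).
#' @export
write_interaction_network <- function(network, edges_path,
                                      census_path = NULL, rbm_path = NULL) {
  utils::write.csv(network$edges, edges_path, row.names = FALSE)
  if (!is.null(census_path))
    jsonlite::write_json(
      list(census = as.list(network$census),
           negative_out_counts = as.list(network$negative_out_counts),
           n_edges = nrow(network$edges)),
      census_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(rbm_path)) {
    con <- file(rbm_path, "w")
    writeLines("# rows = focal strain, columns = partner (mean r_bm)", con)
    utils::write.csv(as.data.frame(rbm_matrix(network)), con)
    close(con)
  }
  invisible(edges_path)
}
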