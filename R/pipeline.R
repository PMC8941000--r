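#' Run the full interaction-inference pipeline
#'
#' Wires the analysis stages end to end from a configuration: growth
#' phenotypes (AUCs, growth rates, d_AUC inhibition matrix, pH deltas),
#' metabolomic depletion profiles and overlaps, phylogenetic distances and
#' the phylogeny-metabolism correlation, the qPCR interaction network, and
#' community composition. Stages run only when their inputs are configured;
#' later stages that need an earlier one (e.g. the overlap-inhibition
#' correlation) are skipped with a note when it is absent. All interchange
#' is via files; rerunning with the same config and seed reproduces every
#' output byte for byte.
#'
#' @param config A list, or path to a YAML file, with (all optional unless
#'   noted):
#' \describe{
#'   \item{out_dir}{Output directory (required).}
#'   \item{seed}{Integer seed recorded in the manifest.}
#'   \item{alpha}{Significance level for all tests (default 0.05).}
#'   \item{growth}{List: `od_csv`, optional `ph_csv`, `blank` (default 0),
#'     `window` (default 5), `min_od` (default 0.02).}
#'   \item{metabolomics}{List: `table_tsv`, `meta_csv`.}
#'   \item{phylogeny}{List: `tree_newick` (path or string).}
#'   \item{network}{List: `qpcr_csv`, optional `standards_csv`.}
#'   \item{community}{List: `composition_csv` with columns
#'     `sample_id,strain,copies`, optional `detection_limit`.}
#' }
#' @return Invisibly, a list with the stage results and the summary; files
#'   are written under `out_dir` together with `run_manifest.json`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an 'out_dir'")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  results <- list()
  summary <- list(alpha = alpha, seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$growth)) {
    results$growth <- stage("growth", {
      g <- config$growth
      curves <- read_od_csv(g$od_csv, blank = if (is.null(g$blank)) 0 else g$blank)
      win <- if (is.null(g$window)) 5L else g$window
      mo <- if (is.null(g$min_od)) 0.02 else g$min_od
      summaries <- do.call(rbind, lapply(curves, summarise_growth,
                                         window_points = win, min_od = mo))
      utils::write.csv(summaries, file.path(out, "growth_summaries.csv"),
                       row.names = FALSE)
      strains <- sort(unique(summaries$strain_id[summaries$medium_id == "fresh"]))
      recs <- NULL
      for (p in strains) for (cns in strains) {
        sm <- summaries$auc[summaries$strain_id == cns &
                              summaries$medium_id == paste0("SM_", p)]
        fr <- summaries$auc[summaries$strain_id == cns &
                              summaries$medium_id == "fresh"]
        if (length(sm) && length(fr))
          recs <- rbind(recs, compute_inhibition_factor(sm, fr, p, cns))
      }
      inhib <- if (!is.null(recs) &&
                   nrow(recs) == length(strains)^2)
        build_inhibition_matrix(recs, strains) else NULL
      if (!is.null(inhib))
        write_inhibition_matrix(inhib, file.path(out, "inhibition_matrix.csv"),
                                file.path(out, "inhibition_summary.json"))
      ph <- if (!is.null(g$ph_csv)) read_ph_csv(g$ph_csv) else NULL
      if (!is.null(ph))
        utils::write.csv(ph, file.path(out, "ph_deltas.csv"), row.names = FALSE)
      list(summaries = summaries, inhibition = inhib, ph = ph)
    })
    if (!is.null(results$growth$inhibition))
      summary$strongly_inhibiting_producers <-
        results$growth$inhibition$strongly_inhibiting_producers
  }

  if (!is.null(config$metabolomics)) {
    results$metabolomics <- stage("metabolomics", {
      m <- config$metabolomics
      tab <- read_feature_table(m$table_tsv, m$meta_csv)
      profiles <- call_feature_changes(tab, alpha = alpha)
      for (p in profiles) {
        utils::write.csv(
          data.frame(feature_id = p$depleted),
          file.path(out, paste0("depleted_", p$strain_id, ".csv")),
          row.names = FALSE)
      }
      ov <- overlap_matrix(profiles)
      write_overlap_matrix(ov, file.path(out, "overlap_percent.csv"),
                           file.path(out, "overlap_counts.csv"))
      frac <- fraction_altered(profiles, nrow(tab$intensities))
      list(profiles = profiles, overlap = ov, fraction_altered = frac,
           n_features = nrow(tab$intensities))
    })
    summary$fraction_altered_percent <- results$metabolomics$fraction_altered
  }

  if (!is.null(config$phylogeny)) {
    results$phylogeny <- stage("phylogeny", {
      tree <- parse_newick(config$phylogeny$tree_newick)
      dm <- patristic_distances(tree)
      utils::write.csv(as.data.frame(dm$d),
                       file.path(out, "patristic_distances.csv"))
      dm
    })
  }

  correlations <- list()
  if (!is.null(results$metabolomics) && !is.null(results$phylogeny)) {
    shared <- intersect(results$metabolomics$overlap$strains,
                        results$phylogeny$strains)
    if (length(shared) >= 3) {
      keep <- function(ov, ids) {
        i <- match(ids, ov$strains)
        structure(list(strains = ids, percent = ov$percent[i, i],
                       counts = ov$counts[i, i], set_sizes = ov$set_sizes[i]),
                  class = "overlap_matrix")
      }
      dkeep <- structure(
        list(strains = shared,
             d = results$phylogeny$d[shared, shared]),
        class = "distance_matrix")
      correlations$distance_vs_shared <- stage(
        "correlation", shared_count_vs_distance(
          keep(results$metabolomics$overlap, shared), dkeep))
    }
  }
  if (!is.null(results$metabolomics) && !is.null(results$growth$inhibition)) {
    correlations$overlap_vs_inhibition <- stage(
      "correlation", overlap_vs_inhibition(results$metabolomics$overlap,
                                           results$growth$inhibition))
  }
  if (length(correlations)) {
    jsonlite::write_json(lapply(correlations, as.list),
                         file.path(out, "correlations.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$correlations <- correlations
    summary$correlations <- lapply(correlations, function(x)
      list(r = x$r, p_value = x$p_value, n = x$n))
  }

  if (!is.null(config$network)) {
    results$network <- stage("network", {
      nw <- config$network
      standards <- if (!is.null(nw$standards_csv))
        read_standards_csv(nw$standards_csv) else NULL
      ab <- read_qpcr_csv(nw$qpcr_csv, standards = standards)
      net <- build_interaction_network(ab, alpha = alpha)
      write_interaction_network(net, file.path(out, "interaction_edges.csv"),
                                file.path(out, "interaction_census.json"),
                                file.path(out, "rbm_matrix.csv"))
      net
    })
    summary$interaction_census <- as.list(results$network$census)
    summary$n_edges <- nrow(results$network$edges)
  }

  if (!is.null(config$community)) {
    results$community <- stage("community", {
      cm <- config$community
      df <- utils::read.csv(cm$composition_csv, stringsAsFactors = FALSE)
      if (!all(c("sample_id", "strain", "copies") %in% names(df)))
        stop("composition CSV needs sample_id, strain, copies")
      dl <- if (is.null(cm$detection_limit)) 1e-4 else cm$detection_limit
      comp <- do.call(rbind, lapply(split(df, df$sample_id), function(s) {
        ra <- relative_abundance(stats::setNames(s$copies, s$strain),
                                 detection_limit = dl)
        ra$sample_id <- s$sample_id[1]
        ra
      }))
      rownames(comp) <- NULL
      utils::write.csv(comp, file.path(out, "composition.csv"),
                       row.names = FALSE)
      wide <- do.call(rbind, lapply(split(comp, comp$sample_id), function(s)
        stats::setNames(s$rel_abundance, s$strain)))
      ord <- if (nrow(wide) >= 3)
        ordinate(wide, n_components = min(2L, min(dim(wide)) - 1L)) else NULL
      if (!is.null(ord))
        utils::write.csv(data.frame(sample_id = rownames(wide), ord$scores),
                         file.path(out, "ordination_scores.csv"),
                         row.names = FALSE)
      list(composition = comp, ordination = ord)
    })
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    package = "ommnet",
    version = as.character(utils::packageVersion("ommnet")),
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    stages = names(results))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(summary = summary)))
}
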