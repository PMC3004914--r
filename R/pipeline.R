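## End-to-end orchestration: simulate -> extract -> profile ->
## correlate/cluster/classify, driven by a config list (or YAML file).

.BIOPHYS_COLUMNS <- c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "UD", "Rev", "tau_off_s")
.BIOPHYS_LOG <- c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "tau_off_s")
.CHEM_COLUMNS <- c("logP", "logD7_3", "MW", "PSA", "aromatic_atom_count",
                   "min_projection_area", "log_n_pka")

#' Default pipeline configuration
#'
#' Every analysis knob with its documented default. Unknown keys in a
#' user config are rejected by [read_config()] / [run_pipeline()].
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    drugs = NULL,             # drugs.csv (metadata; optional)
    recordings = NULL,        # recordings.csv (train protocol)
    availability = NULL,      # availability.csv
    descriptors = NULL,       # descriptors.csv (optional)
    out_dir = ".",
    n_anchor_trains = 3,      # trains averaged per anchor amplitude
    tau_clip_bounds = c(3, 500),  # s
    prepulse_for_kapp = -60,  # mV
    cluster_method = "wpgma",
    cluster_columns = .BIOPHYS_COLUMNS,
    cluster_log_columns = .BIOPHYS_LOG,
    classify_rel_tol = 0.01,
    seed = 1
  )
}

#' Read and validate a pipeline config (YAML)
#'
#' @param path YAML file with a subset of the [default_config()] keys.
#' @return Full config list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Write a config to YAML
#'
#' @param config config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Packaged machine-readable reference tables
#'
#' Returns the packaged per-drug reference tables: drug metadata
#' (`drugs`, 44 rows), train-protocol properties (`train`, 35 analyzed +
#' 9 dropout rows), availability-protocol properties (`availability`,
#' 38 rows: amitriptyline measured at three and riluzole at two
#' concentrations) and a synthetic chemical-descriptor table
#' (`descriptors`; constructed stand-in values, see its file
#' documentation).
#'
#' @return Named list of data.frames.
#' @export
fixture_tables <- function() {
  list(drugs = read_drug_table(sciblock_example("table1_drugs.csv")),
       train = utils::read.csv(sciblock_example("table2_train.csv"),
                               stringsAsFactors = FALSE),
       availability = utils::read.csv(sciblock_example("table3_availability.csv"),
                                      stringsAsFactors = FALSE),
       descriptors = read_descriptors(sciblock_example("descriptors_synthetic.csv")))
}

#' Merged analysis table from the packaged reference tables
#'
#' Joins the train- and availability-protocol reference tables over the
#' 35 analyzed drugs. Drugs measured at several concentrations in the
#' availability protocol (amitriptyline, riluzole) are combined by
#' geometric mean of their per-concentration affinities, and `SD` is
#' recomputed as `Kr/Ki_kapp` of the combined values.
#'
#' @return data.frame with one row per analyzed drug (35 rows).
#' @export
fixture_profiles <- function() {
  fx <- fixture_tables()
  train <- fx$train[fx$train$dropout == 0, ]
  av <- fx$availability
  gm_agg <- stats::aggregate(cbind(Kr_uM, Ki_dV_uM, Ki_kapp_uM) ~ drug_code,
                             data = av, FUN = geometric_mean)
  extra <- stats::aggregate(cbind(Inh_150, dV_half_mV) ~ drug_code, data = av,
                            FUN = mean)
  sd_tab <- merge(gm_agg, extra, by = "drug_code")
  sd_tab$SD <- sd_tab$Kr_uM / sd_tab$Ki_kapp_uM
  out <- merge(train[, setdiff(names(train), "dropout")], sd_tab, by = "drug_code")
  out[order(out$drug_code), , drop = FALSE]
}

.run_log <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Reads recordings and availability curves, computes per-drug profiles
#' (train and availability protocols), merges them, and runs the
#' downstream statistics: correlation matrix, hierarchical clustering
#' (exported as Newick plus a merge table), type classification and
#' radar export. All artifacts are written under `config$out_dir`;
#' deterministic for a fixed config.
#'
#' @param config config list (see [default_config()]) or path to a YAML
#'   file.
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0L)
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("sciblock run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("config: %s", paste(deparse(cfg[setdiff(names(cfg), "cluster_columns")]),
                                             collapse = "")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("[%s] %s", name, conditionMessage(e)))
  }

  if (is.null(cfg$recordings) || is.null(cfg$availability))
    .stopf("[input] config must name 'recordings' and 'availability' files")
  recs <- stage("read", read_recordings(cfg$recordings))
  avail <- stage("read", read_availability(cfg$availability))
  drugs <- if (!is.null(cfg$drugs)) stage("read", read_drug_table(cfg$drugs)) else NULL

  cc_for <- function(code, sub) {
    if (!is.null(drugs) && code %in% drugs$drug_code)
      return(drugs$concentration_tested_uM[match(code, drugs$drug_code)])
    if ("cc_uM" %in% names(sub)) return(sub$cc_uM[1])
    .stopf("no tested concentration known for drug %s", code)
  }

  prof_train <- stage("train_analysis", {
    do.call(rbind, lapply(split(recs, recs$drug_code), function(sub) {
      p <- profile_train(sub, cc_for(sub$drug_code[1], sub),
                         n_anchor_trains = cfg$n_anchor_trains,
                         clip_bounds = cfg$tau_clip_bounds)
      log_lines <<- c(log_lines, sprintf("train %s: n=%d", p$drug_code, p$n_cells))
      p
    }))
  })
  prof_av <- stage("state_dependence", {
    do.call(rbind, lapply(split(avail, avail$drug_code), function(sub) {
      p <- profile_availability(sub, cc_for(sub$drug_code[1], sub),
                                prepulse_for_kapp = cfg$prepulse_for_kapp)
      log_lines <<- c(log_lines, sprintf("availability %s: n=%d", p$drug_code, p$n_cells))
      p
    }))
  })
  profiles <- merge_profiles(prof_train, prof_av)

  paths <- list(profiles = file.path(cfg$out_dir, "profiles.csv"))
  write_profiles(profiles, paths$profiles)

  m <- stage("stats_classify",
             zscore(build_matrix(profiles, cfg$cluster_columns, cfg$cluster_log_columns)))
  cm <- correlation_matrix(m)
  paths$correlations <- file.path(cfg$out_dir, "correlations.csv")
  utils::write.csv(round(cm$r, 4), paths$correlations)
  paths$correlation_flags <- file.path(cfg$out_dir, "correlation_flags.csv")
  utils::write.csv(cm$flags, paths$correlation_flags)

  tree <- hcluster(m, method = cfg$cluster_method)
  paths$newick <- file.path(cfg$out_dir, "linkage.nwk")
  linkage_to_newick(tree, paths$newick)
  paths$merges <- file.path(cfg$out_dir, "linkage_merges.csv")
  utils::write.csv(merge_table(tree), paths$merges, row.names = FALSE)

  cls <- classify_types(profiles, default_type_rules(cfg$classify_rel_tol))
  paths$classification <- file.path(cfg$out_dir, "classification.csv")
  utils::write.csv(cls, paths$classification, row.names = FALSE)

  radar <- export_radar(profiles, cfg$cluster_columns, cfg$cluster_log_columns)
  paths$radar <- file.path(cfg$out_dir, "radar.csv")
  utils::write.csv(radar, paths$radar, row.names = FALSE)

  paths$log <- file.path(cfg$out_dir, "run_log.txt")
  .run_log(log_lines, paths$log)
  invisible(paths)
}
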