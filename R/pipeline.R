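run_config_defaults <- function() {
  list(
    seed = 1L,
    scenario = list(),   # overrides passed to scenario_config()
    trflp = list(channel = "forward", bin_width = 1, size_min = 34,
                 size_max = 966, rel_threshold = 0, enzyme_site = "GCGC",
                 cut_offset = 3L, scale = 10000),
    stats = list(n_perm = 9999L, n_boot = 10000L, n_null = 1000L,
                 alpha = 0.05),
    clone_library_size = 165L,
    verbose = FALSE
  )
}

#' Build and validate a full pipeline run configuration
#'
#' One nested list reaching every stage's parameters: the synthetic
#' scenario (`scenario`, passed through [scenario_config()]), the
#' fingerprinting settings (`trflp`), and the statistical settings
#' (`stats`).  Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (nested lists merged
#'   per key).
#' @return Object of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 7, scenario = list(otu_pool_size = 40))
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  merge_keys <- function(base, over, path) {
    if (path != "scenario.") {  # scenario keys validated by scenario_config
      unknown <- setdiff(names(over), names(base))
      if (length(unknown) > 0)
        stop("unknown config key(s): ",
             paste0(path, unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_keys(base[[k]], over[[k]], paste0(path, k, ".")) else over[[k]]
    }
    base
  }
  cfg <- merge_keys(cfg, over, "")
  # scenario overrides are validated by scenario_config itself
  if (!"seed" %in% names(cfg$scenario)) cfg$scenario$seed <- cfg$seed
  do.call(scenario_config, cfg$scenario)  # validation side-effect
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys mirror [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

pipeline_log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

write_sidecar <- function(path, stage, params) {
  jsonlite::write_json(
    list(stage = stage, parameters = params,
         package = as.character(utils::packageVersion("trflptools"))),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the full simulate-to-succession pipeline
#'
#' Executes simulate, digest, fingerprint, resemble, cluster, relate,
#' diversity and succession in order, writing every intermediate to a
#' stage-named subdirectory of `out_dir` plus a machine-readable
#' `summary.json`.  All randomness derives from the single configured
#' seed, so two runs with the same configuration produce byte-identical
#' numeric outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created; one flat run directory per
#'   invocation).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config"))
    stop("config must be a run_config object", call. = FALSE)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  summary <- list(seed = cfg$seed)

  ## 1: simulate --------------------------------------------------------
  pipeline_log(cfg, "stage 1: simulate")
  scen_cfg <- do.call(scenario_config, cfg$scenario)
  scenario <- generate_scenario(scen_cfg)
  d1 <- stage_dir("01_simulate")
  write_scenario(scenario, d1)
  write_sidecar(file.path(d1, "scenario"), "simulate", unclass(scen_cfg))

  ## 2: digest ----------------------------------------------------------
  pipeline_log(cfg, "stage 2: digest")
  trf <- digest_otus(scenario$otu_sequences,
                     site = cfg$trflp$enzyme_site,
                     cut_offset = cfg$trflp$cut_offset)
  d2 <- stage_dir("02_digest")
  utils::write.csv(trf, file.path(d2, "terminal_fragments.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sidecar(file.path(d2, "terminal_fragments.csv"), "digest",
                cfg$trflp[c("enzyme_site", "cut_offset")])

  ## 3: fingerprint -----------------------------------------------------
  pipeline_log(cfg, "stage 3: fingerprint")
  m <- as_sample_matrix(scenario)
  profiles <- lapply(rownames(m), function(id)
    profile_sample(m[id, ], trf, scale = cfg$trflp$scale, noise_cv = 0,
                   sample_id = id, channel = cfg$trflp$channel))
  fp <- bin_and_standardize(profiles, cfg$trflp$bin_width,
                            cfg$trflp$size_min, cfg$trflp$size_max,
                            cfg$trflp$rel_threshold)
  d3 <- stage_dir("03_fingerprint")
  write_peak_table(profiles, file.path(d3, "peaks.csv"))
  write_fingerprint(fp, file.path(d3, "fingerprint.csv"))
  write_sidecar(file.path(d3, "fingerprint.csv"), "fingerprint", cfg$trflp)

  ## 4: resemble --------------------------------------------------------
  pipeline_log(cfg, "stage 4: resemble")
  bc <- bray_curtis_matrix(fp)
  envd <- env_distance_matrix(scenario$metadata, env_variables())
  biod <- env_distance_matrix(scenario$metadata,
                              c("prokaryotic_abundance",
                                "leucine_incorporation"),
                              log_transform = "prokaryotic_abundance")
  d4 <- stage_dir("04_resemble")
  write_resemblance(bc, file.path(d4, "bray_curtis.csv"))
  write_resemblance(envd, file.path(d4, "env_distance.csv"))
  write_resemblance(biod, file.path(d4, "bio_distance.csv"))

  ## 5: cluster ---------------------------------------------------------
  pipeline_log(cfg, "stage 5: cluster")
  dend <- upgma(bc)
  d5 <- stage_dir("05_cluster")
  write_newick(dend, file.path(d5, "upgma.nwk"))

  ## 6: relate ----------------------------------------------------------
  pipeline_log(cfg, "stage 6: relate")
  # correlate community *distance* with environmental distance so that a
  # positive rho means concordant structure
  bc_dist <- new_resemblance(as_distance_values(bc), "distance",
                             "bray-curtis-dissimilarity")
  rel_env <- relate(bc_dist, envd, n_perm = cfg$stats$n_perm,
                    seed = derive_seed(cfg$seed, "relate"))
  rel_bio <- relate(bc_dist, biod, n_perm = cfg$stats$n_perm,
                    seed = derive_seed(cfg$seed, "relate") + 1L)
  d6 <- stage_dir("06_relate")
  rel_df <- data.frame(
    comparison = c("physico-chemical vs community",
                   "biological vs community"),
    rho = c(rel_env$rho, rel_bio$rho), p = c(rel_env$p, rel_bio$p),
    n_perm = cfg$stats$n_perm)
  utils::write.csv(format_num_df(rel_df), file.path(d6, "relate.csv"),
                   row.names = FALSE, quote = FALSE)

  ## 7: diversity -------------------------------------------------------
  pipeline_log(cfg, "stage 7: diversity")
  d7 <- stage_dir("07_diversity")
  wm_labels <- unique(scenario$metadata$water_mass)
  div_rows <- lapply(wm_labels, function(wm) {
    ids <- scenario$metadata$sample_id[scenario$metadata$water_mass == wm]
    pooled <- colMeans(fp[ids, , drop = FALSE])
    ds <- diversity_summary(pooled)
    data.frame(water_mass = wm, technique = "TRFLP", S_obs = ds$S_obs,
               H_prime = ds$H_prime, SR = NA_real_, chao1 = NA_real_)
  })
  # clone libraries from the central transect station
  central <- scenario$metadata$station[
    which.min(abs(scenario$metadata$along_path_km -
                  stats::median(unique(scenario$metadata$along_path_km))))]
  clone_rows <- lapply(wm_labels, function(wm) {
    sel <- scenario$metadata$sample_id[
      scenario$metadata$water_mass == wm &
      scenario$metadata$station == central][1]
    if (is.na(sel)) return(NULL)
    counts <- sample_clone_library(m[sel, ], cfg$clone_library_size,
                                   seed = derive_seed(cfg$seed, "clones"))
    ds <- diversity_summary(counts)
    data.frame(water_mass = wm, technique = "cloning", S_obs = ds$S_obs,
               H_prime = ds$H_prime, SR = ds$SR, chao1 = ds$chao1)
  })
  div <- do.call(rbind, c(div_rows, clone_rows))
  utils::write.csv(format_num_df(div), file.path(d7, "diversity.csv"),
                   row.names = FALSE, quote = FALSE)
  groups <- stats::setNames(scenario$metadata$group,
                            scenario$metadata$sample_id)
  inc <- incidence_summary(fp, groups)
  jsonlite::write_json(inc[c("n_total", "n_ubiquitous", "pct_ubiquitous",
                             "n_unique", "pct_unique",
                             "n_high_prevalence", "pct_high_prevalence")],
                       file.path(d7, "incidence.json"),
                       auto_unbox = TRUE, digits = NA)
  first_clone <- clone_rows[[which(!vapply(clone_rows, is.null, TRUE))[1]]]
  rar_counts <- sample_clone_library(
    m[scenario$metadata$sample_id[
        scenario$metadata$water_mass == first_clone$water_mass &
        scenario$metadata$station == central][1], ],
    cfg$clone_library_size, seed = derive_seed(cfg$seed, "clones"))
  rar <- rarefaction_curve(rar_counts,
                           unique(round(seq(0, sum(rar_counts),
                                            length.out = 25))))
  utils::write.csv(format_num_df(rar), file.path(d7, "rarefaction.csv"),
                   row.names = FALSE, quote = FALSE)

  ## 8: succession ------------------------------------------------------
  pipeline_log(cfg, "stage 8: succession")
  d8 <- stage_dir("08_succession")
  deep <- intersect(c("AAIW", "NADW", "AABW"), wm_labels)
  if (length(deep) == 0) deep <- wm_labels
  succ <- run_succession_analysis(bc, scenario$metadata,
                                  water_masses = deep,
                                  n_boot = cfg$stats$n_boot,
                                  n_null = cfg$stats$n_null,
                                  seed = cfg$seed)
  utils::write.csv(format_num_df(succ), file.path(d8, "succession.csv"),
                   row.names = FALSE, quote = FALSE)

  summary$incidence <- inc[c("n_total", "pct_ubiquitous", "pct_unique")]
  summary$relate <- rel_df
  summary$succession <- succ
  summary$n_samples <- nrow(fp)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipeline_log(cfg, "pipeline complete: ", out_dir)
  invisible(summary)
}
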