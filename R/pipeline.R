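#' Assemble a pipeline configuration
#'
#' Collects paths, tolerances and stage parameters for [run_screen()].
#' Either file paths (`native_mzml`, `metabolomics_mzml`) or in-memory
#' [ms_run()] objects (`native_run`, `metabolomics_run`) may be supplied.
#' A YAML file with the same keys can be loaded with [read_pipeline_config()].
#'
#' @param native_mzml,metabolomics_mzml mzML paths (optional if runs given).
#' @param native_run,metabolomics_run In-memory runs (optional).
#' @param apo_mass Apoprotein mass, Da; `NULL` triggers [apo_autodetect()].
#' @param mass_tol,rt_tol Matching tolerances (Da, minutes).
#' @param max_stoichiometry Largest ligand count per complex.
#' @param charge_range,peak_tol,min_charge_support Deconvolution parameters.
#' @param trace_window Mass-trace window, Da.
#' @param protein_min_height,metabolite_min_height Feature-detection floors.
#' @param mz_tol Metabolite trace/precursor linking tolerance, ppm.
#' @param score_threshold,min_matched,top_k Networking parameters.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the QC report.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(native_mzml = NULL, metabolomics_mzml = NULL,
                            native_run = NULL, metabolomics_run = NULL,
                            apo_mass = NULL, mass_tol = 4, rt_tol = 0.2,
                            max_stoichiometry = 2L,
                            charge_range = c(5L, 25L), peak_tol = 10,
                            min_charge_support = 3L, trace_window = 5,
                            protein_min_height = 1e3,
                            metabolite_min_height = 1e3, mz_tol = 10,
                            score_threshold = 0.7, min_matched = 6L,
                            top_k = 10L, out_dir = tempfile("nativems_"),
                            seed = 1L) {
  if (mass_tol <= 0 || rt_tol <= 0) stop("tolerances must be > 0")
  if (is.null(native_run) && is.null(native_mzml)) {
    stop("config error: supply native_mzml or native_run")
  }
  if (is.null(metabolomics_run) && is.null(metabolomics_mzml)) {
    stop("config error: supply metabolomics_mzml or metabolomics_run")
  }
  for (p in c(native_mzml, metabolomics_mzml)) {
    if (!is.null(p) && !file.exists(p)) stop("config error: input path not found: ", p)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the native-metabolomics screen end to end
#'
#' Deconvolutes the native run, builds neutral-mass traces and protein
#' features, detects metabolite features on the LC-MS/MS run, matches
#' complexes to ligands by mass offset and retention time, builds the
#' molecular/binding network, and writes the artifact bundle (feature
#' tables, match table, GraphML network, apo XIC with depletion calls, and
#' a QC report) to `config$out_dir`. The pipeline is a pure function of its
#' inputs and configuration: re-running it reproduces the tables exactly.
#'
#' @param config A [pipeline_config()].
#' @return List (invisible) with `protein_features`, `metabolite_features`,
#'   `matches`, `network`, `apo_mass`, `apo_xic`, `depletion`, `components`
#'   and `paths` of the written files.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  native <- .stage("read native run", {
    if (!is.null(config$native_run)) config$native_run else read_mzml(config$native_mzml)
  })
  met <- .stage("read metabolomics run", {
    if (!is.null(config$metabolomics_run)) config$metabolomics_run
    else read_mzml(config$metabolomics_mzml)
  })
  deconv <- .stage("deconvolution", deconvolve_run(
    native, charge_range = config$charge_range, peak_tol = config$peak_tol,
    min_charge_support = config$min_charge_support
  ))
  traces <- .stage("mass traces", build_mass_traces(deconv, window = config$trace_window))
  protein_features <- .stage("protein features", build_protein_features(
    traces, min_height = config$protein_min_height
  ))
  metabolite_features <- .stage("metabolite features", build_metabolite_features(
    met, mz_tol = config$mz_tol, min_height = config$metabolite_min_height
  ))
  apo_mass <- .stage("apo mass", {
    if (!is.null(config$apo_mass)) config$apo_mass
    else apo_autodetect(protein_features,
                        run_rt_range = range(run_rts(native, ms_level = 1L)))
  })
  complexes <- protein_features[abs(protein_features$mass_value - apo_mass) >
                                  config$mass_tol, , drop = FALSE]
  matches <- .stage("complex matching", match_complexes(
    complexes, metabolite_features, apo_mass = apo_mass,
    mass_tol = config$mass_tol, rt_tol = config$rt_tol,
    max_stoichiometry = config$max_stoichiometry
  ))
  ms2 <- .ms2_spectra(met)
  names(ms2) <- vapply(ms2, `[[`, character(1), "scan_id")
  network <- .stage("networking", build_network(
    metabolite_features, ms2, matches,
    score_threshold = config$score_threshold,
    min_matched = config$min_matched, top_k = config$top_k
  ))
  apo_xic <- extract_xic(deconv, apo_mass, window = config$trace_window)
  depletion <- detect_apo_depletion(apo_xic)
  components <- network_components(network)

  paths <- list(
    protein_features = file.path(config$out_dir, "features_protein.csv"),
    metabolite_features = file.path(config$out_dir, "features_metabolite.csv"),
    matches = file.path(config$out_dir, "matches.csv"),
    network = file.path(config$out_dir, "network.graphml"),
    apo_xic = file.path(config$out_dir, "apo_xic.csv"),
    qc_report = file.path(config$out_dir, "qc_report.txt")
  )
  .stage("write outputs", {
    write_feature_csv(protein_features, paths$protein_features)
    write_feature_csv(metabolite_features, paths$metabolite_features)
    m <- matches
    for (col in names(m)) if (is.numeric(m[[col]])) m[[col]] <- round(m[[col]], 6)
    utils::write.csv(m, paths$matches, row.names = FALSE)
    write_graphml(network, paths$network)
    utils::write.csv(within(apo_xic, intensity <- round(intensity, 3)),
                     paths$apo_xic, row.names = FALSE)
    writeLines(c(
      "nativems screen QC report",
      sprintf("seed: %d", config$seed),
      sprintf("apo mass: %.2f Da", apo_mass),
      sprintf("protein features: %d", nrow(protein_features)),
      sprintf("metabolite features: %d", nrow(metabolite_features)),
      sprintf("complex matches: %d (%d flagged stoichiometry >= 2)",
              nrow(matches), sum(matches$nonspecific_flag)),
      sprintf("apo depletion events (>30%% drop): %d", nrow(depletion)),
      if (nrow(depletion)) sprintf("  dip at %.2f min, depth %.0f%%",
                                   depletion$rt, 100 * depletion$depth),
      sprintf("network: %d nodes, %d edges, %d components",
              nrow(network$nodes), nrow(network$edges), nrow(components))
    ), paths$qc_report)
  })
  invisible(list(protein_features = protein_features,
                 metabolite_features = metabolite_features,
                 matches = matches, network = network, apo_mass = apo_mass,
                 apo_xic = apo_xic, depletion = depletion,
                 components = components, paths = paths))
}
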