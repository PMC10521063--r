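# End-to-end orchestration: synthetic scenario (or user tables) ->
# similarity matrices -> reactivity descriptors -> per-residue
# interaction-energy profiles and critical-residue ranking -> PLS QSAR
# statistics per component count -> consolidated CSV/JSON report. Every
# run is deterministic given (config, seed); artifacts are stamped with
# the seed and a hash of the resolved configuration.

#' Default pipeline configuration
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Output directory for the report bundle.
#' @return Named list of configuration values: scenario sizes
#'   (`n_ligands`, `n_residues`, `sigma`), `similarity_subset` (how many
#'   ligands enter the pairwise similarity stage), `operators`,
#'   `n_components` (PLS component counts reported), `align`,
#'   `alignment_mode` (`"structure"`, `"pose"` or `"pose+rescored"`;
#'   synthetic poses coincide with the structure frame) and `top_n`
#'   critical residues.
#' @export
pipeline_config <- function(seed = 42L, outdir = tempfile("mqsar_run_")) {
  list(seed = as.integer(seed), outdir = outdir,
       n_ligands = 40L, n_residues = 10L, sigma = 0.1,
       similarity_subset = 10L,
       operators = c("overlap", "coulomb"),
       n_components = c(2L, 5L, 7L),
       align = TRUE, alignment_mode = "structure", top_n = 4L)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Stages: (1) scenario generation; (2) pairwise quantum-similarity
#' matrices (Carbo + Euclidean) for the first `similarity_subset` ligands
#' under each configured operator; (3) reactivity descriptor table from
#' the generated orbital energies; (4) interaction-energy profiles for
#' all ligands against the shared pocket, with critical-residue ranking;
#' (5) PLS QSAR fits at each component count with training R2 and
#' leave-one-out q2. Each stage logs its row counts; any failure halts
#' with a stage-named error and partial outputs are left in place.
#'
#' @param config Configuration list from [pipeline_config()] (fields may
#'   be overridden before the call).
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with the stage objects, the written file
#'   paths, and the report (also serialised to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  req <- c("seed", "outdir", "n_ligands", "n_residues", "sigma",
           "operators", "n_components")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0)
    stop("invalid config: missing field(s) ", paste(miss, collapse = ", "))
  if (length(config$n_components) == 0)
    stop("invalid config: n_components must be nonempty")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  scen <- stage("scenario", {
    s <- synthetic_scenario(config$seed, n_ligands = config$n_ligands,
                            n_residues = config$n_residues,
                            sigma = config$sigma)
    log_("scenario", "%d ligands, %d residues, %d field columns, seed %d",
         length(s$ligands), config$n_residues, ncol(s$X), config$seed)
    s
  })

  sims <- stage("similarity", {
    sub <- scen$ligands[seq_len(min(config$similarity_subset,
                                    length(scen$ligands)))]
    out <- lapply(config$operators, function(op) {
      sm <- similarity_matrix(sub, operator = op, align = isTRUE(config$align))
      f1 <- file.path(config$outdir, paste0("similarity_", op, "_carbo.csv"))
      f2 <- file.path(config$outdir,
                      paste0("similarity_", op, "_euclidean.csv"))
      export_similarity_csv(sm, f1, "carbo")
      export_similarity_csv(sm, f2, "euclidean")
      paths[[paste0("similarity_", op)]] <<- c(f1, f2)
      log_("similarity", "%s: %d x %d matrix, %d pairs skipped",
           op, length(sm$labels), length(sm$labels), nrow(sm$skipped))
      sm
    })
    names(out) <- config$operators
    out
  })

  react <- stage("cdft", {
    tab <- reactivity_table(scen$descriptors$orbitals)
    f <- file.path(config$outdir, "reactivity.csv")
    write_reactivity_csv(tab, f)
    paths$reactivity <- f
    log_("cdft", "%d compounds", nrow(tab))
    tab
  })

  ie <- stage("ie", {
    tabs <- pocket_energy_tables(scen$ligands, scen$pocket$residues)
    profiles <- lapply(scen$ligands, function(lig)
      build_profile(tabs$complex_energies, tabs$ligand_energies,
                    tabs$residue_energies, lig$name,
                    series = paste0("site1-", attr(lig, "sub1"))))
    ranking <- rank_critical(profiles, top_n = config$top_n)
    f1 <- file.path(config$outdir, "ie_profiles.csv")
    f2 <- file.path(config$outdir, "critical_residues.csv")
    write_profiles_csv(profiles, f1)
    utils::write.csv(ranking, f2, row.names = FALSE, quote = FALSE)
    paths$ie <- c(f1, f2)
    log_("ie", "%d profiles x %d residues; top residue %s",
         length(profiles), nrow(ranking), ranking$residue[1])
    list(profiles = profiles, ranking = ranking)
  })

  qsar <- stage("comfa", {
    stats_rows <- lapply(config$n_components, function(nc) {
      fit <- fit_pls(scen$X, scen$activities, nc)
      data.frame(n_components = nc, r2 = fit$r2,
                 q2 = loo_q2(scen$X, scen$activities, nc),
                 steric_pct = unname(fit$contributions["steric"]),
                 electrostatic_pct = unname(
                   fit$contributions["electrostatic"]))
    })
    tab <- do.call(rbind, stats_rows)
    rownames(tab) <- NULL
    f <- file.path(config$outdir, "qsar_stats.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    paths$qsar <- f
    log_("comfa", "components %s -> q2 %s",
         paste(tab$n_components, collapse = "/"),
         paste(sprintf("%.3f", tab$q2), collapse = "/"))
    tab
  })

  # hash the scientific configuration only (output location excluded)
  hashed <- config[setdiff(sort(names(config)), "outdir")]
  cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(config$outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  report <- list(seed = config$seed, config_hash = cfg_hash,
                 alignment_mode = config$alignment_mode,
                 n_ligands = length(scen$ligands),
                 qsar = qsar,
                 critical_residues = ie$ranking,
                 reactivity_rows = nrow(react),
                 similarity_operators = config$operators)
  report_file <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths$report <- report_file
  invisible(list(scenario = scen, similarity = sims, reactivity = react,
                 ie = ie, qsar = qsar, report = report, paths = paths,
                 config = config))
}
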