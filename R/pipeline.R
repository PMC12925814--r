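# Pipeline driver: runs requested analysis stages on generated inputs,
# writes tidy CSV outputs plus a JSON run manifest, and renders simple
# figure panels from stage outputs. Numeric outputs never depend on
# report rendering.

pepscope_version <- function() {
  as.character(utils::packageVersion("pepscope"))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Run a multi-stage analysis pipeline
#'
#' Executes the requested stages in declared order on synthetic inputs
#' generated from the run seed, writing tidy CSV outputs and a run
#' manifest (`manifest.json`: command, resolved config, package
#' version, seed, output digests, timestamp) into the output directory.
#' A failing stage leaves completed stage outputs in place, writes an
#' error report, and raises an error.
#'
#' Recognised stages and their outputs:
#' \describe{
#'   \item{aggregate}{`clusters.csv` (frame, time, largest, n_clusters)
#'     and `aggregation_propensity.csv`}
#'   \item{lipid}{`lipid_contacts.csv`, `sasa.csv`, `ions.csv`}
#'   \item{complex}{`occupancy.csv`, `rmsd.csv`, `contact_map.csv`}
#'   \item{conserve}{`conservation.csv`, `consensus.txt`,
#'     `logo_matrix.json`}
#'   \item{dnds}{`per_codon_selection.csv`, `omega.json`}
#'   \item{fit}{`dose_response_fits.json`}
#' }
#'
#' @param config named list with elements `seed` (integer), `stages`
#'   (character vector of stage names), and optionally per-stage
#'   parameter lists under the stage name; or a path to a YAML/JSON
#'   file with that structure.
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly; stage outputs and `manifest.json`
#'   inside
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("aggregate", "lipid", "complex", "conserve", "dnds", "fit")
  if (is.null(config$stages) || !length(config$stages))
    stop("config error: no stages requested")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  for (stage in config$stages) {
    pars <- config[[stage]]
    res <- tryCatch({
      switch(stage,
             aggregate = stage_aggregate(pars, seed, out_dir),
             lipid = stage_lipid(pars, seed, out_dir),
             complex = stage_complex(pars, seed, out_dir),
             conserve = stage_conserve(pars, seed, out_dir),
             dnds = stage_dnds(pars, seed, out_dir),
             fit = stage_fit(pars, seed, out_dir))
      done <- c(done, stage)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      write_json_file(list(failed_stage = stage, error = res,
                           completed = done),
                      file.path(out_dir, "error_report.json"))
      stop("stage '", stage, "' failed: ", res)
    }
  }
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(command = "run_pipeline",
                   package_version = pepscope_version(),
                   seed = seed,
                   config = config,
                   outputs = as.list(tools::md5sum(
                     file.path(out_dir, outputs))),
                   timestamp = format(Sys.time(), tz = "UTC"))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

stage_aggregate <- function(pars, seed, out_dir) {
  gen <- do.call(gen_aggregation,
                 c(list(seed = seed),
                   pars[names(pars) %in% names(formals(gen_aggregation))]))
  series <- cluster_size_series(gen$trajectory)
  utils::write.csv(series, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  prop <- interpeptide_residue_propensity(gen$trajectory)
  utils::write.csv(prop, file.path(out_dir, "aggregation_propensity.csv"),
                   row.names = FALSE)
}

stage_lipid <- function(pars, seed, out_dir) {
  gen <- do.call(gen_lipid_interface,
                 c(list(seed = seed),
                   pars[names(pars) %in%
                          names(formals(gen_lipid_interface))]))
  traj <- gen$trajectory
  prof <- residue_lipid_contacts(traj, "headgroup")
  utils::write.csv(prof, file.path(out_dir, "lipid_contacts.csv"),
                   row.names = FALSE)
  heads <- select_particles(traj$system, tag = "headgroup")
  sasa <- sasa_series(traj, heads, label = "headgroup")
  utils::write.csv(sasa, file.path(out_dir, "sasa.csv"),
                   row.names = FALSE)
  ions <- ion_binding_series(traj)
  utils::write.csv(ions, file.path(out_dir, "ions.csv"),
                   row.names = FALSE)
}

stage_complex <- function(pars, seed, out_dir) {
  if (is.null(pars))
    pars <- list(specs = list(list(kind = "cation_pi",
                                   receptor_residue = 5L, p = 0.8)),
                 drift = 0.01)
  gen <- do.call(gen_complex,
                 c(list(seed = seed),
                   pars[names(pars) %in% names(formals(gen_complex))]))
  traj <- gen$trajectory
  occ <- lapply(gen$specs, function(sp) occupancy_series(traj, sp))
  occ_df <- data.frame(
    label = vapply(occ, `[[`, character(1), "label"),
    kind = vapply(occ, `[[`, character(1), "kind"),
    occupancy = vapply(occ, `[[`, numeric(1), "occupancy"),
    mean_distance = vapply(occ, `[[`, numeric(1), "mean_distance"),
    longest_event = vapply(occ, `[[`, integer(1), "longest_event"))
  utils::write.csv(occ_df, file.path(out_dir, "occupancy.csv"),
                   row.names = FALSE)
  rec <- select_particles(traj$system, kind = "receptor")
  pep <- select_particles(traj$system, kind = "peptide", site = "BB")
  rms <- rmsd_series(traj, fit_selection = rec, measure_selection = pep)
  utils::write.csv(rms, file.path(out_dir, "rmsd.csv"), row.names = FALSE)
  grp <- select_particles(traj$system, kind = "peptide",
                          tag = "cation_group")
  if (length(grp)) {
    cmap <- residue_group_contact_map(traj, grp, rec)
    utils::write.csv(cmap, file.path(out_dir, "contact_map.csv"),
                     row.names = FALSE)
  }
}

stage_conserve <- function(pars, seed, out_dir) {
  gen <- do.call(gen_msa,
                 c(list(seed = seed, preset = "conserved_his"),
                   pars[names(pars) %in%
                          setdiff(names(formals(gen_msa)), "preset")]))
  prof <- conservation_profile(gen$msa)
  utils::write.csv(prof, file.path(out_dir, "conservation.csv"),
                   row.names = FALSE)
  writeLines(as.character(consensus_sequence(gen$msa)),
             file.path(out_dir, "consensus.txt"))
  lm_ <- logo_matrix(gen$msa)
  write_json_file(list(frequencies = lm_$frequencies,
                       information = lm_$information),
                  file.path(out_dir, "logo_matrix.json"))
}

stage_dnds <- function(pars, seed, out_dir) {
  gen <- do.call(gen_codon_msa,
                 c(list(seed = seed),
                   pars[names(pars) %in% names(formals(gen_codon_msa))]))
  pcs <- per_codon_selection(gen$msa)
  utils::write.csv(pcs, file.path(out_dir, "per_codon_selection.csv"),
                   row.names = FALSE)
  om <- estimate_omega(gen$msa)
  write_json_file(list(method = "Nei-Gojobori 1986 (equal-weight pathways)",
                       omega = om$omega, dN = om$dN, dS = om$dS,
                       omega_defined = om$omega_defined,
                       planted_omega = gen$truth$omega),
                  file.path(out_dir, "omega.json"))
}

stage_fit <- function(pars, seed, out_dir) {
  if (is.null(pars))
    pars <- list(fourpl = list(bottom = 0, top = 100, ic50 = 1,
                               hill = 1.5),
                 isotherm = list(baseline = 0, amplitude = 1, kd = 2.45),
                 noise_sd = 0.02)
  g1 <- gen_dose_response("fourpl", pars$fourpl,
                          noise_sd = pars$noise_sd, seed = seed)
  g2 <- gen_dose_response("isotherm", pars$isotherm,
                          noise_sd = pars$noise_sd, seed = seed + 1L)
  f1 <- fit_4pl(g1$data)
  f2 <- fit_kd_isotherm(g2$data)
  write_json_file(list(
    fourpl = list(ic50 = f1$ic50, hill = f1$hill, bottom = f1$bottom,
                  top = f1$top, residual_norm = f1$residual_norm,
                  identified = f1$identified),
    isotherm = list(kd = f2$kd, amplitude = f2$amplitude,
                    baseline = f2$baseline,
                    residual_norm = f2$residual_norm,
                    identified = f2$identified)),
    file.path(out_dir, "dose_response_fits.json"))
}

#' Render figure panels and a summary table from pipeline outputs
#'
#' Reads the CSV outputs present in a pipeline output directory and
#' writes one PNG figure per recognised output (cluster-size series,
#' contact-profile bars, SASA series, RMSD series) plus
#' `summary_table.csv`. Missing stage outputs are listed in a warning;
#' rendering never alters numeric outputs. Requires ggplot2.
#'
#' @param out_dir a [run_pipeline()] output directory
#' @return invisible character vector of figure paths written
#' @export
render_report <- function(out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 required for report rendering")
  known <- c(clusters = "clusters.csv",
             lipid_contacts = "lipid_contacts.csv",
             sasa = "sasa.csv", rmsd = "rmsd.csv")
  present <- known[file.exists(file.path(out_dir, known))]
  if (!length(present)) {
    warning("no renderable outputs in ", out_dir)
    return(invisible(character()))
  }
  missing <- setdiff(known, present)
  if (length(missing))
    warning("missing stage outputs: ", paste(missing, collapse = ", "))
  figs <- character()
  summaries <- list()
  for (nm in names(present)) {
    df <- utils::read.csv(file.path(out_dir, present[[nm]]))
    gg <- switch(nm,
      clusters = ggplot2::ggplot(df, ggplot2::aes(x = time, y = largest)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "time (ns)", y = "largest cluster size"),
      lipid_contacts = ggplot2::ggplot(df,
          ggplot2::aes(x = factor(residue_index), y = contact_percentage)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "residue", y = "% of head-group contacts"),
      sasa = ggplot2::ggplot(df, ggplot2::aes(x = time, y = sasa)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (ns)", y = "SASA (nm^2)"),
      rmsd = ggplot2::ggplot(df, ggplot2::aes(x = time, y = rmsd)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (ns)", y = "RMSD (nm)"))
    path <- file.path(out_dir, paste0(nm, ".png"))
    ggplot2::ggsave(path, gg, width = 5, height = 3.5, dpi = 120)
    figs <- c(figs, path)
    num <- vapply(df, is.numeric, logical(1))
    summaries[[nm]] <- data.frame(
      output = nm, column = names(df)[num],
      mean = vapply(df[num], mean, numeric(1)),
      final = vapply(df[num], function(v) v[length(v)], numeric(1)))
  }
  st <- do.call(rbind, summaries)
  rownames(st) <- NULL
  utils::write.csv(st, file.path(out_dir, "summary_table.csv"),
                   row.names = FALSE)
  invisible(figs)
}
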