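# Multi-system orchestration: run every analysis stage over a set of
# trajectories sharing one pair of closed/open references, write
# machine-readable outputs (CSV / JSON / GraphML), and compare systems.
# The pipeline is a pure function of its configuration and input files:
# no stage is stochastic, so repeated runs produce byte-identical output.

REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full comparative analysis pipeline
#'
#' Stages per system, in fixed order: equilibration estimate on the
#' whole-protein RMSD (all later statistics use production frames only),
#' per-domain RMSD, RMSF, radius of gyration, domain distances and hinge
#' angle, delta-RMSD with state call, interaction persistence and the PSN
#' with hubs, and the inter-domain I-III table.  A failing stage is
#' recorded in the report (`errors`) and independent stages continue.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   `systems` (named list; each element a list with `trajectory` path and
#'   optionally `conformation`), `domains` (YAML path or [domain_set()]),
#'   `ref_closed`, `ref_open` (PDB paths), and optional `thresholds` (list
#'   with `k_min`, `threshold_frac`, `p_crit` overrides, `window`,
#'   `slope_tol`), `psn` (list passed to [psn_params()]).
#' @param out_dir output directory; created if needed.  `NULL` disables
#'   file output.
#' @return the report: a nested list (schema version, per-system results,
#'   cross-system comparison, error log).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$systems) || !length(config$systems))
    abort_config("config lists no systems")
  if (anyDuplicated(names(config$systems)))
    abort_config("system names must be unique")
  domains <- if (inherits(config$domains, "mdh_domains")) config$domains
             else read_domains_yaml(config$domains)
  for (nm in names(config$systems)) {
    tp <- config$systems[[nm]]$trajectory
    if (is.null(tp) || !file.exists(tp))
      abort_config(sprintf("system '%s': trajectory file not found (%s)", nm, tp))
  }
  thr <- config$thresholds
  k_min <- if (!is.null(thr$k_min)) thr$k_min else c(4L, 6L)
  threshold_frac <- if (!is.null(thr$threshold_frac)) thr$threshold_frac else 0.2
  pp <- do.call(psn_params, if (is.null(config$psn)) list() else config$psn)

  ref_closed <- traj_frame(read_multimodel_pdb(config$ref_closed), 1L)
  ref_open <- traj_frame(read_multimodel_pdb(config$ref_open), 1L)

  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 parameters = list(k_min = k_min, threshold_frac = threshold_frac,
                                   psn_mode = pp$mode, psn_cutoffs = as.list(pp$cutoffs)),
                 systems = list(), errors = list())
  psn_graphs <- list()

  for (nm in names(config$systems)) {
    sysdir <- if (!is.null(out_dir)) file.path(out_dir, nm) else NULL
    if (!is.null(sysdir)) dir.create(sysdir, showWarnings = FALSE)
    res <- list(conformation = config$systems[[nm]]$conformation)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        report$errors[[length(report$errors) + 1L]] <<-
          list(system = nm, stage = name, message = conditionMessage(e))
        NULL
      })
    }
    traj <- stage("read", read_multimodel_pdb(config$systems[[nm]]$trajectory))
    if (is.null(traj)) { report$systems[[nm]] <- res; next }
    ca <- select_atoms(traj, "CA")

    rmsd <- stage("rmsd", rmsd_series(traj, 1L, ca))
    prod_start <- 1L
    if (!is.null(rmsd)) {
      teq <- stage("equilibration",
                   estimate_equilibration(rmsd, window = thr$window,
                                          slope_tol = if (is.null(thr$slope_tol)) 0.02
                                                      else thr$slope_tol))
      res$t_eq_ns <- if (is.null(teq)) NA_real_ else as.numeric(teq)
      res$equilibrated <- !is.na(res$t_eq_ns)
      if (res$equilibrated) prod_start <- attr(teq, "frame")
      if (!is.null(sysdir)) write_metric_series(rmsd, file.path(sysdir, "rmsd.csv"))
    }
    res$production_start_frame <- prod_start

    dom_rmsd <- stage("per_domain_rmsd", per_domain_rmsd(traj, 1L, domains))
    if (!is.null(dom_rmsd) && !is.null(sysdir))
      for (dn in names(dom_rmsd))
        write_metric_series(dom_rmsd[[dn]], file.path(sysdir, paste0("rmsd_domain_", dn, ".csv")))

    rmsf <- stage("rmsf", rmsf_profile(traj, ca, offset = domains$offset))
    if (!is.null(rmsf)) {
      res$rmsf_mean <- mean(rmsf$values)
      if (!is.null(sysdir))
        write.csv(data.frame(residue = rmsf$residues, rmsf_angstrom = rmsf$values),
                  file.path(sysdir, "rmsf.csv"), row.names = FALSE)
    }

    rg <- stage("rg", radius_of_gyration(traj))
    if (!is.null(rg)) {
      res$rg_mean <- mean(rg$values[prod_start:length(rg$values)])
      if (!is.null(sysdir)) write_metric_series(rg, file.path(sysdir, "rg.csv"))
    }

    geom <- stage("geometry", {
      com <- domain_centers(traj, domains, "com")
      cog <- domain_centers(traj, domains, "cog")
      list(dist = interdomain_distance(com, "I", "III"),
           angle = hinge_angle(cog, "I", "II", "III"))
    })
    if (!is.null(geom)) {
      res$distance_I_III_mean <- mean(geom$dist$values[prod_start:length(geom$dist$values)])
      res$angle_mean <- mean(geom$angle$values[prod_start:length(geom$angle$values)])
      if (!is.null(sysdir)) {
        write_metric_series(geom$dist, file.path(sysdir, "distance_I_III.csv"))
        write_metric_series(geom$angle, file.path(sysdir, "angle_I_II_III.csv"))
      }
    }

    dser <- stage("delta_rmsd", delta_rmsd(traj, ref_closed$coords, ref_open$coords, ca))
    if (!is.null(dser)) {
      call_ <- classify_state(dser, threshold_frac, prod_start)
      res$delta_mean <- mean(dser$delta[prod_start:length(dser$delta)])
      res$delta_D <- dser$D
      res$state_call <- call_$system_label
      res$state_fractions <- as.list(call_$fractions)
      if (!is.null(sysdir))
        write.csv(data.frame(time_ns = dser$times, sigma_closed = dser$sigma_closed,
                             sigma_open = dser$sigma_open, delta = dser$delta),
                  file.path(sysdir, "delta_rmsd.csv"), row.names = FALSE)
    }

    psn_res <- stage("psn", {
      recs <- do.call(rbind, lapply(c("SB", "HB", "HC"), function(cl)
        interaction_persistence(traj, cl, pp, prod_start, offset = domains$offset)))
      pc_hc <- if (!is.null(thr$p_crit)) thr$p_crit
               else {
                 hc <- recs[recs$class == "HC", , drop = FALSE]
                 pc <- tryCatch(as.numeric(persistence_threshold(hc)),
                                error = function(e) 0.5)
                 c(SB = pc, HB = pc, HC = pc)
               }
      list(records = recs,
           psn = build_psn(recs, pc_hc, nodes = sort(unique(traj$atoms$resno)) - domains$offset),
           p_crit = pc_hc)
    })
    if (!is.null(psn_res)) {
      res$p_crit <- as.list(psn_res$p_crit)
      res$n_edges <- nrow(psn_res$psn$edges)
      psn_graphs[[nm]] <- psn_res$psn
      tab <- stage("interdomain_table",
                   interdomain_table(psn_res$records, psn_res$p_crit, domains, "I", "III"))
      res$interdomain_I_III <- tab
      if (!is.null(sysdir)) {
        write.csv(psn_res$records, file.path(sysdir, "psn_records.csv"), row.names = FALSE)
        write.csv(psn_res$psn$edges, file.path(sysdir, "psn_edges.csv"), row.names = FALSE)
        write_psn_graphml(psn_res$psn, file.path(sysdir, "psn.graphml"))
        if (!is.null(tab))
          write.csv(tab, file.path(sysdir, "interdomain_I_III.csv"), row.names = FALSE)
      }
    }
    report$systems[[nm]] <- res
  }

  if (length(psn_graphs)) {
    for (km in k_min) {
      hubs <- find_hubs(psn_graphs, km)
      report[[paste0("hubs_k", km)]] <- hubs
      if (!is.null(out_dir))
        write.csv(hubs, file.path(out_dir, sprintf("hubs_k%d.csv", km)),
                  row.names = FALSE)
    }
    labels <- vapply(report$systems, function(s)
      if (is.null(s$conformation)) "" else s$conformation, character(1))
    op <- names(psn_graphs)[match("open", labels[names(psn_graphs)])]
    cl <- names(psn_graphs)[match("closed", labels[names(psn_graphs)])]
    if (!is.na(op) && !is.na(cl)) {
      dd <- delta_degree(psn_graphs[[op]], psn_graphs[[cl]])
      report$delta_degree <- dd
      if (!is.null(out_dir))
        write.csv(dd, file.path(out_dir, "delta_degree_open_vs_closed.csv"),
                  row.names = FALSE)
    }
  }

  if (length(report$systems) >= 2L)
    report$comparison <- compare_systems(report, threshold_frac)

  if (!is.null(out_dir)) {
    summary <- report
    summary$systems <- lapply(summary$systems, function(s) {
      s$interdomain_I_III <- NULL
      s
    })
    for (km in k_min) summary[[paste0("hubs_k", km)]] <- NULL
    summary$delta_degree <- NULL
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

#' Cross-system comparison table
#'
#' Production-run means (and state flags) of the delta-RMSD progress
#' variable, radius of gyration, I-III distance and hinge angle, one row
#' per system; systems whose mean delta lies inside the intermediate band
#' (`|delta| <= threshold_frac * D`) are flagged.
#'
#' @param report a [run_pipeline()] report.
#' @param threshold_frac intermediate band as a fraction of the
#'   inter-reference RMSD (default 0.2).
#' @return data frame, one row per analysed system.
#' @export
compare_systems <- function(report, threshold_frac = 0.2) {
  sys <- report$systems
  if (length(sys) < 2L) abort_config("need at least 2 analysed systems to compare")
  get_num <- function(s, f) if (is.null(s[[f]])) NA_real_ else s[[f]]
  df <- data.frame(
    system = names(sys),
    state_call = vapply(sys, function(s)
      if (is.null(s$state_call)) NA_character_ else s$state_call, character(1)),
    delta_mean = vapply(sys, get_num, numeric(1), f = "delta_mean"),
    rg_mean = vapply(sys, get_num, numeric(1), f = "rg_mean"),
    distance_I_III_mean = vapply(sys, get_num, numeric(1), f = "distance_I_III_mean"),
    angle_mean = vapply(sys, get_num, numeric(1), f = "angle_mean"),
    row.names = NULL
  )
  D <- vapply(sys, get_num, numeric(1), f = "delta_D")
  df$intermediate_flag <- !is.na(df$delta_mean) & abs(df$delta_mean) <= threshold_frac * D
  df
}
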