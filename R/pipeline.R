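#' Pipeline configuration
#'
#' Bundles every stage's parameters: the simulation (or ingestion)
#' configuration, preprocessing, EMS, cluster-test and estimation
#' settings. Defaults mirror the study settings: 0.1-40 Hz band-pass with
#' a 50 Hz band-stop, epochs -0.1 to 0.4 s with the first 15 of each
#' block excluded, 5-fold stratified EMS cross-validation, alpha 0.05,
#' 1000 sensor / 2000 source permutations, 5000 reshuffles and 5000
#' bootstraps.
#'
#' @param sim a [sim_config()].
#' @param highpass,lowpass,notches FIR band edges and notch list, Hz.
#' @param tmin,tmax epoch window, seconds.
#' @param drop_first leading epochs excluded per block.
#' @param ptp_threshold artifact peak-to-peak threshold, tesla
#'   (default 5e-12; the simulator's artifact-free output stays well
#'   below it).
#' @param bad_channels `"auto"`, a character vector, or `NULL`.
#' @param ems_k EMS folds.
#' @param n_perm_sensor,n_perm_source permutation counts.
#' @param alpha cluster alpha.
#' @param cluster_stat `"mean"` (default) or `"sum"`.
#' @param n_reshuffles,n_boot estimation resampling sizes.
#' @param ci_level confidence level for Cohen's d.
#' @param lambda beamformer covariance regularization.
#' @param sigma_prox ROI proximity-weight width, m (`NULL` = per-ROI
#'   median centroid distance).
#' @param fwer_across_rois pool the group-contrast null across ROIs
#'   (default TRUE; see the vignette).
#' @param group_tail tail of the age-group MMF contrast: `"pos"`
#'   (default) tests the directional hypothesis of larger mismatch
#'   amplitudes in the older group; `"two"` for a two-sided contrast.
#'   The standard- and deviant-amplitude group contrasts are always
#'   two-sided.
#' @param seed analysis seed (resampling); the simulation seed lives in
#'   `sim$seed`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), highpass = 0.1,
                            lowpass = 40, notches = 50, tmin = -0.1,
                            tmax = 0.4, drop_first = 15L,
                            ptp_threshold = 5e-12, bad_channels = "auto",
                            ems_k = 5L, n_perm_sensor = 1000L,
                            n_perm_source = 2000L, alpha = 0.05,
                            cluster_stat = "mean", n_reshuffles = 5000L,
                            n_boot = 5000L, ci_level = 0.95,
                            lambda = 0.05, sigma_prox = NULL,
                            fwer_across_rois = TRUE,
                            group_tail = c("pos", "two"), seed = 1L) {
  group_tail <- match.arg(group_tail)
  stopifnot(inherits(sim, "sim_config"), tmin < tmax, alpha > 0, alpha < 1)
  if (sim$mismatch_center > tmax) {
    stop("the simulated mismatch window lies outside the epoch span")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the optional `sim`
#' mapping holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

primary_cluster_window <- function(test) {
  cl <- test$clusters
  cl <- cl[cl$significant, , drop = FALSE]
  if (!nrow(cl)) return(NULL)
  cl <- cl[order(cl$p, -abs(cl$stat)), , drop = FALSE]
  c(cl$start_time[1L], cl$end_time[1L])
}

#' Run the full mismatch-field pipeline on a synthetic cohort
#'
#' Streams one participant at a time: simulation, zero-phase FIR
#' filtering, epoching with first-epoch exclusion, artifact rejection and
#' channel interpolation, ERF averaging, cross-validated EMS filtering,
#' combined-condition covariance, LCMV ROI filters and ROI projections.
#' Group stages follow the study logic: a whole-cohort one-sample cluster
#' test on the EMS mismatch traces defines the sensor TOI; TOI mean
#' amplitudes feed the group estimation statistics and the age
#' correlation; per-ROI paired cluster tests on the source traces define
#' the right-hemisphere source window; and independent-samples cluster
#' tests inside that window compare the groups' MMF, standard and
#' deviant source amplitudes.
#'
#' @param config a [pipeline_config()].
#' @param progress print one line per participant (default FALSE).
#' @return An `mmf_report`; see [recover_ground_truth()] for scoring
#'   against the simulated truth.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  geometry <- make_default_geometry(cfg)
  plan <- cohort_plan(cfg)
  n <- nrow(plan)
  rois <- setdiff(unique(geometry$grid$roi_labels), "none")
  roi_lf <- list()
  for (roi in rois) {
    for (v in which(geometry$grid$roi_labels == roi)) {
      roi_lf[[v]] <- dipole_leadfield(geometry$grid$positions[v, ],
                                      geometry$array)
    }
  }

  n_t <- round((config$tmax - config$tmin) * cfg$sampling_rate)
  ems_std <- matrix(0, n, n_t)
  ems_dev <- matrix(0, n, n_t)
  roi_std <- lapply(rois, function(r) matrix(0, n, n_t))
  roi_dev <- lapply(rois, function(r) matrix(0, n, n_t))
  names(roi_std) <- names(roi_dev) <- rois
  logs <- vector("list", n)
  truths <- vector("list", n)
  times <- NULL

  for (i in seq_len(n)) {
    ps <- simulate_participant(cfg, group = plan$group[i],
                               seed = plan$seed[i],
                               block_order = as.integer(plan[i, c("order1", "order2", "order3")]),
                               geometry = geometry)
    rec <- fir_filter(ps$recording, config$highpass, config$lowpass,
                      config$notches)
    ep <- epoch_events(rec, tmin = config$tmin, tmax = config$tmax,
                       drop_first = config$drop_first)
    rm(rec)
    if (cfg$epoch_dropout > 0) {
      keep <- with_seed(derive_seeds(plan$seed[i], 4L)[4L],
                        stats::runif(dim(ep$data)[1]) >= cfg$epoch_dropout)
      ep$data <- ep$data[keep, , , drop = FALSE]
      ep$labels <- ep$labels[keep]
      ep$subtype <- ep$subtype[keep]
      ep$log$n_kept <- sum(keep)
    }
    ep <- reject_and_interpolate(ep, config$ptp_threshold,
                                 config$bad_channels)
    evoked <- average_erfs(ep)
    tc <- ems_crossval(ep, k = config$ems_k,
                       seed = derive_seeds(plan$seed[i], 5L)[5L])
    cov <- compute_covariance(ep, config$lambda)
    filters <- lapply(rois, function(roi) {
      roi_spatial_filter(geometry$grid, roi, geometry$array, cov,
                         sigma_prox = config$sigma_prox,
                         leadfields = roi_lf)
    })
    src <- project_rois(filters, evoked)
    ems_std[i, ] <- tc$standard
    ems_dev[i, ] <- tc$deviant
    for (roi in rois) {
      roi_std[[roi]][i, ] <- src$rois[[roi]]$standard
      roi_dev[[roi]][i, ] <- src$rois[[roi]]$deviant
    }
    logs[[i]] <- ep$log
    truths[[i]] <- ps$truth
    times <- ep$times
    if (progress) {
      cat(sprintf("[%s] %s (%s): %d epochs kept\n", format(Sys.time(),
                  "%H:%M:%S"), plan$id[i], plan$group[i], ep$log$n_kept))
    }
    rm(ps, ep, evoked, cov, filters, src)
  }

  aseeds <- derive_seeds(config$seed, 6L)
  sensor_test <- cluster_permutation_test(
    ems_dev - ems_std, mode = "one_sample", n_perm = config$n_perm_sensor,
    alpha = config$alpha, seed = aseeds[1L],
    cluster_stat = config$cluster_stat, times = times)
  toi <- primary_cluster_window(sensor_test)

  older <- plan$group == "older"
  estimation <- NULL
  toi_amplitudes <- rep(NA_real_, n)
  if (!is.null(toi)) {
    sel <- times >= toi[1] & times <= toi[2]
    toi_amplitudes <- rowMeans((ems_dev - ems_std)[, sel, drop = FALSE])
    estimation <- estimate_group_effect(
      toi_amplitudes[older], toi_amplitudes[!older],
      ages = c(plan$age[older], plan$age[!older]),
      n_reshuffles = config$n_reshuffles, n_boot = config$n_boot,
      level = config$ci_level, seed = aseeds[2L])
  }

  paired_tests <- cluster_permutation_test_rois(
    roi_dev, roi_std, mode = "paired", n_perm = config$n_perm_source,
    alpha = config$alpha, seed = aseeds[3L],
    cluster_stat = config$cluster_stat, times = times, joint_null = FALSE)

  right_rois <- intersect(c("rA1", "rSTG", "rIFG"), rois)
  wins <- lapply(paired_tests[right_rois], primary_cluster_window)
  wins <- wins[!vapply(wins, is.null, TRUE)]
  source_window <- if (length(wins)) {
    c(min(vapply(wins, `[`, 1, 1L)), max(vapply(wins, `[`, 1, 2L)))
  } else {
    NULL
  }

  # The age-related source analysis is constrained to the
  # right-hemisphere ROIs and to the window defined by the whole-cohort
  # paired clusters, mirroring the study logic.
  group_tests <- NULL
  if (!is.null(source_window) && sum(older) >= 2 && sum(!older) >= 2) {
    sel <- times >= source_window[1] & times <= source_window[2]
    tsel <- times[sel]
    g_rois <- right_rois
    contrasts <- list(
      mmf = lapply(g_rois, function(r) {
        (roi_dev[[r]] - roi_std[[r]])[, sel, drop = FALSE]
      }),
      standard = lapply(g_rois, function(r) roi_std[[r]][, sel, drop = FALSE]),
      deviant = lapply(g_rois, function(r) roi_dev[[r]][, sel, drop = FALSE]))
    group_tests <- lapply(seq_along(contrasts), function(k) {
      xs <- contrasts[[k]]
      names(xs) <- g_rois
      # older minus younger; the MMF contrast is one-sided when the
      # directional hypothesis (larger mismatch with age) is configured
      tail_k <- if (names(contrasts)[k] == "mmf") config$group_tail else "two"
      cluster_permutation_test_rois(
        xs, groups = plan$group, mode = "independent",
        n_perm = config$n_perm_source, alpha = config$alpha,
        seed = aseeds[3L + k], cluster_stat = config$cluster_stat,
        times = tsel, joint_null = config$fwer_across_rois,
        tail = tail_k)
    })
    names(group_tests) <- names(contrasts)
  }

  structure(list(
    config = config, plan = plan, times = times,
    ems = list(standard = ems_std, deviant = ems_dev),
    sensor_test = sensor_test, toi = toi,
    toi_amplitudes = toi_amplitudes, estimation = estimation,
    source = list(standard = roi_std, deviant = roi_dev),
    paired_tests = paired_tests, source_window = source_window,
    group_tests = group_tests, logs = logs,
    truth = list(per_participant = truths,
                 window = truths[[1L]]$mismatch_window,
                 mismatch_rois = cfg$mismatch_rois,
                 gain_ifg = cfg$group_gain_ifg),
    provenance = list(seed = config$seed, sim_seed = cfg$seed,
                      timestamp = format(Sys.time()),
                      package_version = as.character(utils::packageVersion("mmfpipe")))),
    class = "mmf_report")
}

significant_rois <- function(tests) {
  if (is.null(tests)) return(character(0))
  names(tests)[vapply(tests, function(t) any(t$clusters$significant), TRUE)]
}

#' @export
print.mmf_report <- function(x, ...) {
  cat("<mmf_report>", nrow(x$plan), "participants (",
      sum(x$plan$group == "younger"), "younger /",
      sum(x$plan$group == "older"), "older )\n")
  if (is.null(x$toi)) {
    cat("  sensor MMF: no significant cluster\n")
  } else {
    cat(sprintf("  sensor MMF cluster (TOI): %.3f-%.3f s\n", x$toi[1],
                x$toi[2]))
  }
  if (!is.null(x$estimation)) {
    cat(sprintf("  older vs younger TOI amplitude: P = %.4f, d = %.2f (CI %.2f to %.2f)\n",
                x$estimation$p_perm, x$estimation$d, x$estimation$d_ci[1],
                x$estimation$d_ci[2]))
    cat(sprintf("  amplitude-age correlation: r = %.2f, P = %.4f\n",
                x$estimation$correlation$r, x$estimation$correlation$p))
  }
  cat("  paired deviant>standard ROIs:",
      paste(significant_rois(x$paired_tests), collapse = ", ") %||% "-",
      "\n")
  if (!is.null(x$source_window)) {
    cat(sprintf("  source window: %.3f-%.3f s\n", x$source_window[1],
                x$source_window[2]))
  }
  if (!is.null(x$group_tests)) {
    cat("  group MMF contrast ROIs:",
        paste(significant_rois(x$group_tests$mmf), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mmf_report <- function(object, ...) {
  print(object)
  cat("\nPer-ROI paired tests:\n")
  for (roi in names(object$paired_tests)) {
    cat(" ", roi, ":\n")
    print(object$paired_tests[[roi]])
  }
  invisible(object)
}

overlaps <- function(a, b) !is.null(a) && a[1] <= b[2] && a[2] >= b[1]

#' Score a pipeline report against the simulated ground truth
#'
#' Checks whether the detected sensor and source clusters overlap the
#' injected mismatch window and tabulates per-ROI hits and false alarms
#' for the paired (deviant vs standard) and group (older vs younger MMF)
#' tests against what the simulator injected.
#'
#' @param report an `mmf_report` from a synthetic run.
#' @return A `recovery_summary`: `sensor_hit`, `toi`, `window`,
#'   `roi_table` (per ROI: injected, paired_detected, group_injected,
#'   group_detected), `group_hits`, `group_false_alarms`.
#' @export
recover_ground_truth <- function(report) {
  stopifnot(inherits(report, "mmf_report"))
  win <- report$truth$window
  sensor_hit <- overlaps(report$toi, win)
  rois <- names(report$paired_tests)
  injected <- rois %in% report$truth$mismatch_rois
  group_injected <- rois == "rIFG" & report$truth$gain_ifg != 1
  paired_det <- rois %in% significant_rois(report$paired_tests)
  group_tested <- rois %in% names(report$group_tests$mmf %||% list())
  group_det <- rois %in% significant_rois(report$group_tests$mmf)
  tab <- data.frame(roi = rois, injected = injected,
                    paired_detected = paired_det,
                    group_tested = group_tested,
                    group_injected = group_injected,
                    group_detected = group_det)
  structure(list(sensor_hit = sensor_hit, toi = report$toi, window = win,
                 roi_table = tab,
                 group_hits = sum(group_det & group_injected),
                 group_false_alarms = sum(group_det & !group_injected),
                 paired_hits = sum(paired_det & injected),
                 paired_false_alarms = sum(paired_det & !injected)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("<recovery_summary>\n")
  cat("  sensor cluster overlaps injected window:", x$sensor_hit, "\n")
  print(x$roi_table, row.names = FALSE)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the machine-readable portion of the report (configuration echo,
#' cluster tables, estimation statistics, TOI/window, recovery summary)
#' with seeds and provenance; the heavy trace matrices are omitted.
#'
#' @param report an `mmf_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  cl_tab <- function(t) t$clusters
  out <- list(
    provenance = report$provenance,
    toi = report$toi,
    sensor_clusters = cl_tab(report$sensor_test),
    estimation = if (!is.null(report$estimation)) {
      e <- report$estimation
      list(p_perm = e$p_perm, d = e$d, d_ci = e$d_ci,
           r_age = e$correlation$r, p_age = e$correlation$p)
    },
    source_window = report$source_window,
    paired_clusters = lapply(report$paired_tests, cl_tab),
    group_clusters = if (!is.null(report$group_tests)) {
      lapply(report$group_tests, function(g) lapply(g, cl_tab))
    },
    recovery = unclass(recover_ground_truth(report))[
      c("sensor_hit", "group_hits", "group_false_alarms",
        "paired_hits", "paired_false_alarms")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write per-participant EMS traces as tidy TSV
#'
#' Columns `participant`, `condition`, `time`, `value`.
#'
#' @param report an `mmf_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ems_tsv <- function(report, path) {
  n <- nrow(report$plan)
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(
      data.frame(participant = report$plan$id[i], condition = "standard",
                 time = report$times, value = report$ems$standard[i, ]),
      data.frame(participant = report$plan$id[i], condition = "deviant",
                 time = report$times, value = report$ems$deviant[i, ]))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
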