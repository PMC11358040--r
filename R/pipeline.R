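#' Run the full time-resolved SAXS screen on a plate
#'
#' Composes the analysis stages in order: time-matched buffer subtraction;
#' per-frame Guinier metrics with aggregation QC; control Z-factors (Rg and
#' I(0)) from the first frame; time-resolved V_R traces against the
#' time-matched dimer benchmark plus monomer/dimer significance envelopes and
#' per-sample transition classification; SAXS similarity matrices at the
#' earliest frame and the frame nearest `late_time`, clustered by
#' single-linkage AHC and by k-means (Krzanowski-Lai selected k, with a
#' forced-k assignment always reported alongside); V_R kinetics against the
#' fixed dimer benchmark at `late_time` with k_VR ranking and clustering; and
#' an optional DSF/MST triage merge. Per-sample stage failures are recorded as
#' exclusion reasons without aborting the plate.
#'
#' @param plate A [simulate_screen_plate()] result, or a [load_manifest()]
#'   result (list with `sheet` and `series`; buffer wells are taken from the
#'   manifest roles).
#' @param window,nbins V_R analysis window and bin count.
#' @param late_time Time point (s) used for the late SSM and the fixed kinetic
#'   reference (default 2.1).
#' @param forced_k Cluster number always reported alongside the
#'   Krzanowski-Lai selection (default 4, the expected chemotype count).
#' @param triage Optional [simulate_triage_assays()]-shaped list with `melts`,
#'   `reference_melts`, `mst`, `reference_mst`.
#' @param seed Integer seed for the stochastic clustering steps.
#' @return A `screen_report` list (see the individual components).
#' @export
run_screen <- function(plate, window = c(0.015, 0.15), nbins = 25,
                       late_time = 2.1, forced_k = 4, triage = NULL,
                       seed = 1) {
  sheet <- plate$sheet
  series <- plate$series
  buffers <- plate$buffers
  if (is.null(buffers)) { # manifest-loaded plate: split wells by role
    bwells <- sheet$well[sheet$role == "buffer"]
    buffers <- series[bwells]
    series <- series[setdiff(names(series), bwells)]
  }
  if (is.null(sheet) || nrow(sheet) == 0L) stop("empty plate manifest")
  roles <- stats::setNames(sheet$role, sheet$well)
  compounds <- stats::setNames(sheet$compound_id, sheet$well)
  swells <- names(series)[roles[names(series)] == "sample"]
  mwells <- names(series)[roles[names(series)] == "monomer-control"]
  dwells <- names(series)[roles[names(series)] == "dimer-control"]
  if (length(dwells) < 2L || length(mwells) < 2L) {
    stop("need >= 2 monomer-control and >= 2 dimer-control replicate series")
  }
  exclusions <- list()
  exclude <- function(well, reason) {
    exclusions[[well]] <<- reason
  }

  # stage 1: buffer subtraction
  sub <- list()
  for (well in names(series)) {
    sub[[well]] <- tryCatch(
      subtract_time_matched(series[[well]], unname(buffers)),
      error = function(e) {
        exclude(well, paste("subtraction failed:", conditionMessage(e)))
        NULL
      })
  }
  sub <- Filter(Negate(is.null), sub)

  # stage 2: per-frame Guinier metrics
  metrics <- list()
  for (well in names(sub)) {
    sr <- sub[[well]]
    rows <- lapply(seq_along(sr$curves), function(i) {
      cv <- sr$curves[[i]]
      fit <- tryCatch(guinier_fit(cv), error = function(e) NULL)
      if (is.null(fit)) {
        return(data.frame(well = well, compound = compounds[[well]],
                          time_s = sr$times[i], rg = NA_real_,
                          rg_err = NA_real_, i0 = NA_real_, i0_err = NA_real_,
                          qmin = NA_real_, qmax = NA_real_, r2 = NA_real_,
                          aggregation_flag = NA))
      }
      agg <- aggregation_check(cv, fit)
      data.frame(well = well, compound = compounds[[well]],
                 time_s = sr$times[i], rg = fit$rg, rg_err = fit$rg_se,
                 i0 = fit$i0, i0_err = fit$i0_se, qmin = fit$qmin,
                 qmax = fit$qmax, r2 = fit$r2, aggregation_flag = agg$flag)
    })
    metrics[[well]] <- do.call(rbind, rows)
  }
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))
  for (well in names(sub)) {
    mw <- metrics[metrics$well == well, ]
    if (all(is.na(mw$rg))) exclude(well, "failed Guinier QC in every frame")
  }
  # drop excluded wells from the similarity/kinetics stages
  sub <- sub[setdiff(names(sub), names(exclusions))]
  if (!all(mwells %in% names(sub)) || sum(dwells %in% names(sub)) < 2L) {
    stop("control replicates failed QC; envelopes are infeasible")
  }
  dwells <- intersect(dwells, names(sub))

  # stage 3: control Z-factors at the first frame
  first_vals <- function(wells, col) {
    vapply(wells, function(w) {
      metrics[metrics$well == w, col][1L]
    }, numeric(1))
  }
  z_rg <- z_factor(first_vals(dwells, "rg"), first_vals(mwells, "rg"),
                   metric = "Rg")
  z_i0 <- z_factor(first_vals(dwells, "i0"), first_vals(mwells, "i0"),
                   metric = "I0")

  # stage 4: V_R traces vs the time-matched dimer benchmark; envelopes
  times <- sub[[1L]]$times
  dimer_bench <- frame_series(lapply(seq_along(times), function(i) {
    cv <- average_curves(lapply(dwells, function(w) sub[[w]]$curves[[i]]))
    cv$meta$label <- "dimer-benchmark"
    cv$meta$time <- times[i]
    cv
  }), label = "dimer-benchmark")

  traces_tm <- list()
  for (well in setdiff(names(sub), dwells)) {
    traces_tm[[well]] <- tryCatch(
      vr_trace(sub[[well]], dimer_bench, window = window, nbins = nbins),
      error = function(e) {
        exclude(well, paste("V_R trace failed:", conditionMessage(e)))
        NULL
      })
  }
  traces_tm <- Filter(Negate(is.null), traces_tm)
  monomer_env <- benchmark_envelope(traces_tm[mwells], sense = "monomer",
                                    label = "monomer-vs-dimer")
  # dimer self-similarity: each replicate vs the leave-one-out benchmark
  dimer_self <- lapply(dwells, function(w) {
    others <- setdiff(dwells, w)
    ref <- frame_series(lapply(seq_along(times), function(i) {
      cv <- average_curves(lapply(others, function(o) sub[[o]]$curves[[i]]))
      cv$meta$time <- times[i]
      cv
    }), label = "dimer-loo")
    vr_trace(sub[[w]], ref, window = window, nbins = nbins)
  })
  dimer_env <- benchmark_envelope(dimer_self, sense = "dimer",
                                  label = "dimer-self")
  classifications <- lapply(traces_tm[intersect(swells, names(traces_tm))],
                            classify_transition, monomer_env, dimer_env)

  # stage 5: SSMs at the early and late time points, clustered
  late_idx <- which.min(abs(times - late_time))
  ssm_wells <- intersect(c(swells, mwells, dwells), names(sub))
  ssm_at <- function(idx) {
    curves <- lapply(ssm_wells, function(w) sub[[w]]$curves[[idx]])
    names(curves) <- compounds[ssm_wells]
    similarity_matrix(curves, window = window, nbins = nbins)
  }
  cluster_ssm <- function(ssm) {
    scan <- kl_select_k(ssm, kmax = min(8, nrow(ssm) - 1L), seed = seed)
    list(ahc = single_linkage_cluster(ssm, k = forced_k),
         kmeans_kl = kmeans_cluster(ssm, attr(scan, "chosen_k"), seed = seed),
         kmeans_forced = kmeans_cluster(ssm, forced_k, seed = seed),
         scan = scan)
  }
  ssm_early <- ssm_at(1L)
  ssm_late <- ssm_at(late_idx)
  clust_early <- cluster_ssm(ssm_early)
  clust_late <- cluster_ssm(ssm_late)

  # stage 6: kinetics vs the fixed dimer benchmark at the late time point;
  # only envelope-responsive samples (trace fell below the monomer
  # significance threshold) are fit, mirroring the screening triage
  ref_fixed <- dimer_bench$curves[[late_idx]]
  kinetic_fits <- list()
  for (well in intersect(swells, names(sub))) {
    cls <- classifications[[well]]
    if (is.null(cls) || is.na(cls$first_significant)) next
    tr <- tryCatch(
      vr_trace(sub[[well]], ref_fixed, window = window, nbins = nbins),
      error = function(e) NULL)
    if (is.null(tr)) next
    kinetic_fits[[compounds[[well]]]] <- fit_exponential_decay(tr)
  }
  kinetics <- tryCatch(
    rank_and_cluster_kvr(kinetic_fits, seed = seed),
    error = function(e) {
      # fewer than 2 transitioning compounds: rank without clustering
      trans <- Filter(function(f) isTRUE(f$transitioning), kinetic_fits)
      ranking <- if (length(trans)) {
        data.frame(label = names(trans),
                   k_vr = vapply(trans, function(f) f$k, numeric(1)),
                   k_se = vapply(trans, function(f) f$k_se, numeric(1)),
                   A = vapply(trans, function(f) f$A, numeric(1)),
                   C = vapply(trans, function(f) f$C, numeric(1)),
                   sse = vapply(trans, function(f) f$sse, numeric(1)),
                   rank = seq_along(trans), cluster = NA_integer_,
                   cluster_ahc = NA_integer_, row.names = NULL)
      } else {
        data.frame()
      }
      list(ranking = ranking,
           non_transitioning = setdiff(names(kinetic_fits), names(trans)),
           k_selected = NA_integer_, wss_by_k = numeric(0))
    })

  # stage 7: optional orthogonal-assay triage
  triage_table <- NULL
  if (!is.null(triage)) {
    triage_table <- triage_screen(triage)
  }

  structure(list(
    sheet = sheet, times = times, window = window, nbins = nbins,
    late_time = times[late_idx], seed = seed,
    metrics = metrics, z_rg = z_rg, z_i0 = z_i0,
    traces = traces_tm, monomer_envelope = monomer_env,
    dimer_envelope = dimer_env, classifications = classifications,
    ssm_early = ssm_early, ssm_late = ssm_late,
    clusters_early = clust_early, clusters_late = clust_late,
    kinetic_fits = kinetic_fits, kinetics = kinetics,
    triage = triage_table, exclusions = exclusions
  ), class = "screen_report")
}

#' DSF + MST triage calls for a simulated (or measured) assay set
#'
#' Fits a Boltzmann Tm to every QC-passing melt curve, calls DSF hits at
#' `k` SD of the reference Tm spread (two-sided), computes MST amplitudes and
#' calls MST hits one-sidedly, and merges the calls.
#'
#' @param assays List with `melts`, `reference_melts`, `mst`, `reference_mst`
#'   (see [simulate_triage_assays()]).
#' @param k Threshold multiple (default 3).
#' @return data.frame: compound, qc_pass, qc_reason, tm, delta_tm, dsf_hit,
#'   dsf_class, mst_amplitude, mst_delta, mst_hit, verified (>= 1 assay),
#'   dual_verified.
#' @export
triage_screen <- function(assays, k = 3) {
  ref_tms <- vapply(assays$reference_melts, function(m) fit_boltzmann_tm(m)$tm,
                    numeric(1))
  ids <- names(assays$melts)
  qc <- lapply(assays$melts, qc_melt_curve)
  qc_pass <- vapply(qc, function(x) isTRUE(x$pass), logical(1))
  tms <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    if (qc_pass[i]) tms[i] <- fit_boltzmann_tm(assays$melts[[i]])$tm
  }
  dsf <- threshold_call(stats::setNames(tms[qc_pass], ids[qc_pass]), ref_tms,
                        k = k, sense = "two-sided")
  dsf_hit <- stats::setNames(rep(FALSE, length(ids)), ids)
  dsf_class <- stats::setNames(rep(NA_character_, length(ids)), ids)
  dsf_hit[dsf$calls$label] <- dsf$calls$hit
  dsf_class[dsf$calls$label] <- dsf$calls$class

  ref_amps <- vapply(assays$reference_mst, mst_amplitude, numeric(1))
  amps <- vapply(assays$mst[ids], mst_amplitude, numeric(1))
  mst <- threshold_call(stats::setNames(amps, ids), ref_amps, k = k,
                        sense = "greater")

  data.frame(
    compound = ids,
    qc_pass = unname(qc_pass),
    qc_reason = vapply(qc, function(x) x$reason, character(1)),
    tm = tms,
    delta_tm = tms - dsf$mu,
    dsf_hit = unname(dsf_hit),
    dsf_class = unname(dsf_class),
    mst_amplitude = unname(amps),
    mst_delta = unname(amps - mst$mu),
    mst_hit = mst$calls$hit,
    verified = unname(dsf_hit) | mst$calls$hit,
    dual_verified = unname(dsf_hit) & mst$calls$hit,
    row.names = NULL
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d wells, %d frames (t = %.2g..%.2g s)\n",
              nrow(x$sheet), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  Z-factors: Rg %.3f, I(0) %.3f\n", x$z_rg$z, x$z_i0$z))
  if (nrow(x$kinetics$ranking)) {
    cat(sprintf("  k_VR ranking: %s\n",
                paste(utils::head(x$kinetics$ranking$label, 5),
                      collapse = " > ")))
  }
  if (length(x$exclusions)) {
    cat("  exclusions:", paste(names(x$exclusions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a screen report to CSV and JSON files
#'
#' Writes `compounds.csv` (per-frame Guinier metrics), `ssm_early.csv` /
#' `ssm_late.csv` (square labeled V_R matrices), `kinetics.csv`,
#' `triage.csv` (when present) and `report.json` (scalar summaries plus
#' cluster assignments and run metadata).
#'
#' @param report A [run_screen()] result.
#' @param dir Output directory.
#' @param formats Character subset of `c("csv", "json")`.
#' @return Invisibly, the vector of files written.
#' @export
export_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "screen_report"))
  unknown <- setdiff(formats, c("csv", "json"))
  if (length(unknown)) {
    stop("unknown format(s): ", paste(unknown, collapse = ", "),
         "; supported: csv, json")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(dir, "compounds.csv")
    utils::write.csv(report$metrics, f, row.names = FALSE)
    written <- c(written, f)
    for (nm in c("ssm_early", "ssm_late")) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(unclass(report[[nm]])), f)
      written <- c(written, f)
    }
    if (nrow(report$kinetics$ranking)) {
      f <- file.path(dir, "kinetics.csv")
      utils::write.csv(report$kinetics$ranking, f, row.names = FALSE)
      written <- c(written, f)
    }
    if (!is.null(report$triage)) {
      f <- file.path(dir, "triage.csv")
      utils::write.csv(report$triage, f, row.names = FALSE)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    j <- list(
      run = list(seed = report$seed, window = report$window,
                 nbins = report$nbins, late_time = report$late_time,
                 n_wells = nrow(report$sheet), times = report$times),
      z_factors = list(rg = report$z_rg$z, i0 = report$z_i0$z),
      envelopes = list(
        monomer = list(mean = report$monomer_envelope$mean,
                       sigma_bar = report$monomer_envelope$sigma_bar,
                       threshold = report$monomer_envelope$threshold),
        dimer = list(mean = report$dimer_envelope$mean,
                     sigma_bar = report$dimer_envelope$sigma_bar,
                     threshold = report$dimer_envelope$threshold)),
      clusters_late = list(
        ahc = as.list(report$clusters_late$ahc$cluster),
        kmeans_kl = as.list(report$clusters_late$kmeans_kl$cluster),
        kmeans_forced = as.list(report$clusters_late$kmeans_forced$cluster),
        kl_chosen_k = attr(report$clusters_late$scan, "chosen_k")),
      kinetics = report$kinetics$ranking,
      non_transitioning = report$kinetics$non_transitioning,
      exclusions = report$exclusions
    )
    f <- file.path(dir, "report.json")
    jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
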