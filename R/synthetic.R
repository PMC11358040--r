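#' Analytic sphere scattering profile
#'
#' Uniform-sphere form factor \eqn{P(q) = [3(\sin u - u\cos u)/u^3]^2} with
#' \eqn{u = qR}; the intensity is `scale * V^2 * P(q)` for sphere volume V, so
#' the Guinier radius is \eqn{R_g = \sqrt{3/5}\,R} and the first intensity
#' zero sits at \eqn{u \approx 4.4934} (root of \eqn{\tan u = u}).
#'
#' @param q_grid Strictly increasing positive q values (\eqn{\AA^{-1}}).
#' @param R Sphere radius (\eqn{\AA}).
#' @param scale Intensity scale (contrast^2 prefactor).
#' @param meta Metadata for the returned curve.
#' @return A [scattering_curve()] (no sigma).
#' @export
sphere_profile <- function(q_grid, R, scale = 1, meta = list()) {
  stopifnot(R > 0)
  V <- 4 / 3 * pi * R^3
  scattering_curve(q_grid, scale * V^2 * sphere_form_factor(q_grid * R),
                   meta = meta)
}

#' @rdname sphere_profile
#' @param u Dimensionless qR values.
#' @export
sphere_form_factor <- function(u) {
  u <- as.numeric(u)
  amp <- numeric(length(u))
  small <- u < 0.05 # series branch: the closed form cancels catastrophically
  amp[small] <- 1 - u[small]^2 / 10 + u[small]^4 / 280
  ub <- u[!small]
  amp[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  amp^2
}

#' Analytic tangent two-sphere dimer profile
#'
#' Orientation-averaged intensity of two tangent spheres of radius R (center
#' spacing d = 2R): per particle
#' \eqn{I(q) = 2\,scale\,V^2 P(q) [1 + \sin(qd)/(qd)]}. Forward scattering is
#' 4x the single sphere (coherent addition of two identical amplitudes) and
#' the Guinier radius is \eqn{R_g = \sqrt{8/5}\,R} by the parallel-axis rule.
#'
#' @inheritParams sphere_profile
#' @return A [scattering_curve()] (no sigma).
#' @export
dimer_profile <- function(q_grid, R, scale = 1, meta = list()) {
  stopifnot(R > 0)
  V <- 4 / 3 * pi * R^3
  d <- 2 * R
  u <- q_grid * d
  sinc <- ifelse(u < 1e-6, 1, sin(u) / u)
  ii <- 2 * scale * V^2 * sphere_form_factor(q_grid * R) * (1 + sinc)
  scattering_curve(q_grid, ii, meta = meta)
}

#' Monomer/dimer particle model
#'
#' @param R Sphere radius (\eqn{\AA}).
#' @param scale Contrast scale.
#' @return List with `R`, `scale`, closed-form `rg_monomer` =
#'   \eqn{\sqrt{3/5}R} and `rg_dimer` = \eqn{\sqrt{8/5}R}.
#' @export
particle_model <- function(R = 30, scale = 1) {
  stopifnot(R > 0)
  list(R = R, scale = scale,
       rg_monomer = sqrt(3 / 5) * R,
       rg_dimer = sqrt(8 / 5) * R)
}

#' First-order dimerization kinetics
#'
#' Converted monomer fraction \eqn{x(t) = x_\infty (1 - e^{-k t})}.
#'
#' @param k_true First-order conversion rate (s^-1, >= 0).
#' @param x_inf Final converted fraction in [0, 1].
#' @return List with `k_true`, `x_inf` and the function `x(t)`.
#' @export
dimerization_kinetics <- function(k_true, x_inf) {
  stopifnot(k_true >= 0, x_inf >= 0, x_inf <= 1)
  list(k_true = k_true, x_inf = x_inf,
       x = function(t) x_inf * (1 - exp(-k_true * t)))
}

#' Simulation configuration
#'
#' Defaults reproduce the screening conditions the analysis assumes: 300-ms
#' frames over a 0.3-3.0 s analysis span, a 256-point q grid over
#' 0.01-0.59 \eqn{\AA^{-1}}, duplicate monomer controls, triplicate dimer
#' controls and duplicate buffers. Intensities are normalized so the monomer
#' forward scattering is `i0_monomer`.
#'
#' @param frame_times Frame time stamps (s).
#' @param q_grid Momentum-transfer grid (\eqn{\AA^{-1}}).
#' @param epsilon Gaussian noise scale in forward-scattering units; 0 disables
#'   noise (and the sigma column).
#' @param seed Integer RNG seed (mandatory: identical config + seed gives
#'   bit-identical output).
#' @param n_monomer_controls,n_dimer_controls,n_buffers Replicate counts.
#' @param radius Sphere radius of the particle model (\eqn{\AA}; the default
#'   25 keeps the sphere's first intensity zero, at q = 4.4934/R, above the
#'   0.15 \eqn{\AA^{-1}} similarity-window edge).
#' @param i0_monomer Monomer forward scattering in output units.
#' @param buffer_level Flat buffer background level (same units).
#' @param conc_cv Coefficient of variation of the per-well protein
#'   concentration (pipetting scatter): each well's whole series is scaled by
#'   one factor drawn from N(1, conc_cv). This spreads replicate I(0) values
#'   the way real plate assembly does; V_R (scale-invariant) and Rg are
#'   unaffected.
#' @param exposure Frame exposure duration (s).
#' @return A `sim_config` list.
#' @export
sim_config <- function(frame_times = seq(0.3, 3.0, by = 0.3),
                       q_grid = seq(0.01, 0.59, length.out = 256),
                       epsilon = 5e-4, seed,
                       n_monomer_controls = 2, n_dimer_controls = 3,
                       n_buffers = 2, radius = 25, i0_monomer = 1,
                       buffer_level = 0.1, conc_cv = 0.015,
                       exposure = NULL) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (n_monomer_controls < 2 || n_dimer_controls < 2 || n_buffers < 2) {
    stop("replicate counts below 2 make significance envelopes infeasible")
  }
  if (is.null(exposure)) exposure <- frame_times[1L]
  structure(list(frame_times = frame_times, q_grid = q_grid,
                 epsilon = epsilon, seed = as.integer(seed),
                 n_monomer_controls = n_monomer_controls,
                 n_dimer_controls = n_dimer_controls, n_buffers = n_buffers,
                 radius = radius, i0_monomer = i0_monomer,
                 buffer_level = buffer_level, conc_cv = conc_cv,
                 exposure = exposure),
            class = "sim_config")
}

# noise sd: epsilon * sqrt(I/I0) with a floor of epsilon/10, in output units
noise_sigma <- function(intensity, i0, epsilon) {
  pmax(epsilon * sqrt(pmax(intensity, 0) / i0), epsilon / 10)
}

#' Simulate a two-state monomer-to-dimer SAXS time series
#'
#' Per frame time t the intensity is the number-weighted two-state mixture
#' \deqn{I(q,t) = c\,[(1 - x(t)) I_{mon}(q) + (x(t)/2) I_{dim}(q)]}
#' (the dimer count is half the converted monomer count), which conserves
#' \eqn{I(0,t)/I(0,0) = 1 + x(t)} exactly in the noiseless limit. Gaussian
#' noise with \eqn{\sigma(q) = \epsilon\sqrt{I(q,t)/I(0,t)}} (floored at
#' \eqn{\epsilon/10}) emulates 300-ms frame counting statistics after buffer
#' subtraction.
#'
#' @param model A [particle_model()].
#' @param kinetics A [dimerization_kinetics()].
#' @param config A [sim_config()].
#' @param label Series label.
#' @param x0 Converted fraction already present at t = 0 (1 for a static
#'   dimer control).
#' @return A [frame_series()] of subtracted-signal curves.
#' @export
simulate_two_state_series <- function(model, kinetics, config, label = NULL,
                                      x0 = 0) {
  stopifnot(inherits(config, "sim_config"))
  qg <- config$q_grid
  imon <- sphere_profile(qg, model$R, model$scale)$intensity
  idim <- dimer_profile(qg, model$R, model$scale)$intensity
  V <- 4 / 3 * pi * model$R^3
  cnorm <- config$i0_monomer / (model$scale * V^2)
  curves <- vector("list", length(config$frame_times))
  for (i in seq_along(config$frame_times)) {
    t <- config$frame_times[i]
    x <- min(1, x0 + (1 - x0) * kinetics$x(t))
    ii <- cnorm * ((1 - x) * imon + (x / 2) * idim)
    i0_t <- config$i0_monomer * (1 + x)
    sigma <- NULL
    if (config$epsilon > 0) {
      sigma <- noise_sigma(ii, i0_t, config$epsilon)
      ii <- ii + stats::rnorm(length(ii), sd = sigma)
    }
    curves[[i]] <- scattering_curve(
      qg, ii, sigma = sigma,
      meta = list(label = label, time = t, frame = i,
                  exposure = config$exposure, x_true = x))
  }
  frame_series(curves, label = label)
}

#' Default planted fragment-effect library
#'
#' Twelve compounds in four planted chemotypes mirroring strong (CX1),
#' moderate (CX2), weak (CX3) and absent (CX4/inactive) dimerization
#' responses: CX1 converts fully with the fastest rates, CX2 partially at
#' intermediate rates, CX3 weakly and slowly, and inactive compounds not at
#' all. Planted DSF shifts make dimerizers Tm-lowering (like the native
#' reduced-cofactor ligand) and CX3 mildly Tm-elevating; MST amplitude shifts
#' and one Kd per CX1 compound accompany them.
#'
#' The planted rate constants form a ladder with well-separated adjacent
#' values so the kinetic ranking is resolvable within the 3-s frame span,
#' and the per-class plateaus are chosen so each chemotype's converted
#' fraction at 2.1 s is tight within the class and well separated between
#' classes (slower converters in a class carry slightly higher plateaus).
#'
#' @return data.frame with columns `id`, `chemotype`, `k_true` (s^-1),
#'   `x_inf`, `delta_tm` (degC), `mst_shift` (response units), `kd_um`
#'   (\eqn{\mu M}, NA = not determinable).
#' @export
default_fragment_library <- function() {
  data.frame(
    id = sprintf("F%02d", 1:12),
    chemotype = rep(c("CX1", "CX2", "CX3", "inactive"), each = 3),
    k_true = c(2.0, 1.55, 1.2, 0.80, 0.60, 0.43, 1.05, 0.72, 0.51, 0, 0, 0),
    x_inf = c(1, 1, 1, 0.64, 0.67, 0.74, 0.247, 0.244, 0.243, 0, 0, 0),
    delta_tm = c(-10.8, -9.5, -8.6, -4.0, -3.2, -2.5, 2.4, 2.0, 1.6, 0, 0, 0),
    mst_shift = c(25, 20, 16, 12, 10, 8, 7, 6, 6, 0, 0, 0),
    kd_um = c(200, 320, 450, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full screening plate
#'
#' One two-state series per library compound, plus duplicate monomer controls
#' (no conversion), triplicate static dimer controls, and duplicate flat
#' buffer series. Sample and control wells carry the buffer background so the
#' reduction step performs real work; buffers see only baseline noise.
#'
#' @param library Fragment library data.frame (see
#'   [default_fragment_library()]).
#' @param config A [sim_config()].
#' @return A `sim_plate` list: `sheet` (manifest-shaped data.frame), `series`
#'   (named list of raw [frame_series()]), `buffers` (list of buffer series),
#'   `truth` (planted-truth table), `config`.
#' @export
simulate_screen_plate <- function(library = default_fragment_library(),
                                  config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(library) < 1L) stop("fragment library is empty")
  set.seed(config$seed)
  model <- particle_model(R = config$radius)
  qg <- config$q_grid

  add_buffer <- function(series) {
    for (i in seq_along(series$curves)) {
      series$curves[[i]]$intensity <-
        series$curves[[i]]$intensity + config$buffer_level
    }
    series
  }
  # per-well pipetting scatter: one concentration factor for the whole series
  conc_jitter <- function(series) {
    f <- 1 + stats::rnorm(1, sd = config$conc_cv)
    for (i in seq_along(series$curves)) {
      series$curves[[i]]$intensity <- f * series$curves[[i]]$intensity
      if (!is.null(series$curves[[i]]$sigma)) {
        series$curves[[i]]$sigma <- f * series$curves[[i]]$sigma
      }
      series$curves[[i]]$meta$conc_factor <- f
    }
    series
  }
  series <- list()
  sheet <- list()
  row <- function(well, role, id, repl) {
    data.frame(well = well, role = role, compound_id = id, conc_mM = 0.5,
               replicate = repl,
               path_pattern = paste0(well, "_frame{frame}.dat"),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(library))) {
    well <- sprintf("S%02d", i)
    kin <- dimerization_kinetics(library$k_true[i], library$x_inf[i])
    series[[well]] <- add_buffer(conc_jitter(simulate_two_state_series(
      model, kin, config, label = library$id[i])))
    sheet[[length(sheet) + 1L]] <- row(well, "sample", library$id[i], 1L)
  }
  for (r in seq_len(config$n_monomer_controls)) {
    well <- sprintf("M%02d", r)
    series[[well]] <- add_buffer(conc_jitter(simulate_two_state_series(
      model, dimerization_kinetics(0, 0), config,
      label = sprintf("monomer-DMSO-%d", r))))
    sheet[[length(sheet) + 1L]] <- row(well, "monomer-control",
                                       sprintf("DMSO-mono-%d", r), r)
  }
  for (r in seq_len(config$n_dimer_controls)) {
    well <- sprintf("D%02d", r)
    series[[well]] <- add_buffer(conc_jitter(simulate_two_state_series(
      model, dimerization_kinetics(0, 1), config,
      label = sprintf("dimer-NADH-DMSO-%d", r), x0 = 1)))
    sheet[[length(sheet) + 1L]] <- row(well, "dimer-control",
                                       sprintf("NADH-dimer-%d", r), r)
  }
  buffers <- list()
  for (r in seq_len(config$n_buffers)) {
    well <- sprintf("B%02d", r)
    curves <- vector("list", length(config$frame_times))
    for (i in seq_along(config$frame_times)) {
      ii <- rep(config$buffer_level, length(qg))
      sigma <- NULL
      if (config$epsilon > 0) {
        sigma <- rep(config$epsilon / 10, length(qg))
        ii <- ii + stats::rnorm(length(qg), sd = sigma)
      }
      curves[[i]] <- scattering_curve(
        qg, ii, sigma = sigma,
        meta = list(label = sprintf("buffer-%d", r),
                    time = config$frame_times[i], frame = i,
                    exposure = config$exposure))
    }
    buffers[[well]] <- frame_series(curves, label = sprintf("buffer-%d", r))
    sheet[[length(sheet) + 1L]] <- row(well, "buffer",
                                       sprintf("buffer-%d", r), r)
  }
  structure(list(sheet = do.call(rbind, sheet), series = series,
                 buffers = buffers, truth = library, config = config),
            class = "sim_plate")
}

#' Write a simulated plate to disk as manifest + .dat files
#'
#' @param plate A [simulate_screen_plate()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "sim_plate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_series <- c(plate$series, plate$buffers)
  for (well in names(all_series)) {
    sr <- all_series[[well]]
    for (i in seq_along(sr$curves)) {
      write_dat(sr$curves[[i]],
                file.path(dir, sprintf("%s_frame%d.dat", well, i)))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(plate$sheet, manifest, row.names = FALSE)
  utils::write.csv(plate$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Simulate DSF melt curves and MST traces for a fragment library
#'
#' Melt curves are Boltzmann sigmoids (baseline 100, plateau 1000, slope
#' 1.5 degC) around a reference Tm of 62 degC shifted by each compound's
#' planted delta_tm, with a post-peak SYPRO-like decay, per-curve Tm jitter
#' `sigma_tm` and fluorescence noise. A fixed number
#' `round(pathological_fraction * n)` of compounds (chosen from the seeded
#' RNG) receive pathological curves (flat-high interference or no-transition
#' ramps) that the melt QC must exclude. MST traces are step responses
#' normalized to a pre-excitation baseline, with DMSO reference amplitude
#' 956.3 response units shifted by the planted `mst_shift`.
#'
#' @param library Fragment library data.frame.
#' @param seed Integer RNG seed.
#' @param n_reference Number of DMSO reference replicates for each assay.
#' @param pathological_fraction Fraction of compound melt curves planted as
#'   pathological (default 0.23).
#' @param sigma_tm Spread of the DMSO reference Tm pool (degC): well-to-well
#'   and plate-to-plate variation, the component that sets the screen's
#'   3-sigma cutoff.
#' @param sigma_tm_within Within-plate Tm measurement precision applied to
#'   compound wells (degC); much smaller than the pool spread, which is why
#'   k-sigma hit calls against the pool are reliable.
#' @param noise_frac Fluorescence noise as a fraction of the sigmoid span.
#' @param mst_sigma Spread of the DMSO reference MST amplitude pool
#'   (response units).
#' @param mst_sigma_within Within-plate MST amplitude precision for compound
#'   wells (response units).
#' @return List with `melts` (named list of melt data.frames), `reference_melts`,
#'   `mst` (named list of trace data.frames), `reference_mst`, and `truth`
#'   (library plus `pathological` flag).
#' @export
simulate_triage_assays <- function(library = default_fragment_library(),
                                   seed, n_reference = 6,
                                   pathological_fraction = 0.23,
                                   sigma_tm = 0.15, sigma_tm_within = 0.03,
                                   noise_frac = 0.01,
                                   mst_sigma = 1.4, mst_sigma_within = 0.5) {
  if (missing(seed)) stop("simulate_triage_assays requires a seed")
  set.seed(as.integer(seed))
  n <- nrow(library)
  tm_ref <- 62
  temps <- seq(25, 99, by = 1)
  n_path <- round(pathological_fraction * n)
  path_idx <- if (n_path > 0) sample.int(n, n_path) else integer(0)

  melt_curve <- function(tm) {
    B <- 100; P <- 1000; a <- 1.5
    f <- B + (P - B) / (1 + exp((tm - temps) / a))
    decay <- exp(-pmax(0, temps - (tm + 5)) / 25)
    f <- B + (f - B) * decay
    f <- f + stats::rnorm(length(temps), sd = noise_frac * (P - B))
    data.frame(temperature = temps, fluorescence = f)
  }
  pathological_curve <- function(kind) {
    if (kind == "flat-high") {
      data.frame(temperature = temps,
                 fluorescence = 950 + stats::rnorm(length(temps), sd = 15))
    } else { # monotone ramp, no transition before the end
      data.frame(temperature = temps,
                 fluorescence = 100 + 8 * (temps - 25) +
                   stats::rnorm(length(temps), sd = 5))
    }
  }
  melts <- list()
  pathological <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i %in% path_idx) {
      pathological[i] <- TRUE
      kind <- if (stats::runif(1) < 0.5) "flat-high" else "ramp"
      melts[[library$id[i]]] <- pathological_curve(kind)
    } else {
      tm <- tm_ref + library$delta_tm[i] +
        stats::rnorm(1, sd = sigma_tm_within)
      melts[[library$id[i]]] <- melt_curve(tm)
    }
  }
  reference_melts <- lapply(seq_len(n_reference), function(r) {
    melt_curve(tm_ref + stats::rnorm(1, sd = sigma_tm))
  })
  names(reference_melts) <- sprintf("DMSO-%d", seq_len(n_reference))

  amp_ref <- 956.3
  mst_trace <- function(amplitude) {
    tt <- seq(0, 24, by = 0.1)
    scans <- lapply(1:3, function(s) {
      f <- ifelse(tt >= 3 & tt <= 23, amplitude / 1000, 1)
      f <- f + stats::rnorm(length(tt), sd = 2e-4)
      data.frame(time = tt, fluorescence = f, scan = s)
    })
    do.call(rbind, scans)
  }
  mst <- list()
  for (i in seq_len(n)) {
    amp <- amp_ref + library$mst_shift[i] +
      stats::rnorm(1, sd = mst_sigma_within)
    mst[[library$id[i]]] <- mst_trace(amp)
  }
  reference_mst <- lapply(seq_len(n_reference), function(r) {
    mst_trace(amp_ref + stats::rnorm(1, sd = mst_sigma))
  })
  names(reference_mst) <- sprintf("DMSO-%d", seq_len(n_reference))

  truth <- library
  truth$pathological <- pathological
  list(melts = melts, reference_melts = reference_melts, mst = mst,
       reference_mst = reference_mst, truth = truth)
}

#' Simulate a one-site binding titration
#'
#' Sixteen-point twofold dilution series from 150 nM to ~5 mM (matching a
#' typical MST titration layout) with Gaussian response noise.
#'
#' @param kd_um Dissociation constant (\eqn{\mu M}).
#' @param r0,delta_r Baseline response and span.
#' @param noise SD of Gaussian response noise.
#' @param seed Optional seed.
#' @return data.frame with `conc_um` and `response`.
#' @export
simulate_titration <- function(kd_um, r0 = 900, delta_r = 60, noise = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  conc <- 0.15 * 2^(0:15) # microM: 0.15 .. ~4915
  resp <- r0 + delta_r * conc / (kd_um + conc)
  if (noise > 0) resp <- resp + stats::rnorm(length(conc), sd = noise)
  data.frame(conc_um = conc, response = resp)
}
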