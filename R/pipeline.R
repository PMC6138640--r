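#' Measure every division of a synthetic scene from its rendered stacks
#'
#' Runs the full measurement pipeline on one ground-truth series: each
#' cycle's telophase frame is rendered (membrane channel), the dividing
#' cell is segmented with a seed at the neuroblast centre, and the
#' division axis is extracted from the telophase shape (or from the
#' centrosome channel, oriented by the shape axis, when
#' `method = "centrosome"`).
#'
#' @param truth a [sample_division_series()] result.
#' @param noise logical; render with the scene's noise model.
#' @param method `"shape"` or `"centrosome"`.
#' @param nb_id identifier used in the returned records.
#' @param on_error `"skip"` drops cycles whose segmentation or pole
#'   extraction fails (listed in `skipped`, as with unmeasurable divisions
#'   in real recordings); `"error"` propagates the failure.
#' @return list with `records` (list of [division_record()]s), `angles`
#'   (data.frame from [measure_alpha_beta()]), `axis_errors_deg`
#'   (per-cycle angle between measured and true axis, NA where skipped)
#'   and `skipped` (messages for dropped cycles).
#' @export
quantify_scene <- function(truth, noise = TRUE,
                           method = c("shape", "centrosome"),
                           nb_id = "nb1", on_error = c("skip", "error")) {
  stopifnot(inherits(truth, "scene_truth"))
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  records <- vector("list", truth$n_cycles)
  errs <- rep(NA_real_, truth$n_cycles)
  skipped <- character()
  for (i in seq_len(truth$n_cycles)) {
    cy <- truth$cycles[[i]]
    ch <- if (method == "centrosome") c("membrane", "centrosomes") else "membrane"
    res <- tryCatch({
      fr <- render_frame(truth, cy$telophase_frame, channels = ch, noise = noise)
      mask <- segment_cell(fr$membrane, seed_point = truth$nb_centre)
      ax <- find_poles_from_shape(mask)
      if (method == "centrosome")
        ax <- centrosome_axis(fr$centrosomes, reference_axis = ax)
      ax
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "error") stop(res)
      skipped <- c(skipped, sprintf("%s cycle %d: %s", nb_id, i, conditionMessage(res)))
      next
    }
    records[[i]] <- division_record(nb_id, i, res, method = method,
                                    telophase_frame = cy$telophase_frame,
                                    rounding_frame = cy$rounding_frame,
                                    qc = attr(res, "qc") %||% character())
    errs[i] <- axis_angle(res, cy$true_axis)
  }
  records <- records[!vapply(records, is.null, logical(1L))]
  list(records = records,
       angles = measure_alpha_beta(records),
       axis_errors_deg = errs,
       skipped = skipped)
}

#' Ground-truth alpha and beta angles of a scene
#'
#' Computes, from the truth alone (no rendering), the deviation of each
#' division axis from the previous one (alpha) and from the cue axis
#' defined by the previous cycle's daughter position at rounding onset
#' (beta).
#'
#' @param truth a [sample_division_series()] result.
#' @return data.frame with `cycle`, `alpha_deg`, `beta_deg` (one row per
#'   cycle from the second on).
#' @export
truth_angles <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  n <- truth$n_cycles
  if (n < 2L) stop("need at least 2 cycles")
  out <- data.frame(cycle = 2:n, alpha_deg = NA_real_, beta_deg = NA_real_)
  for (i in 2:n) {
    a_prev <- truth$cycles[[i - 1L]]
    a_cur <- truth$cycles[[i]]
    out$alpha_deg[i - 1L] <- axis_angle(a_prev$true_axis, a_cur$true_axis)
    cue <- axis3d(truth$nb_centre, a_prev$gmc_centre)
    out$beta_deg[i - 1L] <- axis_angle(cue, a_cur$true_axis)
  }
  out
}

#' End-to-end parameter recovery for a condition preset
#'
#' Samples `n_series` ground-truth series, renders and measures each
#' division through the full pipeline ([quantify_scene()]), and collects
#' the measured alpha angles next to the true ones. With
#' `render = FALSE` the measurement step uses the true axes (generator
#' validation without the raster stages).
#'
#' @param preset preset name or list, see [sample_division_series()].
#' @param n_series number of independent series.
#' @param n_cycles cycles per series (yields `n_cycles - 1` alphas each).
#' @param seed integer base seed; series seeds are derived from it.
#' @param noise logical; render with noise.
#' @param render logical; run the raster pipeline or use truth axes.
#' @param config,noise_model_obj scene configuration and noise model.
#' @return data.frame with `series`, `cycle`, `alpha_measured_deg`,
#'   `alpha_true_deg`.
#' @export
simulate_alpha_recovery <- function(preset, n_series, n_cycles = 3L, seed = 1L,
                                    noise = TRUE, render = TRUE,
                                    config = scene_config(),
                                    noise_model_obj = noise_model()) {
  out <- vector("list", n_series)
  for (s in seq_len(n_series)) {
    tr <- sample_division_series(preset, n_cycles,
                                 seed = derive_seed(seed, s),
                                 config = config, noise = noise_model_obj)
    ta <- truth_angles(tr)
    if (render) {
      q <- quantify_scene(tr, noise = noise, nb_id = paste0("nb", s))
      al <- q$angles[q$angles$kind == "alpha", ]
      meas <- al$angle_deg[match(ta$cycle, al$cycle_ref)]
    } else {
      meas <- ta$alpha_deg
    }
    out[[s]] <- data.frame(series = s, cycle = ta$cycle,
                           alpha_measured_deg = meas,
                           alpha_true_deg = ta$alpha_deg)
  }
  do.call(rbind, out)
}

#' Read a landmarks CSV
#'
#' Landmark files carry manually placed points: columns `nb_id`, `frame`
#' (0-based), `z`, `y`, `x` (0-based voxel indices) and `label` in
#' `bisect_p1`, `bisect_p2`, `apical_centrosome`, `basal_centrosome`.
#'
#' @param path CSV path (comment lines prefixed `#` allowed).
#' @param spacing `(dz, dy, dx)` to convert voxel indices to um.
#' @return data.frame with physical `z_um`, `y_um`, `x_um` columns added.
#' @export
read_landmarks <- function(path, spacing) {
  df <- read_report_csv(path)
  need <- c("nb_id", "frame", "z", "y", "x", "label")
  if (!all(need %in% names(df)))
    stop("landmarks CSV must have columns: ", paste(need, collapse = ", "))
  ok <- c("bisect_p1", "bisect_p2", "apical_centrosome", "basal_centrosome")
  if (!all(df$label %in% ok))
    stop("unknown landmark label(s): ",
         paste(setdiff(df$label, ok), collapse = ", "))
  sp <- unclass(as_voxel_spacing(spacing))
  df$z_um <- df$z * sp[1L]
  df$y_um <- df$y * sp[2L]
  df$x_um <- df$x * sp[3L]
  df
}

#' Write division records and angle measurements as CSV
#'
#' `divisions.csv`: one row per record with pole coordinates in um and qc
#' flags; `angles.csv`: the [measure_alpha_beta()] table.
#'
#' @param records list of [division_record()]s.
#' @param angles data.frame from [measure_alpha_beta()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_divisions_csv <- function(records, angles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  div <- do.call(rbind, lapply(records, function(r)
    data.frame(nb_id = r$nb_id, cycle = r$cycle,
               frame_telophase = r$telophase_frame,
               frame_rounding = r$rounding_frame, method = r$method,
               az = r$axis$a[1L], ay = r$axis$a[2L], ax = r$axis$a[3L],
               bz = r$axis$b[1L], by = r$axis$b[2L], bx = r$axis$b[3L],
               qc = paste(r$qc, collapse = ";"))))
  write_report_csv(div, file.path(dir, "divisions.csv"),
                   c("one row per measured division; coordinates in physical um (z,y,x), frames 0-based",
                     "a = apical pole, b = basal pole"))
  write_report_csv(angles, file.path(dir, "angles.csv"),
                   c("alpha: angle to previous division axis; beta: angle to daughter-cue axis; degrees in [0,180]"))
  invisible(dir)
}
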