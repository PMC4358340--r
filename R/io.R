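#' Read a centroid track file
#'
#' Delimited text with header `time_s,x_mm,y_mm`, one row per frame.
#' Sampling must be uniform; the frame rate is inferred from the median
#' time step.
#'
#' @param path File path.
#' @return A [worm_track()].
#' @export
read_track_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_track_file: no such file: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("read_track_file: header must contain %s",
                 paste(need, collapse = ",")))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("read_track_file: missing/NaN values at row %d", bad[1L]))
  worm_track(df$time_s, df$x_mm, df$y_mm)
}

#' Write a centroid track file
#'
#' @param track A [worm_track()].
#' @param path Output path.
#' @export
write_track_file <- function(track, path) {
  df <- data.frame(time_s = track$times, x_mm = track$x, y_mm = track$y)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_schema <- list(
  grid = c("n_x", "n_y", "cell_size_mm"),
  prior = c("sigma", "center_x", "center_y"),
  odor = c("a", "rho", "D", "tau"),
  belief = c("log_one_minus_p0", "pnohit_mode"),
  search = c("max_steps", "stall_limit", "border_margin",
             "transition_epsilon", "start_offset_sigma", "speed_mm_s",
             "rho1_as_printed"),
  ddm = c("drift_A", "noise_c", "x0", "dt", "max_time"),
  chemotaxis = c("lambda_max", "lambda_ss", "tau_adapt",
                 "concentration_gain"),
  synth = c("speed_mm_s", "fps", "duration_s", "arena_mm", "local_rate",
            "global_rate", "turn_kernel", "heading_jitter_deg", "ramp_s",
            "transition_type", "transition_t", "transition_drift",
            "transition_noise"),
  analysis = c("bin_width", "angle_threshold_deg", "window_s",
               "n_restarts"),
  seed = NULL, out_dir = NULL)

#' Read and validate a run configuration (YAML)
#'
#' Sections: `grid`, `prior`, `odor`, `belief`, `search`, `ddm`,
#' `chemotaxis`, `synth`, `analysis`, plus top-level `seed` and `out_dir`.
#' Unknown sections or keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list of validated sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("read_run_config: not a mapping")
  for (sec in names(cfg)) {
    if (!sec %in% names(run_config_schema))
      stop(sprintf("read_run_config: unknown section '%s'", sec))
    allowed <- run_config_schema[[sec]]
    if (is.null(allowed)) next
    extra <- setdiff(names(cfg[[sec]]), allowed)
    if (length(extra))
      stop(sprintf("read_run_config: unknown key '%s.%s'", sec, extra[1L]))
  }
  cfg
}

# fill a search_config from a (possibly partial) run config
search_config_from_run <- function(cfg) {
  g <- cfg$grid; p <- cfg$prior; o <- cfg$odor; b <- cfg$belief
  s <- cfg$search
  grid <- grid_spec(g$n_x %||% 128L, g$n_y %||% 128L,
                    g$cell_size_mm %||% 0.2)
  sigma <- p$sigma %||% 16
  prior <- if (!is.null(p$center_x))
    gaussian_prior(c(p$center_x, p$center_y), sigma) else NULL
  odor <- odor_params(o$a %||% 1, o$rho %||% 0.7, o$D %||% 1,
                      o$tau %||% 400)
  search_config(grid = grid, prior = prior, odor = odor, sigma = sigma,
                log_one_minus_p0 = b$log_one_minus_p0 %||% -100,
                pnohit_mode = b$pnohit_mode %||% "averaged",
                rho1_as_printed = isTRUE(s$rho1_as_printed),
                max_steps = s$max_steps %||% 2500L,
                stall_limit = s$stall_limit %||% 15L,
                border_margin = s$border_margin %||% 1L,
                transition_epsilon = s$transition_epsilon %||% 1e-3,
                start_offset_sigma = s$start_offset_sigma %||% 2,
                speed_mm_s = s$speed_mm_s %||% 0.17)
}

synth_config_from_run <- function(cfg) {
  sy <- cfg$synth
  tsrc <- if (identical(sy$transition_type, "fixed"))
    list(type = "fixed", t = sy$transition_t %||% 900)
  else list(type = "ddm", drift = sy$transition_drift %||% (1 / 9),
            noise = sy$transition_noise %||% 0.5, x0 = -100)
  synth_config(speed_mm_s = sy$speed_mm_s %||% 0.17, fps = sy$fps %||% 3,
               duration_s = sy$duration_s %||% 1680,
               arena_mm = sy$arena_mm %||% 25.4,
               local_rate = sy$local_rate %||% 4,
               global_rate = sy$global_rate %||% 0.5,
               transition_source = tsrc,
               turn_kernel = sy$turn_kernel %||% "sharp",
               heading_jitter_deg = sy$heading_jitter_deg %||% 3,
               ramp_s = sy$ramp_s %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
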