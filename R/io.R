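# Run configuration and the pipeline surface behind the command-line tool.

#' Default run configuration
#'
#' All physical quantities carry unit suffixes in their field names. The
#' defaults reproduce the reference setting: 5-layer head model, channel 1
#' of the standard montage (31.3 mm long / 8.3 mm short), situation-1
#' protocol at 10 Hz, DPF = 6, noise off, seed 0.
#'
#' @return Nested list (schema `layernirs-config-v1`).
#' @export
default_config <- function() {
  list(
    schema = "layernirs-config-v1",
    medium = "head_model",
    layout = list(channel_id = 1L, long_mm = 31.3, short_mm = 8.3),
    protocol = list(situation = 1L, sample_rate_hz = 10, n_blocks = 5L),
    hrf = list(peak_delay = 6, under_delay = 16, disp_peak = 1,
               disp_under = 1, ratio = 1 / 6),
    extinction = "default",
    solver = list(cylinder_radius_mm = 150, max_terms = 4000L,
                  tol = 1e-8, fd_rel_step = 1e-4),
    mode = "nonlinear",
    methods = c("homogeneous", "short_corrected", "layered2", "layered5"),
    dpf = 6,
    noise_sd = 0,
    seed = 0L)
}

#' Read and validate a YAML run configuration
#'
#' Fields missing from the file fall back to [default_config()]; unknown
#' fields raise an error naming the offending path.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, where = "") {
    for (k in names(upd)) {
      key <- paste0(where, k)
      if (!k %in% names(base))
        stop("unknown config field: '", key, "'")
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(key, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_into(cfg, user)
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  l <- cfg$layout
  if (!is.numeric(l$long_mm) || !is.numeric(l$short_mm) ||
      any(l$short_mm >= l$long_mm))
    stop("config field 'layout': short_mm must be smaller than long_mm")
  if (!cfg$protocol$situation %in% c(1, 2))
    stop("config field 'protocol.situation': must be 1 or 2")
  if (cfg$dpf <= 0) stop("config field 'dpf': must be positive")
  if (cfg$noise_sd < 0) stop("config field 'noise_sd': must be >= 0")
  invisible(TRUE)
}

# polynomial rolling hash (exact in doubles below 2^53) over the canonical
# YAML serialisation; enough to fingerprint a config in artifact sidecars.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.cfg_medium <- function(cfg) {
  if (identical(cfg$medium, "head_model"))
    return(head_model(cylinder_radius = cfg$solver$cylinder_radius_mm))
  layers <- lapply(cfg$medium$layers, function(x)
    optical_layer(x$mua_per_mm, x$musp_per_mm,
                  if (is.null(x$d_mm)) Inf else x$d_mm,
                  if (is.null(x$n)) 1.33 else x$n,
                  if (is.null(x$label)) NA_character_ else x$label))
  layered_medium(layers, cylinder_radius = cfg$solver$cylinder_radius_mm)
}

.cfg_table <- function(cfg) {
  if (identical(cfg$extinction, "default")) default_extinction_table()
  else read_extinction_table(cfg$extinction)
}

#' Run one pipeline stage and write its artifacts
#'
#' Deterministic artifacts for a fixed config and seed:
#' \describe{
#'   \item{simulate}{`data.csv` (tidy attenuation) + `data.json` sidecar.}
#'   \item{mppl}{`mppl.csv`: one row per layer, wavelength and separation.}
#'   \item{reconstruct}{`results.csv` (time_s, role, delta_hbo_uM,
#'     delta_hbr_uM, method) + `report.json` (K values, condition
#'     numbers).}
#'   \item{evaluate}{`grid_mua.csv` / `grid_thickness.csv` sensitivity
#'     surfaces.}
#' }
#'
#' @param config a config list from [read_run_config()].
#' @param command one of `"simulate"`, `"mppl"`, `"reconstruct"`,
#'   `"evaluate"`.
#' @param out_dir output directory (created if needed).
#' @param grid_steps,grid_range evaluation-grid resolution and ranges.
#' @return Named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("simulate", "mppl", "reconstruct",
                                     "evaluate"),
                         out_dir = ".",
                         grid_steps = 5L,
                         grid_range = c(mua = 0.5, thickness = 0.25)) {
  command <- match.arg(command)
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  medium <- .cfg_medium(config)
  table <- .cfg_table(config)
  layout <- probe_layout(config$layout$channel_id, config$layout$long_mm,
                         config$layout$short_mm)
  solver <- list(tol = config$solver$tol,
                 max_terms = config$solver$max_terms)
  simulate_data <- function() {
    proto <- situation_protocol(config$protocol$situation,
                                sample_rate = config$protocol$sample_rate_hz,
                                n_blocks = config$protocol$n_blocks)
    cs <- concentration_timeseries(proto, hrf_args = config$hrf,
                                   table = table)
    as <- do.call(forward_attenuation,
                  c(list(series = cs, medium = medium, layout = layout,
                         table = table, mode = config$mode,
                         noise_sd = config$noise_sd, seed = config$seed),
                    solver))
    list(cs = cs, as = as)
  }
  written <- character()

  if (command == "simulate") {
    sim <- simulate_data()
    f <- file.path(out_dir, "data.csv")
    write_attenuation_csv(sim$as, f,
                          meta = list(config_hash = hash,
                                      seed = config$seed,
                                      situation = config$protocol$situation))
    written <- c(data = f, sidecar = sub("\\.csv$", ".json", f))
  } else if (command == "mppl") {
    rows <- list()
    rhos <- c(layout$short_mm[1], layout$long_mm[1])
    for (w in c(690, 830)) {
      m <- medium
      roles <- roles_head_model(medium)
      for (r in c("U", "L")) {
        conc <- mua_to_conc(medium$mua[roles[[r]]], table)
        m <- set_mua(m, conc_to_mua(conc[["hbo"]], conc[["hbr"]], w, table),
                     roles[[r]])
      }
      for (rho in rhos) {
        L <- do.call(mppl, c(list(medium = m, rho = rho), solver))
        rows[[length(rows) + 1L]] <- data.frame(
          layer = names(L), wavelength_nm = w, separation_mm = rho,
          mppl_mm = unname(L))
      }
    }
    f <- file.path(out_dir, "mppl.csv")
    df <- do.call(rbind, rows)
    df$config_hash <- hash
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    written <- c(mppl = f)
  } else if (command == "reconstruct") {
    sim <- simulate_data()
    res <- list(); report <- list(config_hash = hash, seed = config$seed)
    for (meth in config$methods) {
      fit <- switch(meth,
        homogeneous = reconstruct_hb(sim$as, "homogeneous", dpf = config$dpf,
                                     table = table),
        short_corrected = reconstruct_hb(sim$as, "short_corrected",
                                         dpf = config$dpf, table = table),
        layered2 = do.call(reconstruct_hb,
                           c(list(sim$as, "layered",
                                  medium = two_layer_merge(medium),
                                  table = table), solver)),
        layered5 = do.call(reconstruct_hb,
                           c(list(sim$as, "layered", medium = medium,
                                  table = table), solver)),
        stop("unknown method '", meth, "' in config"))
      d <- fit$delta
      if (fit$method == "layered") {
        for (r in c("U", "L"))
          res[[paste(meth, r)]] <- data.frame(
            time_s = d$time_s, role = r,
            delta_hbo_uM = d[[paste0("dhbo_", r)]],
            delta_hbr_uM = d[[paste0("dhbr_", r)]], method = meth)
        report[[meth]] <- list(condition_number = fit$condition)
      } else {
        res[[meth]] <- data.frame(time_s = d$time_s, role = "L",
                                  delta_hbo_uM = d$dhbo,
                                  delta_hbr_uM = d$dhbr, method = meth)
        if (!is.null(fit$K)) report[[meth]] <- list(K = as.list(fit$K))
      }
    }
    f <- file.path(out_dir, "results.csv")
    utils::write.csv(do.call(rbind, res), f, row.names = FALSE,
                     quote = FALSE)
    fr <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, fr, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(results = f, report = fr)
  } else { # evaluate
    sim <- simulate_data()
    for (wh in c("mua", "thickness")) {
      g <- do.call(prior_sensitivity,
                   c(list(sim$as, sim$cs, medium, which = wh,
                          rel_range = grid_range[[wh]],
                          n_steps = grid_steps, table = table), solver))
      f <- file.path(out_dir, paste0("grid_", wh, ".csv"))
      df <- as.data.frame(g)
      names(df)[1:2] <- if (wh == "mua") c("mua_U_per_mm", "mua_L_per_mm")
                        else c("d_U_mm", "d_L_mm")
      df$config_hash <- hash
      utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
      written <- c(written, stats::setNames(f, paste0("grid_", wh)))
    }
  }
  message(sprintf("[layernirs %s] config %s -> %s", command, hash,
                  paste(basename(written), collapse = ", ")))
  invisible(written)
}
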