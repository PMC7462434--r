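#' Load a simulation configuration from YAML
#'
#' Reads a run configuration with blocks `model`, `grid`, `fhn`,
#' `stimulus`, and `output`, validates it, and fills the reference
#' defaults (`a = 0.7`, `b = 0.5`, `eps = 0.1`, `dt = 0.05`, `dz = 0.5`,
#' `dx = 1`, 50 lateral nodes, stimulus amplitude 2, duration 2, axial
#' window `[0, 4]`). Exactly one of `R` (discrete model) or `K`
#' (continuum) must be present; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return an `ephapse_config`: list with `model`, `grid`
#'   ([grid_spec()]), `fhn` ([fhn_params()]), `coupling` (R or K),
#'   `protocol`, `output`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw a list with the same structure as the YAML file (useful for
#'   programmatic construction).
#' @export
config_from_list <- function(raw) {
  known_top <- c("model", "grid", "fhn", "stimulus", "output", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("config error: unknown top-level keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- raw$model
  if (is.null(m) || is.null(m$type) ||
      !m$type %in% c("discrete", "continuum"))
    stop("config error: model$type must be 'discrete' or 'continuum'",
         call. = FALSE)
  has_R <- !is.null(m$R); has_K <- !is.null(m$K)
  if (has_R && has_K)
    stop("config error: specify exactly one of R or K, not both",
         call. = FALSE)
  if (m$type == "discrete" && !has_R)
    stop("config error: discrete model requires R", call. = FALSE)
  if (m$type == "continuum" && !has_K)
    stop("config error: continuum model requires K", call. = FALSE)
  unknown_m <- setdiff(names(m), c("type", "R", "K"))
  if (length(unknown_m))
    stop("config error: unknown model keys: ",
         paste(unknown_m, collapse = ", "), call. = FALSE)

  gdef <- list(n_lateral = 50, z_extent = NULL, dz = 0.5, dx = 1,
               dt = 0.05, t_end = 100, snapshot_every = 1.0)
  g <- utils::modifyList(gdef, as.list(raw$grid))
  unknown_g <- setdiff(names(g), names(gdef))
  if (length(unknown_g))
    stop("config error: unknown grid keys: ",
         paste(unknown_g, collapse = ", "), call. = FALSE)
  grid <- do.call(grid_spec, g)

  fdef <- list(a = 0.7, b = 0.5, eps = 0.1)
  f <- utils::modifyList(fdef, as.list(raw$fhn))
  unknown_f <- setdiff(names(f), names(fdef))
  if (length(unknown_f))
    stop("config error: unknown fhn keys: ",
         paste(unknown_f, collapse = ", "), call. = FALSE)
  fhn <- do.call(fhn_params, f)

  st <- raw$stimulus
  protocol <- if (is.null(st)) {
    impulse_protocol(list())
  } else if (!is.null(st$pairs)) {
    pr <- st$pairs
    if (!is.list(pr)) pr <- asplit(pr, 1)
    impulse_protocol(pr,
                     duration = st$duration %||% 2,
                     amplitude = st$amplitude %||% 2,
                     z_window = st$z_window %||% c(0, 4),
                     n_lateral = grid$n_lateral)
  } else if (!is.null(st$train)) {
    tr <- st$train
    poisson_train_protocol(
      n_lateral = grid$n_lateral,
      n_impulses = tr$n_impulses %||% 10,
      mean_interval = tr$mean_interval %||% 10,
      seed = tr$seed %||% raw$seed %||%
        stop("config error: stimulus train needs a seed", call. = FALSE),
      randomize_count = isTRUE(tr$randomize_count))
  } else {
    stop("config error: stimulus must contain `pairs` or `train`",
         call. = FALSE)
  }

  structure(list(model = m$type, grid = grid, fhn = fhn,
                 coupling = if (has_R) list(R = m$R) else list(K = m$K),
                 protocol = protocol,
                 output = as.list(raw$output), seed = raw$seed),
            class = "ephapse_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / reload a configuration as YAML
#'
#' `save_config()` writes a YAML file that [load_config()] reads back into
#' an identical configuration.
#'
#' @param config an `ephapse_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  g <- config$grid
  lst <- list(
    model = c(list(type = config$model), config$coupling),
    grid = list(n_lateral = g$n_lateral, z_extent = g$z_extent, dz = g$dz,
                dx = g$dx, dt = g$dt, t_end = g$t_end,
                snapshot_every = g$snapshot_every),
    fhn = list(a = config$fhn$a, b = config$fhn$b, eps = config$fhn$eps))
  ev <- config$protocol$events
  lst$stimulus <- if (identical(config$protocol$generator, "poisson_train")) {
    list(train = list(
      n_impulses = max(table(ev$lateral_index)),
      mean_interval = NA, seed = config$protocol$seed))
  } else {
    list(pairs = lapply(seq_len(nrow(ev)),
                        function(i) c(ev$lateral_index[i], ev$onset[i])),
         duration = if (nrow(ev)) ev$duration[1] else 2,
         amplitude = if (nrow(ev)) ev$amplitude[1] else 2,
         z_window = if (nrow(ev)) c(ev$z_min[1], ev$z_max[1]) else c(0, 4))
  }
  if (length(config$output)) lst$output <- config$output
  if (!is.null(config$seed)) lst$seed <- config$seed
  lst <- rapply(lst, function(x) x, how = "replace")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Run a configuration
#'
#' Dispatches a validated configuration to [simulate_discrete()] or
#' [simulate_continuum()].
#'
#' @param config an `ephapse_config` from [load_config()].
#' @param ... passed on to the solver (e.g. `record_z`, `record_w`).
#' @return an `ephapse_result`.
#' @export
run_config <- function(config, ...) {
  if (config$model == "discrete")
    simulate_discrete(config$grid, R = config$coupling$R, fhn = config$fhn,
                      protocol = config$protocol, ...)
  else
    simulate_continuum(config$grid, K = config$coupling$K, fhn = config$fhn,
                       protocol = config$protocol, ...)
}

#' Persist a simulation result archive
#'
#' Writes the full result -- snapshots, times, grid, model parameters, the
#' protocol echoed as JSON, and the package version -- to a single archive
#' file (R serialization, version 3). [load_result()] inverts it
#' losslessly; two identical runs produce archives whose `/v` payloads are
#' bit-identical.
#'
#' @param result an `ephapse_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_result <- function(result, path) {
  stopifnot(inherits(result, "ephapse_result"))
  result$timing <- NULL      # session metadata; keeps archives deterministic
  saveRDS(result, path, version = 3)
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) {
  if (!file.exists(path))
    stop("result archive not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!inherits(x, "ephapse_result"))
    stop("not an ephapse result archive: ", path, call. = FALSE)
  x
}

#' Sweep a coupling parameter and classify each regime
#'
#' Runs the standard two-impulse scenario for every value in `values`,
#' classifies the outcome with [classify_regime()], and returns (and
#' optionally writes) a regime table. When `out_dir` is given, completed
#' runs are cached on disk keyed by a configuration hash and skipped on
#' re-invocation, so an interrupted sweep resumes where it stopped. A
#' propagation failure at some value is recorded in the table and the scan
#' continues.
#'
#' @param values numeric vector of R (discrete) or K (continuum) values.
#' @param model `"discrete"` or `"continuum"`.
#' @param grid a [grid_spec()].
#' @param fhn an [fhn_params()].
#' @param protocol the stimulus; defaults to the standard two-impulse
#'   protocol (lateral 30 at t = 0, lateral 20 at t = 10).
#' @param out_dir optional cache/result directory.
#' @return data frame with `value`, `label`, `k`, `retro_chains`,
#'   `low_confidence`, `error`.
#' @export
scan_regimes <- function(values, model = c("discrete", "continuum"),
                         grid = grid_spec(t_end = 800, z_extent = 300),
                         fhn = fhn_params(), protocol = NULL,
                         out_dir = NULL) {
  model <- match.arg(model)
  if (is.null(protocol))
    protocol <- impulse_protocol(list(c(30, 0), c(20, 10)),
                                 n_lateral = grid$n_lateral)
  rows <- lapply(values, function(val) {
    key <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      cfg_tag <- sprintf("%d_%g_%g_%g_%g", grid$n_lateral,
                         grid$z_extent %||% -1, grid$t_end, grid$dt,
                         fhn$eps)
      key <- file.path(out_dir,
                       sprintf("scan_%s_%g_%s.rds", model, val, cfg_tag))
      if (file.exists(key)) return(readRDS(key))
    }
    row <- tryCatch({
      res <- if (model == "discrete")
        simulate_discrete(grid, R = val, fhn = fhn, protocol = protocol)
      else simulate_continuum(grid, K = val, fhn = fhn, protocol = protocol)
      reg <- classify_regime(res)
      data.frame(value = val, label = reg$label, k = reg$k,
                 retro_chains = reg$evidence$retro_chains,
                 low_confidence = reg$low_confidence, error = NA_character_)
    }, error = function(e)
      data.frame(value = val, label = NA_character_, k = NA_integer_,
                 retro_chains = NA_integer_, low_confidence = NA,
                 error = conditionMessage(e)))
    if (!is.null(key)) saveRDS(row, key)
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(), label = character(), k = integer(),
               retro_chains = integer(), low_confidence = logical(),
               error = character())
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, sprintf("regimes_%s.csv", model)),
                     row.names = FALSE)
  out
}
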