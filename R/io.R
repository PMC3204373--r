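#' Reproducibility manifest for a run
#'
#' Captures everything needed to reproduce a run bitwise: the full
#' configuration echo, the master seed and the derived substream seeds,
#' the package version and a timestamp.
#'
#' @param cfg An `experiment_config`.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(cfg) {
  structure(
    list(
      config = config_as_list(cfg),
      seed = cfg$seed,
      seed_inputs = cfg$seed_inputs,
      seed_topology = cfg$seed_topology,
      package_version = as.character(utils::packageVersion("dynsynrl")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

# flatten an experiment_config into plain lists for YAML/JSON
config_as_list <- function(cfg) {
  list(
    network = list(n_hidden = cfg$n_hidden),
    experiment = list(
      episode_ms = cfg$episode_ms, dt = cfg$dt,
      window_ms = cfg$window_ms, input_rate_hz = cfg$input_rate_hz,
      n_episodes = cfg$n_episodes, seed = cfg$seed,
      seed_inputs = cfg$seed_inputs, seed_topology = cfg$seed_topology,
      tau_c = cfg$tau_c, sigma_bins = cfg$sigma_bins
    ),
    neuron = unclass(cfg$neuron),
    synapse = list(
      U_SE = cfg$U_SE_init, tau_rec = cfg$tau_rec_init,
      tau_fac = cfg$tau_fac_init, A = cfg$A,
      literal_params = cfg$literal_params
    ),
    learning = list(
      eta = cfg$learning$eta, mu = cfg$learning$mu,
      alpha = cfg$learning$alpha, lambda_trace = cfg$learning$lambda_trace,
      trainable = as.list(cfg$learning$trainable),
      signs = as.list(cfg$learning$signs),
      bounds = lapply(cfg$learning$bounds, as.list),
      flip_inhibitory = cfg$learning$flip_inhibitory,
      attribution = cfg$learning$attribution,
      td_coupling = cfg$learning$td_coupling
    )
  )
}

#' Read and validate a configuration file
#'
#' Configurations are YAML with the nested sections `network`,
#' `experiment`, `neuron`, `synapse` and `learning`; every missing key
#' falls back to the package default, so an empty file yields the default
#' 7-hidden-neuron protocol. Invalid combinations (episode length not
#' divisible by the window, `|eta| >= 1`, `alpha <= 0`, ...) are rejected
#' with messages naming the offending keys.
#'
#' @param path Path to a YAML config file.
#' @return A validated `experiment_config`.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' @rdname load_config
#' @param x A nested list as produced by [config_as_list()] / YAML.
#' @export
config_from_list <- function(x) {
  g <- function(section, key, default) {
    v <- x[[section]][[key]]
    if (is.null(v)) default else v
  }
  neuron <- liaf_params(
    tau_V = g("neuron", "tau_V", 20),
    V_rest = g("neuron", "V_rest", 0),
    V_th = g("neuron", "V_th", 50),
    tau_refr = g("neuron", "tau_refr", 2)
  )
  ldef <- learning_config()
  signs <- g("learning", "signs", as.list(ldef$signs))
  bounds <- g("learning", "bounds", lapply(ldef$bounds, as.list))
  learning <- learning_config(
    eta = g("learning", "eta", ldef$eta),
    mu = g("learning", "mu", ldef$mu),
    alpha = g("learning", "alpha", ldef$alpha),
    lambda_trace = g("learning", "lambda_trace", ldef$lambda_trace),
    trainable = unlist(g("learning", "trainable", as.list(ldef$trainable))),
    signs = unlist(signs),
    bounds = lapply(bounds, unlist),
    flip_inhibitory = g("learning", "flip_inhibitory", ldef$flip_inhibitory),
    attribution = g("learning", "attribution", ldef$attribution),
    td_coupling = g("learning", "td_coupling", ldef$td_coupling)
  )
  experiment_config(
    n_hidden = g("network", "n_hidden", 7),
    episode_ms = g("experiment", "episode_ms", 200),
    dt = g("experiment", "dt", 1),
    window_ms = g("experiment", "window_ms", 5),
    input_rate_hz = g("experiment", "input_rate_hz", 50),
    n_episodes = g("experiment", "n_episodes", 300),
    seed = g("experiment", "seed", 1L),
    seed_inputs = x[["experiment"]][["seed_inputs"]],
    seed_topology = x[["experiment"]][["seed_topology"]],
    tau_c = g("experiment", "tau_c", 15),
    sigma_bins = g("experiment", "sigma_bins", 1),
    U_SE_init = g("synapse", "U_SE", 0.5),
    tau_rec_init = g("synapse", "tau_rec", 100),
    tau_fac_init = g("synapse", "tau_fac", 50),
    A = g("synapse", "A", default_A()),
    literal_params = g("synapse", "literal_params", FALSE),
    neuron = neuron,
    learning = learning
  )
}

#' Write a configuration to YAML
#'
#' @param cfg An `experiment_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_as_list(cfg), path)
  invisible(path)
}

#' Serialize spike trains
#'
#' Two plain-text formats are supported. The columnar format is a CSV
#' with columns `episode`, `neuron`, `t_ms`, one row per spike (empty
#' trains leave no rows but are recoverable from the `episodes` /
#' `neurons` arguments of the reader). The line format puts one train per
#' line: `episode_id,neuron_id,t1 t2 t3 ...` with space-separated integer
#' millisecond times.
#'
#' @param trains Named or nested list: `trains[[episode]][[neuron]]` is a
#'   `spike_train`, or a flat list of trains with `episode` / `neuron`
#'   supplied via `ids`.
#' @param path Output path.
#' @param ids Optional tibble with one row per train (`episode`,
#'   `neuron`) when `trains` is a flat list.
#' @param format `"csv"` (columnar) or `"lines"`.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path, ids = NULL, format = c("csv", "lines")) {
  format <- match.arg(format)
  flat <- flatten_trains(trains, ids)
  if (format == "csv") {
    rows <- purrr::pmap_dfr(flat, function(episode, neuron, train) {
      tibble::tibble(
        episode = episode, neuron = neuron,
        t_ms = if (n_spikes(train)) train$times else integer(),
        length_ms = train$length_ms
      )
    })
    # keep train lengths even for empty trains: one header row per train
    header <- purrr::pmap_dfr(flat, function(episode, neuron, train) {
      tibble::tibble(episode = episode, neuron = neuron,
                     t_ms = NA_integer_, length_ms = train$length_ms)
    })
    readr::write_csv(dplyr::bind_rows(header, rows), path)
  } else {
    lines <- purrr::pmap_chr(flat, function(episode, neuron, train) {
      sprintf("%d,%d,%d,%s", episode, neuron, train$length_ms,
              paste(train$times, collapse = " "))
    })
    writeLines(lines, path)
  }
  invisible(path)
}

flatten_trains <- function(trains, ids) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (!is.null(ids)) {
    stopifnot(nrow(ids) == length(trains))
    return(tibble::tibble(episode = ids$episode, neuron = ids$neuron,
                          train = trains))
  }
  if (all(vapply(trains, inherits, logical(1), "spike_train"))) {
    return(tibble::tibble(episode = seq_along(trains),
                          neuron = rep(1L, length(trains)),
                          train = trains))
  }
  purrr::imap_dfr(trains, function(ep_list, ep) {
    tibble::tibble(episode = as.integer(ep),
                   neuron = seq_along(ep_list), train = ep_list)
  })
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, format = c("csv", "lines")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    df |>
      dplyr::group_by(.data$episode, .data$neuron) |>
      dplyr::group_map(function(rows, key) {
        tibble::tibble(
          episode = key$episode, neuron = key$neuron,
          train = list(spike_train(
            sort(rows$t_ms[!is.na(rows$t_ms)]),
            length_ms = rows$length_ms[1]
          ))
        )
      }) |>
      dplyr::bind_rows()
  } else {
    lines <- readLines(path)
    purrr::map_dfr(lines, function(line) {
      parts <- strsplit(line, ",", fixed = TRUE)[[1]]
      times <- if (length(parts) < 4L || !nzchar(parts[4])) {
        integer()
      } else {
        scan(text = parts[4], quiet = TRUE)
      }
      tibble::tibble(
        episode = as.integer(parts[1]), neuron = as.integer(parts[2]),
        train = list(spike_train(times, length_ms = as.integer(parts[3])))
      )
    })
  }
}

#' Persist a training run as plain-text artifacts
#'
#' Writes `episodes.csv` (per-episode records), `parameters.csv` (the
#' eligible-synapse parameter trajectories), `strength.csv` (per-episode
#' time-averaged dynamic strengths), `config.yaml` (configuration echo)
#' and `manifest.json` into `out_dir`. Files round-trip losslessly
#' through [read_results()].
#'
#' @param result An `xor_training` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "xor_training"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$episodes, file.path(out_dir, "episodes.csv"))
  readr::write_csv(result$parameters, file.path(out_dir, "parameters.csv"))
  readr::write_csv(result$strength, file.path(out_dir, "strength.csv"))
  write_config(result$config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(unclass(result$manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname write_results
#' @param dir Directory previously written by [write_results()].
#' @return `read_results()` returns a list with the `episodes`,
#'   `parameters` and `strength` tibbles, the `config`
#'   (`experiment_config`) and the `manifest` list.
#' @export
read_results <- function(dir) {
  spec_ep <- readr::cols(
    episode = readr::col_integer(),
    n_output_spikes = readr::col_integer(),
    n_reference_spikes = readr::col_integer(),
    .default = readr::col_double()
  )
  spec_par <- readr::cols(
    episode = readr::col_integer(),
    syn_id = readr::col_integer(),
    inhibitory = readr::col_logical(),
    parameter = readr::col_character(),
    value = readr::col_double()
  )
  spec_str <- readr::cols(
    episode = readr::col_integer(),
    syn_id = readr::col_integer(),
    layer = readr::col_character(),
    inhibitory = readr::col_logical(),
    trained = readr::col_logical(),
    mean_S = readr::col_double()
  )
  list(
    episodes = readr::read_csv(file.path(dir, "episodes.csv"),
                               col_types = spec_ep),
    parameters = readr::read_csv(file.path(dir, "parameters.csv"),
                                 col_types = spec_par),
    strength = readr::read_csv(file.path(dir, "strength.csv"),
                               col_types = spec_str),
    config = load_config(file.path(dir, "config.yaml")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
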