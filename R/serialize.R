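#' Save and load networks as portable JSON
#'
#' Weights are stored column-major with explicit dimensions, so archives
#' are plain text and portable across platforms.
#'
#' @param net A [pcn_network()].
#' @param path File path.
#' @return `read_network()` returns the reconstructed [pcn_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  payload <- list(
    layer_sizes = net$layer_sizes,
    activation = net$activation,
    weights = lapply(net$weights, function(w)
      list(dim = dim(w), data = as.numeric(w))),
    update_mask = if (is.null(net$update_mask)) NULL else
      lapply(net$update_mask, function(w)
        list(dim = dim(w), data = as.numeric(w)))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(m) matrix(m$data, nrow = m$dim[1], ncol = m$dim[2])
  net <- pcn_network(payload$layer_sizes,
                     activation = payload$activation, init_sd = 0)
  net$weights <- if (is.data.frame(payload$weights)) {
    lapply(seq_len(nrow(payload$weights)), function(i)
      unpack(list(dim = payload$weights$dim[[i]],
                  data = payload$weights$data[[i]])))
  } else {
    lapply(payload$weights, unpack)
  }
  if (!is.null(payload$update_mask) && length(payload$update_mask)) {
    net$update_mask <- if (is.data.frame(payload$update_mask)) {
      lapply(seq_len(nrow(payload$update_mask)), function(i)
        unpack(list(dim = payload$update_mask$dim[[i]],
                    data = payload$update_mask$data[[i]])))
    } else {
      lapply(payload$update_mask, unpack)
    }
  }
  net
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys: `gamma0`, `max_steps`, `adaptive`, `activation`,
#'   `seed`, `rule`. Missing keys fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `control` (a [relax_control()]), `activation`,
#'   `seed` and `rule`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- relax_control()
  list(
    control = relax_control(
      gamma0 = cfg$gamma0 %||% defaults$gamma0,
      max_steps = cfg$max_steps %||% defaults$max_steps,
      adaptive = cfg$adaptive %||% defaults$adaptive
    ),
    activation = cfg$activation %||% "linear",
    seed = cfg$seed,
    rule = cfg$rule %||% "pc"
  )
}

#' Write a relaxation energy/step trace to CSV
#'
#' @param relaxation A [pcn_relax()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(relaxation, path) {
  tr <- relaxation$energy_trace
  df <- data.frame(step = seq_len(nrow(tr)) - 1L)
  for (j in seq_len(ncol(tr))) df[[paste0("energy", j)]] <- tr[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
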