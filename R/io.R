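#' Write and read takeover samples with provenance
#'
#' Samples travel as a CSV (`run_id`, `T`) plus a JSON sidecar holding
#' the provenance needed to replay the experiment: topology, parameters,
#' takeover fraction, seed, source and method. `read_samples()`
#' reconstructs a `takeover_samples` tibble from the pair.
#'
#' @param samples A `takeover_samples` tibble.
#' @param path CSV path; the sidecar defaults to the same path with a
#'   `.json` extension.
#' @param sidecar Optional explicit sidecar path.
#' @return `write_samples()`: `path` invisibly; `read_samples()`: a
#'   `takeover_samples` tibble.
#' @export
write_samples <- function(samples, path, sidecar = NULL) {
  sidecar <- sidecar %||% paste0(sub("\\.csv$", "", path), ".json")
  readr::write_csv(tibble(run_id = samples$run, T = samples$time), path)
  prov <- list(
    topology = attr(samples, "topology"),
    params = attr(samples, "params"),
    theta = attr(samples, "theta"),
    seed = attr(samples, "seed"),
    source = attr(samples, "source"),
    method = attr(samples, "method")
  )
  jsonlite::write_json(prov[!vapply(prov, is.null, logical(1))],
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path, sidecar = NULL) {
  sidecar <- sidecar %||% paste0(sub("\\.csv$", "", path), ".json")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  prov <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else list()
  new_takeover_samples(
    tab$T,
    topology = prov$topology %||% "custom",
    params = as.list(prov$params %||% list()),
    theta = prov$theta %||% 1,
    method = prov$method %||% "unknown",
    seed = prov$seed,
    source = prov$source
  )
}
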