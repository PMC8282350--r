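#' Ground-truth sidecar for synthetic datasets
#'
#' Every generator in the package returns, alongside the rendered data, a
#' `synthetic_truth` object recording the generating parameters, placements
#' and the RNG seed. Sidecars serialize to JSON and round-trip losslessly, so
#' recovery tests can always compare estimates against the exact truth.
#'
#' @param kind one of `"structure_image"`, `"nmj_image"`, `"mtf_video"`,
#'   `"ephys_trace"`, `"count_matrix"`.
#' @param params named list of generator parameters and placements.
#' @param seed integer seed the dataset was generated with.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(kind, params, seed) {
  kind <- match.arg(kind, c("structure_image", "nmj_image", "mtf_video",
                            "ephys_trace", "count_matrix"))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> kind=%s seed=%d params: %s\n",
              x$kind, x$seed, paste(names(x$params), collapse = ", ")))
  invisible(x)
}

#' Write / read a truth sidecar as JSON
#'
#' @param truth a [synthetic_truth] object.
#' @param path path of the `.json` file.
#' @return `write_truth` returns `path` invisibly; `read_truth` the object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(x$kind, x$params, x$seed)
}
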