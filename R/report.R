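#' Write and read a JSON analysis report
#'
#' Serializes an [md_analyze()] result together with its provenance
#' (input file, columns, transform, package version, seed) to JSON at full
#' double precision, and reads it back.  Numeric values round-trip
#' losslessly.
#'
#' @param result an `"md_result"`.
#' @param path output/input file path.
#' @param input optional provenance list (file, columns, ...).
#' @param seed optional seed recorded in the report.
#' @param plots optional character vector of rendered plot paths.
#' @return `write_md_report()` returns `path` invisibly;
#'   `read_md_report()` returns the report as a nested list.
#' @export
write_md_report <- function(result, path, input = NULL, seed = NULL,
                            plots = NULL) {
  if (!inherits(result, "md_result"))
    stop("`result` must be an `md_result`", call. = FALSE)
  strip <- function(iv) {
    out <- unclass(iv)
    out$gamma <- if (is.na(iv$gamma)) NULL else iv$gamma
    out
  }
  bundle <- list(
    software = list(package = "mdtol",
                    version = as.character(utils::packageVersion("mdtol"))),
    input = input,
    seed = seed,
    plots = plots,
    analysis = list(
      scale = result$scale,
      back_transformed = result$back_transformed,
      base = if (is.na(result$base)) NULL else result$base,
      beta = result$beta,
      gamma = result$gamma,
      summary = unclass(result$summary),
      normality_p = result$normality_p,
      intervals = lapply(result$intervals, strip),
      acceptance = if (is.null(result$acceptance)) NULL
                   else unclass(result$acceptance),
      decision = result$decision,
      means = result$md$means,
      diffs = result$md$diffs,
      subject_ids = result$md$subject_ids
    )
  )
  # 17 significant digits: doubles survive the text round trip bit-for-bit
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_md_report
#' @export
read_md_report <- function(path) {
  if (!file.exists(path))
    stop("report not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
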