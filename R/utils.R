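# Internal helpers: seed scoping and CSV conventions.

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive a child seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483647)
}

#' Write a results table as CSV with declared conventions
#'
#' All tabular outputs share one dialect: UTF-8, comma-separated, with
#' leading comment lines prefixed `#` declaring the coordinate and
#' statistical conventions (physical um, 0-based frames, type-7 quartiles).
#'
#' @param df a data.frame.
#' @param path output path.
#' @param comments character vector of comment lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by this package, skipping `#` comment lines
#' @param path file path.
#' @return data.frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
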