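#' Read cleavage time courses from a delimited table
#'
#' Expects header columns `time` and `fraction_intact`, plus optional
#' `construct_id` and `replicate`. The time unit may be declared either via
#' the `time_unit` argument or a `#units: s|min|h` comment line at the top of
#' the file (the comment wins). Comma- and tab-separated files are detected
#' from the extension.
#'
#' @param path CSV/TSV file
#' @param time_unit fallback unit when the file has no `#units:` header
#' @param condition_id label attached to every returned time course
#' @return a named list of [time_course()] objects, one per
#'   construct/replicate combination
#' @export
read_timecourse_table <- function(path, time_unit = "s",
                                  condition_id = "condition") {
  first <- readLines(path, n = 5)
  units_line <- grep("^#\\s*units:", first, value = TRUE)
  if (length(units_line)) {
    time_unit <- trimws(sub("^#\\s*units:", "", units_line[1]))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  for (col in c("time", "fraction_intact")) {
    if (!col %in% names(d)) {
      stop(sprintf("%s: missing required column '%s'", path, col),
           call. = FALSE)
    }
  }
  if (!"construct_id" %in% names(d)) d$construct_id <- "construct"
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  key <- interaction(d$construct_id, d$replicate, drop = TRUE)
  out <- lapply(split(d, key), function(g) {
    g <- g[order(g$time), ]
    time_course(g$time, g$fraction_intact,
                construct_id = g$construct_id[1],
                condition_id = condition_id,
                time_unit = time_unit)
  })
  out
}

#' Read a Mg2+ titration table
#'
#' Expects columns `mg_mM` and `k_obs_per_s`.
#'
#' @param path CSV/TSV file
#' @return an [mg_titration()]
#' @export
read_titration_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  for (col in c("mg_mM", "k_obs_per_s")) {
    if (!col %in% names(d)) {
      stop(sprintf("%s: missing required column '%s'", path, col),
           call. = FALSE)
    }
  }
  d <- d[order(d$mg_mM), ]
  mg_titration(d$mg_mM, d$k_obs_per_s)
}

#' Serialize an exponential fit to a JSON-ready list
#'
#' @param fit an `exp_fit`
#' @return a plain list with all fit fields and any selection diagnostics
#' @export
exp_fit_as_list <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  out <- unclass(fit)
  out$fitted <- NULL
  sel <- attr(fit, "selection")
  if (!is.null(sel)) out$selection <- sel
  out
}
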