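# Run configuration: a flat INI-style text format, [section] headers and
# key = value lines; values are parsed as logical, numeric, or
# comma-separated vectors, falling back to strings. The shipped baseline
# configuration reproduces the packaged reference-method defaults.

#' Read a run configuration file
#'
#' @param path Path to an INI-style config file (`[section]`,
#'   `key = value`, `#` comments).
#' @return Nested named list, one element per section.
#' @export
#' @examples
#' cfg <- read_run_config(default_config_path())
#' cfg$simulator$reference_rt
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    check_that(length(kv) == 2, "cannot parse config line: %s", ln)
    key <- trimws(kv[1])
    cfg[[section]][[key]] <- parse_config_value(trimws(kv[2]))
  }
  cfg
}

parse_config_value <- function(v) {
  parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  one <- function(x) {
    if (tolower(x) %in% c("true", "false")) return(as.logical(toupper(x)))
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) return(num)
    x
  }
  out <- lapply(parts, one)
  if (length(out) == 1L) out[[1]] else unlist(out)
}

#' @rdname read_run_config
#' @export
default_config_path <- function() {
  system.file("extdata", "baseline_config.ini", package = "qamskit",
              mustWork = TRUE)
}

# build an instrument profile / response model from a parsed config
profile_from_config <- function(cfg) {
  s <- cfg$simulator
  if (is.null(s)) return(instrument_profile())
  args <- list()
  for (k in c("reference_rt", "width_half", "tailing", "noise_sd",
              "drift", "dt", "run_length")) {
    if (!is.null(s[[k]])) args[[k]] <- s[[k]]
  }
  do.call(instrument_profile, args)
}
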