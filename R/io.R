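# Delimited-text formats. Every file opens with a schema-version comment so
# readers can refuse files they do not understand; floating point is written
# with fixed decimal precision so that identical runs are byte-identical and
# write(read(x)) round-trips exactly.

fmt_col <- function(x, digits = 6) {
  if (is.logical(x)) return(ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE")))
  if (is.integer(x)) return(ifelse(is.na(x), "NA", as.character(x)))
  if (is.numeric(x)) return(ifelse(is.na(x), "NA", sprintf("%.*f", digits, x)))
  ifelse(is.na(x), "NA", as.character(x))
}

write_tabular <- function(x, path, kind, header_extra = character(),
                          digits = 6) {
  body <- vapply(x, fmt_col, character(nrow(x)), digits = digits)
  body <- matrix(body, nrow = nrow(x))
  lines <- c(
    sprintf("# moodfit-%s v1", kind),
    header_extra,
    paste(names(x), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

read_tabular <- function(path, kind) {
  lines <- readLines(path)
  if (!startsWith(lines[1], sprintf("# moodfit-%s v1", kind))) {
    abort(sprintf("'%s' is not a moodfit %s file (v1).", path, kind))
  }
  meta_lines <- lines[startsWith(lines, "# ")][-1]
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^# ", "", l), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!startsWith(lines, "# ")]
  con <- textConnection(body)
  on.exit(close(con))
  d <- utils::read.delim(con, stringsAsFactors = FALSE)
  list(data = as_tibble(d), meta = meta)
}

session_col_types <- c(
  trial = "integer", choice = "character", certain_amount = "numeric",
  gamble_hi = "numeric", gamble_lo = "numeric", gamble_p = "numeric",
  p_win = "numeric", alt_hi = "numeric", alt_lo = "numeric",
  outcome = "numeric", revealed = "logical", cr = "numeric", ev = "numeric",
  rpe = "numeric", probe = "logical", rating = "numeric"
)

#' Read and write session files
#'
#' Sessions are stored as tab-delimited text with a schema-version header,
#' one row per trial (index, variant, choice, certain amount, gamble
#' high/low/probability, outcome, reveal flag, probe flag, rating on
#' \[0, 1\]). Ratings and money amounts are written with 6 decimal places,
#' so writing a session read from a canonical file reproduces it
#' byte-for-byte. `read_session()` validates the structural invariants
#' (probe gaps of 2-3 trials, zero RPE on unrevealed outcomes, term
#' exclusivity) and refuses violating files.
#'
#' @param session A `mood_session`.
#' @param path File path.
#' @param strict Enforce the variant's canonical trial/probe counts.
#' @return `write_session()` the path, invisibly; `read_session()` a
#'   `mood_session` tibble.
#' @export
write_session <- function(session, path) {
  extra <- c(
    sprintf("# variant: %s", session_variant(session)),
    sprintf("# endowment: %s",
            fmt_col(session_endowment(session), digits = 0))
  )
  write_tabular(session, path, "session", header_extra = extra)
}

#' @rdname write_session
#' @export
read_session <- function(path, strict = TRUE) {
  raw <- read_tabular(path, "session")
  d <- raw$data
  variant <- raw$meta$variant %||% abort("Session file lacks a variant header.")
  needed <- c("trial", "choice", "certain_amount", "gamble_hi", "gamble_lo",
              "gamble_p", "outcome", "revealed", "cr", "ev", "rpe", "probe",
              "rating")
  absent <- setdiff(needed, names(d))
  if (length(absent) > 0) {
    abort(sprintf("Session file '%s' is missing column(s): %s.", path,
                  paste(absent, collapse = ", ")))
  }
  for (col in names(d)) {
    type <- session_col_types[[col]]
    if (!is.null(type)) {
      d[[col]] <- switch(type,
        integer = as.integer(d[[col]]),
        numeric = as.numeric(d[[col]]),
        logical = as.logical(d[[col]]),
        character = as.character(d[[col]])
      )
    }
  }
  endow <- suppressWarnings(as.numeric(raw$meta$endowment %||% NA))
  s <- new_mood_session(d, variant, endow)
  validate_session(s, strict = strict)
  s
}

#' Read and write mood-model parameter files
#'
#' Parameters are stored as `key: value` text with full double precision
#' (17 significant digits), so a written file reads back to exactly the
#' same parameter values.
#'
#' @param params A [mood_params()] object.
#' @param path File path.
#' @return `write_params()` the path, invisibly; `read_params()` a
#'   `mood_params` object.
#' @export
write_params <- function(params, path) {
  flat <- params[!vapply(params, is.null, logical(1))]
  writeLines(c(
    "# moodfit-params v1",
    sprintf("%s: %.17g", names(flat), unlist(flat))
  ), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# moodfit-params v1") {
    abort(sprintf("'%s' is not a moodfit parameter file (v1).", path))
  }
  kv <- strsplit(lines[-1], ": ", fixed = TRUE)
  vals <- setNames(
    lapply(kv, function(x) as.numeric(x[2])),
    vapply(kv, `[`, character(1), 1)
  )
  do.call(mood_params, vals)
}

#' Read and write cohort configurations
#'
#' Configurations round-trip through YAML, a structured key-value text
#' format.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_config()` the path, invisibly; `read_config()` a
#'   `cohort_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$bdi_components <- lapply(raw$bdi_components, as.numeric)
  for (nm in c("hamd_mdd", "hamd_control", "phq_mdd", "phq_control",
               "age", "education")) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }
  keep <- intersect(names(raw), names(formals(cohort_config)))
  do.call(cohort_config, raw[keep])
}

#' Read and write tidy fit tables
#'
#' One row per participant and model family with all fitted parameters and
#' fit statistics, as tab-delimited text with a schema header.
#'
#' @param fit_table A fit table from [fit_cohort()].
#' @param path File path.
#' @return `write_fit_table()` the path, invisibly; `read_fit_table()` a
#'   tibble.
#' @export
write_fit_table <- function(fit_table, path) {
  write_tabular(fit_table, path, "fits", digits = 8)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  read_tabular(path, "fits")$data
}

#' Write a tidy statistics table
#'
#' @param stats_table A tibble of stacked [spearman_test()]-style rows.
#' @param path File path.
#' @return The path, invisibly (`read_stats_table()` returns the tibble).
#' @export
write_stats_table <- function(stats_table, path) {
  write_tabular(stats_table, path, "stats", digits = 8)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  read_tabular(path, "stats")$data
}
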