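#' The colony-count table
#'
#' Long-format table of plate-count observations, the exchange object of
#' the whole package. Columns (exact names):
#' \describe{
#'   \item{context}{community label, e.g. `"four_species"`, `"mono_Kv"`,
#'     `"no_Bc"`; planktonic contexts carry the `"planktonic"` prefix and
#'     are in cfu ml^-1.}
#'   \item{species}{species label.}
#'   \item{replicate}{integer >= 1.}
#'   \item{time_h}{sampling time in hours.}
#'   \item{cfu_per_cm2}{observed density, > 0; equals `detection_limit`
#'     on censored rows.}
#'   \item{censored}{logical, `TRUE` when the observation was below the
#'     detection limit.}
#'   \item{detection_limit}{detection limit of the plating assay.}
#' }
#' The key (context, species, replicate, time_h) must be unique.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `count_table` prepended.
#' @export
count_table <- function(df) {
  validate_count_table(df)
}

count_table_cols <- c("context", "species", "replicate", "time_h",
                      "cfu_per_cm2", "censored", "detection_limit")

#' @rdname count_table
#' @export
validate_count_table <- function(df) {
  if (!is.data.frame(df)) stop("count table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(count_table_cols, names(df))
  if (length(missing_cols)) {
    stop("count table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  df$censored <- as.logical(df$censored)
  bad <- which(!is.finite(df$cfu_per_cm2) | df$cfu_per_cm2 <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite cfu_per_cm2 at row ", bad[1L], call. = FALSE)
  }
  bad <- which(df$censored & df$cfu_per_cm2 != df$detection_limit)
  if (length(bad)) {
    stop("censored row ", bad[1L],
         " must carry the detection limit as its value", call. = FALSE)
  }
  bad <- which(df$replicate < 1L)
  if (length(bad)) stop("replicate < 1 at row ", bad[1L], call. = FALSE)
  key <- paste(df$context, df$species, df$replicate, df$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (context, species, replicate, time_h) key at row ",
         dup[1L], call. = FALSE)
  }
  class(df) <- unique(c("count_table", class(df)))
  df
}

#' Read / write a colony-count CSV
#'
#' CSV with the exact header
#' `context,species,replicate,time_h,cfu_per_cm2,censored,detection_limit`.
#' All [count_table()] invariants are checked on read; violations are
#' reported with their row number.
#'
#' @param path File path.
#' @return `read_count_table()` returns a validated [count_table()];
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), count_table_cols)) {
    stop("unexpected CSV header in ", path, "; expected exactly: ",
         paste(count_table_cols, collapse = ","), call. = FALSE)
  }
  validate_count_table(df)
}

#' @rdname read_count_table
#' @param table A [count_table()].
#' @export
write_count_table <- function(table, path) {
  table <- validate_count_table(table)
  utils::write.csv(as.data.frame(table)[, count_table_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-context fit results as CSV
#'
#' One row per (species, context), columns `species, context, x0, mu, K,
#' tau, status, sse, n_points` (see [fit_all_contexts()]).
#'
#' @param fits Data.frame as returned by [fit_all_contexts()].
#' @param path File path.
#' @export
write_fit_results <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_results
#' @export
read_fit_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' Small plain-text (YAML) record tying a pipeline output to the command,
#' configuration hash and seed that produced it, so any stochastic output
#' can be reproduced exactly.
#'
#' @param command Character description of the invocation.
#' @param config The configuration object used (hashed into the manifest).
#' @param seed Integer seed(s) governing the run.
#' @param outputs Character vector of output paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = NULL, seed = NA_integer_,
                         outputs = character()) {
  structure(list(
    command = command,
    config_hash = config_hash(config),
    seed = seed,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mixbiofilm"))),
    class = "run_manifest")
}

# order-stable polynomial rolling hash of the deparsed object; no external deps
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
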