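## Serialization: traces as CSV with '#' metadata headers; parameter sets
## and ensembles as structured text (YAML / CSV).  CSV is comma-separated,
## dot-decimal, UTF-8; anything else is a format error, never a silent
## misparse.

#' Write / read a membrane-PD trace as CSV
#'
#' Columns `time_s,pd_mV`, preceded by `#`-prefixed `key: value` metadata
#' lines.  Values round-trip at full precision; the uniform grid is
#' validated on read.
#'
#' @param tr an [ap_trace()].
#' @param path file path.
#' @return `read_trace` returns an [ap_trace()]; `write_trace` the path,
#'   invisibly.
#' @export
write_trace <- function(tr, path) {
  stopifnot(inherits(tr, "ap_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(tr$meta))
    writeLines(sprintf("# %s: %s", nm, format(tr$meta[[nm]], digits = 17)),
               con)
  writeLines("time_s,pd_mV", con)
  writeLines(paste(format(tr$t, digits = 17, trim = TRUE, scientific = FALSE),
                   format(tr$v, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      key <- trimws(substr(kv, 1, sep - 1))
      val <- trimws(substr(kv, sep + 1, nchar(kv)))
      numval <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(numval)) numval else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body) || trimws(body[1]) != "time_s,pd_mV")
    stop_arg("read_trace: expected header 'time_s,pd_mV' in ", path)
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(vapply(cells, length, integer(1)) != 2)
  if (length(bad))
    stop_arg("read_trace: row ", bad[1] + 1, " does not have two fields ",
             "(decimal commas are not a valid number format)")
  t <- suppressWarnings(as.numeric(vapply(cells, `[`, character(1), 1)))
  v <- suppressWarnings(as.numeric(vapply(cells, `[`, character(1), 2)))
  if (any(is.na(t)) || any(is.na(v)))
    stop_arg("read_trace: non-numeric value at data row ",
             which(is.na(t) | is.na(v))[1])
  dt <- diff(t)
  if (any(dt <= 0))
    stop_arg("read_trace: time not strictly increasing at row ",
             which(dt <= 0)[1] + 1, " (interval ", format(dt[dt <= 0][1]),
             " s)")
  if (max(dt) - min(dt) > 1e-9)
    stop_arg("read_trace: non-uniform sampling; first bad interval after ",
             "row ", which.max(abs(dt - dt[1])) + 1)
  ap_trace(t, v, meta)
}

#' Write / read an ensemble trace as CSV
#'
#' Columns `time_s,mean_mV,sd_mV,n`.
#'
#' @param e an [ensemble_trace()].
#' @param path file path.
#' @return `read_ensemble` an [ensemble_trace()]; `write_ensemble` the
#'   path, invisibly.
#' @export
write_ensemble <- function(e, path) {
  stopifnot(inherits(e, "ensemble_trace"))
  df <- data.frame(time_s = e$t, mean_mV = e$mean, sd_mV = e$sd, n = e$n)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "mean_mV", "sd_mV", "n")
  if (!all(need %in% names(df)))
    stop_arg("read_ensemble: expected columns ", paste(need, collapse = ","))
  ensemble_trace(df$time_s, df$mean_mV, df$sd_mV, df$n[1])
}

## known YAML fields per component (lazy: constructors live in another file)
ps_schema <- function() list(
  kinetics = names(formals(store_kinetics)),
  pump = names(formals(pump_params)),
  passive = names(formals(passive_params)),
  schedule = c("kappa_ramp", "gcl_decay"))

#' Write / read a parameter set as YAML
#'
#' The on-disk form mirrors the bundled tables' inheritance convention:
#' a file may name a registry base with `inherit: {table: N, column: L}`
#' and then override any subset of fields; fields not overridden are
#' inherited exactly as the registry resolves table blanks.  A file with
#' no `inherit` key must specify every component.  Unknown fields are a
#' schema error.
#'
#' @param ps a [parameter_set()].
#' @param path file path.
#' @return `read_parameter_set` a [parameter_set()];
#'   `write_parameter_set` the path, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  obj <- list(label = ps$label,
              V0 = if (is.na(ps$V0)) NULL else ps$V0,
              V_post = if (is.na(ps$V_post)) NULL else ps$V_post,
              kinetics = unclass(ps$kinetics),
              pump = if (is.null(ps$pump)) "none" else unclass(ps$pump),
              passive = unclass(ps$passive),
              schedule = list(kappa_ramp = ps$schedule$kappa_ramp,
                              gcl_decay = ps$schedule$gcl_decay))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  obj <- yaml::read_yaml(path)
  known_top <- c("label", "V0", "V_post", "inherit", "kinetics", "pump",
                 "passive", "schedule")
  extra <- setdiff(names(obj), known_top)
  if (length(extra))
    stop_arg("read_parameter_set: unknown field(s): ",
             paste(extra, collapse = ", "))
  base <- NULL
  if (!is.null(obj$inherit)) {
    if (!all(c("table", "column") %in% names(obj$inherit)))
      stop_arg("read_parameter_set: inherit needs 'table' and 'column'")
    base <- load_parameter_set(obj$inherit$table, obj$inherit$column)
  }
  get_comp <- function(name, ctor) {
    given <- obj[[name]]
    if (identical(given, "none") && name == "pump") return(NULL)
    if (!is.null(given)) {
      extra <- setdiff(names(given), ps_schema()[[name]])
      if (length(extra))
        stop_arg("read_parameter_set: unknown ", name, " field(s): ",
                 paste(extra, collapse = ", "))
    }
    if (is.null(base)) {
      if (is.null(given))
        stop_arg("read_parameter_set: missing '", name,
                 "' and no inherit source")
      if (name == "schedule")
        return(ap_schedule(kappa_ramp = given$kappa_ramp,
                           gcl_decay = given$gcl_decay))
      return(do.call(ctor, given))
    }
    base_comp <- base[[name]]
    if (is.null(given)) return(base_comp)
    if (name == "schedule") {
      merged <- modifyList(list(kappa_ramp = base_comp$kappa_ramp,
                                gcl_decay = base_comp$gcl_decay), given)
      return(ap_schedule(kappa_ramp = merged$kappa_ramp,
                         gcl_decay = merged$gcl_decay))
    }
    if (is.null(base_comp) && name == "pump") return(do.call(ctor, given))
    fields <- ps_schema()[[name]]
    merged <- modifyList(unclass(base_comp)[fields[fields %in% names(unclass(base_comp))]], given)
    do.call(ctor, merged)
  }
  kin <- get_comp("kinetics", store_kinetics)
  pump <- get_comp("pump", pump_params)
  pas <- get_comp("passive", passive_params)
  sched <- get_comp("schedule", NULL)
  if (is.null(sched)) sched <- ap_schedule()
  label <- obj$label %||% (if (!is.null(base)) base$label else "unnamed")
  V0 <- obj$V0 %||% (if (!is.null(base)) base$V0 else NA_real_)
  V_post <- obj$V_post %||% (if (!is.null(base)) base$V_post else NA_real_)
  parameter_set(label, kin, pump, pas, sched, V0 = V0, V_post = V_post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
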