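# Delimited-table readers/writers and rule-file serialization.

#' Read a subject-level survival table
#'
#' Expects one row per subject with at least a time and a cause column
#' (cause 0 = censored, positive integers = failure causes); remaining
#' columns are treated as covariates.  Lines starting with `#` are ignored.
#'
#' @param path input file (comma-delimited by default; any delimiter
#'   [data.table::fread()] can sniff).
#' @param time,cause,id column names.
#' @return data.frame with attributes recording the column mapping.
#' @export
read_survival_table <- function(path, time = "time", cause = "cause",
                                id = "id") {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  for (col in c(time, cause))
    if (!col %in% names(df))
      stop("input is missing required column '", col, "'")
  if (any(df[[time]] < 0)) stop("negative times in column '", time, "'")
  if (any(df[[cause]] < 0)) stop("negative cause codes in '", cause, "'")
  attr(df, "mapping") <- list(time = time, cause = cause, id = id)
  df
}

# standard output header: version, config echo, seed; no timestamps so that
# identical configurations reproduce files byte-for-byte
output_header <- function(config) {
  cfg <- vapply(config, function(v) paste(format(v), collapse = ","),
                character(1))
  c(sprintf("# pseudoDTR %s",
            as.character(utils::packageVersion("pseudoDTR"))),
    sprintf("# %s: %s", names(cfg), cfg))
}

write_table_with_header <- function(df, path, config = list()) {
  writeLines(output_header(config), path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a long-format multi-stage panel
#'
#' Column convention: per stage k the file carries `eta_k`, `a_k`, and
#' covariate columns prefixed `x{k}_` (stage 2 may also use a single `x2`
#' column).  Stage-k history features are the concatenation of all stage
#' `<= k` covariates and stage `< k` treatments.
#'
#' @param path delimited file.
#' @param stages number of stages K (default: inferred from `eta_*`
#'   columns).
#' @return a [stage_panel()]; the original data.frame is kept as attribute
#'   `data`.
#' @export
read_stage_panel <- function(path, stages = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (is.null(stages))
    stages <- sum(grepl("^eta_[0-9]+$", names(df)))
  if (stages < 1L) stop("no eta_k columns found")
  hist_cols <- character(0)
  stage_list <- vector("list", stages)
  for (k in seq_len(stages)) {
    eta_col <- paste0("eta_", k); a_col <- paste0("a_", k)
    for (col in c(eta_col, a_col))
      if (!col %in% names(df)) stop("input is missing column '", col, "'")
    xcols <- grep(paste0("^x", k, "(_|$)"), names(df), value = TRUE)
    hist_cols <- c(hist_cols, xcols)
    feats <- as.matrix(df[, hist_cols, drop = FALSE])
    stage_list[[k]] <- list(eta = df[[eta_col]], treatment = df[[a_col]],
                            features = feats)
    hist_cols <- c(hist_cols, a_col)  # treatments enter later histories
  }
  pn <- stage_panel(stage_list)
  attr(pn, "data") <- df
  pn
}

#' Serialize fitted regime rules to a structured text file
#'
#' One block per stage: stage index, objective, positive action, then
#' `feature, coefficient` pairs with the intercept first.  [read_rules()]
#' round-trips the file.
#'
#' @param fit a [fit_dtr()] object.
#' @param path output file.
#' @param feature_names optional list (per stage) of feature names.
#' @param config named list echoed into the header.
#' @export
write_rules <- function(fit, path, feature_names = NULL, config = list()) {
  stopifnot(inherits(fit, "dtr_fit"))
  lines <- output_header(c(list(objective = fit$objective,
                                method = fit$method), config))
  for (k in seq_len(fit$K)) {
    r <- fit$rules[[k]]
    nm <- if (!is.null(feature_names)) feature_names[[k]]
          else paste0("h", seq_along(r$coefficients))
    lines <- c(lines,
               sprintf("stage %d positive_action %s", k, r$positive_action),
               sprintf("(Intercept)\t%.17g", r$intercept),
               sprintf("%s\t%.17g", nm, r$coefficients))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rules
#' @param path rules file written by [write_rules()].
#' @return list of [linear_rule()] objects (one per stage) with attribute
#'   `feature_names`.
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  starts <- grep("^stage ", lines)
  stopifnot(length(starts) >= 1L)
  ends <- c(starts[-1L] - 1L, length(lines))
  rules <- vector("list", length(starts))
  fnames <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(lines[starts[i]], " ")[[1L]]
    block <- lines[(starts[i] + 1L):ends[i]]
    block <- block[nzchar(block)]
    parts <- strsplit(block, "\t")
    vals <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
    nms <- vapply(parts, `[`, character(1), 1L)
    rules[[i]] <- linear_rule(vals[1L], vals[-1L],
                              positive_action = utils::type.convert(
                                hdr[4L], as.is = TRUE))
    fnames[[i]] <- nms[-1L]
  }
  attr(rules, "feature_names") <- fnames
  rules
}
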