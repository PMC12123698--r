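#' Write / read a cohort as delimited text
#'
#' A cohort is stored as plain CSV files in a directory: `biopsies.csv`
#' (subject_id, biopsy_time, result), `covariates.csv` (subject_id, time,
#' z1..zp) and, when truth is retained, `truth.csv` (subject_id, T, C).
#'
#' @param cohort an `as_cohort`.
#' @param dir output directory (created if missing).
#' @param truth also write `truth.csv` when available.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- cohort$biopsies
  utils::write.csv(data.frame(subject_id = b$id, biopsy_time = b$time,
                              result = b$result),
                   file.path(dir, "biopsies.csv"), row.names = FALSE)
  cv <- cohort$covariates
  names(cv)[names(cv) == "id"] <- "subject_id"
  utils::write.csv(cv, file.path(dir, "covariates.csv"), row.names = FALSE)
  if (truth && !is.null(cohort$truth)) {
    tr <- cohort$truth
    utils::write.csv(data.frame(subject_id = tr$id, T = tr$T, C = tr$C),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param config a [scenario_config()] describing the stored cohort
#'   (landmark grid, tau, p); defaults to the package defaults.
#' @export
read_cohort <- function(dir, config = scenario_config()) {
  b <- utils::read.csv(file.path(dir, "biopsies.csv"))
  biopsies <- data.frame(id = as.integer(b$subject_id), time = b$biopsy_time,
                         result = as.integer(b$result))
  cv <- utils::read.csv(file.path(dir, "covariates.csv"))
  names(cv)[names(cv) == "subject_id"] <- "id"
  cv$id <- as.integer(cv$id)
  n <- max(biopsies$id, cv$id)
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    truth <- data.frame(id = as.integer(tr$subject_id), T = tr$T, C = tr$C)
  }
  new_cohort(biopsies, cv, truth, config, seed = NA_integer_, n = n)
}

#' Serialize / restore a fitted rule as JSON
#'
#' @param fit an [osf_i()] object (or a bare [linear_rule()]).
#' @param path output JSON file.
#' @return `path` invisibly; `read_rule()` returns an `osf_i` object.
#' @export
write_rule <- function(fit, path) {
  if (inherits(fit, "linear_rule")) {
    fit <- list(rule = fit, method = "linear_rule", landmarks = NULL,
                tau = NULL, lambda = fit$lambda, C_b = fit$C_b, xi = NULL)
  }
  obj <- list(method = fit$method,
              coefficients = as.list(fit$rule$coefficients),
              intercept = fit$rule$intercept,
              lambda = fit$lambda, C_b = fit$C_b,
              landmarks = fit$landmarks, tau = fit$tau,
              xi = if (is.null(fit$xi)) NULL else as.list(fit$xi))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rule <- linear_rule(unlist(obj$coefficients), obj$intercept,
                      lambda = obj$lambda %||% NA_real_,
                      C_b = obj$C_b %||% NA_real_)
  structure(list(rule = rule, xi = unlist(obj$xi),
                 sample_size = NA_integer_, n = NA_integer_,
                 objective = NA_real_, landmarks = obj$landmarks,
                 tau = obj$tau, lambda = obj$lambda %||% NA_real_,
                 C_b = obj$C_b %||% NA_real_, tradeoff = NULL,
                 method = obj$method %||% "OSF-I", call = NULL),
            class = "osf_i")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flat key-value configuration files
#'
#' Reads / writes a `key: value` text file mirroring [scenario_config()]
#' field names (Debian-control style, one field per line; vectors
#' comma-separated).
#'
#' @param path file path.
#' @return `read_config()` returns a [scenario_config()].
#' @export
read_config <- function(path) {
  dcf <- read.dcf(path)
  kv <- stats::setNames(as.list(dcf[1, ]), colnames(dcf))
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  args <- list()
  for (nm in names(kv)) {
    if (nm == "slope_cov") {
      v <- num(kv[[nm]])
      args[[nm]] <- matrix(v, 2, 2)
    } else {
      args[[nm]] <- num(kv[[nm]])
    }
  }
  do.call(scenario_config, args)
}

#' @rdname read_config
#' @param config a [scenario_config()].
#' @export
write_config <- function(config, path) {
  flat <- lapply(config, function(v) paste(as.vector(v), collapse = ","))
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}
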