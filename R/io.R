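# Configuration files: one YAML document per parameter table, each
# field annotated in the packaged defaults with its data provenance.
# Loading is strict: unknown keys are rejected and every probability is
# range-checked by the parameter constructors.

param_constructors <- function() {
  list(mammography = mammography_params,
       asthma = asthma_params,
       economics = economic_assumptions)
}

as_num <- function(x) {
  if (is.list(x)) vapply(x, as.numeric, numeric(1)) else
    stats::setNames(as.numeric(x), names(x))
}

#' Load a parameter set from a YAML configuration file
#'
#' The file must carry a top-level `model:` key (`mammography`,
#' `asthma` or `economics`); remaining keys mirror the arguments of
#' [mammography_params()], [asthma_params()] or
#' [economic_assumptions()]. Unknown keys are rejected; omitted keys
#' take the packaged base-case defaults; all probabilities are
#' validated to `[0, 1]` and distributions to sum to 1 (within `1e-6`,
#' then normalised exactly).
#'
#' Packaged base-case files live in `system.file("extdata", ...,
#' package = "hedisim")`.
#'
#' @param path Path to a YAML file.
#' @return A `mammography_params`, `asthma_params` or
#'   `economic_assumptions` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model) ||
      !cfg$model %in% names(param_constructors())) {
    stop("config must declare model: one of ",
         paste(names(param_constructors()), collapse = ", "))
  }
  kind <- cfg$model
  cfg$model <- NULL
  cfg$notes <- NULL
  ctor <- param_constructors()[[kind]]
  unknown <- setdiff(names(cfg), names(formals(ctor)))
  if (length(unknown)) {
    stop("unknown key(s) in ", kind, " config: ",
         paste(unknown, collapse = ", "))
  }
  if (kind == "mammography") {
    for (k in intersect(names(cfg), c(
      "incidence_screened", "stage_dist_unscreened",
      "p_remission_dx_year", "p_continued_remission",
      "annual_cancer_death_rate", "utility_remission",
      "disutility_treatment", "emp_treatment", "emp_remission",
      "cost_treatment", "days_multiplier"))) {
      cfg[[k]] <- as_num(cfg[[k]])
    }
    if (!is.null(cfg$stage_dist_screened)) {
      cfg$stage_dist_screened <- lapply(cfg$stage_dist_screened, as_num)
    }
  } else if (kind == "asthma") {
    for (k in intersect(names(cfg), c(
      "p_exac", "p_er", "p_admit", "daily_utilities",
      "days_available", "days_missed", "cost_event"))) {
      cfg[[k]] <- as_num(cfg[[k]])
    }
    if (!is.null(cfg$persistence)) {
      cfg$persistence <- lapply(cfg$persistence, as_num)
    }
    if (!is.null(cfg$utility_month)) {
      cfg$utility_month <- do.call(rbind, lapply(cfg$utility_month,
                                                 as_num))
    }
  }
  do.call(ctor, cfg)
}

#' Write a parameter set to a YAML configuration file
#'
#' Inverse of [load_params()]: `load_params(write_params(p, f))`
#' reproduces `p` exactly.
#'
#' @param params A parameter object from one of the constructors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  kind <- switch(class(params)[1L],
                 mammography_params = "mammography",
                 asthma_params = "asthma",
                 economic_assumptions = "economics",
                 stop("not a parameter object: ",
                      class(params)[1L]))
  x <- unclass(params)
  if (kind == "mammography") {
    x$stage_dist_screened <- lapply(x$stage_dist_screened, as.list)
    for (k in c("incidence_screened", "stage_dist_unscreened",
                "p_remission_dx_year", "p_continued_remission",
                "annual_cancer_death_rate", "utility_remission",
                "disutility_treatment", "emp_treatment",
                "emp_remission", "cost_treatment", "days_multiplier")) {
      x[[k]] <- as.list(x[[k]])
    }
  } else if (kind == "asthma") {
    x$persistence <- lapply(x$persistence, as.list)
    x$utility_month <- apply(x$utility_month, 1L, as.list,
                             simplify = FALSE)
    for (k in c("p_exac", "p_er", "p_admit", "daily_utilities",
                "days_available", "days_missed", "cost_event")) {
      x[[k]] <- as.list(x[[k]])
    }
  }
  x <- c(list(model = kind), x)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Path to a packaged base-case configuration file
#'
#' @param kind `"mammography"`, `"asthma"` or `"economics"`.
#' @return File path inside the installed package.
#' @export
default_config <- function(kind = c("mammography", "asthma",
                                    "economics")) {
  kind <- match.arg(kind)
  system.file("extdata", paste0(kind, ".yaml"), package = "hedisim",
              mustWork = TRUE)
}

config_hash <- function(params) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_params(params, f)
  unname(tools::md5sum(f))
}
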