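# Run configuration, report writers and the command-line front end.
# Configs are plain YAML or JSON (decided by file extension); unknown keys are
# rejected so typos fail loudly rather than silently falling back to defaults.

config_defaults <- function(model_family) {
  common <- list(
    m = NULL, seed = NULL, recode_policy = "recode_max_plus_one",
    tolerance_multiplier = 3, run_theorem2 = TRUE, output_dir = "."
  )
  if (model_family == "binomial") {
    c(common, list(
      n = NULL,
      hypotheses = list(
        specific = list(type = "point", theta0 = 0.5, label = "H0"),
        general = list(type = "beta", a = 1, b = 1, lower = 0, upper = 1,
                       label = "H1")
      )
    ))
  } else {
    c(common, list(
      generator = list(J = 3, per_group_n = 50, sigma2 = 0.5, alpha0 = 0,
                       r_gen = 0.5, scale_effects_by_sigma2 = TRUE),
      analysis_scale = "medium"
    ))
  }
}

reject_unknown_keys <- function(x, allowed, context) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown configuration key(s) in %s: %s", context,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

parse_hypothesis_spec <- function(spec, context) {
  reject_unknown_keys(spec, c("type", "theta0", "a", "b", "lower", "upper",
                              "label"), context)
  type <- spec$type
  if (is.null(type) || !type %in% c("point", "beta")) {
    stop(sprintf("%s: hypothesis `type` must be 'point' or 'beta'", context),
         call. = FALSE)
  }
  label <- spec$label %||% if (type == "point") "H0" else "H1"
  if (type == "point") {
    if (is.null(spec$theta0)) {
      stop(sprintf("%s: point hypothesis needs `theta0`", context),
           call. = FALSE)
    }
    point_hypothesis(spec$theta0, label)
  } else {
    beta_hypothesis(spec$a %||% 1, spec$b %||% 1, spec$lower %||% 0,
                    spec$upper %||% 1, label)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration, applies
#' defaults (point null at 1/2 vs Beta(1, 1) for the binomial family; the
#' three-arm medium-scale design for the ANOVA family), validates every key
#' and rejects unknown ones. A missing seed is drawn and stored so the run
#' stays reproducible.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config` (a validated named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  # restrict implicit booleans to true/false so that short keys such as `n`
  # (YAML 1.1 would read it as "no" = FALSE) survive as names
  yaml_handlers <- list(
    "bool#yes" = function(x) if (tolower(x) == "true") TRUE else x,
    "bool#no" = function(x) if (tolower(x) == "false") FALSE else x
  )
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path, handlers = yaml_handlers),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("configuration must be a .yaml/.yml or .json file", call. = FALSE)
  )
  if (!is.list(raw)) {
    stop("configuration must be a mapping of keys to values", call. = FALSE)
  }
  family <- raw$model_family
  if (is.null(family) || !family %in% c("binomial", "anova")) {
    stop("`model_family` must be 'binomial' or 'anova'", call. = FALSE)
  }
  defaults <- config_defaults(family)
  reject_unknown_keys(raw, c("model_family", names(defaults)), "configuration")

  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), "model_family")])
  cfg$model_family <- family

  if (is.null(cfg$m) || cfg$m < 2 || cfg$m != round(cfg$m)) {
    stop("`m` must be an integer >= 2", call. = FALSE)
  }
  cfg$m <- as.integer(cfg$m)
  cfg$seed <- materialize_seed(cfg$seed)
  if (!cfg$recode_policy %in% c("recode_max_plus_one", "drop", "fail")) {
    stop("`recode_policy` must be recode_max_plus_one, drop or fail",
         call. = FALSE)
  }

  if (family == "binomial") {
    if (is.null(cfg$n)) {
      stop("binomial configuration needs `n` (trials per data set)",
           call. = FALSE)
    }
    check_outcome(cfg$n, 0)
    cfg$n <- as.integer(cfg$n)
    reject_unknown_keys(cfg$hypotheses, c("specific", "general"),
                        "`hypotheses`")
    cfg$hypotheses$specific <- utils::modifyList(
      config_defaults("binomial")$hypotheses$specific,
      cfg$hypotheses$specific %||% list())
    cfg$hypotheses$general <- utils::modifyList(
      config_defaults("binomial")$hypotheses$general,
      cfg$hypotheses$general %||% list())
    # construct now so invalid hypothesis specs fail at load time
    parse_hypothesis_spec(cfg$hypotheses$specific, "`hypotheses$specific`")
    parse_hypothesis_spec(cfg$hypotheses$general, "`hypotheses$general`")
  } else {
    reject_unknown_keys(cfg$generator,
                        names(config_defaults("anova")$generator),
                        "`generator`")
    cfg$generator <- utils::modifyList(config_defaults("anova")$generator,
                                       cfg$generator %||% list())
    do.call(anova_gen_config, cfg$generator)
    as_jzs_prior(cfg$analysis_scale)
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to disk
#'
#' Round-trip companion to [load_config()]; the format follows the file
#' extension.
#'
#' @param config A `run_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(out, path, handlers = list(
      logical = function(x) {
        res <- ifelse(x, "true", "false")
        class(res) <- "verbatim"
        res
      }
    )),
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("configuration must be written as .yaml/.yml or .json",
         call. = FALSE)
  )
  invisible(path)
}

#' Build the model pair described by a configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return A [model_pair()].
#' @export
config_model_pair <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$model_family == "binomial") {
    binom_model_pair(
      parse_hypothesis_spec(config$hypotheses$specific, "specific"),
      parse_hypothesis_spec(config$hypotheses$general, "general"),
      n = config$n
    )
  } else {
    anova_model_pair(do.call(anova_gen_config, config$generator),
                     analysis_prior = as_jzs_prior(config$analysis_scale))
  }
}

report_as_list <- function(report) {
  stopifnot(inherits(report, "bf_check"))
  list(
    pair = as.list(report$pair_labels),
    m = report$m,
    seed = report$seed,
    observed_bf = report$observed_bf,
    theorem1 = report$theorem1,
    theorem2 = report$theorem2,
    universal_bound = report$universal_bound,
    weight_of_evidence = report$woe,
    undefined_count = report$sample_general_true$undefined_count,
    failed_count = report$sample_general_true$failed_count,
    recode_policy = report$sample_general_true$recode_policy
  )
}

#' Write a check report and its series to a directory
#'
#' Emits `report.json` (numbers at 17 significant digits), `bf_draws.csv`
#' (one row per replicate with undefined/failed bookkeeping) and
#' `cumulative_mean.csv`, and returns a manifest with MD5 checksums; a rerun
#' under the same configuration and seed reproduces the files bit for bit.
#'
#' @param report A `bf_check` from [run_full_check()].
#' @param directory Output directory (created if needed).
#' @return A data.frame manifest with columns `file` and `md5`.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "bf_check"))
  if (!is.character(directory) || length(directory) != 1L ||
      !nzchar(directory)) {
    stop("`directory` must be a nonempty path", call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  json_path <- file.path(directory, "report.json")
  jsonlite::write_json(report_as_list(report), json_path, auto_unbox = TRUE,
                       digits = 17, pretty = TRUE, null = "null")

  draws <- report$sample_general_true$draws
  draws$generated_under <- report$sample_general_true$generated_under
  draws$favor <- report$sample_general_true$direction
  draws <- draws[, c("replicate", "generated_under", "favor", "bf",
                     "was_undefined", "was_failed")]
  draws_path <- file.path(directory, "bf_draws.csv")
  utils::write.csv(draws, draws_path, row.names = FALSE)

  cm_path <- file.path(directory, "cumulative_mean.csv")
  utils::write.csv(
    data.frame(m = seq_along(report$cumulative_means),
               cumulative_mean = report$cumulative_means),
    cm_path, row.names = FALSE)

  files <- c(json_path, draws_path, cm_path)
  data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

#' Validate a written report against the packaged schema
#'
#' Checks that `report.json` carries every field required by the schema
#' shipped at `inst/schema/check-report-schema.json`.
#'
#' @param path Path to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first missing field.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::fromJSON(system.file("schema",
                                           "check-report-schema.json",
                                           package = "bfcheck"),
                               simplifyVector = TRUE)
  report <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- schema$required
  missing <- setdiff(required, names(report))
  if (length(missing)) {
    stop(sprintf("report is missing required field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  th1_req <- schema$properties$theorem1$required
  missing1 <- setdiff(th1_req, names(report$theorem1))
  if (length(missing1)) {
    stop(sprintf("theorem1 record is missing field(s): %s",
                 paste(missing1, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

cli_usage <- function() {
  paste(
    "usage: bfcheck <subcommand> [options]",
    "subcommands:",
    "  check     --config FILE [--out DIR]     run the full check workflow",
    "  simulate  --config FILE --under LABEL --out FILE",
    "            write prior-predictive binomial draws as CSV (replicate, k)",
    "  moments   --n N --order K --favor LABEL --true LABEL",
    "            exact enumeration moment for the default binomial pair",
    "  binom-bf  --n N --k K [--theta0 P] [--a A --b B]",
    "  anova-bf  --data FILE.csv [--scale medium|ultrawide|R]",
    sep = "\n"
  )
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) {
      stop(sprintf("malformed option: %s", key), call. = FALSE)
    }
    flags[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_default_pair_hyps <- function(flags) {
  list(
    specific = point_hypothesis(as.numeric(flags$theta0 %||% 0.5)),
    general = beta_hypothesis(as.numeric(flags$a %||% 1),
                              as.numeric(flags$b %||% 1),
                              as.numeric(flags$lower %||% 0),
                              as.numeric(flags$upper %||% 1))
  )
}

#' Command-line entry point
#'
#' Implements the `check`, `simulate`, `moments`, `binom-bf` and `anova-bf`
#' subcommands used by the `bfcheck` launcher script
#' (`system.file("scripts", "bfcheck", package = "bfcheck")`). Every run
#' prints the seed and counts of undefined and failed evaluations so results
#' can be regenerated.
#'
#' @param argv Character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv = character()) {
  status <- tryCatch({
    if (length(argv) == 0) {
      message(cli_usage())
      return(invisible(1L))
    }
    sub <- argv[1]
    flags <- parse_cli_flags(argv[-1])
    switch(sub,
      "check" = {
        if (is.null(flags$config)) stop("check needs --config", call. = FALSE)
        config <- load_config(flags$config)
        pair <- config_model_pair(config)
        report <- run_full_check(
          pair, m = config$m, seed = config$seed,
          run_theorem2 = isTRUE(config$run_theorem2),
          recode_policy = config$recode_policy,
          tolerance_multiplier = config$tolerance_multiplier
        )
        out_dir <- flags$out %||% config$output_dir
        manifest <- write_report(report, out_dir)
        summary(report)
        cat(sprintf("  undefined: %d, failed: %d\n",
                    report$sample_general_true$undefined_count,
                    report$sample_general_true$failed_count))
        cat(sprintf("wrote %s to %s\n",
                    paste(manifest$file, collapse = ", "), out_dir))
        0L
      },
      "simulate" = {
        if (is.null(flags$config) || is.null(flags$under) ||
            is.null(flags$out)) {
          stop("simulate needs --config, --under and --out", call. = FALSE)
        }
        config <- load_config(flags$config)
        if (config$model_family != "binomial") {
          stop("simulate writes binomial outcome batches only",
               call. = FALSE)
        }
        hyps <- list(
          specific = parse_hypothesis_spec(config$hypotheses$specific, "s"),
          general = parse_hypothesis_spec(config$hypotheses$general, "g"))
        hyp <- if (flags$under == hyps$specific$label) {
          hyps$specific
        } else if (flags$under == hyps$general$label) {
          hyps$general
        } else {
          stop(sprintf("unknown hypothesis label: %s", flags$under),
               call. = FALSE)
        }
        k <- simulate_binomial(hyp, config$n, config$m, config$seed)
        utils::write.csv(data.frame(replicate = seq_along(k), k = as.integer(k)),
                         flags$out, row.names = FALSE)
        cat(sprintf("wrote %d draws (seed %d) to %s\n", length(k),
                    attr(k, "seed"), flags$out))
        0L
      },
      "moments" = {
        for (req in c("n", "order", "favor", "true")) {
          if (is.null(flags[[req]])) {
            stop(sprintf("moments needs --%s", req), call. = FALSE)
          }
        }
        hyps <- cli_default_pair_hyps(flags)
        pick <- function(lab) {
          if (lab == hyps$specific$label) hyps$specific
          else if (lab == hyps$general$label) hyps$general
          else stop(sprintf("unknown hypothesis label: %s", lab),
                    call. = FALSE)
        }
        favor <- pick(flags$favor)
        truth <- pick(flags$true)
        other <- if (identical(favor, hyps$specific)) hyps$general else
          hyps$specific
        value <- exact_bf_moment(favor, other, truth,
                                 n = as.integer(flags$n),
                                 order = as.integer(flags$order))
        cat(sprintf("%.4f\n", value))
        0L
      },
      "binom-bf" = {
        if (is.null(flags$n) || is.null(flags$k)) {
          stop("binom-bf needs --n and --k", call. = FALSE)
        }
        hyps <- cli_default_pair_hyps(flags)
        n <- as.integer(flags$n)
        k <- as.integer(flags$k)
        bf01 <- binom_bf(hyps$specific, hyps$general, n, k)
        cat(sprintf("BF[%s/%s](n = %d, k = %d) = %.6g\n",
                    hyps$specific$label, hyps$general$label, n, k, bf01))
        cat(sprintf("BF[%s/%s](n = %d, k = %d) = %.6g\n",
                    hyps$general$label, hyps$specific$label, n, k, 1 / bf01))
        0L
      },
      "anova-bf" = {
        if (is.null(flags$data)) stop("anova-bf needs --data", call. = FALSE)
        tab <- utils::read.csv(flags$data)
        d <- as_anova_data(tab)
        prior <- as_jzs_prior(flags$scale %||% "medium")
        bf10 <- jzs_bf10(d, prior)
        cat(sprintf("JZS ANOVA BF10 (scale r = %g): %.6g (BF01 = %.6g)\n",
                    prior$r, bf10, 1 / bf10))
        0L
      },
      {
        message(cli_usage())
        1L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(cli_usage())
    1L
  })
  invisible(as.integer(status))
}
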