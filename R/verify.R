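# Orchestration: configuration -> model + formula + test -> result.

default_run_config <- function() {
  list(
    model = list(preset = NULL, params = list(), custom = NULL),
    formula = NULL,
    test = list(theta0 = NULL, prior = c(1, 1), bayes_threshold = 100,
                eta = 1, concentration_b = NULL, max_samples = 1e6),
    grid = list(t_end = NULL, dt = NULL),
    perturbation = list(mode = "off", theta_max = 0),
    seed = 1L,
    outputs = list(result = NULL, audit = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a verification run configuration
#'
#' Configurations are flat, human-readable YAML mirroring the arguments of
#' [run_verify()]: a `model` block (either `preset:` with optional
#' `params:` overrides, or `custom:` with expression strings for the drift
#' and diffusion of each equation), a BLTL `formula`, a `test` block
#' (`theta0`, `prior`, `bayes_threshold`, `eta`, `max_samples`), a `grid`
#' block (`t_end`, `dt`), a `perturbation` block (`mode`, `theta_max`), a
#' `seed` and optional `outputs` paths. Every field can also be overridden
#' programmatically (or from the command line) after reading. See
#' `system.file("extdata", "example-config.yaml", package = "sdemc")`.
#'
#' @param path Path to a YAML file.
#' @return A configuration list for [run_verify()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  cfg <- yaml::read_yaml(path)
  merge_config(default_run_config(), cfg)
}

# Build an sde_model from expression strings, one per equation. Each
# expression may use `t` and the variable names as vectors.
model_from_expressions <- function(drift, diffusion, initial_state,
                                   variables, positive = FALSE) {
  drift_exprs <- lapply(as.character(drift), function(s) parse(text = s)[[1]])
  diff_exprs <- lapply(as.character(diffusion), function(s) parse(text = s)[[1]])
  variables <- as.character(variables)
  d <- length(variables)
  if (length(drift_exprs) != d || length(diff_exprs) != d ||
      length(initial_state) != d) {
    abort("custom model needs one drift, one diffusion and one initial value per variable.")
  }
  eval_exprs <- function(exprs) {
    function(t, x) {
      env <- new.env(parent = baseenv())
      assign("t", t, env)
      for (j in seq_len(d)) assign(variables[[j]], x[, j], env)
      cols <- lapply(exprs, function(e) {
        v <- eval(e, env)
        if (length(v) == 1L) v <- rep(v, nrow(x))
        v
      })
      do.call(cbind, cols)
    }
  }
  sde_model(eval_exprs(drift_exprs), eval_exprs(diff_exprs),
            as.numeric(initial_state), variables, positive = isTRUE(positive))
}

build_model <- function(model_cfg) {
  if (!is.null(model_cfg$custom)) {
    cu <- model_cfg$custom
    return(list(
      model = model_from_expressions(
        cu$drift, cu$diffusion, cu$initial_state,
        cu$variables %||% cu$variable_names,
        positive = isTRUE(cu$positive)
      ),
      formula = NULL, theta0 = NULL, grid = NULL
    ))
  }
  if (is.null(model_cfg$preset)) {
    abort("configuration must name a `model: preset:` or define `model: custom:`.")
  }
  get_preset(model_cfg$preset, model_cfg$params %||% list())
}

#' Run one sequential verification
#'
#' Wires the three stages together: the SDE engine draws (possibly
#' Girsanov-perturbed) trajectories, the BLTL monitor turns each into a
#' satisfaction outcome, and the Bayesian sequential test folds the
#' outcomes into a decision about `Pr(formula) >= theta0`. Configuration
#' errors (unknown variables, bad parameters) are raised before any
#' simulation starts. When `perturbation mode` is `"off"`, `eta` is forced
#' to 1 (i.i.d. sampling needs no correction).
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @return An `smc_result` (see [sequential_verify()]) with a
#'   `provenance` field recording model, parameters, formula, grid,
#'   policy and seed; written as JSON/CSV when output paths are
#'   configured.
#' @examples
#' cfg <- list(
#'   model = list(preset = "brownian_barrier"),
#'   test = list(theta0 = 0.1, bayes_threshold = 100, max_samples = 500),
#'   grid = list(t_end = 1, dt = 0.02),
#'   seed = 42
#' )
#' res <- run_verify(cfg)
#' res$decision
#' @export
run_verify <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)

  built <- build_model(config$model)
  model <- built$model
  formula_text <- config$formula %||% built$formula
  if (is.null(formula_text)) abort("no `formula` in the configuration.")
  formula <- parse_formula(formula_text)
  unknown <- setdiff(formula_variables(formula), model$variable_names)
  if (length(unknown)) {
    abort(sprintf(
      "formula refers to variable(s) %s not present in the model (%s).",
      paste0("'", unknown, "'", collapse = ", "),
      paste(model$variable_names, collapse = ", ")
    ))
  }

  grid_cfg <- config$grid
  if (is.null(grid_cfg$t_end)) grid_cfg <- built$grid
  if (is.null(grid_cfg$t_end) || is.null(grid_cfg$dt)) {
    abort("configuration must provide `grid: t_end` and `grid: dt`.")
  }
  grid <- sim_grid(grid_cfg$t_end, grid_cfg$dt)

  policy <- perturb_policy(
    config$perturbation$theta_max %||% 0,
    config$perturbation$mode %||% "off"
  )
  eta <- config$test$eta %||% 1
  if (policy$mode == "off" && eta != 1) {
    warn("perturbation mode 'off' forces eta = 1.")
    eta <- 1
  }
  theta0 <- config$test$theta0 %||% built$theta0
  if (is.null(theta0)) abort("configuration must provide `test: theta0`.")
  spec <- test_spec(
    theta0 = theta0,
    prior = config$test$prior %||% c(1, 1),
    bayes_threshold = config$test$bayes_threshold %||% 100,
    eta = eta,
    concentration_b = config$test$concentration_b,
    max_samples = config$test$max_samples %||% 1e6
  )

  seed <- as.integer(config$seed %||% 1L)
  sampler <- sde_sampler(model, formula, grid, policy, seed = seed)
  keep <- !is.null(config$outputs$audit)
  result <- sequential_verify(sampler, spec, keep_history = keep)
  result$provenance <- list(
    model = model$name %||% "custom",
    params = model$params,
    formula = formula_text,
    grid = list(t_end = grid$t_end, dt = grid$dt),
    perturbation = list(mode = policy$mode, theta_max = policy$theta_max),
    seed = seed
  )

  if (!is.null(config$outputs$result)) {
    write_result_json(result, config$outputs$result)
  }
  if (keep) write_audit_csv(result, config$outputs$audit)
  result
}

#' Write a verification result record as JSON
#'
#' The record carries full provenance (model, parameters, formula, grid,
#' perturbation policy, seed), so the run can be reproduced exactly.
#'
#' @param result An `smc_result` from [run_verify()] or
#'   [sequential_verify()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  rec <- list(
    decision = result$decision,
    n_samples = result$n_samples,
    satisfied_count = result$satisfied_count,
    raw_log_bf = result$raw_log_bf,
    adjusted_log_bf = result$adjusted_log_bf,
    theta0 = result$spec$theta0,
    prior = c(result$spec$prior_alpha, result$spec$prior_beta),
    bayes_threshold = result$spec$bayes_threshold,
    eta = result$spec$eta
  )
  if (!is.null(result$provenance)) {
    rec <- c(rec, list(
      seed = result$provenance$seed,
      model = result$provenance$model,
      params = result$provenance$params,
      formula = result$provenance$formula,
      grid = result$provenance$grid,
      perturbation = result$provenance$perturbation
    ))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Sweep samples-to-decision across Bayes-factor thresholds
#'
#' For each decision threshold `T` in `bayes_thresholds` and each sampling
#' mode (i.i.d., and non-i.i.d. under the configured perturbation policy),
#' runs `replicates` independent sequential verifications with derived
#' seeds and tabulates the number of samples each needed. This is the
#' experiment that exhibits the rare-event advantage of biased sampling:
#' for rare satisfying behaviour the non-i.i.d. curve grows more slowly in
#' `log T` than the i.i.d. one.
#'
#' @param config Run configuration as for [run_verify()]; its
#'   `perturbation` block defines the non-i.i.d. mode and its `test: eta`
#'   the asserted fairness bound (the i.i.d. mode always runs with the
#'   natural measure and `eta = 1`).
#' @param bayes_thresholds Increasing vector of thresholds `T` (> 1).
#' @param replicates Runs per `(mode, T)` cell.
#' @param out Optional CSV output path.
#' @return A tibble of class `smc_sweep` with columns `mode`, `T`,
#'   `replicate`, `n_samples`, `decision`, `satisfied_count`.
#' @export
run_sweep <- function(config, bayes_thresholds, replicates = 10L,
                      out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  bayes_thresholds <- as.numeric(bayes_thresholds)
  if (length(bayes_thresholds) == 0L || any(diff(bayes_thresholds) <= 0) ||
      any(bayes_thresholds <= 1)) {
    abort("`bayes_thresholds` must be a non-empty increasing vector of values > 1.")
  }
  replicates <- max(1L, as.integer(replicates))
  root_seed <- as.integer(config$seed %||% 1L)

  cells <- tidyr::expand_grid(
    mode = c("iid", "non_iid"),
    T = bayes_thresholds,
    replicate = seq_len(replicates)
  )
  counter <- 0L
  rows <- purrr::pmap(cells, function(mode, T, replicate) {
    counter <<- counter + 1L
    cfg <- config
    cfg$test$bayes_threshold <- T
    cfg$seed <- rng_substream(root_seed, counter, purpose = 3L)
    if (mode == "iid") {
      cfg$perturbation <- list(mode = "off", theta_max = 0)
      cfg$test$eta <- 1
    }
    cfg$outputs <- list(result = NULL, audit = NULL)
    res <- tryCatch(run_verify(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(
        mode = mode, T = T, replicate = replicate,
        n_samples = NA_integer_, decision = "error",
        satisfied_count = NA_integer_
      )
    } else {
      tibble::tibble(
        mode = mode, T = T, replicate = replicate,
        n_samples = res$n_samples, decision = res$decision,
        satisfied_count = res$satisfied_count
      )
    }
  })
  sweep <- dplyr::bind_rows(rows)
  class(sweep) <- c("smc_sweep", class(sweep))
  if (!is.null(out)) utils::write.csv(sweep, out, row.names = FALSE)
  sweep
}

#' Summarise a sweep
#'
#' Median and quartiles of samples-to-decision per `(mode, T)` cell.
#'
#' @param sweep The tibble from [run_sweep()].
#' @return A tibble with one row per cell.
#' @export
summarise_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$mode, .data$T),
    n_median = stats::median(.data$n_samples, na.rm = TRUE),
    n_q1 = stats::quantile(.data$n_samples, 0.25, na.rm = TRUE, names = FALSE),
    n_q3 = stats::quantile(.data$n_samples, 0.75, na.rm = TRUE, names = FALSE),
    n_runs = dplyr::n(),
    .groups = "drop"
  )
}

#' @rdname run_sweep
#' @param object An `smc_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.smc_sweep <- function(object, ...) {
  s <- summarise_sweep(object)
  ggplot2::ggplot(s, ggplot2::aes(.data$T, .data$n_median,
                                  colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$n_q1, ymax = .data$n_q3, fill = .data$mode),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Bayes factor threshold T", y = "samples to decision",
      colour = "sampling", fill = "sampling"
    ) +
    ggplot2::theme_minimal()
}
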