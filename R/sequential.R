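#' Sequential Bayesian verification on a stream of satisfaction outcomes
#'
#' Draws satisfaction outcomes one at a time from `sampler`, updates the
#' counts `(n, x)`, computes the running log Bayes factor of
#' `H0: rho >= theta0` against `H1: rho < theta0`, applies the conservative
#' `eta^(2n)` fairness adjustment ([adjust_log_bf()]), and stops as soon as
#' the adjusted Bayes factor exceeds `T` (accept H0) or falls below `1/T`
#' (accept H1). Exhausting `max_samples` yields `undecided`. Ties at
#' exactly `T` or `1/T` continue sampling.
#'
#' @param sampler A function of the 1-based sample index returning either a
#'   logical outcome or a list with elements `outcome` (logical) and
#'   optionally `theta`, `log_weight`, `bias_factor` (per-sample audit
#'   metadata). See [bernoulli_sampler()], [sde_sampler()],
#'   [toy_sampler()].
#' @param spec A [test_spec()].
#' @param keep_history Record per-sample audit rows (outcome, perturbation,
#'   weight, running Bayes factors)? Off by default: it dominates memory
#'   and I/O when `n` runs into the thousands.
#' @return An object of class `smc_result`: decision (`"accept_H0"`,
#'   `"accept_H1"` or `"undecided"`), `n_samples`, `satisfied_count`,
#'   `raw_log_bf`, `adjusted_log_bf`, the spec, and (optionally) the
#'   history tibble. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' sp <- test_spec(theta0 = 0.01, bayes_threshold = 100)
#' res <- sequential_verify(bernoulli_sampler(0.2, seed = 1), sp)
#' glance(res)
#' @export
sequential_verify <- function(sampler, spec, keep_history = FALSE) {
  stopifnot(inherits(spec, "test_spec"), is.function(sampler))
  log_T <- log(spec$bayes_threshold)
  n <- 0L
  x <- 0L
  lbf <- log_bayes_factor(0L, 0L, spec)
  albf <- adjust_log_bf(lbf, spec$eta, 0L)
  decision <- "undecided"
  hist <- if (keep_history) vector("list", 256L)

  while (n < spec$max_samples) {
    s <- tryCatch(
      sampler(n + 1L),
      error = function(e) {
        abort(
          sprintf(
            "sampler failed at sample %d (state so far: n = %d, x = %d).",
            n + 1L, n, x
          ),
          parent = e
        )
      }
    )
    if (!is.list(s)) s <- list(outcome = s)
    outcome <- isTRUE(as.logical(s$outcome))
    n <- n + 1L
    x <- x + outcome
    lbf <- log_bayes_factor(x, n, spec)
    albf <- adjust_log_bf(lbf, spec$eta, n)
    if (keep_history) {
      if (n > length(hist)) hist <- c(hist, vector("list", length(hist)))
      hist[[n]] <- tibble::tibble(
        sample = n,
        outcome = outcome,
        theta = list(s$theta %||% NA_real_),
        log_weight = s$log_weight %||% NA_real_,
        bias_factor = s$bias_factor %||% NA_real_,
        log_bf = lbf,
        adjusted_log_bf = albf
      )
    }
    if (albf > log_T) {
      decision <- "accept_H0"
      break
    }
    if (albf < -log_T) {
      decision <- "accept_H1"
      break
    }
  }

  structure(
    list(
      decision = decision,
      n_samples = n,
      satisfied_count = x,
      raw_log_bf = lbf,
      adjusted_log_bf = albf,
      spec = spec,
      history = if (keep_history) dplyr::bind_rows(hist[seq_len(n)])
    ),
    class = "smc_result"
  )
}

#' @export
print.smc_result <- function(x, ...) {
  verdict <- switch(x$decision,
    accept_H0 = sprintf("H0 accepted: satisfaction probability >= %g", x$spec$theta0),
    accept_H1 = sprintf("H1 accepted: satisfaction probability < %g", x$spec$theta0),
    "undecided (sample budget exhausted)"
  )
  cat(sprintf(
    "<smc_result> %s\n  %d samples, %d satisfying; log BF = %.4g (adjusted %.4g), T = %g, eta = %g\n",
    verdict, x$n_samples, x$satisfied_count, x$raw_log_bf, x$adjusted_log_bf,
    x$spec$bayes_threshold, x$spec$eta
  ))
  invisible(x)
}

#' @rdname sequential_verify
#' @param x,object An `smc_result`.
#' @param ... Unused.
#' @export
tidy.smc_result <- function(x, ...) {
  if (is.null(x$history)) {
    abort("no per-sample history: rerun `sequential_verify()` with `keep_history = TRUE`.")
  }
  x$history
}

#' @rdname sequential_verify
#' @export
glance.smc_result <- function(x, ...) {
  tibble::tibble(
    decision = x$decision,
    n_samples = x$n_samples,
    satisfied_count = x$satisfied_count,
    raw_log_bf = x$raw_log_bf,
    adjusted_log_bf = x$adjusted_log_bf,
    theta0 = x$spec$theta0,
    prior_alpha = x$spec$prior_alpha,
    prior_beta = x$spec$prior_beta,
    bayes_threshold = x$spec$bayes_threshold,
    eta = x$spec$eta
  )
}

#' @rdname sequential_verify
#' @export
autoplot.smc_result <- function(object, ...) {
  h <- tidy(object)
  log_T <- log(object$spec$bayes_threshold)
  ggplot2::ggplot(h, ggplot2::aes(.data$sample)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$log_bf, colour = "raw")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$adjusted_log_bf, colour = "adjusted")) +
    ggplot2::geom_hline(yintercept = c(-log_T, log_T), linetype = "dashed") +
    ggplot2::labs(
      x = "sample", y = "log Bayes factor", colour = NULL,
      title = "Sequential Bayes factor trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Write the per-sample audit log to CSV
#'
#' Columns: `sample_index`, `outcome`, `theta` (comma-separated components),
#' `log_weight`, `running_log_bf`, `running_adjusted_log_bf`.
#'
#' @param result An `smc_result` produced with `keep_history = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(result, path) {
  h <- tidy(result)
  df <- data.frame(
    sample_index = h$sample,
    outcome = as.integer(h$outcome),
    theta = vapply(
      h$theta,
      function(th) paste(format(th, digits = 10), collapse = ";"),
      character(1)
    ),
    log_weight = h$log_weight,
    running_log_bf = h$log_bf,
    running_adjusted_log_bf = h$adjusted_log_bf
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
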