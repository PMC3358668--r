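# Vectorised bottom-up evaluation: returns the verdict of `node` at every
# start index 1..N of the trace in one pass. Bounded Until is O(N) via a
# two-pointer window (findInterval on the cumulative durations), a
# next-failure pointer for the left operand and a cumulative count of right
# witnesses.
bltl_eval_all <- function(node, trace) {
  states <- trace$states
  n <- nrow(states)
  durations <- trace$durations
  recurse <- function(node) {
    switch(node$kind,
      atom = {
        j <- match(node$var, trace$variable_names)
        if (is.na(j)) {
          abort(sprintf(
            "formula refers to variable '%s', but the trace only has: %s.",
            node$var, paste(trace$variable_names, collapse = ", ")
          ))
        }
        v <- states[, j]
        switch(node$rel,
          ">" = v > node$value,
          "<" = v < node$value,
          "=" = v == node$value
        )
      },
      not = !recurse(node$child),
      and = recurse(node$left) & recurse(node$right),
      or = recurse(node$left) | recurse(node$right),
      until = {
        right <- recurse(node$right)
        cumdur <- c(0, cumsum(durations)) # cumdur[m]: time elapsed before state m
        # furthest witness index reachable within the bound from each start
        reach <- findInterval(cumdur[seq_len(n)] + node$bound, cumdur)
        reach <- pmin(reach, n)
        if (identical(node$sugar, "F")) {
          # F-sugar: the left operand is (phi | !phi), identically true
          upper <- reach
        } else {
          left <- recurse(node$left)
          # first index >= k at which `left` fails (n + 1 if never)
          idx <- seq_len(n)
          idx[left] <- n + 1L
          nf <- rev(cummin(rev(idx)))
          upper <- pmin(reach, nf) # witness j needs left on k..j-1 only
        }
        cs_right <- c(0, cumsum(right))
        cs_right[upper + 1L] - cs_right[seq_len(n)] > 0
      }
    )
  }
  recurse(node)
}

check_at <- function(trace, at) {
  n <- nrow(trace$states)
  at <- as.integer(at)[1]
  if (is.na(at) || at < 1L || at > n) {
    abort(sprintf("start index `at` = %s is outside the trace (1..%d).", at, n))
  }
  at
}

#' Does a trace satisfy a BLTL formula?
#'
#' Decides satisfaction of `formula` on the finite timed trace, starting at
#' state `at` (1-based). The semantics are the usual ones for bounded
#' temporal logic on finite traces: an atom `x ~ v` holds at `k` iff the
#' value of `x` in state `k` compares as stated; Boolean connectives are
#' pointwise; and `phi1 U[t] phi2` holds at `k` iff some state `k + i`
#' satisfies `phi2` with the elapsed duration of states `k .. k+i-1` at most
#' `t`, and `phi1` holds at every state strictly before the witness. A
#' bounded Until with no witness inside the trace is false (finite-trace
#' semantics; no third truth value).
#'
#' @param trace A [bltl_trace()] (or anything [as_trace()] accepts).
#' @param formula A `bltl_formula` from [parse_formula()], or a string.
#' @param at Start state, 1-based.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- bltl_trace(c(0, 0, 0, 20), c(4, 4, 1, 0), "x")
#' bltl_satisfies(tr, "F[10](x > 10)") # elapsed 9 <= 10: TRUE
#' tr2 <- bltl_trace(c(0, 0, 0, 20), c(4, 4, 4, 0), "x")
#' bltl_satisfies(tr2, "F[10](x > 10)") # elapsed 12 > 10: FALSE
#' @seealso [bltl_satisfies_naive()] for the reference recursive evaluator.
#' @export
bltl_satisfies <- function(trace, formula, at = 1L) {
  trace <- as_trace(trace)
  if (is.character(formula)) formula <- parse_formula(formula)
  at <- check_at(trace, at)
  as.logical(bltl_eval_all(formula, trace)[[at]])
}

#' Satisfaction verdicts at every start index
#'
#' @inheritParams bltl_satisfies
#' @return Logical vector, element `k` giving the verdict at start state `k`.
#' @export
bltl_satisfies_all <- function(trace, formula) {
  trace <- as_trace(trace)
  if (is.character(formula)) formula <- parse_formula(formula)
  as.logical(bltl_eval_all(formula, trace))
}

#' Reference BLTL evaluator (direct recursion)
#'
#' A literal recursive transcription of the satisfaction rules, with no
#' sharing, vectorisation or early exit. Exponentially slower than
#' [bltl_satisfies()] on nested Until but independent of it; used to
#' cross-check the optimised monitor.
#'
#' @inheritParams bltl_satisfies
#' @return `TRUE` or `FALSE`.
#' @export
bltl_satisfies_naive <- function(trace, formula, at = 1L) {
  trace <- as_trace(trace)
  if (is.character(formula)) formula <- parse_formula(formula)
  at <- check_at(trace, at)
  n <- nrow(trace$states)
  durations <- trace$durations
  value_at <- function(k, var) {
    j <- match(var, trace$variable_names)
    if (is.na(j)) {
      abort(sprintf("formula refers to unknown variable '%s'.", var))
    }
    trace$states[[k, j]]
  }
  sat <- function(node, k) {
    switch(node$kind,
      atom = {
        v <- value_at(k, node$var)
        switch(node$rel,
          ">" = v > node$value,
          "<" = v < node$value,
          "=" = v == node$value
        )
      },
      not = !sat(node$child, k),
      and = sat(node$left, k) && sat(node$right, k),
      or = sat(node$left, k) || sat(node$right, k),
      until = {
        res <- FALSE
        for (i in 0:(n - k)) {
          elapsed <- if (i == 0L) 0 else sum(durations[k:(k + i - 1L)])
          ok <- elapsed <= node$bound && sat(node$right, k + i)
          if (ok && i > 0L) {
            for (j in 0:(i - 1L)) ok <- ok && sat(node$left, k + j)
          }
          res <- res || ok
        }
        res
      }
    )
  }
  sat(formula, at)
}
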