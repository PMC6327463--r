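#' Classify a converged state into expression calls
#'
#' Values strictly greater than 0 are called `expressed` (upregulated),
#' strictly less than 0 `repressed` (downregulated / not expressed). A value
#' of exactly 0 — a node with no inputs and no clamp — carries no signal
#' either way and is called `indeterminate`; validation excludes such nodes
#' rather than silently scoring them.
#'
#' @param state named numeric vector (a `final_state` from
#'   [run_simulation()]), or unnamed with `map` supplied for labels.
#' @param map optional [knowledge_map] providing labels.
#' @return data frame with columns `label`, `value`, `call`.
#' @export
classify_state <- function(state, map = NULL) {
  labels <- if (!is.null(map)) {
    if (length(state) != n_nodes(map)) {
      stop_ncm("format_error", "state length does not match map size")
    }
    map$labels
  } else {
    names(state)
  }
  if (is.null(labels)) {
    stop_ncm("format_error", "state must be named or a map supplied")
  }
  data.frame(
    label = labels,
    value = unname(as.numeric(state)),
    call = ifelse(state > 0, "expressed",
                  ifelse(state < 0, "repressed", "indeterminate"))
  )
}

#' Pretest probabilities of the network
#'
#' The network's fraction of positive determinate edges is the chance-level
#' probability that a prediction comes out positive (the "system bias"); its
#' complement is the negative pretest probability. These parameterize the
#' biased null of the binomial validation test.
#'
#' @param map a [knowledge_map] with at least one determinate nonzero edge.
#' @return named numeric vector `c(positive = p, negative = 1 - p)`.
#' @export
pretest_probabilities <- function(map) {
  s <- compute_statistics(map)
  if (is.na(s$positive_fraction)) {
    stop_ncm("domain_error",
             "map has no determinate edges; pretest probabilities undefined")
  }
  c(positive = s$positive_fraction, negative = s$negative_fraction)
}

#' Exact binomial probability under a biased null
#'
#' Computes, exactly (log-space, no normal approximation), the probability of
#' the observed agreement count under a null where each prediction succeeds
#' independently with probability `p_success`:
#' \describe{
#'   \item{`all_success`}{requires `k == n`; returns `p^n`, the probability
#'     that every prediction agrees by chance.}
#'   \item{`point_mass`}{`choose(n, k) * p^k * (1-p)^(n-k)`.}
#'   \item{`upper_tail`}{`P(K >= k)`, the conventional one-sided p-value.}
#' }
#'
#' @param k number of agreements, `0 <= k <= n`.
#' @param n number of evaluated predictions.
#' @param p_success null success probability, strictly inside (0, 1).
#' @param mode one of `"all_success"`, `"point_mass"`, `"upper_tail"`.
#' @return a probability in `[0, 1]`.
#' @examples
#' binomial_pvalue(15, 15, 0.66, "all_success")   # ~0.002
#' binomial_pvalue(16, 17, 0.66, "point_mass")    # ~0.0075
#' @export
binomial_pvalue <- function(k, n, p_success,
                            mode = c("all_success", "point_mass",
                                     "upper_tail")) {
  mode <- match.arg(mode)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 0 || k < 0 || k > n) {
    stop_ncm("domain_error", "require integer counts with 0 <= k <= n")
  }
  if (!is.finite(p_success) || p_success <= 0 || p_success >= 1) {
    stop_ncm("domain_error", "p_success must lie strictly inside (0, 1)")
  }
  log_point <- function(j) {
    lchoose(n, j) + j * log(p_success) + (n - j) * log1p(-p_success)
  }
  p <- switch(mode,
    all_success = {
      if (k != n) {
        stop_ncm("domain_error", "mode 'all_success' requires k = n")
      }
      p_success^n
    },
    point_mass = exp(log_point(k)),
    upper_tail = if (k == 0) 1 else sum(exp(log_point(k:n)))
  )
  min(1, max(0, p))
}

#' Score expression calls against an expected-outcome panel
#'
#' Joins predicted calls to a panel of expected directions (`up`/`down`),
#' counts agreements, and computes the exact binomial probability of doing at
#' least this well by chance under the network's bias-adjusted null.
#' Indeterminate calls (value exactly 0) are excluded from `n` and reported
#' separately.
#'
#' Two nulls are available. The default, `null = "uniform"`, applies the
#' positive pretest probability to every prediction regardless of the expected
#' direction — the convention under which an all-correct panel of size n has
#' probability `p_positive^n`. The stricter `null = "per_sign"` uses the
#' positive pretest probability for expected-up and the negative one for
#' expected-down entries (a Poisson-binomial null, evaluated exactly).
#'
#' @param calls data frame from [classify_state()].
#' @param expected a named character vector (`label -> "up"/"down"`) or a
#'   two-column data frame `(label, expected)`.
#' @param map optional [knowledge_map]; used to derive pretest probabilities
#'   when `pretest` is not given.
#' @param pretest optional length-2 numeric `(p_positive, p_negative)`
#'   override, e.g. `c(0.66, 0.34)` for comparability across maps.
#' @param mode binomial mode; default `all_success` when every prediction
#'   agrees, `point_mass` otherwise. See [binomial_pvalue()].
#' @param null `"uniform"` (default) or `"per_sign"`; see Details.
#' @return an object of class `validation_report`.
#' @export
evaluate_predictions <- function(calls, expected, map = NULL, pretest = NULL,
                                 mode = NULL,
                                 null = c("uniform", "per_sign")) {
  null <- match.arg(null)
  expected <- normalize_panel(expected)
  if (is.null(pretest)) {
    if (is.null(map)) {
      stop_ncm("domain_error",
               "supply either a map or explicit pretest probabilities")
    }
    pretest <- pretest_probabilities(map)
  }
  pretest <- as.numeric(pretest)
  if (length(pretest) != 2L || any(!is.finite(pretest)) ||
      abs(sum(pretest) - 1) > 1e-8 || any(pretest <= 0)) {
    stop_ncm("domain_error",
             "pretest must be two positive probabilities summing to 1")
  }
  missing <- setdiff(expected$label, calls$label)
  if (length(missing)) {
    stop_ncm("panel_error", "expected panel names unknown concept(s): ",
             paste(missing, collapse = ", "))
  }
  idx <- match(expected$label, calls$label)
  per_node <- data.frame(
    label = expected$label,
    expected = expected$expected,
    value = calls$value[idx],
    call = calls$call[idx]
  )
  per_node$agree <- (per_node$expected == "up" &
                       per_node$call == "expressed") |
    (per_node$expected == "down" & per_node$call == "repressed")
  determinate <- per_node$call != "indeterminate"
  n <- sum(determinate)
  k <- sum(per_node$agree[determinate])
  if (is.null(mode)) mode <- if (k == n) "all_success" else "point_mass"
  p_per <- ifelse(per_node$expected[determinate] == "up",
                  pretest[1L], pretest[2L])
  p_value <- if (n == 0L) {
    1
  } else if (null == "uniform") {
    binomial_pvalue(k, n, pretest[1L], mode)
  } else {
    poisson_binomial_pvalue(k, p_per, mode)
  }
  structure(list(
    n_evaluated = n,
    n_correct = k,
    n_indeterminate_excluded = as.integer(sum(!determinate)),
    pretest_positive = pretest[1L],
    pretest_negative = pretest[2L],
    p_value = p_value,
    test_mode = mode,
    null = null,
    per_node = per_node
  ), class = "validation_report")
}

# exact distribution of a sum of independent non-identical Bernoullis,
# by convolution; n is panel-sized so O(n^2) is irrelevant
poisson_binomial_pvalue <- function(k, p, mode) {
  d <- 1
  for (pi in p) d <- c(d * (1 - pi), 0) + c(0, d * pi)
  switch(mode,
    all_success = {
      if (k != length(p)) {
        stop_ncm("domain_error", "mode 'all_success' requires k = n")
      }
      d[length(d)]
    },
    point_mass = d[k + 1L],
    upper_tail = sum(d[(k + 1L):length(d)])
  )
}

normalize_panel <- function(expected) {
  if (is.data.frame(expected)) {
    if (ncol(expected) < 2L) {
      stop_ncm("panel_error", "panel needs columns (label, expected)")
    }
    panel <- data.frame(label = trimws(as.character(expected[[1L]])),
                        expected = tolower(trimws(as.character(
                          expected[[2L]]))))
  } else {
    panel <- data.frame(label = names(expected),
                        expected = tolower(trimws(as.character(expected))))
  }
  bad <- setdiff(unique(panel$expected), c("up", "down"))
  if (length(bad)) {
    stop_ncm("panel_error", "expected direction must be 'up' or 'down', got: ",
             paste(bad, collapse = ", "))
  }
  if (anyDuplicated(panel$label)) {
    stop_ncm("panel_error", "duplicate label in expected panel: ",
             paste(unique(panel$label[duplicated(panel$label)]),
                   collapse = ", "))
  }
  panel
}

#' @export
print.validation_report <- function(x, digits = 2, ...) {
  cat(sprintf(
    "validation: %d/%d correct (%d indeterminate excluded)\n",
    x$n_correct, x$n_evaluated, x$n_indeterminate_excluded))
  cat(sprintf("pretest probabilities: %.2f positive / %.2f negative (%s null)\n",
              x$pretest_positive, x$pretest_negative, x$null))
  cat(sprintf("binomial p-value (%s): %s\n",
              x$test_mode, format(signif(x$p_value, digits))))
  invisible(x)
}
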