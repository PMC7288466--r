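#' Fit an origin-count versus chromosome-length trend line
#'
#' Ordinary least squares fit of per-chromosome origin counts against
#' chromosome length, `y = a x + b`, as used to compare origin-mapping
#' methods against the minimum-origins threshold.  The fit is unweighted
#' and keeps a free intercept.  When every count is identical (as for a
#' genome needing a single origin per chromosome, where the line is simply
#' `y = 1`) the slope is exactly 0, the intercept is the common count, and
#' `constant_flag` is set.
#'
#' @param data A data frame of points.
#' @param length,count Columns of `data` holding chromosome length (bp) and
#'   origin count; tidy-eval, defaulting to `length_bp` and `count`.
#' @param method Optional label for the mapping method the counts came from.
#' @return An object of class `orimin_trend`: a list with elements
#'   `method`, `slope` (origins per bp), `intercept` (origins),
#'   `n_points`, `constant_flag` and `data`.
#' @examples
#' pts <- tibble::tibble(length_bp = c(1e6, 2e6), count = c(2, 4))
#' fit_trend(pts) # slope 2e-6, intercept 0
#' @export
fit_trend <- function(data, length = NULL, count = NULL, method = NULL) {
  if (!is.data.frame(data)) abort_domain("`data` must be a data frame.")
  len_quo <- rlang::enquo(length)
  cnt_quo <- rlang::enquo(count)
  x <- if (rlang::quo_is_null(len_quo)) data[["length_bp"]] else
    rlang::eval_tidy(len_quo, data)
  y <- if (rlang::quo_is_null(cnt_quo)) data[["count"]] else
    rlang::eval_tidy(cnt_quo, data)
  if (is.null(x) || is.null(y)) {
    abort_domain("`data` must supply length and count columns (default `length_bp`, `count`).")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2L) {
    abort_domain("A trend line needs at least 2 points.")
  }
  if (length(unique(x)) < 2L) {
    abort_domain("A trend line needs at least 2 distinct chromosome lengths.")
  }
  constant <- length(unique(y)) == 1L
  if (constant) {
    slope <- 0
    intercept <- as.numeric(y[[1]])
  } else {
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[["x"]])
    intercept <- unname(coef(fit)[["(Intercept)"]])
  }
  structure(
    list(
      method = method, slope = slope, intercept = intercept,
      n_points = length(x), constant_flag = constant,
      data = tibble(length_bp = x, count = y)
    ),
    class = "orimin_trend"
  )
}

#' @export
print.orimin_trend <- function(x, ...) {
  lab <- x$method %||% "trend"
  if (x$constant_flag) {
    cat(sprintf("<orimin_trend> %s: y = %g (constant, %d points)\n",
                lab, x$intercept, x$n_points))
  } else {
    cat(sprintf("<orimin_trend> %s: y = %.6g x + %.6g (%d points)\n",
                lab, x$slope, x$intercept, x$n_points))
  }
  invisible(x)
}

#' @export
tidy.orimin_trend <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.orimin_trend <- function(x, ...) {
  r2 <- if (x$constant_flag) NA_real_ else {
    stats::cor(x$data$length_bp, x$data$count)^2
  }
  tibble(
    method = x$method %||% NA_character_,
    slope = x$slope,
    intercept = x$intercept,
    n_points = x$n_points,
    constant_flag = x$constant_flag,
    r_squared = r2
  )
}

#' Fold of origin usage over the minimum-origins trend
#'
#' Ratio of the slopes (angular coefficients) of two trend lines fitted on
#' the same karyotype: a mapping method's origin counts versus chromosome
#' length, over the minimum-origins line.  When the minimum-origins line is
#' flat (every chromosome needs the same minimum, slope 0) the ratio tends
#' to infinity and is returned as `Inf`; serialisers render it as the
#' string `"inf"` rather than a floating-point overflow.
#'
#' @param method_line,mo_line `orimin_trend` objects for the mapping method
#'   and the minimum-origins threshold, fitted on the same karyotype.
#' @return A one-row tibble with columns `method`, `ratio` and `infinite`.
#' @examples
#' mo <- fit_trend(tibble::tibble(length_bp = c(1e6, 2e6), count = c(1, 2)))
#' cm <- fit_trend(tibble::tibble(length_bp = c(1e6, 2e6), count = c(2, 4)))
#' fold_over_minimum(cm, mo) # ratio 2
#' @export
fold_over_minimum <- function(method_line, mo_line) {
  if (!inherits(method_line, "orimin_trend") ||
      !inherits(mo_line, "orimin_trend")) {
    abort_domain("`method_line` and `mo_line` must be orimin_trend objects.")
  }
  if (method_line$slope <= 0) {
    abort_domain(paste0(
      "Degenerate method trend: slope must be positive to compare against ",
      "the minimum-origins line."
    ))
  }
  infinite <- mo_line$constant_flag || mo_line$slope == 0
  tibble(
    method = method_line$method %||% NA_character_,
    ratio = if (infinite) Inf else method_line$slope / mo_line$slope,
    infinite = infinite
  )
}

#' Per-chromosome sufficiency of a mapping method against the MO threshold
#'
#' Flags every chromosome whose mapped origin count falls below the minimum
#' number of origins needed to finish replication within the S phase.  A
#' single deficit makes the method insufficient on its own for that genome
#' (it cannot account for complete replication), which is the expected
#' outcome for low-resolution methods that see mostly constitutive origins.
#'
#' @param profile A tibble of per-chromosome counts (`chromosome`, `count`),
#'   e.g. from [read_origin_counts()].
#' @param mo_table A tibble with columns `chromosome` and `mo`, e.g. from
#'   [genome_mo_table()].  Every profile chromosome must appear in it.
#' @return A tibble of class `orimin_sufficiency` with columns
#'   `chromosome`, `count`, `mo`, `deficit`, and attribute `verdict`
#'   (`"sufficient"` or `"insufficient"`).
#' @export
sufficiency_report <- function(profile, mo_table) {
  if (!is.data.frame(profile) ||
      !all(c("chromosome", "count") %in% names(profile))) {
    abort_domain("`profile` must have columns `chromosome` and `count`.")
  }
  if (!is.data.frame(mo_table) ||
      !all(c("chromosome", "mo") %in% names(mo_table))) {
    abort_domain("`mo_table` must have columns `chromosome` and `mo`.")
  }
  unknown <- setdiff(profile$chromosome, mo_table$chromosome)
  if (length(unknown) > 0L) {
    abort_io(sprintf(
      "Chromosome(s) in `profile` missing from `mo_table`: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- left_join(
    as_tibble(profile[, c("chromosome", "count")]),
    as_tibble(mo_table[, c("chromosome", "mo")]),
    by = "chromosome"
  )
  out$deficit <- out$count < out$mo
  verdict <- if (any(out$deficit)) "insufficient" else "sufficient"
  new_tibble(out, verdict = verdict, method = attr(profile, "method"),
             class = "orimin_sufficiency")
}

#' @export
glance.orimin_sufficiency <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_chromosomes = nrow(x),
    n_deficit = sum(x$deficit),
    verdict = attr(x, "verdict")
  )
}

#' @export
print.orimin_sufficiency <- function(x, ...) {
  cat(sprintf("# Sufficiency against the MO threshold: %s (%d of %d chromosomes in deficit)\n",
              attr(x, "verdict"), sum(x$deficit), nrow(x)))
  print(as_tibble(x), ...)
  invisible(x)
}
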