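#' Exponential growth model of an asynchronous population
#'
#' Couples the population doubling time `T` (hours) with the specific growth
#' rate `alpha = ln(2) / T` (per hour).  All phase-duration arithmetic in the
#' package is expressed in terms of this pair.
#'
#' @param doubling_time Population doubling time in hours; must be positive.
#' @return An object of class `growth_model` with elements `doubling_time`
#'   and `growth_rate`.
#' @examples
#' g <- growth_model(24)
#' g$growth_rate # ln(2) / 24
#' @export
growth_model <- function(doubling_time) {
  check_number(doubling_time, "doubling_time", min = 0, strict_min = TRUE)
  structure(
    list(doubling_time = doubling_time, growth_rate = log(2) / doubling_time),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf(
    "<growth_model> doubling time %.4g h, specific growth rate %.6g / h\n",
    x$doubling_time, x$growth_rate
  ))
  invisible(x)
}

as_growth_model <- function(x, arg = "growth") {
  if (inherits(x, "growth_model")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(growth_model(x))
  abort_domain(sprintf(
    "`%s` must be a growth_model or a doubling time in hours.", arg
  ))
}

#' Cumulative time to reach a cell-cycle position (Williams equation)
#'
#' For an asynchronous exponentially growing population, the cumulative time
#' `x` within the cycle needed to reach the start of a phase is related to
#' the cumulative proportion `y` of cells up to that phase by
#' `x = -ln(1 - y/2) / alpha`.  The factor 2 reflects the age structure of
#' exponential growth: young cells are twice as frequent as dividing ones.
#'
#' @param y Cumulative proportion of cells up to the phase, as a fraction in
#'   `[0, 1]`.  Vectorised.
#' @param growth A [growth_model()] or a doubling time in hours.
#' @return Cumulative time in hours, in `[0, T]`; `y = 0` gives 0 and
#'   `y = 1` gives the doubling time exactly.
#' @examples
#' williams_time(0.95, 24)
#' @export
williams_time <- function(y, growth) {
  growth <- as_growth_model(growth)
  if (!is.numeric(y) || anyNA(y) || any(y < 0 | y > 1)) {
    abort_domain("`y` must be a fraction (or fractions) in [0, 1].")
  }
  -log1p(-y / 2) / growth$growth_rate
}

#' Duration of cytokinesis from the fraction of cells in cytokinesis
#'
#' Cytokinesis closes the cycle, so its duration is the doubling time minus
#' the cumulative time to its start, obtained from the Williams equation with
#' `y = 1 - f_C`.
#'
#' @param frac_cytokinesis Fraction of cells observed in cytokinesis, in
#'   `[0, 1)`.  A value of 1 (the whole population dividing) is rejected as
#'   degenerate.
#' @inheritParams williams_time
#' @return Duration of cytokinesis in hours (0 when `frac_cytokinesis` is 0).
#' @examples
#' duration_cytokinesis(0.05, 24)
#' @export
duration_cytokinesis <- function(frac_cytokinesis, growth) {
  growth <- as_growth_model(growth)
  check_fraction(frac_cytokinesis, "frac_cytokinesis", allow_one = FALSE)
  growth$doubling_time - williams_time(1 - frac_cytokinesis, growth)
}

#' Duration of mitosis from the fraction of cells in mitosis or cytokinesis
#'
#' The Williams equation with `y = 1 - f_MC` gives the combined duration of
#' mitosis plus cytokinesis; subtracting the previously computed cytokinesis
#' duration leaves mitosis.
#'
#' @param frac_mitosis_cyto Fraction of cells in mitosis or cytokinesis, in
#'   `[0, 1)`; must be at least the fraction in cytokinesis alone.
#' @param cytokinesis Duration of cytokinesis in hours, as returned by
#'   [duration_cytokinesis()].
#' @inheritParams williams_time
#' @return Duration of mitosis in hours.
#' @examples
#' cc <- duration_cytokinesis(0.05, 24)
#' duration_mitosis(0.10, cc, 24)
#' @export
duration_mitosis <- function(frac_mitosis_cyto, cytokinesis, growth) {
  growth <- as_growth_model(growth)
  check_fraction(frac_mitosis_cyto, "frac_mitosis_cyto", allow_one = FALSE)
  check_number(cytokinesis, "cytokinesis", min = 0)
  mc <- growth$doubling_time - williams_time(1 - frac_mitosis_cyto, growth)
  m <- mc - cytokinesis
  if (m < 0) {
    abort_inconsistent(paste0(
      "`frac_mitosis_cyto` and the cytokinesis duration are inconsistent: ",
      sprintf("M + C = %.4g h is shorter than C = %.4g h. ", mc, cytokinesis),
      "The fraction in mitosis+cytokinesis must be at least the fraction in ",
      "cytokinesis."
    ))
  }
  m
}

#' Duration of G2 from the two-labeled-nuclei chase time
#'
#' The minimum chase time after an EdU pulse at which a single cell with two
#' labeled nuclei appears measures G2 + M; subtracting the mitosis duration
#' leaves G2.
#'
#' @param two_nuclei_time Minimum chase time (hours) to observe one cell with
#'   two EdU-labeled nuclei; must be positive.
#' @param mitosis Duration of mitosis in hours.
#' @return Duration of G2 in hours.
#' @export
duration_g2 <- function(two_nuclei_time, mitosis) {
  check_number(two_nuclei_time, "two_nuclei_time", min = 0, strict_min = TRUE)
  check_number(mitosis, "mitosis", min = 0)
  if (two_nuclei_time < mitosis) {
    abort_inconsistent(sprintf(
      paste0(
        "`two_nuclei_time` (%.4g h) is shorter than the mitosis duration ",
        "(%.4g h); G2 would be negative."
      ),
      two_nuclei_time, mitosis
    ))
  }
  two_nuclei_time - mitosis
}

#' Duration of the S phase (Stanners-Till equation)
#'
#' After an EdU pulse of length `t` hours, the labeled fraction `L` of an
#' asynchronous exponentially growing population satisfies
#' `S = (1/alpha) * ln(L + exp(alpha * Z)) - (Z + t)`,
#' where `Z = G2 + M + C`.
#'
#' @param frac_labeled Fraction of EdU-labeled cells, in `[0, 1]`.
#' @param z Combined duration of G2 + M + C in hours.
#' @param pulse EdU pulse duration in hours; must be positive.
#' @inheritParams williams_time
#' @return Duration of the S phase in hours.
#' @examples
#' duration_s(0.442378, z = 8.23, pulse = 0.5, growth = 24)
#' @export
duration_s <- function(frac_labeled, z, pulse, growth) {
  growth <- as_growth_model(growth)
  check_fraction(frac_labeled, "frac_labeled")
  check_number(z, "z", min = 0)
  check_number(pulse, "pulse", min = 0, strict_min = TRUE)
  al <- growth$growth_rate
  s <- log(frac_labeled + exp(al * z)) / al - (z + pulse)
  if (s < 0) {
    abort_labeling(sprintf(
      paste0(
        "`frac_labeled` (%.4g) is too low for the given Z and pulse: the ",
        "Stanners-Till equation gives a negative S phase (%.4g h)."
      ),
      frac_labeled, s
    ))
  }
  if (s + z > growth$doubling_time + 1e-9) {
    abort_inconsistent(sprintf(
      paste0(
        "`frac_labeled` and `z` are inconsistent: S + Z = %.4g h exceeds ",
        "the doubling time (%.4g h)."
      ),
      s + z, growth$doubling_time
    ))
  }
  s
}

#' Duration of G1 as the remainder of the cycle
#'
#' @param s Duration of the S phase in hours.
#' @param z Combined duration of G2 + M + C in hours.
#' @inheritParams williams_time
#' @return Duration of G1 in hours.
#' @examples
#' duration_g1(9.86, 8.23, 24) # 5.91
#' @export
duration_g1 <- function(s, z, growth) {
  growth <- as_growth_model(growth)
  check_number(s, "s", min = 0)
  check_number(z, "z", min = 0)
  g1 <- growth$doubling_time - (s + z)
  if (g1 < 0) {
    abort_inconsistent(sprintf(
      paste0(
        "`s` + `z` = %.4g h exceeds the doubling time (%.4g h); ",
        "G1 would be negative."
      ),
      s + z, growth$doubling_time
    ))
  }
  g1
}

#' Construct a set of cell-cycle phase durations
#'
#' A validated container for the five phase durations (hours).  The durations
#' must tile the doubling time: `G1 + S + G2 + M + C = T`.
#'
#' @param g1,s,g2,m,c Phase durations in hours; all non-negative.
#' @param doubling_time Doubling time in hours.  Defaults to the sum of the
#'   five phases; if supplied it must agree with that sum to within 1e-9 h.
#' @return A tibble of class `orimin_phases` with columns `phase` and
#'   `hours`, ordered G1, S, G2, M, C, and attributes `doubling_time` and
#'   `z` (= G2 + M + C).
#' @examples
#' phase_durations(g1 = 5.91, s = 9.86, g2 = 5.43, m = 1.2, c = 1.6)
#' @export
phase_durations <- function(g1, s, g2, m, c, doubling_time = NULL) {
  for (nm in c("g1", "s", "g2", "m", "c")) {
    check_number(get(nm), nm, min = 0)
  }
  total <- g1 + s + g2 + m + c
  if (is.null(doubling_time)) {
    doubling_time <- total
  } else {
    check_number(doubling_time, "doubling_time", min = 0, strict_min = TRUE)
    if (abs(total - doubling_time) > 1e-9) {
      abort_inconsistent(sprintf(
        "Phase durations sum to %.10g h but `doubling_time` is %.10g h.",
        total, doubling_time
      ))
    }
  }
  if (total <= 0) abort_domain("Phase durations must not all be zero.")
  out <- tibble(
    phase = factor(c("G1", "S", "G2", "M", "C"),
                   levels = c("G1", "S", "G2", "M", "C")),
    hours = c(g1, s, g2, m, c)
  )
  new_tibble(out,
    doubling_time = doubling_time,
    z = g2 + m + c,
    class = "orimin_phases"
  )
}

phase_hours <- function(phases, which) {
  phases$hours[match(which, as.character(phases$phase))]
}

#' Express phase durations in cell-cycle units (ccu)
#'
#' One cell-cycle unit (ccu) is the population doubling time, so each
#' phase's ccu value is its duration in hours divided by `T`.  The values
#' sum to exactly 1 because the phases tile the cycle.
#'
#' @param phases An `orimin_phases` object from [phase_durations()] or
#'   [estimate_phases()].
#' @return The same tibble with an added `ccu` column.
#' @examples
#' to_ccu(phase_durations(5.91, 9.86, 5.43, 1.2, 1.6))
#' @export
to_ccu <- function(phases) {
  stopifnot(inherits(phases, "orimin_phases"))
  doubling_time <- attr(phases, "doubling_time")
  out <- mutate(as_tibble(phases), ccu = .data$hours / doubling_time)
  new_tibble(out,
    doubling_time = doubling_time,
    z = attr(phases, "z"),
    class = "orimin_phases"
  )
}

#' Estimate all cell-cycle phase durations from population observations
#'
#' Runs the full estimation pipeline on a snapshot of an asynchronous
#' exponentially growing population, in the order cytokinesis, mitosis, G2,
#' S, G1:
#' \enumerate{
#'   \item C and M + C from the phase fractions via the Williams equation;
#'   \item G2 as the two-labeled-nuclei chase time minus M;
#'   \item S from the labeled fraction via the Stanners-Till equation;
#'   \item G1 as the remainder of the doubling time.
#' }
#'
#' @param snapshot A [population_snapshot()] (or any one-row data frame with
#'   columns `frac_cytokinesis`, `frac_mitosis_cyto`, `frac_labeled`,
#'   `pulse`, `two_nuclei_time`).
#' @inheritParams williams_time
#' @return An `orimin_phases` tibble with columns `phase`, `hours`, `ccu`.
#' @examples
#' snap <- population_snapshot(
#'   frac_cytokinesis = 0.05, frac_mitosis_cyto = 0.10,
#'   frac_labeled = 0.44, pulse = 0.5, two_nuclei_time = 2.0
#' )
#' estimate_phases(snap, growth = 24)
#' @export
estimate_phases <- function(snapshot, growth) {
  growth <- as_growth_model(growth)
  snapshot <- validate_snapshot(snapshot)

  stage <- function(name, expr) {
    tryCatch(expr, orimin_error = function(e) {
      rlang::abort(
        sprintf("while estimating %s: %s", name, conditionMessage(e)),
        class = grep("^orimin_", class(e), value = TRUE),
        parent = e
      )
    })
  }

  c_h <- stage("cytokinesis",
    duration_cytokinesis(snapshot$frac_cytokinesis, growth))
  m_h <- stage("mitosis",
    duration_mitosis(snapshot$frac_mitosis_cyto, c_h, growth))
  g2_h <- stage("G2", duration_g2(snapshot$two_nuclei_time, m_h))
  z_h <- g2_h + m_h + c_h
  s_h <- stage("S",
    duration_s(snapshot$frac_labeled, z_h, snapshot$pulse, growth))
  g1_h <- stage("G1", duration_g1(s_h, z_h, growth))

  to_ccu(phase_durations(g1_h, s_h, g2_h, m_h, c_h,
                         doubling_time = growth$doubling_time))
}

#' @export
tidy.orimin_phases <- function(x, ...) {
  out <- as_tibble(x)
  if (!"ccu" %in% names(out)) {
    out$ccu <- out$hours / attr(x, "doubling_time")
  }
  out
}

#' @export
glance.orimin_phases <- function(x, ...) {
  h <- setNames(x$hours, tolower(as.character(x$phase)))
  tibble(
    doubling_time = attr(x, "doubling_time"),
    g1 = h[["g1"]], s = h[["s"]], g2 = h[["g2"]], m = h[["m"]], c = h[["c"]],
    z = attr(x, "z")
  )
}

#' @export
print.orimin_phases <- function(x, ...) {
  cat(sprintf(
    "# Cell-cycle phase durations (doubling time %.4g h, Z = %.4g h)\n",
    attr(x, "doubling_time"), attr(x, "z")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
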