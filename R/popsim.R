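#' Observed snapshot of an asynchronous population
#'
#' The five observables the phase-duration estimator consumes: the fractions
#' of cells in cytokinesis and in mitosis-plus-cytokinesis, the EdU-labeled
#' fraction after a pulse, the pulse length, and the minimum chase time at
#' which a single cell with two labeled nuclei is seen.
#'
#' @param frac_cytokinesis Fraction of cells in cytokinesis, in `[0, 1)`.
#' @param frac_mitosis_cyto Fraction in mitosis or cytokinesis, in `[0, 1)`;
#'   at least `frac_cytokinesis`.
#' @param frac_labeled EdU-labeled fraction in `[0, 1]`.
#' @param pulse EdU pulse duration in hours (> 0).
#' @param two_nuclei_time Chase time in hours to the first two-labeled-nuclei
#'   cell (> 0); this measures G2 + M.
#' @return A one-row tibble of class `orimin_snapshot`.
#' @examples
#' population_snapshot(0.05, 0.10, 0.44, pulse = 0.5, two_nuclei_time = 2)
#' @export
population_snapshot <- function(frac_cytokinesis, frac_mitosis_cyto,
                                frac_labeled, pulse, two_nuclei_time) {
  check_fraction(frac_cytokinesis, "frac_cytokinesis", allow_one = FALSE)
  check_fraction(frac_mitosis_cyto, "frac_mitosis_cyto", allow_one = FALSE)
  check_fraction(frac_labeled, "frac_labeled")
  check_number(pulse, "pulse", min = 0, strict_min = TRUE)
  check_number(two_nuclei_time, "two_nuclei_time", min = 0, strict_min = TRUE)
  if (frac_mitosis_cyto < frac_cytokinesis) {
    abort_inconsistent(sprintf(
      paste0(
        "`frac_mitosis_cyto` (%.4g) is smaller than `frac_cytokinesis` ",
        "(%.4g); cells in cytokinesis are a subset of cells in M+C."
      ),
      frac_mitosis_cyto, frac_cytokinesis
    ))
  }
  new_tibble(
    tibble(
      frac_cytokinesis = frac_cytokinesis,
      frac_mitosis_cyto = frac_mitosis_cyto,
      frac_labeled = frac_labeled,
      pulse = pulse,
      two_nuclei_time = two_nuclei_time
    ),
    class = "orimin_snapshot"
  )
}

validate_snapshot <- function(snapshot) {
  needed <- c("frac_cytokinesis", "frac_mitosis_cyto", "frac_labeled",
              "pulse", "two_nuclei_time")
  if (!is.data.frame(snapshot) || !all(needed %in% names(snapshot)) ||
      nrow(snapshot) != 1L) {
    abort_domain(paste0(
      "`snapshot` must be a one-row data frame with columns ",
      paste0("`", needed, "`", collapse = ", "), "."
    ))
  }
  snapshot
}

#' Sample cell ages from the exponential-growth age distribution
#'
#' In an asynchronous exponentially growing population the density of cell
#' ages on `[0, T]` is `f(a) = 2 * alpha * exp(-alpha * a)`: newborns are
#' twice as frequent as cells about to divide.  Ages are drawn by inverting
#' the CDF `F(a) = 2 * (1 - exp(-alpha * a))`, giving
#' `a = -ln(1 - u/2) / alpha` for `u` uniform on `[0, 1)`.
#'
#' @param n Number of cells to draw.
#' @inheritParams williams_time
#' @param seed Optional integer seed.  When supplied the draw is performed
#'   in an isolated RNG state (the global stream is untouched); when `NULL`
#'   the current RNG stream is used.
#' @return Numeric vector of `n` ages in hours, in `[0, T)`.
#' @examples
#' ages <- sample_cell_ages(1000, growth = 24, seed = 1)
#' mean(ages <= 12) # about 2 - sqrt(2)
#' @export
sample_cell_ages <- function(n, growth, seed = NULL) {
  growth <- as_growth_model(growth)
  if (!is.numeric(n) || length(n) != 1L || !is_wholeish(n) || n < 1) {
    abort_domain("`n` must be a single integer >= 1.")
  }
  draw <- function() {
    u <- runif(n)
    -log1p(-u / 2) / growth$growth_rate
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Classify cell ages into cell-cycle phases
#'
#' Deterministic interval lookup on the cumulative phase boundaries
#' `[0, G1, G1+S, G1+S+G2, G1+S+G2+M, T]` with half-open intervals
#' `[lo, hi)`; an age exactly equal to `T` maps to the final phase.
#' The phase order within the cycle is G1, S, G2, M, C.
#'
#' @param age Numeric vector of cell ages in hours, each in `[0, T]`.
#' @param phases An `orimin_phases` object giving the true durations.
#' @return Factor with levels `G1, S, G2, M, C`.
#' @export
classify_phase <- function(age, phases) {
  stopifnot(inherits(phases, "orimin_phases"))
  doubling_time <- attr(phases, "doubling_time")
  if (!is.numeric(age) || anyNA(age) ||
      any(age < 0 | age > doubling_time)) {
    abort_domain("`age` values must lie in [0, doubling_time].")
  }
  bounds <- cumsum(phase_hours(phases, c("G1", "S", "G2", "M")))
  idx <- findInterval(age, c(0, bounds)) # [lo, hi) intervals
  idx <- pmin(idx, 5L)
  factor(c("G1", "S", "G2", "M", "C")[idx],
         levels = c("G1", "S", "G2", "M", "C"))
}

#' Simulate a population snapshot with known phase durations
#'
#' Forward model of the observables the estimator consumes: draws `n_cells`
#' ages from the exponential-growth age distribution, classifies them into
#' phases to produce the cytokinesis and mitosis+cytokinesis fractions, and
#' labels the cells that pass through S during an EdU pulse of `pulse`
#' hours.  The pulse is anchored so that the expected labeled fraction
#' equals the Stanners-Till closed form
#' `L = exp(alpha*(S+Z+t)) - exp(alpha*Z)`: ages are drawn at pulse start
#' and a cell is labeled iff its age at pulse end lies in
#' `(G1, G1 + S + pulse]`, i.e. its start age lies in `(G1 - pulse, G1 + S]`.
#' The two-nuclei chase time is emitted noiselessly as exactly `G2 + M`.
#'
#' The model excludes configurations in which a labeled cell could divide
#' during the pulse (`pulse > Z`) or a newborn could inherit label from a
#' mother cell labeled before division (`pulse > G1`), and degenerate
#' populations with `S = 0`; these raise an `orimin_error_config`.
#'
#' @param phases True phase durations, an `orimin_phases` object.
#' @param n_cells Number of cells observed (>= 1).
#' @param pulse EdU pulse duration in hours; must satisfy
#'   `0 < pulse <= min(G1, Z)`.
#' @param seed Integer seed; mandatory so that snapshots are reproducible.
#' @param detection_prob Probability that an EdU-labeled cell is detected as
#'   labeled (default 1, i.e. perfect detection).
#' @return An `orimin_snapshot` tibble with attributes `n_cells`, `seed`
#'   and `truth` (the input `phases`).
#' @examples
#' truth <- phase_durations(g1 = 5.91, s = 9.86, g2 = 5.43, m = 1.2, c = 1.6)
#' snap <- simulate_snapshot(truth, n_cells = 1e4, pulse = 0.5, seed = 1)
#' estimate_phases(snap, growth = 24)
#' @export
simulate_snapshot <- function(phases, n_cells, pulse, seed,
                              detection_prob = 1) {
  stopifnot(inherits(phases, "orimin_phases"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L ||
      !is_wholeish(n_cells) || n_cells < 1) {
    abort_domain("`n_cells` must be a single integer >= 1.")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is_wholeish(seed)) {
    abort_domain("`seed` must be a single integer (mandatory).")
  }
  check_number(pulse, "pulse", min = 0, strict_min = TRUE)
  check_fraction(detection_prob, "detection_prob")

  g1 <- phase_hours(phases, "G1")
  s <- phase_hours(phases, "S")
  z <- attr(phases, "z")
  if (s <= 0) {
    abort_config("`phases` must have S > 0; an unlabelable population is degenerate.")
  }
  if (pulse > z) {
    abort_config(sprintf(
      paste0(
        "`pulse` (%.4g h) exceeds Z = G2+M+C (%.4g h): a labeled cell would ",
        "divide during the pulse, breaking the closed-form labeling model."
      ),
      pulse, z
    ))
  }
  if (pulse > g1) {
    abort_config(sprintf(
      paste0(
        "`pulse` (%.4g h) exceeds G1 (%.4g h): newborn cells would inherit ",
        "label from mothers, breaking the closed-form labeling model."
      ),
      pulse, g1
    ))
  }

  growth <- growth_model(attr(phases, "doubling_time"))
  snap <- withr::with_seed(as.integer(seed), {
    ages <- sample_cell_ages(n_cells, growth)
    phase <- classify_phase(ages, phases)
    labeled <- ages > g1 - pulse & ages <= g1 + s
    if (detection_prob < 1) {
      labeled <- labeled & runif(n_cells) < detection_prob
    }
    population_snapshot(
      frac_cytokinesis = mean(phase == "C"),
      frac_mitosis_cyto = mean(phase == "M" | phase == "C"),
      frac_labeled = mean(labeled),
      pulse = pulse,
      two_nuclei_time = phase_hours(phases, "G2") + phase_hours(phases, "M")
    )
  })
  attr(snap, "n_cells") <- n_cells
  attr(snap, "seed") <- as.integer(seed)
  attr(snap, "truth") <- phases
  snap
}

#' Expected phase fraction under exponential growth
#'
#' Closed-form expected fraction of cells whose age lies in `[a_lo, a_hi)`:
#' `2 * (exp(-alpha * a_lo) - exp(-alpha * a_hi))`.  Used as the analytic
#' reference for simulated fractions.
#'
#' @param a_lo,a_hi Age interval bounds in hours, `0 <= a_lo <= a_hi <= T`.
#' @inheritParams williams_time
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_age_fraction <- function(a_lo, a_hi, growth) {
  growth <- as_growth_model(growth)
  check_number(a_lo, "a_lo", min = 0, max = growth$doubling_time)
  check_number(a_hi, "a_hi", min = a_lo, max = growth$doubling_time)
  al <- growth$growth_rate
  2 * (exp(-al * a_lo) - exp(-al * a_hi))
}
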