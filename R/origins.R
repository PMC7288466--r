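# Minimum-origins arithmetic.
#
# The capacity of one origin is 2 * v * S base pairs (two forks moving in
# opposite directions for the whole S phase), so the smallest origin count
# able to replicate a chromosome of N bp is ceiling(N / (2 * v * S)).
# Several bundled karyotype cells sit within 0.5% of a ceiling boundary,
# where binary floating point could flip the result, so the default path
# uses exact integer arithmetic: the fork rate is scaled to an integer in
# units of 10^-2 bp/min (i.e. 10^-5 kb/min) and the S-phase duration to
# integer deciminutes.  Stress factors are carried as exact rationals p/q.
# All intermediates stay far below 2^53, so double %/% and %% are exact.

stress_fraction <- function(stress) {
  if (is.character(stress)) {
    if (length(stress) != 1L ||
        !stress %in% c("none", "mild", "harsh")) {
      abort_domain('`stress` must be one of "none", "mild", "harsh" or a number in (0, 1].')
    }
    return(switch(stress,
      none = list(p = 1, q = 1),
      mild = list(p = 2, q = 3),
      harsh = list(p = 1, q = 3)
    ))
  }
  check_number(stress, "stress", min = 0, max = 1, strict_min = TRUE)
  # small-denominator exact rationalization; NULL -> floating-point path
  for (q in 1:1000) {
    p <- stress * q
    if (abs(p - round(p)) < 1e-9) return(list(p = round(p), q = q))
  }
  NULL
}

scaled_params <- function(fork_rate_kb_min, s_phase_min) {
  check_number(fork_rate_kb_min, "fork_rate_kb_min", min = 0, strict_min = TRUE)
  check_number(s_phase_min, "s_phase_min", min = 0, strict_min = TRUE)
  vu <- round(fork_rate_kb_min * 1e5) # 10^-2 bp/min units
  sd <- round(s_phase_min * 10)       # deciminutes
  exact <- abs(vu / 1e5 - fork_rate_kb_min) <= 1e-9 * fork_rate_kb_min &&
    abs(sd / 10 - s_phase_min) <= 1e-9 * s_phase_min && vu > 0 && sd > 0
  list(vu = vu, sd = sd, exact = exact)
}

check_lengths <- function(length_bp) {
  if (!is.numeric(length_bp) || length(length_bp) == 0L || anyNA(length_bp) ||
      any(!is_wholeish(length_bp)) || any(length_bp < 1)) {
    abort_domain("`length_bp` must be positive whole numbers of base pairs.")
  }
  round(length_bp)
}

ceil_div <- function(num, den) {
  num %/% den + (num %% den > 0)
}

#' Minimum number of replication origins per chromosome
#'
#' The smallest number of origins able to replicate a chromosome of
#' `length_bp` base pairs within an S phase of `s_phase_min` minutes, with
#' bidirectional forks moving at `fork_rate_kb_min` kb/min:
#' `MO = ceiling(N / (2 * v * S))`.  Exact integer results are not bumped;
#' the ceiling only raises true fractions.  Replication stress is modelled
#' as a multiplier on the fork rate only (the S-phase duration is held
#' fixed, reflecting its robustness): `"mild"` scales `v` by 2/3 and
#' `"harsh"` by 1/3.
#'
#' Computation is performed in exact integer arithmetic (fork rate at
#' 10^-5 kb/min resolution, S phase at 0.1 min resolution, scenario factors
#' as exact rationals), so results at ceiling boundaries are bit-exact.
#' Numeric `stress` values with no small exact rational representation fall
#' back to guarded floating point.
#'
#' @param length_bp Chromosome length(s) in base pairs; vectorised.
#' @param fork_rate_kb_min Mean replication-fork rate in kb per minute.
#' @param s_phase_min S-phase duration in minutes.
#' @param stress `"none"` (default), `"mild"` (2/3), `"harsh"` (1/3), or a
#'   numeric factor in (0, 1] multiplying the fork rate.
#' @return Integer vector of minimum origin counts (each >= 1).
#' @examples
#' # T. brucei chromosome VII
#' minimum_origins(2205233, fork_rate_kb_min = 3.06, s_phase_min = 138.6)
#' # S. pombe chromosome I
#' minimum_origins(5598923, 0.91, 24)
#' @export
minimum_origins <- function(length_bp, fork_rate_kb_min, s_phase_min,
                            stress = "none") {
  n <- check_lengths(length_bp)
  fr <- stress_fraction(stress)
  sp <- scaled_params(fork_rate_kb_min, s_phase_min)
  if (!is.null(fr) && sp$exact) {
    # MO = ceil(N * 1000 * q / (2 * vu * sd * p)); units cancel to bp/bp
    as.integer(ceil_div(n * 1000 * fr$q, 2 * sp$vu * sp$sd * fr$p))
  } else {
    factor_num <- if (is.null(fr)) stress else fr$p / fr$q
    minimum_origins_float(n, fork_rate_kb_min, s_phase_min, factor_num)
  }
}

# Floating-point fallback with a one-ulp guard at the ceiling boundary:
# values within 1e-9 (relative) of an integer are taken as that integer.
minimum_origins_float <- function(length_bp, fork_rate_kb_min, s_phase_min,
                                  stress_factor = 1) {
  n <- check_lengths(length_bp)
  val <- n / (2 * fork_rate_kb_min * 1000 * stress_factor * s_phase_min)
  near <- round(val)
  as.integer(ifelse(abs(val - near) <= 1e-9 * pmax(1, val) & near >= 1,
                    near, ceiling(val)))
}

#' Minimum origins under a replication-stress scenario
#'
#' Convenience wrapper around [minimum_origins()] for the two named
#' scenarios: mild stress (fork rate at 2/3 of the wild-type average) and
#' harsh stress (1/3).
#'
#' @inheritParams minimum_origins
#' @param scenario `"mild"` or `"harsh"`.
#' @return Integer vector of minimum origin counts.
#' @examples
#' stressed_minimum_origins(5223313, 3.06, 138.6, "harsh") # 19
#' @export
stressed_minimum_origins <- function(length_bp, fork_rate_kb_min,
                                     s_phase_min,
                                     scenario = c("mild", "harsh")) {
  scenario <- match.arg(scenario)
  minimum_origins(length_bp, fork_rate_kb_min, s_phase_min, stress = scenario)
}

#' Origin count from DNA-combing inter-origin distances
#'
#' Estimates the average number of origins fired on a chromosome during the
#' S phase as the ceiling of the chromosome length over the mean
#' inter-origin distance measured by DNA combing:
#' `Oc = ceiling(N / IOD)`.
#'
#' @param length_bp Chromosome length(s) in base pairs; vectorised.
#' @param iod_kb Mean inter-origin distance in kb (> 0); scalar or one value
#'   per chromosome.  Interpreted at 0.01 kb resolution so the ceiling is
#'   computed in exact integer arithmetic.
#' @return Integer vector of origin counts (each >= 1).
#' @examples
#' combing_origins(1e6, iod_kb = 160) # ceiling(6.25) = 7
#' combing_origins(1e6, iod_kb = 200) # exactly 5, no bump
#' @export
combing_origins <- function(length_bp, iod_kb) {
  n <- check_lengths(length_bp)
  if (!is.numeric(iod_kb) || anyNA(iod_kb) || any(iod_kb <= 0)) {
    abort_domain("`iod_kb` must be positive inter-origin distances in kb.")
  }
  if (!length(iod_kb) %in% c(1L, length(n))) {
    abort_domain("`iod_kb` must have length 1 or one value per chromosome.")
  }
  iodc <- round(iod_kb * 100) # 10^-2 kb = 10 bp units
  if (any(abs(iodc / 100 - iod_kb) > 1e-9 * iod_kb)) {
    # finer than 0.01 kb: floating path with boundary guard
    val <- n / (1000 * iod_kb)
    near <- round(val)
    return(as.integer(ifelse(abs(val - near) <= 1e-9 * pmax(1, val) & near >= 1,
                             near, ceiling(val))))
  }
  as.integer(ceil_div(n * 1, 10 * iodc))
}

#' Per-chromosome minimum-origin table for a karyotype
#'
#' Applies [minimum_origins()] to every chromosome of a karyotype under one
#' or more stress scenarios, producing one row per chromosome in the input
#' order.
#'
#' @param karyotype A karyotype tibble with columns `chromosome` and
#'   `length_bp` (see [read_karyotype_tsv()] or [organism_fixture()]).
#' @inheritParams minimum_origins
#' @param stress Character vector of scenarios among `"none"`, `"mild"`,
#'   `"harsh"`.  `"none"` yields column `mo`; the others `mo_mild` and
#'   `mo_harsh`.
#' @return A tibble with columns `chromosome`, `length_bp` and one column
#'   per requested scenario.
#' @examples
#' fx <- organism_fixture("tbrucei")
#' genome_mo_table(fx$karyotype, fx$fork_rate_kb_min, fx$s_phase_min,
#'                 stress = c("none", "mild", "harsh"))
#' @export
genome_mo_table <- function(karyotype, fork_rate_kb_min, s_phase_min,
                            stress = "none") {
  karyotype <- validate_karyotype(karyotype, allow_empty = TRUE)
  if (!is.character(stress) || length(stress) < 1L ||
      !all(stress %in% c("none", "mild", "harsh")) || anyDuplicated(stress)) {
    abort_domain('`stress` must be distinct scenarios among "none", "mild", "harsh".')
  }
  cols <- c(none = "mo", mild = "mo_mild", harsh = "mo_harsh")[stress]
  out <- tibble(
    chromosome = karyotype$chromosome,
    length_bp = karyotype$length_bp
  )
  for (i in seq_along(stress)) {
    out[[cols[[i]]]] <- if (nrow(out) == 0L) integer(0) else {
      minimum_origins(out$length_bp, fork_rate_kb_min, s_phase_min,
                      stress = stress[[i]])
    }
  }
  out
}
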