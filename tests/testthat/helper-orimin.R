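# Shared helpers: independent oracles and the documented erratum list.

# Closed-form ordinary-least-squares fit via the normal equations,
# independent of the lm-based implementation.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Smallest integer k whose k origins can replicate N bp in S minutes at
# fork rate v_kb kb/min (factor applied to v): found by linear search.
oracle_mo_search <- function(n_bp, v_kb, s_min, factor = 1) {
  capacity <- 2 * v_kb * 1000 * factor * s_min
  k <- 1
  while (k * capacity < n_bp) k <- k + 1
  k
}

# Published minimum-origin cells that disagree with the ceiling formula
# evaluated at the stated parameters (printed errata).  Columns refer to
# published_mo() column names.
mo_errata <- tibble::tribble(
  ~organism,     ~chromosome, ~column,
  "tcruzi",      "XXV",       "mo_published",
  "tcruzi",      "XXVII",     "mo_published",
  "tbrucei",     "V",         "mo_published",
  "tbrucei",     "IX",        "mo_published",
  "tbrucei",     "XI",        "mo_published",
  "scerevisiae", "V",         "mo_published",
  "tbrucei",     "V",         "mo_base_published",
  "tbrucei",     "IX",        "mo_base_published",
  "tbrucei",     "XI",        "mo_base_published",
  "scerevisiae", "V",         "mo_base_published",
  "scerevisiae", "V",         "mo_mild_published",
  "tcruzi",      "XXXIX",     "mo_harsh_published",
  "tcruzi",      "XL",        "mo_harsh_published",
  "tcruzi",      "XLI",       "mo_harsh_published",
  "lmajor",      "XIV",       "mo_harsh_published",
  "scerevisiae", "V",         "mo_harsh_published",
  "scerevisiae", "XIII",      "mo_harsh_published"
)

# Published cells and formula output side by side for one organism.
published_vs_computed <- function(organism) {
  fx <- organism_fixture(organism)
  computed <- genome_mo_table(fx$karyotype, fx$fork_rate_kb_min,
                              fx$s_phase_min,
                              stress = c("none", "mild", "harsh"))
  dplyr::left_join(published_mo(organism), computed, by = "chromosome")
}

# True phase-duration sets spanning the bundled organisms' doubling times
# and phase splits: three doubling times crossed with three (G1, S, Z)
# splits; Z is divided 50/25/25 into G2/M/C.
phase_grid <- function() {
  doubling <- c(8.5, 10.5, 24)
  splits <- list(
    c(g1 = 0.246, s = 0.411, z = 0.343),
    c(g1 = 0.53, s = 0.30, z = 0.17),
    c(g1 = 0.397, s = 0.272, z = 0.331)
  )
  out <- list()
  for (T in doubling) {
    for (sp in splits) {
      z <- sp[["z"]] * T
      out[[length(out) + 1]] <- phase_durations(
        g1 = sp[["g1"]] * T, s = sp[["s"]] * T,
        g2 = 0.5 * z, m = 0.25 * z, c = 0.25 * z
      )
    }
  }
  out
}

# element-wise minimum_origins over parallel (N, v, S) vectors
minimum_origins_vec <- function(n, v, s) {
  vapply(seq_along(n), function(i) minimum_origins(n[[i]], v[[i]], s[[i]]),
         integer(1))
}

phase_hours_for_test <- function(phases, which) {
  phases$hours[match(which, as.character(phases$phase))]
}

# Monte-Carlo standard error of each estimated phase duration, from the
# spread of estimates over replicate simulations at the same true
# durations (independent seeds).
roundtrip_se <- function(truth, n_cells, pulse, seeds) {
  ests <- vapply(seeds, function(sd) {
    snap <- simulate_snapshot(truth, n_cells = n_cells, pulse = pulse,
                              seed = sd)
    est <- estimate_phases(snap, attr(truth, "doubling_time"))
    stats::setNames(est$hours, as.character(est$phase))
  }, numeric(5))
  apply(ests, 1, stats::sd)
}
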