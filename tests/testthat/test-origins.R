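test_that("minimum origins reproduce reference chromosome values", {
  # T. brucei chromosome VII
  expect_identical(minimum_origins(2205233, 3.06, 138.6), 3L)
  # S. pombe chromosomes I and III
  expect_identical(minimum_origins(5598923, 0.91, 24), 129L)
  expect_identical(minimum_origins(2465919, 0.91, 24), 57L)
  # S. cerevisiae chromosome IV
  expect_identical(minimum_origins(1522190, 1.6, 30), 16L)
  # an exact multiple of the per-origin capacity is not bumped
  expect_identical(minimum_origins(96000, 1.6, 30), 1L)
  expect_identical(minimum_origins(192000, 1.6, 30), 2L)
  expect_identical(minimum_origins(192001, 1.6, 30), 3L)
})

test_that("stress scenarios scale the fork rate by exact rationals", {
  # harsh: T. brucei XI and S. cerevisiae IV
  expect_identical(minimum_origins(5223313, 3.06, 138.6, stress = "harsh"), 19L)
  expect_identical(
    stressed_minimum_origins(1522190, 1.6, 30, "harsh"), 48L)
  # mild: T. cruzi XXXIX
  expect_identical(minimum_origins(1854104, 2.05, 591.6, stress = "mild"), 2L)
  # stress "none" and factor 1 are the identity
  n <- c(230190, 1522190, 5598923)
  expect_identical(minimum_origins(n, 1.6, 30, stress = "none"),
                   minimum_origins(n, 1.6, 30))
  expect_identical(minimum_origins(n, 1.6, 30, stress = 1),
                   minimum_origins(n, 1.6, 30))
  # numeric 2/3 matches the named scenario (exact rationalization)
  expect_identical(minimum_origins(n, 1.6, 30, stress = 2 / 3),
                   minimum_origins(n, 1.6, 30, stress = "mild"))
})

test_that("stress ordering MO^HR >= MO^MR >= MO holds across all fixtures", {
  for (org in c("tcruzi", "lmajor", "tbrucei", "scerevisiae", "spombe")) {
    fx <- organism_fixture(org)
    tab <- genome_mo_table(fx$karyotype, fx$fork_rate_kb_min, fx$s_phase_min,
                           stress = c("none", "mild", "harsh"))
    expect_true(all(tab$mo_harsh >= tab$mo_mild))
    expect_true(all(tab$mo_mild >= tab$mo))
    expect_true(all(tab$mo >= 1L))
  }
})

test_that("MO is monotone in chromosome size, fork rate and S-phase length", {
  lengths <- round(seq(5e4, 6e6, length.out = 40))
  for (v in c(0.91, 1.6, 3.06)) {
    expect_true(all(diff(minimum_origins(lengths, v, 60)) >= 0))
  }
  for (n in c(987654, 3542885)) {
    by_v <- vapply(seq(0.5, 4, by = 0.25), function(v)
      minimum_origins(n, v, 60), integer(1))
    expect_true(all(diff(by_v) <= 0))
    by_s <- vapply(seq(20, 600, by = 20), function(s)
      minimum_origins(n, 2, s), integer(1))
    expect_true(all(diff(by_s) <= 0))
  }
})

test_that("halving the fork rate at most doubles MO and never lowers it", {
  set.seed(7)
  n <- sample(1e4:8e6, 300)
  v <- sample(seq(0.5, 4, by = 0.01), 300, replace = TRUE)
  s <- sample(seq(20, 600, by = 0.1), 300, replace = TRUE)
  mo1 <- minimum_origins_vec(n, v, s)
  mo_half <- minimum_origins_vec(n, v / 2, s)
  expect_true(all(mo_half >= mo1))
  expect_true(all(mo_half <= 2 * mo1))
})

test_that("the ceiling formula agrees with a linear-search oracle", {
  set.seed(42)
  k <- 1000
  n <- sample(1e3:1e6, k, replace = TRUE)
  v <- round(runif(k, 0.2, 4), 2)
  s <- round(runif(k, 10, 600), 1)
  scen <- sample(c("none", "mild", "harsh"), k, replace = TRUE)
  factors <- c(none = 1, mild = 2 / 3, harsh = 1 / 3)
  got <- vapply(seq_len(k), function(i)
    minimum_origins(n[[i]], v[[i]], s[[i]], stress = scen[[i]]), integer(1))
  want <- vapply(seq_len(k), function(i)
    oracle_mo_search(n[[i]], v[[i]], s[[i]], factors[[scen[[i]]]]), numeric(1))
  expect_identical(got, as.integer(want))
})

test_that("exact-rational and floating-point paths agree off the boundary", {
  set.seed(8)
  n <- sample(1e4:6e6, 500)
  exact <- minimum_origins(n, 2.44, 192, stress = "harsh")
  float <- orimin:::minimum_origins_float(n, 2.44, 192, 1 / 3)
  expect_identical(exact, float)
  # rounding-sensitive reference case: L. major XIV under harsh stress is
  # 622,644 / (2 * (2.44/3) * 192 * 1000) = 1.9936 -> 2 on both paths; the
  # published cell (3) arises only if the stressed rate is rounded first
  expect_identical(minimum_origins(622644, 2.44, 192, stress = "harsh"), 2L)
  expect_identical(orimin:::minimum_origins_float(622644, 2.44, 192, 1 / 3), 2L)
})

test_that("combing origin counts take the ceiling of N over the IOD", {
  expect_identical(combing_origins(160000, 160), 1L) # one origin spans it
  expect_identical(combing_origins(1e6, 160), 7L)    # ceiling(6.25)
  expect_identical(combing_origins(1e6, 200), 5L)    # exact, no bump
  expect_identical(combing_origins(c(1e6, 2e6), c(200, 160)), c(5L, 13L))
  expect_error(combing_origins(1e6, 0), class = "orimin_error_domain")
  expect_error(combing_origins(1e6, c(1, 2, 3)), class = "orimin_error_domain")
})

test_that("genome MO tables reproduce the published cells except errata", {
  total <- 0L
  mismatches <- NULL
  for (org in c("tcruzi", "lmajor", "tbrucei", "scerevisiae", "spombe")) {
    both <- published_vs_computed(org)
    for (col in c("mo_published", "mo_base_published", "mo_mild_published",
                  "mo_harsh_published")) {
      fcol <- switch(col,
        mo_published = "mo", mo_base_published = "mo",
        mo_mild_published = "mo_mild", mo_harsh_published = "mo_harsh")
      keep <- !is.na(both[[col]])
      total <- total + sum(keep & col == "mo_published")
      bad <- both$chromosome[keep & both[[col]] != both[[fcol]]]
      if (length(bad) > 0L) {
        mismatches <- rbind(mismatches, data.frame(
          organism = org, chromosome = bad, column = col
        ))
      }
    }
  }
  expect_identical(total, 107L) # populated base-table cells
  # the only disagreements are the documented printed errata
  expect_identical(
    dplyr::arrange(tibble::as_tibble(mismatches), organism, column, chromosome),
    dplyr::arrange(mo_errata, organism, column, chromosome)
  )
})

test_that("genome_mo_table preserves order and handles empty karyotypes", {
  k <- karyotype(c("b", "a"), c(2e6, 1e6))
  tab <- genome_mo_table(k, 1.6, 30, stress = c("none", "harsh"))
  expect_identical(tab$chromosome, c("b", "a"))
  expect_identical(names(tab), c("chromosome", "length_bp", "mo", "mo_harsh"))
  empty <- genome_mo_table(karyotype(character(0), numeric(0)), 1.6, 30)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("chromosome", "length_bp", "mo"))
})

test_that("L. major chromosomes needing several origins sit above 2vS", {
  fx <- organism_fixture("lmajor")
  tab <- genome_mo_table(fx$karyotype, fx$fork_rate_kb_min, fx$s_phase_min)
  threshold <- 2 * fx$fork_rate_kb_min * 1000 * fx$s_phase_min # 936,960 bp
  expect_identical(tab$chromosome[tab$mo >= 2],
                   tab$chromosome[tab$length_bp > threshold])
})

test_that("input validation rejects non-genomic lengths and bad stress", {
  expect_error(minimum_origins(0, 1.6, 30), class = "orimin_error_domain")
  expect_error(minimum_origins(1.5e3 + 0.5, 1.6, 30),
               class = "orimin_error_domain")
  expect_error(minimum_origins(1e6, -1, 30), class = "orimin_error_domain")
  expect_error(minimum_origins(1e6, 1.6, 0), class = "orimin_error_domain")
  expect_error(minimum_origins(1e6, 1.6, 30, stress = "severe"),
               class = "orimin_error_domain")
  expect_error(minimum_origins(1e6, 1.6, 30, stress = 0),
               class = "orimin_error_domain")
  expect_error(minimum_origins(1e6, 1.6, 30, stress = 1.2),
               class = "orimin_error_domain")
})
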