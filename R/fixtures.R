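orimin_organisms <- c("tcruzi", "lmajor", "tbrucei", "scerevisiae", "spombe")

extdata_path <- function(...) {
  path <- system.file("extdata", ..., package = "orimin", mustWork = FALSE)
  if (!nzchar(path)) {
    abort_io(sprintf("Bundled fixture %s not found.", file.path(...)))
  }
  path
}

check_organism <- function(organism) {
  if (!is.character(organism) || length(organism) != 1L ||
      !organism %in% orimin_organisms) {
    abort_domain(sprintf(
      "`organism` must be one of %s.",
      paste0('"', orimin_organisms, '"', collapse = ", ")
    ))
  }
  organism
}

#' Bundled karyotype and replication parameters for a reference organism
#'
#' Five reference organisms are bundled: *Trypanosoma cruzi* (41 nuclear
#' chromosomes), *Leishmania major* (36), *Trypanosoma brucei* (11
#' megabase chromosomes), *Saccharomyces cerevisiae* (16) and
#' *Schizosaccharomyces pombe* (3), together with the mean replication-fork
#' rate (kb/min) and S-phase duration (min) used for their minimum-origin
#' calculations.
#'
#' @param organism One of `"tcruzi"`, `"lmajor"`, `"tbrucei"`,
#'   `"scerevisiae"`, `"spombe"`.
#' @return A list with elements `organism`, `karyotype` (a karyotype
#'   tibble), `fork_rate_kb_min` and `s_phase_min`.
#' @examples
#' fx <- organism_fixture("spombe")
#' fx$fork_rate_kb_min # 0.91
#' nrow(fx$karyotype)  # 3
#' @export
organism_fixture <- function(organism) {
  organism <- check_organism(organism)
  k <- read_karyotype_tsv(
    extdata_path(paste0("karyotype_", organism, ".tsv")),
    organism = organism
  )
  par <- readr::read_tsv(
    extdata_path("replication_params.tsv"),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  row <- par[par$organism == organism, ]
  list(
    organism = organism,
    karyotype = k,
    fork_rate_kb_min = row$fork_rate_kb_min[[1]],
    s_phase_min = row$s_phase_min[[1]]
  )
}

#' Published per-chromosome minimum-origin counts
#'
#' The per-chromosome MO values as originally published for the bundled
#' karyotypes: `mo_published` from the base table and
#' `mo_base_published` / `mo_mild_published` / `mo_harsh_published` from the
#' replication-stress table (mild = fork rate at 2/3, harsh = 1/3; `NA`
#' where no stress prediction was published).  A small number of published
#' cells disagree with the ceiling formula evaluated at the stated
#' parameters; these documented errata are listed in the methods vignette.
#'
#' @param organism A bundled organism name, or `NULL` (default) for all.
#' @return A tibble with columns `organism`, `chromosome`, `mo_published`,
#'   `mo_base_published`, `mo_mild_published`, `mo_harsh_published`.
#' @export
published_mo <- function(organism = NULL) {
  tab <- readr::read_tsv(
    extdata_path("published_mo.tsv"),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    na = "NA"
  )
  if (!is.null(organism)) {
    tab <- tab[tab$organism == check_organism(organism), ]
  }
  tab
}
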