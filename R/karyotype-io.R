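#' Construct a karyotype
#'
#' A karyotype is a tibble with one row per chromosome: a unique name and a
#' positive integer length in base pairs, in source order.
#'
#' @param chromosome Character vector of chromosome names (unique).
#' @param length_bp Chromosome lengths in base pairs (positive integers).
#' @param organism Optional organism label, stored as an attribute.
#' @return A tibble of class `orimin_karyotype`.
#' @export
karyotype <- function(chromosome, length_bp, organism = NULL) {
  if (length(chromosome) != length(length_bp)) {
    abort_io("`chromosome` and `length_bp` must have the same length.")
  }
  chromosome <- as.character(chromosome)
  if (anyNA(chromosome) || any(chromosome == "")) {
    abort_io("Chromosome names must be non-empty.")
  }
  dup <- unique(chromosome[duplicated(chromosome)])
  if (length(dup) > 0L) {
    abort_io(sprintf(
      "Duplicate chromosome name(s): %s.", paste(dup, collapse = ", ")
    ))
  }
  if (length(length_bp) > 0L &&
      (!is.numeric(length_bp) || anyNA(length_bp) ||
       any(!is_wholeish(length_bp)) || any(length_bp < 1))) {
    abort_io("Chromosome lengths must be positive integers (bp).")
  }
  out <- new_tibble(
    tibble(chromosome = chromosome, length_bp = as.numeric(round(length_bp))),
    organism = organism,
    class = "orimin_karyotype"
  )
  out
}

validate_karyotype <- function(x, allow_empty = FALSE) {
  if (!is.data.frame(x) || !all(c("chromosome", "length_bp") %in% names(x))) {
    abort_io("`karyotype` must be a data frame with columns `chromosome` and `length_bp`.")
  }
  if (!allow_empty && nrow(x) == 0L) {
    abort_io("`karyotype` is empty.")
  }
  karyotype(x$chromosome, x$length_bp, organism = attr(x, "organism"))
}

read_nonblank_lines <- function(path, strip_comments = FALSE) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (strip_comments) lines <- lines[!grepl("^\\s*#", lines)]
  lines[nzchar(trimws(lines))]
}

# Parse a chromosome-length field.  Accepts plain integers, thousands
# separators ("1,064,672"), decimal points or decimal commas with a unit
# suffix ("230.19kb", "230,19 kb", "2.6 Mb"); bare numbers are base pairs.
parse_length_field <- function(x) {
  raw <- trimws(x)
  m <- regmatches(raw, regexec("^([0-9][0-9.,]*)\\s*([KkMm][Bb]|[Bb][Pp])?$", raw))
  vapply(seq_along(raw), function(i) {
    parts <- m[[i]]
    if (length(parts) == 0L) {
      abort_io(sprintf("Cannot parse chromosome length '%s'.", raw[[i]]))
    }
    num <- parts[[2]]
    unit <- tolower(parts[[3]])
    if (grepl("^[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$", num)) {
      num <- gsub(",", "", num, fixed = TRUE) # thousands separators
    } else if (grepl("^[0-9]+,[0-9]+$", num)) {
      num <- sub(",", ".", num, fixed = TRUE) # decimal comma
    } else if (grepl(",", num, fixed = TRUE)) {
      abort_io(sprintf("Ambiguous number format in length '%s'.", raw[[i]]))
    }
    val <- suppressWarnings(as.numeric(num))
    if (is.na(val)) {
      abort_io(sprintf("Cannot parse chromosome length '%s'.", raw[[i]]))
    }
    mult <- switch(if (unit == "") "bp" else unit, bp = 1, kb = 1e3, mb = 1e6)
    bp <- round(val * mult)
    if (bp < 1) abort_io(sprintf("Non-positive chromosome length '%s'.", raw[[i]]))
    if (unit %in% c("", "bp") && val != bp) {
      abort_io(sprintf("Chromosome length '%s' is not an integer number of bp.", raw[[i]]))
    }
    bp
  }, numeric(1))
}

#' Read a karyotype from a FASTA index (.fai) file
#'
#' A `.fai` file (as written by `samtools faidx`) has one tab-separated line
#' per sequence whose first two columns are the sequence name and its length
#' in bases; any further columns are ignored.
#'
#' @param path Path to the `.fai` file.
#' @param organism Optional organism label.
#' @return A karyotype tibble (see [karyotype()]), rows in file order.
#' @export
read_karyotype_fai <- function(path, organism = NULL) {
  lines <- read_nonblank_lines(path)
  if (length(lines) == 0L) abort_io(sprintf("Empty .fai file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort_io(sprintf("Line %d of %s has fewer than 2 tab-separated columns.",
                     bad[[1]], path))
  }
  name <- vapply(fields, `[[`, character(1), 1L)
  len <- vapply(fields, `[[`, character(1), 2L)
  if (!all(grepl("^[0-9]+$", len))) {
    abort_io(sprintf("Non-integer length field in %s.", path))
  }
  karyotype(name, as.numeric(len), organism = organism)
}

#' Read a karyotype from a two-column TSV file
#'
#' Expects tab-separated lines `name<TAB>length`; an optional header line
#' and `#` comment lines are skipped.  Lengths may carry a `kb`/`Mb`/`bp`
#' unit suffix (e.g. `230.19kb`), with decimal commas tolerated; bare
#' numbers are base pairs.
#'
#' @inheritParams read_karyotype_fai
#' @return A karyotype tibble, rows in file order.
#' @export
read_karyotype_tsv <- function(path, organism = NULL) {
  lines <- read_nonblank_lines(path, strip_comments = TRUE)
  if (length(lines) == 0L) abort_io(sprintf("Empty karyotype file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort_io(sprintf("Line %d of %s has fewer than 2 tab-separated columns.",
                     bad[[1]], path))
  }
  # header detection: first line whose length field does not parse
  is_header <- !grepl("^[0-9]", trimws(fields[[1]][[2]]))
  if (is_header) {
    fields <- fields[-1]
    if (length(fields) == 0L) abort_io(sprintf("No data rows in %s.", path))
  }
  name <- vapply(fields, `[[`, character(1), 1L)
  len <- parse_length_field(vapply(fields, `[[`, character(1), 2L))
  karyotype(name, len, organism = organism)
}

#' Write a karyotype as a two-column TSV file
#'
#' Writes a header line `chromosome<TAB>length_bp` followed by one row per
#' chromosome with lengths as plain base-pair integers.  Reading the file
#' back with [read_karyotype_tsv()] and writing it again is byte-stable.
#'
#' @param karyotype A karyotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype_tsv <- function(karyotype, path) {
  karyotype <- validate_karyotype(karyotype)
  lines <- c(
    "chromosome\tlength_bp",
    sprintf("%s\t%d", karyotype$chromosome, as.integer(karyotype$length_bp))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read per-chromosome origin counts
#'
#' Two formats are supported.  A TSV of `(chromosome, count)` pairs gives
#' counts directly; a BED file (0-based, half-open intervals, one origin
#' site per record) is tallied per chromosome, using only the chromosome
#' field (strand, score and further columns are ignored).  Chromosomes of
#' the karyotype absent from the file receive count 0; a record on a
#' chromosome not in the karyotype is an error.  Names are matched as exact
#' strings (no "chr"-prefix normalisation), optionally after applying an
#' alias map.
#'
#' @param path Path to the counts file.
#' @param karyotype The karyotype the counts must resolve against.
#' @param format `"auto"` (by file extension), `"tsv"` or `"bed"`.
#' @param method Optional label describing the mapping method (e.g.
#'   `"combing"`, `"MFA-seq"`); stored as an attribute.
#' @param aliases Optional named character vector mapping file names to
#'   karyotype names.
#' @return A tibble with columns `chromosome` and `count`, one row per
#'   karyotype chromosome in karyotype order, with attribute `method`.
#' @export
read_origin_counts <- function(path, karyotype,
                               format = c("auto", "tsv", "bed"),
                               method = NULL, aliases = NULL) {
  karyotype <- validate_karyotype(karyotype)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  lines <- read_nonblank_lines(path, strip_comments = TRUE)
  lines <- lines[!grepl("^(track|browser)\\b", lines)]
  if (length(lines) == 0L) abort_io(sprintf("No records in %s.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (format == "bed") {
    bad <- which(lengths(fields) < 3L)
    if (length(bad) > 0L) {
      abort_io(sprintf("Malformed BED line %d in %s: fewer than 3 columns.",
                       bad[[1]], path))
    }
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- vapply(fields, `[[`, character(1), 2L)
    end <- vapply(fields, `[[`, character(1), 3L)
    if (!all(grepl("^[0-9]+$", start)) || !all(grepl("^[0-9]+$", end))) {
      abort_io(sprintf("Malformed BED coordinates in %s.", path))
    }
    if (any(as.numeric(end) <= as.numeric(start))) {
      abort_io(sprintf("Malformed BED interval in %s: end <= start.", path))
    }
    file_counts <- table(chrom)
    counts <- tibble(
      chromosome = names(file_counts),
      count = as.numeric(file_counts)
    )
  } else {
    if (any(lengths(fields) < 2L)) {
      abort_io(sprintf("Count lines in %s need 2 tab-separated columns.", path))
    }
    chrom <- vapply(fields, `[[`, character(1), 1L)
    cnt <- vapply(fields, `[[`, character(1), 2L)
    if (!grepl("^[0-9]+$", cnt[[1]])) { # header
      chrom <- chrom[-1]
      cnt <- cnt[-1]
      if (length(chrom) == 0L) abort_io(sprintf("No data rows in %s.", path))
    }
    if (!all(grepl("^[0-9]+$", cnt))) {
      abort_io(sprintf("Non-integer origin count in %s.", path))
    }
    if (anyDuplicated(chrom)) {
      abort_io(sprintf("Duplicate chromosome in counts file %s.", path))
    }
    counts <- tibble(chromosome = chrom, count = as.numeric(cnt))
  }

  if (!is.null(aliases)) {
    hit <- counts$chromosome %in% names(aliases)
    counts$chromosome[hit] <- unname(aliases[counts$chromosome[hit]])
  }
  unknown <- setdiff(counts$chromosome, karyotype$chromosome)
  if (length(unknown) > 0L) {
    abort_io(sprintf(
      "Chromosome(s) absent from the karyotype: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- left_join(
    select(as_tibble(karyotype), "chromosome"),
    counts,
    by = "chromosome"
  )
  out$count[is.na(out$count)] <- 0
  attr(out, "method") <- method
  out
}
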