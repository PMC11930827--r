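#' Read raw visit records
#'
#' Reads a delimited visit-record file with header columns
#' `patient_id,sex,age,icd10` (comma- or tab-separated; gzip-compressed files
#' are read transparently). One row is one diagnosis event for one patient.
#'
#' @param path path to a CSV/TSV file, optionally `.gz`.
#' @param sep field separator; `NULL` (default) guesses from the extension
#'   (`.tsv`/`.tsv.gz` means tab, otherwise comma).
#' @return a data frame with columns `patient_id` (character), `sex`
#'   (factor `male`/`female`), `age` (integer), `code` (character, the raw
#'   ICD-10 string).
#' @export
read_records <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  needed <- c("patient_id", "sex", "age", "icd10")
  if (!all(needed %in% names(df))) {
    stop("record file must have header columns ", paste(needed, collapse = ","))
  }
  data.frame(
    patient_id = df$patient_id,
    sex = factor(df$sex, levels = c("male", "female")),
    age = suppressWarnings(as.integer(df$age)),
    code = df$icd10,
    stringsAsFactors = FALSE
  )
}

#' Validate an ICD-10 code string
#'
#' A code is valid when it is one uppercase letter, two digits, and
#' optionally a dot followed by one to three digits (e.g. `A01.001`, `I10`).
#' Leading/trailing whitespace, lowercase letters, and anything else is
#' rejected. Total function: never errors, `NA` input gives `FALSE`.
#'
#' @param code character vector of raw diagnosis strings.
#' @return logical vector, one element per code.
#' @export
#' @examples
#' validate_icd10(c("A01.001", "I10", "", "1A0.b3", " I10"))
validate_icd10 <- function(code) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,3})?$", code)
  ok & !is.na(code)
}

#' Collapse repeat visits into one record per patient and disease
#'
#' Repeat visits by the same patient for the same (raw or recoded) code are
#' counted once; the first occurrence is kept so the output order is stable.
#'
#' @param records visit-record data frame.
#' @return the records with exactly one row per distinct
#'   `(patient_id, code)` pair.
#' @export
deduplicate <- function(records) {
  stop_if_not_records(records)
  keep <- !duplicated(paste0(records$patient_id, "\r", records$code))
  records[keep, , drop = FALSE]
}

#' Build a recoding rule set
#'
#' Each rule maps a set of ICD-10 source codes or code prefixes to one merged
#' code (e.g. `ee03` for the E03.8 + E03.9 hypothyroidism codes, `ii2520`
#' for chronic ischaemic heart disease I25 plus angina I20). Matching is by
#' exact code or prefix, longest prefix wins. Source sets of distinct rules
#' must be disjoint; overlap is a configuration error caught here, at load
#' time.
#'
#' @param new_code character vector of merged code labels (recycled against
#'   `sources` when given as a list).
#' @param sources list (parallel to `new_code`) of character vectors of
#'   source codes/prefixes.
#' @return a `recode_rules` object (data frame with columns `new_code`,
#'   `source`).
#' @export
recode_rules <- function(new_code, sources) {
  if (length(new_code) != length(sources)) {
    stop("new_code and sources must have the same length")
  }
  if (any(lengths(sources) < 1L)) stop("every rule must map at least one source")
  df <- data.frame(
    new_code = rep(new_code, lengths(sources)),
    source = unlist(sources, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(df$source)
  if (any(dup)) {
    stop("overlapping rule sources: ",
         paste(unique(df$source[dup]), collapse = ", "))
  }
  class(df) <- c("recode_rules", "data.frame")
  df
}

#' Apply disease recoding rules
#'
#' Replaces each raw code by its rule's merged code when any rule source
#' matches by exact code or by prefix (longest prefix wins); unmatched codes
#' pass through unchanged. Records are re-deduplicated afterwards, so a
#' patient holding two source codes of the same merged disease (say I25.1
#' and I20.0 under `ii2520`) contributes a single record; the number of
#' records merged away is returned in attribute `"n_merged"`.
#'
#' @param records visit-record data frame (deduplicated at raw-code level).
#' @param rules a [recode_rules] object.
#' @return recoded, re-deduplicated records with attribute `n_merged`.
#' @export
apply_recoding <- function(records, rules) {
  stop_if_not_records(records)
  if (!inherits(rules, "recode_rules")) {
    stop("rules must be built with recode_rules() or load_panel_config()")
  }
  ord <- order(-nchar(rules$source))   # longest prefix wins
  code <- records$code
  out <- code
  assigned <- rep(FALSE, length(code))
  for (k in ord) {
    hit <- !assigned & startsWith(code, rules$source[k])
    out[hit] <- rules$new_code[k]
    assigned <- assigned | hit
  }
  records$code <- out
  n_before <- nrow(records)
  records <- deduplicate(records)
  attr(records, "n_merged") <- n_before - nrow(records)
  records
}

new_exclusion_report <- function(stage, n_in, n_out) {
  rep <- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                    n_dropped = n_in - n_out, stringsAsFactors = FALSE)
  class(rep) <- c("exclusion_report", "data.frame")
  rep
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Record exclusion report:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %10d -> %10d  (dropped %d)\n",
                x$stage[i], x$n_in[i], x$n_out[i], x$n_dropped[i]))
  }
  invisible(x)
}

#' Apply the chronic-disease exclusion cascade
#'
#' Drops records in four ordered stages: (1) codes failing ICD-10 validation
#' (merged codes produced by [apply_recoding()] are whitelisted implicitly by
#' stage 2, so stage 1 only catches garbled raw codes that survived
#' upstream); (2) codes not on the chronic-disease allowlist; (3) diseases
#' whose prevalence is below `min_prevalence` of the population at that
#' stage; (4) patients left with exactly one disease, which carry no
#' comorbidity information. Prevalence is computed once, on the
#' post-recoding population, not iteratively.
#'
#' @param records recoded visit-record data frame.
#' @param chronic_allowlist character vector of retained (recoded) disease
#'   codes. `NULL` skips the allowlist stage (drops nothing there).
#' @param min_prevalence minimum disease prevalence as a fraction (the study
#'   used 0.01).
#' @param denominator whether prevalence divides by distinct `"patients"`
#'   (default) or by total `"records"` at that stage.
#' @return a list with elements `records` (the surviving records) and
#'   `report` (an `exclusion_report` data frame with columns
#'   `stage, n_in, n_out, n_dropped`; `n_out = n_in - n_dropped` at every
#'   stage).
#' @export
apply_exclusions <- function(records, chronic_allowlist = NULL,
                             min_prevalence = 0.01,
                             denominator = c("patients", "records")) {
  stop_if_not_records(records)
  denominator <- match.arg(denominator)
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage); n_in <<- c(n_in, before); n_out <<- c(n_out, after)
  }

  ## merged codes (lowercase labels such as ii2520) are not raw ICD-10 but
  ## are legitimate after recoding
  valid <- validate_icd10(records$code) |
    grepl("^[a-z][a-z0-9_]*$", records$code) |
    records$code %in% chronic_allowlist
  n0 <- nrow(records)
  records <- records[valid, , drop = FALSE]
  note("invalid_code", n0, nrow(records))

  if (!is.null(chronic_allowlist)) {
    n0 <- nrow(records)
    records <- records[records$code %in% chronic_allowlist, , drop = FALSE]
    note("non_chronic", n0, nrow(records))
  } else {
    note("non_chronic", nrow(records), nrow(records))
  }

  n0 <- nrow(records)
  denom <- if (denominator == "patients") {
    length(unique(records$patient_id))
  } else {
    nrow(records)
  }
  if (n0 > 0) {
    carriers <- tapply(records$patient_id, records$code,
                       function(p) length(unique(p)))
    keep_codes <- names(carriers)[carriers / denom >= min_prevalence]
    records <- records[records$code %in% keep_codes, , drop = FALSE]
  }
  note("low_prevalence", n0, nrow(records))

  n0 <- nrow(records)
  per_patient <- table(records$patient_id)
  multi <- names(per_patient)[per_patient >= 2L]
  records <- records[records$patient_id %in% multi, , drop = FALSE]
  note("single_disease", n0, nrow(records))

  if (nrow(records) == 0L) {
    stop("all records excluded; the pipeline cannot proceed", call. = FALSE)
  }
  list(records = records,
       report = new_exclusion_report(stages, n_in, n_out))
}

#' Select the disease panel around the most prevalent diseases
#'
#' Determines the `n_top` most prevalent diseases, then for each of them
#' ranks every other disease by its comorbidity rate with the index disease
#' and keeps the `n_comorbid` highest. The panel is the union of those lists
#' plus the top diseases themselves, duplicates removed, ordered by overall
#' prevalence (descending, ties broken lexicographically by code). With the
#' study configuration `n_top = 5, n_comorbid = 40` this reproduces the
#' 38-disease panel construction.
#'
#' @param records fully filtered visit-record data frame.
#' @param n_top number of index diseases (study value 5).
#' @param n_comorbid number of top comorbid diseases kept per index disease
#'   (study value 40).
#' @param rate comorbidity-rate definition: `"conditional"` (default,
#'   co-occurring patients / index-disease patients) or `"jaccard"`.
#' @return a `disease_panel` data frame with columns `code`, `display_name`
#'   (`NA` unless set later from config) and `is_top` flagging the index
#'   diseases.
#' @export
build_panel <- function(records, n_top = 5L, n_comorbid = 40L,
                        rate = c("conditional", "jaccard")) {
  stop_if_not_records(records)
  rate <- match.arg(rate)
  carriers <- lapply(split(records$patient_id, records$code), unique)
  if (length(carriers) < n_top) {
    stop("fewer distinct diseases (", length(carriers), ") than n_top (",
         n_top, ")")
  }
  prev <- vapply(carriers, length, integer(1))
  ## descending prevalence, lexicographic code on ties
  ord <- order(-prev, names(prev))
  top <- names(prev)[ord][seq_len(n_top)]

  chosen <- top
  for (d in top) {
    others <- setdiff(names(prev), d)
    co <- vapply(others, function(o) {
      inter <- length(intersect(carriers[[d]], carriers[[o]]))
      if (rate == "conditional") {
        inter / length(carriers[[d]])
      } else {
        inter / length(union(carriers[[d]], carriers[[o]]))
      }
    }, numeric(1))
    oo <- order(-co, others)
    chosen <- c(chosen, others[oo][seq_len(min(n_comorbid, length(others)))])
  }
  codes <- unique(chosen)
  codes <- codes[order(-prev[codes], codes)]
  panel <- data.frame(code = codes,
                      display_name = NA_character_,
                      is_top = codes %in% top,
                      stringsAsFactors = FALSE)
  class(panel) <- c("disease_panel", "data.frame")
  panel
}

#' Build the binary comorbidity matrix
#'
#' One row per patient, one column per panel disease, entry 1 iff the
#' patient carries that disease. The single-disease exclusion has already
#' been applied on the full recoded disease set; rows that hold fewer than
#' two panel diseases are retained by default (the matrix reflects panel
#' restriction only) but can be dropped.
#'
#' @param records filtered visit-record data frame.
#' @param panel a `disease_panel` or character vector of panel codes.
#' @param keep_rows `"all"` (default) or `"min2"` to drop rows with fewer
#'   than two panel diseases.
#' @return a `comorbidity_matrix`: list with `x` (integer 0/1 matrix,
#'   rownames = patient ids, colnames = panel codes in panel order) and
#'   `sex` (factor, one label per row).
#' @export
build_matrix <- function(records, panel, keep_rows = c("all", "min2")) {
  stop_if_not_records(records)
  keep_rows <- match.arg(keep_rows)
  codes <- if (is.data.frame(panel)) panel$code else as.character(panel)
  records <- records[records$code %in% codes, , drop = FALSE]
  pids <- unique(records$patient_id)
  x <- matrix(0L, nrow = length(pids), ncol = length(codes),
              dimnames = list(pids, codes))
  x[cbind(match(records$patient_id, pids), match(records$code, codes))] <- 1L
  sex <- records$sex[match(pids, records$patient_id)]
  if (keep_rows == "min2") {
    keep <- rowSums(x) >= 2L
    x <- x[keep, , drop = FALSE]
    sex <- sex[keep]
  }
  comorbidity_matrix(x, sex)
}

#' Construct a comorbidity matrix object
#'
#' @param x integer/numeric 0-1 matrix, patients in rows, diseases in
#'   columns (colnames are the disease codes).
#' @param sex optional factor/character of per-row sex labels.
#' @return a `comorbidity_matrix` object.
#' @export
comorbidity_matrix <- function(x, sex = NULL) {
  x <- as.matrix(x)
  if (length(x) && !all(x %in% c(0, 1))) {
    stop("comorbidity matrix entries must be 0/1")
  }
  storage.mode(x) <- "integer"
  if (!is.null(sex)) {
    sex <- factor(as.character(sex), levels = c("male", "female"))
    if (length(sex) != nrow(x)) stop("one sex label per row required")
  }
  structure(list(x = x, sex = sex), class = "comorbidity_matrix")
}

#' @export
print.comorbidity_matrix <- function(x, ...) {
  cat(sprintf("comorbidity matrix: %d patients x %d diseases\n",
              nrow(x$x), ncol(x$x)))
  if (!is.null(x$sex)) {
    tab <- table(x$sex)
    cat("  sex:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stratified random sampling of matrix rows by sex
#'
#' Uniform sampling without replacement within each sex stratum,
#' reproducible under a fixed seed. A stratum smaller than `n_per_sex` is
#' returned whole with a warning (the study sampled 150,000 records per
#' gender).
#'
#' @param m a `comorbidity_matrix` with per-row sex labels.
#' @param n_per_sex rows to draw per sex.
#' @param seed integer RNG seed.
#' @return a `comorbidity_matrix` with at most `2 * n_per_sex` rows.
#' @export
sample_by_sex <- function(m, n_per_sex, seed = 20230601L) {
  if (is.null(m$sex)) stop("matrix rows carry no sex labels")
  keep <- integer(0)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  for (s in levels(m$sex)) {
    idx <- which(m$sex == s)
    if (length(idx) == 0L) next
    if (length(idx) <= n_per_sex) {
      if (length(idx) < n_per_sex) {
        warning(sprintf("stratum %s has %d < %d rows; taking all",
                        s, length(idx), n_per_sex))
      }
      keep <- c(keep, idx)
    } else {
      keep <- c(keep, sort(sample(idx, n_per_sex)))
    }
  }
  comorbidity_matrix(m$x[keep, , drop = FALSE], m$sex[keep])
}

#' Load the disease-panel configuration
#'
#' Reads a YAML file describing the merged disease codes: each entry has a
#' merged `code`, a human-readable `name`, its `sources` (raw ICD-10 codes or
#' prefixes) and optionally a `top5` flag. The package ships the 38-disease
#' chronic panel of the Shanghai study as `panel38.yaml` (source sets beyond
#' the two documented examples are reconstructed from the merged-code names).
#'
#' @param path YAML file; default is the shipped 38-disease panel.
#' @return list with `rules` (a [recode_rules] object), `allowlist`
#'   (character vector of merged codes), `panel` (a `disease_panel` data
#'   frame) and `seed` (default sampling seed, if present in the file).
#' @export
load_panel_config <- function(path = system.file("extdata", "panel38.yaml",
                                                 package = "comorbnet")) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$panel
  codes <- vapply(entries, `[[`, character(1), "code")
  names <- vapply(entries, function(e) e$name %||% NA_character_, character(1))
  top5 <- vapply(entries, function(e) isTRUE(e$top5), logical(1))
  sources <- lapply(entries, `[[`, "sources")
  rules <- recode_rules(codes, sources)
  panel <- data.frame(code = codes, display_name = names, is_top = top5,
                      stringsAsFactors = FALSE)
  class(panel) <- c("disease_panel", "data.frame")
  list(rules = rules, allowlist = codes, panel = panel,
       seed = cfg$seed %||% 20230601L)
}

#' Run the full ETL stage
#'
#' Age filter, ICD-10 validation, deduplication, recoding (with re-dedup),
#' chronic allowlist, low-prevalence and single-disease exclusions, matrix
#' construction — with record counts logged at every stage as a
#' machine-readable exclusion report (the study's processing flowchart).
#'
#' @param records raw visit-record data frame (or path readable by
#'   [read_records()]).
#' @param rules [recode_rules] for disease merging (`NULL` = no recoding).
#' @param allowlist chronic-disease allowlist of recoded codes (`NULL` = keep
#'   all).
#' @param min_prevalence prevalence cutoff fraction (default 0.01).
#' @param age_range inclusive age window, default `c(60, 99)`.
#' @param panel optional fixed `disease_panel`; when `NULL` the panel is
#'   built with [build_panel()] using `n_top`/`n_comorbid`.
#' @param n_top,n_comorbid panel construction parameters (defaults 5 and 40).
#' @param denominator passed to [apply_exclusions()].
#' @return list with `matrix` (`comorbidity_matrix`), `panel`, `records`
#'   (surviving records) and `report` (`exclusion_report` covering stages
#'   `age, invalid_code, duplicate, recode_merge, non_chronic,
#'   low_prevalence, single_disease`).
#' @export
run_etl <- function(records, rules = NULL, allowlist = NULL,
                    min_prevalence = 0.01, age_range = c(60L, 99L),
                    panel = NULL, n_top = 5L, n_comorbid = 40L,
                    denominator = "patients") {
  if (is.character(records)) records <- read_records(records)
  if ("icd10" %in% names(records) && !"code" %in% names(records)) {
    names(records)[names(records) == "icd10"] <- "code"
  }
  stop_if_not_records(records)

  n0 <- nrow(records)
  ok_age <- !is.na(records$age) &
    records$age >= age_range[1] & records$age <= age_range[2]
  records <- records[ok_age, , drop = FALSE]
  rep_age <- new_exclusion_report("age", n0, nrow(records))

  n0 <- nrow(records)
  ## merged-style lowercase codes are legitimate inputs too (already-recoded
  ## feeds); only garbled strings fall here
  ok_code <- validate_icd10(records$code) |
    grepl("^[a-z][a-z0-9_]*$", records$code)
  records <- records[ok_code, , drop = FALSE]
  rep_valid <- new_exclusion_report("invalid_code", n0, nrow(records))

  n0 <- nrow(records)
  records <- deduplicate(records)
  rep_dup <- new_exclusion_report("duplicate", n0, nrow(records))

  n0 <- nrow(records)
  n_merged <- 0L
  if (!is.null(rules)) {
    records <- apply_recoding(records, rules)
    n_merged <- attr(records, "n_merged")
  }
  rep_rec <- new_exclusion_report("recode_merge", n0, n0 - n_merged)

  excl <- apply_exclusions(records, chronic_allowlist = allowlist,
                           min_prevalence = min_prevalence,
                           denominator = denominator)
  records <- excl$records
  report <- rbind(rep_age, rep_valid, rep_dup, rep_rec, excl$report)
  class(report) <- c("exclusion_report", "data.frame")

  if (is.null(panel)) {
    panel <- build_panel(records, n_top = n_top, n_comorbid = n_comorbid)
  }
  m <- build_matrix(records, panel)
  list(matrix = m, panel = panel, records = records, report = report)
}
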