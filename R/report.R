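#' Disease prevalence table
#'
#' Per-disease visit counts and percentages in the layout of the study's
#' "top single-diagnosed diseases" table: total deduplicated records
#' (one record = one patient-disease pair), percent of all processed
#' records, and male/female splits. Percentages are rounded half away from
#' zero to two decimals, matching the published tables.
#'
#' Accepts cleaned visit records, a `comorbidity_matrix`, or an already
#' aggregated count table (columns `disease, total, male, female`) with an
#' explicit denominator — the latter lets published counts be re-checked
#' directly.
#'
#' @param x records data frame, `comorbidity_matrix`, or count table.
#' @param top_k rows to keep (default 10); `Inf` keeps all.
#' @param n_total denominator (total processed records); required for count
#'   tables, derived otherwise.
#' @return a `prevalence_table` data frame with columns
#'   `disease, total, pct, male, female`, sorted by `total` descending
#'   (ties lexicographic).
#' @export
prevalence_table <- function(x, top_k = 10, n_total = NULL) {
  if (inherits(x, "comorbidity_matrix")) {
    total <- colSums(x$x)
    male <- if (!is.null(x$sex)) colSums(x$x[x$sex == "male", , drop = FALSE]) else NA
    female <- if (!is.null(x$sex)) colSums(x$x[x$sex == "female", , drop = FALSE]) else NA
    tab <- data.frame(disease = colnames(x$x), total = as.integer(total),
                      male = as.integer(male), female = as.integer(female),
                      stringsAsFactors = FALSE)
    n_total <- n_total %||% sum(x$x)
  } else if (is.data.frame(x) && all(c("disease", "total") %in% names(x))) {
    if (is.null(n_total)) stop("n_total denominator required for count tables")
    tab <- x
    if (is.null(tab$male)) tab$male <- NA_integer_
    if (is.null(tab$female)) tab$female <- NA_integer_
  } else {
    stop_if_not_records(x)
    cnt <- function(r) {
      t <- table(r$code)
      setNames(as.integer(t), names(t))
    }
    total <- cnt(x)
    male <- cnt(x[!is.na(x$sex) & x$sex == "male", , drop = FALSE])
    female <- cnt(x[!is.na(x$sex) & x$sex == "female", , drop = FALSE])
    tab <- data.frame(disease = names(total), total = total,
                      male = as.integer(male[names(total)]),
                      female = as.integer(female[names(total)]),
                      stringsAsFactors = FALSE)
    tab$male[is.na(tab$male)] <- 0L
    tab$female[is.na(tab$female)] <- 0L
    n_total <- n_total %||% nrow(x)
  }
  tab$pct <- round_half_up(100 * tab$total / n_total, 2)
  tab <- tab[order(-tab$total, tab$disease),
             c("disease", "total", "pct", "male", "female")]
  if (is.finite(top_k)) tab <- head(tab, top_k)
  rownames(tab) <- NULL
  attr(tab, "n_total") <- n_total
  class(tab) <- c("prevalence_table", "data.frame")
  tab
}

#' Age distribution by 10-year band and sex
#'
#' Counts and percentages per 10-year band (60-69 … 90-99) by sex and
#' overall, plus mean age with standard deviation per sex and pooled — the
#' layout of the study's population-characteristics table. Percentages are
#' of the grand total and rounded half away from zero to two decimals.
#' Each input row (one visit record, or one patient if pre-deduplicated)
#' counts once.
#'
#' @param records data frame with `age` and `sex` columns.
#' @return an `age_distribution`: list with `bands` (data frame
#'   `band, total, total_pct, male, male_pct, female, female_pct`) and
#'   `summary` (data frame `group, n, mean, sd`).
#' @export
age_distribution <- function(records) {
  if (!all(c("age", "sex") %in% names(records))) {
    stop("records must have age and sex columns")
  }
  age <- records$age
  sex <- records$sex
  band <- cut(age, c(60, 70, 80, 90, 100), right = FALSE,
              labels = c("60-69", "70-79", "80-89", "90-99"))
  if (anyNA(band)) stop("ages outside [60, 99]; apply the age filter first")
  n <- length(age)
  tab <- function(sel) as.integer(table(band[sel]))
  bands <- data.frame(
    band = levels(band),
    total = tab(TRUE),
    male = tab(!is.na(sex) & sex == "male"),
    female = tab(!is.na(sex) & sex == "female"),
    stringsAsFactors = FALSE)
  bands$total_pct <- round_half_up(100 * bands$total / n, 2)
  bands$male_pct <- round_half_up(100 * bands$male / n, 2)
  bands$female_pct <- round_half_up(100 * bands$female / n, 2)
  bands <- bands[, c("band", "total", "total_pct", "male", "male_pct",
                     "female", "female_pct")]
  grp <- list(overall = rep(TRUE, n),
              male = !is.na(sex) & sex == "male",
              female = !is.na(sex) & sex == "female")
  summary <- do.call(rbind, lapply(names(grp), function(gn) {
    a <- age[grp[[gn]]]
    data.frame(group = gn, n = length(a), mean = mean(a),
               sd = stats::sd(a), stringsAsFactors = FALSE)
  }))
  structure(list(bands = bands, summary = summary),
            class = "age_distribution")
}

#' @export
print.age_distribution <- function(x, ...) {
  cat("age distribution (counts and % of all records):\n")
  print.data.frame(x$bands, row.names = FALSE)
  cat("\nmean age:\n")
  print.data.frame(transform(x$summary, mean = round(mean, 2),
                             sd = round(sd, 3)), row.names = FALSE)
  invisible(x)
}

#' Write a weighted edge list as TSV
#'
#' @param net an `ising_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- edge_list(net)
  el$weight <- sprintf("%.10g", el$weight)
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write node thresholds as TSV
#'
#' @param net an `ising_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(net, path) {
  df <- data.frame(node = names(net$b),
                   threshold = sprintf("%.10g", net$b))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network (optionally with communities) as GraphML
#'
#' Produces a GraphML file with `weight` edge attributes and, when a
#' partition is given, a `community` node attribute — the hand-off format
#' for downstream network rendering.
#'
#' @param net an `ising_network`.
#' @param path output file.
#' @param partition optional `community_partition`.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, partition = NULL) {
  g <- igraph::graph_from_adjacency_matrix(net$w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(partition)) {
    igraph::V(g)$community <- as.integer(partition$labels[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write an exclusion report as TSV
#'
#' @param report an `exclusion_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 20230601L,
    age_range = c(60L, 99L),
    min_prevalence = 0.01,
    prevalence_denominator = "patients",
    n_top = 5L,
    n_comorbid = 40L,
    n_per_sex = 150000L,
    ebic_gamma = 0.25,
    rule = "AND",
    n_lambda = 100L,
    lambda_ratio = 0.01,
    gamma_res = 1
  )
}

#' Run the full comorbidity-network pipeline
#'
#' ETL (validation, deduplication, recoding, exclusions, matrix), stratified
#' sampling by sex, then per sex stratum: eLasso network estimation,
#' centrality, positive-subgraph extraction and fast-greedy community
#' detection. All artifacts are written as TSV/GraphML under `out_dir`
#' together with the exclusion report, a JSON run manifest (seeds and
#' hyperparameters) and a plain-text log. Reruns with the same config and
#' seed produce byte-identical tables.
#'
#' @param records raw visit records (data frame or file path).
#' @param config named list of settings; missing entries take the defaults
#'   of `seed = 20230601`, `min_prevalence = 0.01`, `n_top = 5`,
#'   `n_comorbid = 40`, `n_per_sex = 150000`, `ebic_gamma = 0.25`,
#'   `rule = "AND"`, `n_lambda = 100`, `lambda_ratio = 0.01`,
#'   `gamma_res = 1`. A path to a YAML file is also accepted.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param rules,allowlist,panel optional recoding rules / chronic allowlist
#'   / fixed panel (see [run_etl()]); by default no recoding is applied.
#' @return list with `etl` (see [run_etl()]) and `strata` — per sex stratum
#'   a list with `matrix`, `network`, `centrality`, `graph`, `partition`.
#' @export
run_pipeline <- function(records, config = list(), out_dir = NULL,
                         rules = NULL, allowlist = NULL, panel = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  say("pipeline start: seed=%d min_prevalence=%g n_top=%d n_comorbid=%d",
      cfg$seed, cfg$min_prevalence, cfg$n_top, cfg$n_comorbid)
  etl <- run_etl(records, rules = rules, allowlist = allowlist,
                 min_prevalence = cfg$min_prevalence,
                 age_range = cfg$age_range, panel = panel,
                 n_top = cfg$n_top, n_comorbid = cfg$n_comorbid,
                 denominator = cfg$prevalence_denominator)
  for (i in seq_len(nrow(etl$report))) {
    say("etl %-14s %d -> %d", etl$report$stage[i], etl$report$n_in[i],
        etl$report$n_out[i])
  }

  m <- etl$matrix
  strata <- list()
  sexes <- if (is.null(m$sex) || all(is.na(m$sex))) "all" else c("male", "female")
  for (s in sexes) {
    sub <- if (s == "all") m else {
      comorbidity_matrix(m$x[!is.na(m$sex) & m$sex == s, , drop = FALSE])
    }
    if (nrow(sub$x) > cfg$n_per_sex) {
      set.seed(derive_seed(cfg$seed, match(s, sexes)))
      keep <- sort(sample(nrow(sub$x), cfg$n_per_sex))
      sub <- comorbidity_matrix(sub$x[keep, , drop = FALSE])
    } else if (nrow(sub$x) < cfg$n_per_sex) {
      say("stratum %s has %d < %d rows; using all", s, nrow(sub$x),
          cfg$n_per_sex)
    }
    say("stratum %s: fitting eLasso on %d x %d", s, nrow(sub$x), ncol(sub$x))
    net <- fit_ising(sub, gamma = cfg$ebic_gamma, rule = cfg$rule,
                     n_lambda = cfg$n_lambda, lambda_ratio = cfg$lambda_ratio)
    cent <- centrality_table(net)
    gpos <- positive_subgraph(net)
    say("stratum %s: %d edges, %d negative dropped for clustering", s,
        sum(net$w[upper.tri(net$w)] != 0), attr(gpos, "n_negative_dropped"))
    part <- fast_greedy(gpos, gamma_res = cfg$gamma_res)
    say("stratum %s: %d communities, Q = %.4f", s,
        length(unique(part$labels)), part$q)
    strata[[s]] <- list(matrix = sub, network = net, centrality = cent,
                        graph = gpos, partition = part)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_exclusion_report(etl$report, file.path(out_dir, "exclusion_report.tsv"))
    for (s in names(strata)) {
      st <- strata[[s]]
      write_edge_list(st$network, file.path(out_dir, paste0("network_", s, ".tsv")))
      write_thresholds(st$network, file.path(out_dir, paste0("thresholds_", s, ".tsv")))
      write_graphml(st$network, file.path(out_dir, paste0("network_", s, ".graphml")),
                    partition = st$partition)
      write_centrality_table(st$centrality,
                             file.path(out_dir, paste0("centrality_", s, ".tsv")))
      write_partition(st$partition, file.path(out_dir, paste0("communities_", s, ".tsv")))
    }
    manifest <- c(cfg, list(strata = names(strata),
                            panel = etl$panel$code,
                            n_records_in = etl$report$n_in[1]))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  structure(list(etl = etl, strata = strata, config = cfg, log = log),
            class = "comorbnet_run")
}
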