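#' Construct a planted block Ising network
#'
#' Ground truth for estimator and community-detection validation. The `p`
#' nodes are split into `k` near-equal blocks (sizes differing by at most
#' one); within-block node pairs receive weight `w_in` (each edge present
#' independently with probability `density`), between-block pairs weight
#' `w_out`, and every node gets threshold `b`.
#'
#' @param p number of nodes.
#' @param k number of planted communities (`p >= k >= 1`).
#' @param w_in within-block edge weight (must be positive).
#' @param w_out between-block edge weight (0 = no between-block edges).
#' @param b node threshold (baseline log-odds of activation).
#' @param density probability a within-block edge is present (default 1, so
#'   the planted structure is unambiguous).
#' @param seed RNG seed (used only when `density < 1`).
#' @param labels optional node labels; defaults to `d01..dp`.
#' @return a `ground_truth` object: list with `w` (symmetric weight matrix,
#'   zero diagonal), `b` (threshold vector), `partition` (planted block id
#'   per node) and the sampler settings slot `sampler` (filled by
#'   [gibbs_sample()] callers).
#' @export
make_planted_network <- function(p, k, w_in = 1, w_out = 0, b = 0,
                                 density = 1, seed = 1L, labels = NULL) {
  stopifnot(p >= k, k >= 1, w_in > 0, density >= 0, density <= 1)
  if (is.null(labels)) labels <- sprintf("d%02d", seq_len(p))
  ## balanced split: first (p %% k) blocks get the extra node
  sizes <- rep(p %/% k, k) + c(rep(1L, p %% k), rep(0L, k - p %% k))
  part <- rep(seq_len(k), sizes)
  w <- matrix(0, p, p, dimnames = list(labels, labels))
  set.seed(seed)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      same <- part[i] == part[j]
      wij <- if (same) {
        if (density >= 1 || runif(1) < density) w_in else 0
      } else {
        w_out
      }
      w[i, j] <- w[j, i] <- wij
    }
  }
  structure(list(w = w, b = rep(b, p), partition = setNames(part, labels),
                 labels = labels),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground-truth Ising network: %d nodes, %d edges, %d blocks\n",
              length(x$b), sum(x$w[upper.tri(x$w)] != 0),
              length(unique(x$partition))))
  invisible(x)
}

#' Gibbs-sample binary rows from an Ising model
#'
#' Systematic-scan Gibbs sampling from the pairwise binary Markov random
#' field with weights `w` and thresholds `b`: each node is updated in fixed
#' order from its exact conditional
#' `P(x_i = 1 | rest) = logistic(b_i + sum_j w_ij x_j)`.
#' Two chain layouts are supported. `"parallel"` (default) runs `n`
#' independent chains, one per output row, for `burn_in` full sweeps each —
#' rows are then independent draws. `"single"` runs one chain and records
#' every `thin`-th state after `burn_in` sweeps (rows are then a thinned
#' Markov chain, useful when a literal single-chain trace is wanted).
#'
#' @param gt a `ground_truth` object (or any list with `w` and `b`).
#' @param n number of binary rows to return.
#' @param burn_in full sweeps discarded before recording (default 500).
#' @param thin record every `thin`-th sweep in single-chain mode (default 10).
#' @param chains `"parallel"` or `"single"`.
#' @param seed RNG seed; the draw is reproducible given `(gt, n, seed)`.
#' @return a `comorbidity_matrix` (no sex labels) with `n` rows and one
#'   column per node.
#' @export
gibbs_sample <- function(gt, n, burn_in = 500L, thin = 10L,
                         chains = c("parallel", "single"), seed = 1L) {
  chains <- match.arg(chains)
  w <- gt$w; b <- gt$b
  p <- length(b)
  stopifnot(isSymmetric(unname(w)), all(diag(w) == 0), burn_in >= 0, thin >= 1)
  set.seed(seed)
  if (chains == "parallel") {
    x <- matrix(as.integer(runif(n * p) < 0.5), n, p)
    ## incremental local field: eta = x %*% w, rank-1-updated on each flip
    ## (w[i,i] = 0, so a node's own state never enters its conditional)
    eta <- x %*% w
    for (s in seq_len(burn_in)) {
      for (i in seq_len(p)) {
        pr <- plogis(eta[, i] + b[i])
        new <- as.integer(runif(n) < pr)
        delta <- new - x[, i]
        idx <- which(delta != 0L)
        if (length(idx)) {
          x[idx, i] <- new[idx]
          eta[idx, ] <- eta[idx, ] + tcrossprod(delta[idx], w[i, ])
        }
      }
    }
  } else {
    x <- matrix(0L, n, p)
    state <- as.integer(runif(p) < 0.5)
    sweep1 <- function(state) {
      for (i in seq_len(p)) {
        pr <- plogis(sum(w[, i] * state) + b[i])
        state[i] <- as.integer(runif(1) < pr)
      }
      state
    }
    for (s in seq_len(burn_in)) state <- sweep1(state)
    for (r in seq_len(n)) {
      for (t in seq_len(thin)) state <- sweep1(state)
      x[r, ] <- state
    }
  }
  colnames(x) <- gt$labels %||% colnames(w) %||% sprintf("d%02d", seq_len(p))
  rownames(x) <- sprintf("s%06d", seq_len(n))
  comorbidity_matrix(x)
}

#' Exact configuration distribution of a small Ising model
#'
#' Enumerates all `2^p` binary configurations and normalizes their
#' unnormalized probabilities `exp(sum_{i<j} w_ij x_i x_j + sum_i b_i x_i)`.
#' Intended for validating the Gibbs sampler at `p <= 20` (practically
#' `p <= 4` in routine tests).
#'
#' @param gt a `ground_truth` object (or list with `w`, `b`).
#' @return data frame with one row per configuration: the `p` node columns
#'   plus `prob`.
#' @export
ising_exact_distribution <- function(gt) {
  w <- gt$w; b <- gt$b; p <- length(b)
  stopifnot(p <= 20)
  grid <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(grid) <- colnames(w) %||% sprintf("d%02d", seq_len(p))
  loglik <- apply(grid, 1, function(x) {
    sum(w[upper.tri(w)] * tcrossprod(x)[upper.tri(w)]) + sum(b * x)
  })
  pr <- exp(loglik - max(loglik))
  out <- as.data.frame(grid)
  out$prob <- pr / sum(pr)
  out
}

band_breaks <- c(60, 70, 80, 90, 100)
band_names <- c("60-69", "70-79", "80-89", "90-99")

#' Generate a messy raw record file with a known exclusion ledger
#'
#' Emits a visit-record table (and optionally a CSV file) that emulates raw
#' claims data: a core cohort of multi-disease patients whose disease sets
#' are drawn from given prevalences, plus injected mess — duplicate rows,
#' garbled codes, valid-but-non-chronic codes, patients with out-of-range
#' ages, single-disease patients, rare low-prevalence diseases, and
#' "recode twins" (a second raw source code of a merged disease already
#' held, which the recoding stage collapses). Every injection is counted in
#' the returned ledger so the ETL exclusion report can be checked exactly.
#'
#' Age-band proportions default to the study population's distribution
#' (47.28 / 33.99 / 14.37 / 4.36 percent for bands 60-69 … 90-99) and the
#' sex split to 45.9 percent male.
#'
#' @param n_patients core multi-disease patients.
#' @param diseases character vector of recoded panel codes, or a
#'   `disease_panel`; raw codes are emitted via `raw_codes`.
#' @param raw_codes named list mapping each panel code to its raw ICD-10
#'   source codes (first element is the canonical emission; defaults to the
#'   codes themselves, i.e. no recoding needed).
#' @param prevalence per-disease inclusion weights for the core cohort
#'   (recycled; default uniform).
#' @param mean_diseases mean diseases per core patient (truncated at >= 2).
#' @param n_duplicates duplicate rows injected (copies of core rows).
#' @param n_garbled garbled/invalid code rows injected on core patients.
#' @param n_nonchronic valid ICD-10 rows with non-panel codes injected on
#'   core patients (distinct code per patient).
#' @param n_badage_patients extra patients (2 rows each) with ages outside
#'   60-99.
#' @param n_singles extra patients carrying exactly one panel disease.
#' @param n_recode_twins rows adding a second raw source code of a merged
#'   disease a core patient already holds (requires a multi-source entry in
#'   `raw_codes`).
#' @param rare_codes character vector of extra low-prevalence disease codes;
#'   each is given to `rare_carriers` core patients.
#' @param rare_carriers core patients per rare disease (keep below the
#'   prevalence cutoff of the ETL run being validated).
#' @param age_band_probs probabilities of the four 10-year age bands.
#' @param p_male probability a patient is male.
#' @param seed RNG seed.
#' @param path optional path; when given the records are written as CSV
#'   with header `patient_id,sex,age,icd10`.
#' @return list with `records` (the raw table, shuffled), `path` (or `NULL`)
#'   and `ledger` — a `record_ledger` list with the injected counts
#'   (`n_badage_records`, `n_duplicates`, `n_garbled`, `n_recode_twins`,
#'   `n_nonchronic`, `n_rare_records`, `n_single_records`), the expected
#'   per-stage drops, per-disease carrier counts, and per-sex/age-band
#'   counts of the clean cohort.
#' @export
make_record_file <- function(n_patients = 300L,
                             diseases,
                             raw_codes = NULL,
                             prevalence = NULL,
                             mean_diseases = 3,
                             n_duplicates = 0L,
                             n_garbled = 0L,
                             n_nonchronic = 0L,
                             n_badage_patients = 0L,
                             n_singles = 0L,
                             n_recode_twins = 0L,
                             rare_codes = character(0),
                             rare_carriers = 1L,
                             age_band_probs = c(0.4728, 0.3399, 0.1437, 0.0436),
                             p_male = 0.459,
                             seed = 1L,
                             path = NULL) {
  if (is.data.frame(diseases)) diseases <- diseases$code
  p <- length(diseases)
  stopifnot(p >= 2, mean_diseases >= 2)
  if (is.null(raw_codes)) {
    raw_codes <- as.list(setNames(diseases, diseases))
  }
  prevalence <- rep_len(prevalence %||% 1, p)
  set.seed(seed)

  draw_age <- function(n) {
    band <- sample.int(4L, n, replace = TRUE, prob = age_band_probs)
    band_breaks[band] + sample.int(10L, n, replace = TRUE) - 1L
  }
  draw_sex <- function(n) ifelse(runif(n) < p_male, "male", "female")

  ## core cohort: every patient gets >= 2 distinct diseases
  core_ids <- sprintf("P%05d", seq_len(n_patients))
  core_sex <- draw_sex(n_patients)
  core_age <- draw_age(n_patients)
  k_dis <- pmin(p, pmax(2L, rpois(n_patients, mean_diseases - 2) + 2L))
  core <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    dis <- sample(diseases, k_dis[i], prob = prevalence)
    raw <- vapply(dis, function(d) raw_codes[[d]][1], character(1))
    data.frame(patient_id = core_ids[i], sex = core_sex[i],
               age = core_age[i], icd10 = raw, panel_code = dis,
               stringsAsFactors = FALSE)
  }))

  ## per-disease carrier counts and sex/age-band tallies of the clean cohort
  carriers <- table(factor(core$panel_code, levels = diseases))

  mess <- list()
  ## single-disease patients (one panel disease each)
  if (n_singles > 0) {
    sid <- sprintf("S%05d", seq_len(n_singles))
    mess$singles <- data.frame(
      patient_id = sid, sex = draw_sex(n_singles), age = draw_age(n_singles),
      icd10 = vapply(sample(diseases, n_singles, replace = TRUE),
                     function(d) raw_codes[[d]][1], character(1)),
      panel_code = NA_character_, stringsAsFactors = FALSE)
  }
  ## out-of-range-age patients, 2 rows each
  if (n_badage_patients > 0) {
    bid <- sprintf("B%05d", seq_len(n_badage_patients))
    bad_age <- ifelse(runif(n_badage_patients) < 0.5,
                      sample(30:59, n_badage_patients, replace = TRUE),
                      sample(100:110, n_badage_patients, replace = TRUE))
    mess$badage <- do.call(rbind, lapply(seq_len(n_badage_patients), function(i) {
      dis <- sample(diseases, 2L)
      data.frame(patient_id = bid[i], sex = draw_sex(1), age = bad_age[i],
                 icd10 = vapply(dis, function(d) raw_codes[[d]][1], character(1)),
                 panel_code = NA_character_, stringsAsFactors = FALSE)
    }))
  }
  ## duplicates: exact copies of core rows (with replacement across rows,
  ## but each copied row only once so the dedup drop count is exact)
  if (n_duplicates > 0) {
    idx <- sample(nrow(core), min(n_duplicates, nrow(core)))
    n_duplicates <- length(idx)
    mess$dups <- core[idx, , drop = FALSE]
  }
  ## garbled codes: syntactically invalid, unique per row
  if (n_garbled > 0) {
    host <- sample(core_ids, n_garbled, replace = TRUE)
    mess$garbled <- data.frame(
      patient_id = host, sex = core_sex[match(host, core_ids)],
      age = core_age[match(host, core_ids)],
      icd10 = sprintf("zz!%04d", seq_len(n_garbled)),
      panel_code = NA_character_, stringsAsFactors = FALSE)
  }
  ## valid but non-chronic codes: one distinct code per chosen patient
  if (n_nonchronic > 0) {
    host <- sample(core_ids, n_nonchronic,
                   replace = n_nonchronic > length(core_ids))
    mess$nonchronic <- data.frame(
      patient_id = host, sex = core_sex[match(host, core_ids)],
      age = core_age[match(host, core_ids)],
      icd10 = sprintf("C%02d.%d", seq_len(n_nonchronic) %% 90 + 10,
                      seq_len(n_nonchronic) %% 10),
      panel_code = NA_character_, stringsAsFactors = FALSE)
  }
  ## recode twins: second raw source of a held merged disease
  if (n_recode_twins > 0) {
    multi_src <- names(raw_codes)[lengths(raw_codes) >= 2]
    cand <- core[core$panel_code %in% multi_src, , drop = FALSE]
    if (nrow(cand) < n_recode_twins) {
      stop("not enough multi-source disease rows for n_recode_twins")
    }
    idx <- sample(nrow(cand), n_recode_twins)
    twin <- cand[idx, , drop = FALSE]
    twin$icd10 <- vapply(twin$panel_code,
                         function(d) raw_codes[[d]][2], character(1))
    mess$twins <- twin
  }
  ## rare diseases: below the prevalence cutoff, hosted on core patients
  n_rare_records <- 0L
  if (length(rare_codes) > 0) {
    rare <- do.call(rbind, lapply(rare_codes, function(rc) {
      host <- sample(core_ids, rare_carriers)
      data.frame(patient_id = host, sex = core_sex[match(host, core_ids)],
                 age = core_age[match(host, core_ids)], icd10 = rc,
                 panel_code = NA_character_, stringsAsFactors = FALSE)
    }))
    n_rare_records <- nrow(rare)
    mess$rare <- rare
  }

  all_rows <- rbind(core, do.call(rbind, unname(mess)))
  all_rows <- all_rows[sample(nrow(all_rows)), , drop = FALSE]
  records <- all_rows[, c("patient_id", "sex", "age", "icd10")]
  rownames(records) <- NULL

  cohort <- rbind(
    data.frame(patient_id = core_ids, sex = core_sex, age = core_age),
    if (n_singles > 0) unique(mess$singles[, c("patient_id", "sex", "age")])
  )
  band <- cut(cohort$age, band_breaks, right = FALSE, labels = band_names)
  ledger <- structure(list(
    n_core_patients = n_patients,
    n_single_patients = n_singles,
    n_badage_records = if (n_badage_patients > 0) nrow(mess$badage) else 0L,
    n_duplicates = n_duplicates,
    n_garbled = n_garbled,
    n_recode_twins = n_recode_twins,
    n_nonchronic = n_nonchronic,
    n_rare_records = n_rare_records,
    n_single_records = n_singles,
    expected_drops = c(age = if (n_badage_patients > 0) nrow(mess$badage) else 0L,
                       invalid_code = n_garbled,
                       duplicate = n_duplicates,
                       recode_merge = n_recode_twins,
                       non_chronic = n_nonchronic,
                       low_prevalence = n_rare_records,
                       single_disease = n_singles),
    disease_counts = as.integer(carriers),
    disease_codes = diseases,
    sex_counts = table(factor(cohort$sex, levels = c("male", "female"))),
    age_band_counts = table(band),
    n_records_emitted = nrow(records)
  ), class = "record_ledger")

  if (!is.null(path)) {
    write.table(records, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  list(records = records, path = path, ledger = ledger)
}

#' @export
print.record_ledger <- function(x, ...) {
  cat("synthetic record ledger:\n")
  cat(sprintf("  core patients %d, singles %d, records emitted %d\n",
              x$n_core_patients, x$n_single_patients, x$n_records_emitted))
  cat("  expected stage drops:\n")
  for (s in names(x$expected_drops)) {
    cat(sprintf("    %-14s %d\n", s, x$expected_drops[[s]]))
  }
  invisible(x)
}
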