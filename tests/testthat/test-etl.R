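test_that("ICD-10 validation accepts well-formed codes and nothing else", {
  expect_true(validate_icd10("A01.001"))
  expect_true(all(validate_icd10(c("I10", "E03.8", "K21", "Z99.9"))))
  expect_false(any(validate_icd10(c(
    "", "1A0.b3", " I10", "I10 ", "i10", "I1", "I100", "A01.", "A01.0001",
    "A01,001", NA))))
})

test_that("deduplication keeps one record per patient-disease pair, stably", {
  r <- rec(c("P1", "P1", "P1", "P2", "P1"),
           c("I10", "I10", "E11", "I10", "I10"))
  d <- deduplicate(r)
  expect_equal(nrow(d), 3L)
  expect_equal(d$code, c("I10", "E11", "I10"))   # first-occurrence order
  ## idempotence
  expect_identical(deduplicate(d), d)
  ## no-op on duplicate-free input
  r2 <- rec(c("P1", "P1", "P2"), c("I10", "E11", "I10"))
  expect_equal(nrow(deduplicate(r2)), 3L)
})

test_that("recoding merges sources, longest prefix wins, and re-deduplicates", {
  rules <- recode_rules(c("ee03", "ii2520", "x25x"),
                        list(c("E03.8", "E03.9"), c("I25", "I20"), "I25.9"))
  r <- rec(rep("P1", 5), c("E03.8", "I25.1", "I20.0", "I25.9", "K29"))
  out <- apply_recoding(r, rules)
  ## I25.1 and I20.0 merge into one ii2520 record; I25.9 hits the longer
  ## prefix rule; unmatched K29 passes through
  expect_equal(out$code, c("ee03", "ii2520", "x25x", "K29"))
  expect_equal(attr(out, "n_merged"), 1L)
  ## recoding never increases the distinct pair count
  expect_lte(nrow(out), nrow(deduplicate(r)))
})

test_that("overlapping rule sources are a configuration error at load time", {
  expect_error(recode_rules(c("a", "b"), list("I10", c("I10", "I20"))),
               "overlapping")
  expect_error(recode_rules("a", list(character(0))), "at least one source")
})

test_that("exclusion cascade drops in order and the report balances", {
  ## 200 patients with two common diseases; one disease carried by 1 patient
  r <- rbind(
    rec(sprintf("P%03d", 1:200), "i10"),
    rec(sprintf("P%03d", 1:200), "kk29"),
    rec("P001", "rare1"),
    rec("P005", "C34.1"),        # valid ICD-10 but not chronic
    rec("P006", "garbled??")
  )
  res <- apply_exclusions(r, chronic_allowlist = c("i10", "kk29", "rare1"),
                          min_prevalence = 0.01)
  rep <- res$report
  expect_equal(rep$stage, c("invalid_code", "non_chronic",
                            "low_prevalence", "single_disease"))
  expect_equal(rep$n_out, rep$n_in - rep$n_dropped)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$n_dropped, c(1L, 1L, 1L, 0L))   # 1/200 = 0.5% < 1%
  expect_false("rare1" %in% res$records$code)

  ## a patient reduced to a single disease is dropped
  r2 <- rbind(rec(c("P1", "P1", "P2"), c("i10", "kk29", "i10")))
  res2 <- apply_exclusions(r2, min_prevalence = 0)
  expect_false("P2" %in% res2$records$patient_id)

  ## raising min_prevalence never adds a disease back (monotone)
  set.seed(11)
  r3 <- rec(sample(sprintf("P%02d", 1:40), 300, replace = TRUE),
            sample(c("i10", "kk29", "e78", "m81", "r42"), 300, TRUE,
                   prob = c(.4, .3, .15, .1, .05)))
  r3 <- deduplicate(r3)
  kept <- lapply(c(0, 0.05, 0.15, 0.3), function(mp) {
    unique(apply_exclusions(r3, min_prevalence = mp)$records$code)
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("empty exclusion output is an error, not an empty pipeline", {
  r <- rec("P1", "i10")
  expect_error(apply_exclusions(r, min_prevalence = 0), "excluded")
})

test_that("panel construction matches a hand-enumerable toy cohort", {
  ## 3 diseases, n_top = 3: union saturates to all of them
  r <- rbind(rec(c("P1", "P1"), c("a", "b")), rec(c("P2", "P2"), c("b", "c")))
  pan <- build_panel(r, n_top = 3, n_comorbid = 2)
  expect_setequal(pan$code, c("a", "b", "c"))
  expect_equal(pan$code[1], "b")    # most prevalent first

  ## planted cohort, rates brute-force checkable: 6 diseases, 12 patients
  set.seed(4)
  pats <- sprintf("Q%02d", 1:12)
  dis <- c("d1", "d2", "d3", "d4", "d5", "d6")
  rows <- do.call(rbind, lapply(seq_along(pats), function(i) {
    k <- 2 + i %% 3
    rec(rep(pats[i], k), sample(dis, k))
  }))
  rows <- deduplicate(rows)
  pan2 <- build_panel(rows, n_top = 2, n_comorbid = 1)
  carriers <- table(rows$code)
  top2 <- names(sort(carriers, decreasing = TRUE))
  ## recompute by brute force: top-2 prevalent + their single best comorbid
  prev_order <- names(carriers)[order(-carriers, names(carriers))]
  top <- prev_order[1:2]
  expected <- top
  for (d in top) {
    others <- setdiff(dis, d)
    rate <- vapply(others, function(o) oracle_comorbidity_rate(rows, d, o),
                   numeric(1))
    expected <- c(expected, others[order(-rate, others)][1])
  }
  expected <- unique(expected)
  expected <- expected[order(-carriers[expected], expected)]
  expect_equal(pan2$code, unname(expected))

  expect_error(build_panel(r, n_top = 10), "fewer distinct diseases")
})

test_that("matrix construction is faithful to records and panel order", {
  r <- rbind(rec(c("P1", "P1"), c("ii2520", "kk29")),
             rec(c("P2", "P2", "P2"), c("i10", "kk29", "e78")))
  panel <- c("i10", "ii2520", "kk29", "e78", "m81")
  m <- build_matrix(r, panel)
  expect_equal(colnames(m$x), panel)
  expect_equal(sum(m$x["P1", ]), 2L)
  expect_equal(unname(m$x["P2", ]), c(1L, 0L, 1L, 1L, 0L))
  expect_equal(unname(colSums(m$x)), c(1L, 1L, 2L, 1L, 0L))
  ## empty patient set
  m0 <- build_matrix(r[0, ], panel)
  expect_equal(nrow(m0$x), 0L)
})

test_that("sex-stratified sampling is reproducible and caps at stratum size", {
  x <- matrix(rbinom(400, 1, 0.5), 200, 2,
              dimnames = list(sprintf("P%03d", 1:200), c("a", "b")))
  m <- comorbidity_matrix(x, rep(c("male", "female"), each = 100))
  s1 <- sample_by_sex(m, 30, seed = 9)
  s2 <- sample_by_sex(m, 30, seed = 9)
  expect_identical(rownames(s1$x), rownames(s2$x))
  expect_equal(as.integer(table(s1$sex)), c(30L, 30L))
  expect_false(identical(rownames(sample_by_sex(m, 30, seed = 10)$x),
                         rownames(s1$x)))
  ## both strata are short, so the warning fires once per sex
  expect_warning(expect_warning(s3 <- sample_by_sex(m, 150, seed = 1),
                                "taking all"), "taking all")
  expect_equal(nrow(s3$x), 200L)
})

test_that("the ETL pipeline reproduces a synthetic ledger exactly", {
  cfg <- load_panel_config()
  raw <- lapply(setNames(cfg$panel$code, cfg$panel$code),
                function(cd) cfg$rules$source[cfg$rules$new_code == cd])
  gen <- make_record_file(
    n_patients = 150, diseases = cfg$panel$code[1:8], raw_codes = raw[1:8],
    n_duplicates = 20, n_garbled = 12, n_nonchronic = 9,
    n_badage_patients = 5, n_singles = 10, n_recode_twins = 6,
    rare_codes = c("Q89.9", "Q90.0"), rare_carriers = 1, seed = 21)
  res <- run_etl(gen$records, rules = cfg$rules,
                 allowlist = c(cfg$panel$code, "Q89.9", "Q90.0"),
                 min_prevalence = 0.01)
  drops <- tapply(res$report$n_dropped, res$report$stage, sum)
  exp <- gen$ledger$expected_drops
  expect_equal(drops[names(exp)], exp, ignore_attr = TRUE)
  ## stage arithmetic balances and totals add up
  expect_equal(res$report$n_out, res$report$n_in - res$report$n_dropped)
  expect_equal(sum(res$report$n_dropped),
               res$report$n_in[1] - res$report$n_out[nrow(res$report)])
  ## matrix column sums equal the generator's per-disease carrier counts
  m <- build_matrix(res$records, gen$ledger$disease_codes)
  expect_equal(unname(colSums(m$x)), gen$ledger$disease_counts)
})
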