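# Carrier aggregation, odds ratios, Fisher p-values, age comparisons.

mini_classified <- function() {
  data.frame(
    variant_id = paste0("v", 1:6),
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    gene = c("CHEK2", "CHEK2", "ATM", "ATM", "CHEK2", "PALB2"),
    transcript_id = "T", chrom = "c", pos = 1:6, ref = "A", alt = "T",
    cdot = c("c.1100del", NA, NA, NA, NA, NA),
    category = "nonsense", splice_detail = NA, cds_anchor = 1L,
    is_ptv = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    iarc_class = c(5L, 5L, 5L, 5L, 5L, 5L),
    rationale = "ptv_class5", damaging_missense = FALSE, note = NA,
    stringsAsFactors = FALSE)
}

mini_patients <- function() {
  data.frame(
    patient_id = paste0("P", 1:6),
    aad_years = c(40, 45, 50, 55, 60, 35),
    bilateral = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    oc_family_history = FALSE,
    er = c("positive", "negative", "unknown", "positive", "negative",
           "positive"),
    pr = "positive", her2 = "negative", stringsAsFactors = FALSE)
}

test_that("carrier aggregation deduplicates within and across genes", {
  cls <- mini_classified(); pat <- mini_patients()
  # P1 has two CHEK2 PTVs: counts once
  expect_equal(aggregate_carriers(cls, pat, "CHEK2")$carriers, 2L)
  # ALL: P1 (CHEK2 x2), P2, P3 (ATM + CHEK2), not P4 (non-PTV)
  expect_equal(aggregate_carriers(cls, pat, "ALL", "ptv_only")$carriers, 3L)
  expect_equal(aggregate_carriers(cls, pat, "ALL", "class45")$carriers, 4L)
  # founder key
  expect_equal(aggregate_carriers(cls, pat, "CHEK2_c1100del")$carriers, 1L)
  # subgroup predicate restricts numerator and denominator
  bil <- aggregate_carriers(cls, pat, "ALL", "ptv_only",
                            subgroup = function(p) p$bilateral)
  expect_equal(bil$n, 2L)
  expect_equal(bil$carriers, 2L)
  # unknown patient is an error
  cls_bad <- cls; cls_bad$patient_id[1] <- "P99"
  expect_error(aggregate_carriers(cls_bad, pat, "CHEK2"), "P99")
})

test_that("subgroup carrier counts match a brute-force scan", {
  set.seed(123)
  n <- 400
  pat <- data.frame(patient_id = sprintf("Q%03d", 1:n),
                    aad_years = sample(25:70, n, TRUE),
                    bilateral = runif(n) < 0.2,
                    oc_family_history = runif(n) < 0.15,
                    er = sample(c("positive", "negative", "unknown"), n, TRUE),
                    pr = "unknown", her2 = "unknown",
                    stringsAsFactors = FALSE)
  carriers <- sample(pat$patient_id, 60)
  cls <- data.frame(variant_id = paste0("w", seq_along(carriers)),
                    patient_id = carriers, gene = "ATM",
                    transcript_id = "T", chrom = "c",
                    pos = seq_along(carriers), ref = "A", alt = "T",
                    cdot = NA, category = "nonsense", splice_detail = NA,
                    cds_anchor = 1L, is_ptv = TRUE, iarc_class = 5L,
                    rationale = "ptv_class5", damaging_missense = FALSE,
                    note = NA, stringsAsFactors = FALSE)
  got <- aggregate_carriers(cls, pat, "ATM",
                            subgroup = function(p) p$bilateral)
  # independent linear scan
  want <- 0L
  for (i in seq_len(n))
    if (pat$bilateral[i] && pat$patient_id[i] %in% carriers)
      want <- want + 1L
  expect_equal(got$carriers, want)
  expect_equal(got$n, sum(pat$bilateral))
})

test_that("odds ratio and Wald CI reproduce published comparisons", {
  o <- odds_ratio_2x2(71, 5589, 96, 27173)
  expect_equal(round_half_up(o$odds_ratio, 2), 3.63)
  expect_equal(round_half_up(o$ci_low, 2), 2.67)
  expect_equal(round_half_up(o$ci_high, 2), 4.94)
  o <- odds_ratio_2x2(5, 629, 12, 4960)
  expect_equal(round_half_up(o$odds_ratio, 2), 3.30)
  expect_equal(round_half_up(o$ci_low, 2), 1.16)
  expect_equal(round_half_up(o$ci_high, 2), 9.41)
  # identical proportions
  expect_equal(odds_ratio_2x2(10, 110, 10, 110)$odds_ratio, 1.0)
  # zero cell: undefined, no continuity correction
  o0 <- odds_ratio_2x2(0, 100, 5, 100)
  expect_false(o0$defined)
  expect_true(is.na(o0$odds_ratio))
  expect_error(odds_ratio_2x2(1, 0, 1, 10), "empty group")
})

test_that("odds ratio equals the logistic-regression oracle", {
  set.seed(11)
  for (i in 1:8) {
    a_n <- sample(50:400, 1); b_n <- sample(50:400, 1)
    a <- sample(1:(a_n - 1), 1); b <- sample(1:(b_n - 1), 1)
    mine <- odds_ratio_2x2(a, a_n, b, b_n)
    ref <- oracle_or_glm(a, a_n, b, b_n)
    expect_equal(mine$odds_ratio, ref$odds_ratio, tolerance = 1e-5)
    expect_equal(mine$ci_low, ref$ci_low, tolerance = 1e-4)
    expect_equal(mine$ci_high, ref$ci_high, tolerance = 1e-4)
  }
})

test_that("Fisher p matches brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_two_sided(2, 3, 4, 5), oracle_fisher(2, 3, 4, 5),
               tolerance = 1e-10)
  expect_lt(fisher_exact_two_sided(71, 5518, 96, 27077), 1e-4)
  expect_warning(p <- fisher_exact_two_sided(0, 0, 3, 4), "degenerate")
  expect_equal(p, 1)
  # symmetry under simultaneous row and column swap
  expect_equal(fisher_exact_two_sided(2, 7, 5, 3),
               fisher_exact_two_sided(3, 5, 7, 2))
})

test_that("age comparison handles ties, degeneracy and both modes", {
  x <- c(40, 45, 50)
  same <- aad_compare(x, x)
  expect_equal(same$p, 1.0)
  expect_equal(same$t, 0)
  one <- aad_compare(39, x)
  expect_equal(one$mean_a, 39)
  expect_true(is.na(one$p))
  m <- aad_compare(c(30, 35), c(50, 55, 60), mode = "vs_overall")
  expect_equal(m$mode, "vs_overall")
  expect_lt(m$p, 0.05)
})

test_that("young carrier ages are detected at published group sizes", {
  # carriers drawn around 40 vs a reference around 47 at n = 17 vs 5523:
  # the pooled t test rejects in the large majority of replicates
  set.seed(55)
  hits <- 0L
  for (r in 1:40) {
    carr <- rnorm(17, 40, 9)
    ref <- rnorm(5523, 46.7, 11)
    if (aad_compare(carr, ref)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.6)
})

test_that("burden scan orders rows and renders undefined cells", {
  cls <- mini_classified(); pat <- mini_patients()
  ctrl <- data.frame(
    cohort = rep("REF", 4), n_total = 1000L,
    gene = c("ATM", "CHEK2", "PALB2", "ALL"),
    carriers = c(5L, 8L, 0L, 13L), metric = "ptv", stringsAsFactors = FALSE)
  # the PALB2 row has an empty carrier column on both sides: the Fisher
  # margin degenerates (warned) and the OR is undefined
  expect_warning(bs <- burden_scan(cls, pat, ctrl, class_filter = "ptv_only"),
                 "degenerate margin")
  expect_equal(bs$gene, c("ATM", "CHEK2", "PALB2", "ALL"))
  # PALB2 has no qualifying case PTV and zero control carriers: undefined
  expect_false(bs$defined[bs$gene == "PALB2"])
  fmt <- format_burden_table(bs)
  expect_match(fmt$or_ci_p[fmt$gene == "PALB2"], "^n\\.a\\.")
  # carrier conservation: per-gene carrier sum >= ALL-gene carriers
  per_gene <- sum(bs$a_carriers[bs$gene != "ALL"])
  expect_gte(per_gene, bs$a_carriers[bs$gene == "ALL"])
})

test_that("stratified scan excludes unknown receptor status from denominators", {
  cls <- mini_classified(); pat <- mini_patients()
  st <- stratified_scan(cls, pat, strata = "er", class_filter = "class45",
                        genes = "ALL")
  expect_equal(st$a_n, sum(pat$er == "positive"))
  expect_equal(st$b_n, sum(pat$er == "negative"))
  stb <- stratified_scan(cls, pat, strata = "bilateral_vs_unilateral",
                         class_filter = "class45", genes = "ALL")
  expect_equal(stb$a_n + stb$b_n, nrow(pat))
})

test_that("VUS summary counts patients, distinct variants and singles", {
  cls <- data.frame(
    variant_id = paste0("u", 1:5),
    patient_id = c("P1", "P1", "P2", "P3", "P4"),
    gene = c("ATM", "CHEK2", "ATM", "ATM", "PALB2"),
    transcript_id = "T", chrom = "c",
    pos = c(10L, 20L, 10L, 10L, 30L), ref = "A", alt = "T", cdot = NA,
    category = "missense", splice_detail = NA, cds_anchor = 1L,
    is_ptv = FALSE, iarc_class = c(3L, 3L, 3L, 3L, 5L),
    rationale = "default_vus", damaging_missense = FALSE, note = NA,
    stringsAsFactors = FALSE)
  s <- summarize_vus(cls, mini_patients())
  expect_equal(s$patients_with_vus, 3L)       # P1, P2, P3 (P4 is class 5)
  expect_equal(s$distinct_vus, 2L)            # ATM:10 shared, CHEK2:20
  expect_equal(s$fraction_single_vus, 2 / 3)  # P2, P3 single; P1 double
  expect_equal(s$per_gene_vus_patient_counts$ATM, 3L)
})
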