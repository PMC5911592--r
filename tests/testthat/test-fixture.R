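# The deterministic pseudo-cohort must hit every published margin exactly.

test_that("fixture reproduces the per-gene carrier counts", {
  fx <- fixture_from_tables()
  genes <- c("ATM", "CDH1", "CHEK2", "NBN", "PALB2", "RAD51C", "RAD51D",
             "TP53")
  del <- c(81, 8, 138, 12, 68, 11, 6, 17)
  ptv <- c(71, 7, 103, 12, 64, 9, 5, 3)
  for (i in seq_along(genes)) {
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, genes[i],
                                    "class45")$carriers, del[i],
                 info = genes[i])
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, genes[i],
                                    "ptv_only")$carriers, ptv[i],
                 info = genes[i])
  }
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes,
                                  "CHEK2_c1100del", "ptv_only")$carriers, 79L)
  # dual-gene carriers collapse in the any-gene rows
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, "ALL",
                                  "ptv_only")$carriers, 272L)
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, "ALL",
                                  "class45")$carriers, 339L)
  # carrier conservation: equality fails exactly because of the two duals
  expect_equal(sum(ptv) - 272L, 2L)
})

test_that("fixture reproduces the phenotype margins", {
  fx <- fixture_from_tables()
  ph <- fx$phenotypes
  expect_equal(nrow(ph), 5589L)
  expect_equal(sum(ph$bilateral), 629L)
  expect_equal(sum(ph$oc_family_history), 934L)
  expect_equal(sum(ph$er != "unknown"), 3104L)
  expect_equal(sum(ph$er == "positive"), 2355L)
  expect_equal(sum(ph$pr == "positive"), 2188L)
  expect_equal(sum(ph$her2 == "positive"), 657L)
  tnbc <- ph$er == "negative" & ph$pr == "negative" & ph$her2 == "negative"
  expect_equal(sum(tnbc), 482L)
  expect_equal(sum(is.na(ph$aad_years)), 49L)
  expect_equal(mean(ph$aad_years, na.rm = TRUE), 46.7, tolerance = 1e-3)
})

test_that("fixture reproduces the bilateral and receptor sub-margins", {
  fx <- fixture_from_tables()
  genes <- c("ATM", "CDH1", "CHEK2", "NBN", "PALB2", "RAD51C", "RAD51D",
             "TP53")
  bil <- c(10, 1, 20, 0, 14, 1, 1, 5)
  sa <- c(47, 7, 90, 5, 40, 4, 3, 10)
  erp <- c(43, 6, 76, 4, 31, 3, 1, 7)
  h2p <- c(7, 1, 34, 0, 4, 1, 0, 5)
  tnb <- c(2, 1, 4, 1, 8, 1, 2, 1)
  known <- function(p) p$er != "unknown"
  tnbc <- function(p) p$er == "negative" & p$pr == "negative" &
    p$her2 == "negative"
  for (i in seq_along(genes)) {
    g <- genes[i]
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, g,
                                    "class45",
                                    subgroup = function(p) p$bilateral
                                    )$carriers, bil[i], info = g)
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, g,
                                    "class45", subgroup = known)$carriers,
                 sa[i], info = g)
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, g,
                                    "class45",
                                    subgroup = function(p)
                                      p$er == "positive")$carriers,
                 erp[i], info = g)
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, g,
                                    "class45",
                                    subgroup = function(p)
                                      p$her2 == "positive")$carriers,
                 h2p[i], info = g)
    expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, g,
                                    "class45", subgroup = tnbc)$carriers,
                 tnb[i], info = g)
  }
  # founder sub-margins
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes,
                                  "CHEK2_c1100del", "class45",
                                  subgroup = function(p) p$bilateral
                                  )$carriers, 16L)
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes,
                                  "CHEK2_c1100del", "class45",
                                  subgroup = known)$carriers, 52L)
  # distinct carriers with known receptor status (dual carriers excluded)
  expect_equal(aggregate_carriers(fx$classified, fx$phenotypes, "ALL",
                                  "class45", subgroup = known)$carriers,
               206L)
})

test_that("fixture carrier ages match the published per-gene means", {
  fx <- fixture_from_tables()
  means <- c(ATM = 45.0, CHEK2 = 47.1, PALB2 = 45.8, TP53 = 39.7)
  for (g in names(means)) {
    qual <- fx$classified$iarc_class >= 4 & fx$classified$gene == g
    ids <- unique(fx$classified$patient_id[qual])
    ages <- fx$phenotypes$aad_years[fx$phenotypes$patient_id %in% ids]
    expect_equal(mean(ages, na.rm = TRUE), means[[g]], tolerance = 0.02,
                 info = g)
  }
  # young TP53 carriers are detected against the overall sample
  sc <- aad_scan(fx$classified, fx$phenotypes, mode = "vs_overall",
                 genes = "TP53")
  expect_lt(sc$p_t, 0.05)
  expect_equal(round_half_up(sc$mean_carriers, 1), 39.7)
})

test_that("fixture damaging-missense prevalences match the published ones", {
  fx <- fixture_from_tables()
  mb <- missense_burden(fx$classified, fx$phenotypes, fx$controls)
  chek2 <- mb[mb$gene == "CHEK2", ]
  tp53 <- mb[mb$gene == "TP53", ]
  expect_equal(round_half_up(chek2$a_pct, 2), 1.43)
  expect_equal(round_half_up(chek2$b_pct, 2), 0.71)
  expect_lt(chek2$p_fisher, 1e-4)
  expect_equal(round_half_up(tp53$a_pct, 2), 0.41)
  expect_equal(round_half_up(tp53$b_pct, 2), 0.18)
  expect_lt(tp53$p_fisher, 0.01)
})

test_that("report formatting matches the published table style", {
  expect_equal(round_half_up(2.945, 2), 2.95)
  expect_equal(round_half_up(0.125, 2), 0.13)   # half away from zero
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(format_p(3.2e-5), "<0.0001")
  expect_equal(format_p(0.363), "0.3630")
  fx <- fixture_from_tables()
  st <- stratified_scan(fx$classified, fx$phenotypes,
                        strata = "bilateral_vs_unilateral")
  fmt <- format_burden_table(st)
  expect_equal(fmt$or_ci_p[fmt$gene == "PALB2"], "2.07 (1.14-3.75, 0.0201)")
  expect_equal(fmt$or_ci_p[fmt$gene == "NBN"], "n.a. (n.a., 0.3830)")
  expect_equal(fmt$group_a[fmt$gene == "TP53"], "5 (0.79)")
  # JSON twin carries machine precision plus a BH column
  f <- tempfile(fileext = ".json")
  out <- write_report(st, path_json = f)
  expect_true("p_bh" %in% names(out))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$odds_ratio[back$gene == "PALB2"],
               st$odds_ratio[st$gene == "PALB2"], tolerance = 1e-9)
})
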