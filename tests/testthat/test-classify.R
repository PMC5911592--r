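# Consequence calling and five-tier class assignment.

test_that("coding SNVs are classified by codon translation", {
  tx <- toy_transcript()
  # codon 17 TGG -> TGA via third-base G>A at cds 51 (genomic 181)
  cons <- call_consequence(toy_variant(181, "G", "A"), tx)
  expect_equal(cons$category, "nonsense")
  expect_equal(cons$cds_anchor, 49L)
  # same codon TGG -> TGC: missense
  expect_equal(call_consequence(toy_variant(181, "G", "C"), tx)$category,
               "missense")
  # filler GCT -> GCA (third base of codon 2, cds 6, genomic 136): synonymous
  expect_equal(call_consequence(toy_variant(136, "T", "A"), tx)$category,
               "synonymous")
  # reference mismatch is refused with a position
  expect_error(call_consequence(toy_variant(181, "C", "A"), tx),
               "mismatch.*181")
})

test_that("indels are frameshift or in-frame by length rule", {
  tx <- toy_transcript()
  # delete cds 120 (genomic 350): anchor at the deleted base
  g119 <- cds_to_genomic(tx, 119L)
  cons <- call_consequence(
    toy_variant(g119, substr(tx$cds_sequence, 119, 120), "G"), tx)
  expect_equal(cons$category, "frameshift")
  expect_equal(cons$cds_anchor, 120L)
  # 3-bp deletion: in-frame
  cons3 <- call_consequence(
    toy_variant(g119, substr(tx$cds_sequence, 119, 122), "G"), tx)
  expect_equal(cons3$category, "inframe_indel")
  # 1-bp insertion between cds 119 and 120
  consi <- call_consequence(toy_variant(g119, "G", "GT"), tx)
  expect_equal(consi$category, "frameshift")
  expect_equal(consi$cds_anchor, 120L)
})

test_that("invariant splice sites and donor-last bases are essential splice", {
  tx <- toy_transcript()
  d1 <- call_consequence(toy_variant(201, "G", "T"), tx)
  expect_equal(d1$category, "essential_splice")
  expect_equal(d1$splice_detail, "donor_plus1")
  d2 <- call_consequence(toy_variant(202, "G", "T"), tx)
  expect_equal(d2$splice_detail, "donor_plus2")
  a2 <- call_consequence(toy_variant(299, "G", "T"), tx)
  expect_equal(a2$splice_detail, "acceptor_minus2")
  # last exonic base of exon 1 (genomic 200, coding)
  lb <- call_consequence(toy_variant(200, "T", "C"), tx)
  expect_equal(lb$category, "essential_splice")
  expect_equal(lb$splice_detail, "exon_last_base")
  expect_true(is_ptv(lb))
  expect_true(is_ptv(d1))
  expect_false(is_ptv(list(category = "missense")))
})

test_that("SNVs fall back to HGVS p. annotation without a sequence", {
  tx <- toy_transcript()
  tx$cds_sequence <- NULL
  v <- toy_variant(181, "G", "A", hgvs_p = "p.Trp17Ter")
  expect_equal(call_consequence(v, tx)$category, "nonsense")
  v2 <- toy_variant(181, "G", "C", hgvs_p = "p.Trp17Cys")
  expect_equal(call_consequence(v2, tx)$category, "missense")
  v3 <- toy_variant(181, "G", "C")
  expect_equal(call_consequence(v3, tx)$category, "other")
})

test_that("class assignment follows the documented precedence", {
  tx <- toy_transcript()     # zone [216, 300], domain aa 60-70 (cds 178-210)
  nonsense_at <- function(codon) {
    g <- cds_to_genomic(tx, 3L * (codon - 1L) + 3L)  # TGG codons: G>A
    list(v = toy_variant(g, "G", "A"),
         cons = call_consequence(toy_variant(g, "G", "A"), tx))
  }
  # early nonsense (codon 17, anchor 49): class 5
  x <- nonsense_at(17)
  cl <- assign_class(x$v, x$cons, tx)
  expect_equal(cl$iarc_class, 5L)
  expect_equal(cl$rationale, "ptv_class5")
  # in-zone nonsense (codon 91, anchor 271), domain upstream: VUS
  x <- nonsense_at(91)
  cl <- assign_class(x$v, x$cons, tx)
  expect_equal(cl$iarc_class, 3L)
  expect_equal(cl$rationale, "nmd_escape_vus")
  # in-zone nonsense with a domain in the truncated tail: rescued to 5
  tx2 <- toy_transcript(domains = data.frame(name = "CT", aa_start = 75,
                                             aa_end = 80))  # cds 223-240
  x <- nonsense_at(75)  # anchor 223, zone [216,300]
  cl <- assign_class(x$v, call_consequence(x$v, tx2), tx2)
  expect_equal(cl$iarc_class, 5L)
  expect_true(all(c("ptv_class5", "domain_rescue") %in% cl$rationale))
  # common variants are benign even when nonsense
  x <- nonsense_at(17)
  x$v$mafs <- c(exac = 0.02)
  cl <- assign_class(x$v, x$cons, tx)
  expect_equal(cl$iarc_class, 1L)
  expect_equal(cl$rationale, "maf_benign")
  # override forces the class
  ov <- data.frame(gene = "TOY", key = "TOY:c.470C>T", forced_class = 3L,
                   reason = "population-specific low-risk allele")
  x <- nonsense_at(17)
  x$v$cdot <- "c.470C>T"
  cl <- assign_class(x$v, x$cons, tx, overrides = ov)
  expect_equal(cl$iarc_class, 3L)
  expect_equal(cl$rationale, "override")
  # everything else is VUS
  mv <- toy_variant(181, "G", "C")
  cl <- assign_class(mv, call_consequence(mv, tx), tx)
  expect_equal(cl$iarc_class, 3L)
  expect_true("missense_vus" %in% cl$rationale)
})

test_that("essential splice variants demote only at the final junction", {
  tx <- toy_transcript()
  # intron 1 donor +1: upstream junction, always class 5
  v1 <- toy_variant(201, "G", "T")
  cl1 <- assign_class(v1, call_consequence(v1, tx), tx)
  expect_equal(cl1$iarc_class, 5L)
  # final intron donor +1 (genomic 501): evaluated at last exon start
  # (cds 271, inside zone [216,300]); no domain downstream -> VUS, flagged
  v2 <- toy_variant(501, "G", "T")
  cl2 <- assign_class(v2, call_consequence(v2, tx), tx)
  expect_equal(cl2$iarc_class, 3L)
  expect_match(cl2$note, "final_intron")
  # with a C-terminal domain the same variant is rescued
  tx2 <- toy_transcript(domains = data.frame(name = "CT", aa_start = 92,
                                             aa_end = 97))
  cl3 <- assign_class(v2, call_consequence(v2, tx2), tx2)
  expect_equal(cl3$iarc_class, 5L)
})

test_that("damaging-missense flag needs rarity and predictor consensus", {
  tx <- toy_transcript()
  cons <- call_consequence(toy_variant(181, "G", "C"), tx)
  mk <- function(maf, p1, p2)
    toy_variant(181, "G", "C", mafs = c(exac = maf),
                preds = c(pred1 = p1, pred2 = p2))
  expect_true(flag_damaging_missense(mk(0.0005, "damaging", "damaging"),
                                     cons))
  expect_false(flag_damaging_missense(mk(0.0005, "damaging", "tolerated"),
                                      cons))
  expect_false(flag_damaging_missense(mk(0.002, "damaging", "damaging"),
                                      cons))
  # absent MAF counts as rare
  expect_true(flag_damaging_missense(mk(NA_real_, "damaging", "damaging"),
                                     cons))
  # non-missense never flagged
  nons <- call_consequence(toy_variant(181, "G", "A"), tx)
  expect_false(flag_damaging_missense(mk(0.0005, "damaging", "damaging"),
                                      nons))
})

test_that("no variant at or above the MAF threshold is ever class 4/5", {
  set.seed(202)
  tx <- make_transcript("PREC", 4, 900, seed = 31)
  ptvs <- simulate_ptvs(tx, 60, zone_fraction = 0.3, seed = 32)
  for (k in seq_len(nrow(ptvs))) {
    v <- list(chrom = tx$chrom, pos = ptvs$pos[k], ref = ptvs$ref[k],
              alt = ptvs$alt[k], gene_symbol = "PREC",
              mafs = c(exac = stats::runif(1, 0.01, 0.5)))
    cl <- assign_class(v, call_consequence(v, tx), tx)
    expect_equal(cl$iarc_class, 1L)
  }
})

test_that("enlarging a domain never turns a class-5 PTV into VUS", {
  set.seed(77)
  tx_base <- make_transcript("MONO", 3, 600, seed = 41,
                             domain_layout = NULL)
  ptvs <- simulate_ptvs(tx_base, 40, zone_fraction = 0.5, seed = 42)
  pl <- tx_base$protein_length
  dom_small <- data.frame(name = "D", aa_start = pl - 20L, aa_end = pl - 10L)
  dom_large <- data.frame(name = "D", aa_start = pl - 60L, aa_end = pl - 5L)
  tx_s <- tx_base; tx_s$domains <- dom_small
  tx_l <- tx_base; tx_l$domains <- dom_large
  for (k in seq_len(nrow(ptvs))) {
    v <- list(chrom = tx_base$chrom, pos = ptvs$pos[k], ref = ptvs$ref[k],
              alt = ptvs$alt[k], gene_symbol = "MONO", mafs = NULL)
    cl_s <- assign_class(v, call_consequence(v, tx_s), tx_s)
    cl_l <- assign_class(v, call_consequence(v, tx_l), tx_l)
    if (cl_s$iarc_class == 5L) expect_equal(cl_l$iarc_class, 5L)
  }
})

test_that("classification is deterministic and skips unknown transcripts", {
  tx <- toy_transcript()
  vars <- data.frame(
    variant_id = c("a", "b", "c"), patient_id = c("P1", "P1", "P2"),
    chrom = "chrT", pos = c(181L, 201L, 181L), ref = "G",
    alt = c("A", "T", "C"), gene = "TOY",
    transcript_id = c("TOY_TX", "TOY_TX", "NOPE"),
    maf_exac = c(NA, NA, NA), stringsAsFactors = FALSE)
  expect_warning(res <- classify_variants(vars, list(TOY_TX = tx)),
                 "unknown transcript")
  expect_equal(res$summary$n_skipped, 1L)
  expect_equal(nrow(res$classified), 2L)
  res2 <- suppressWarnings(classify_variants(vars, list(TOY_TX = tx)))
  expect_identical(res$classified, res2$classified)
})
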