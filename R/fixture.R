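# Deterministic regression fixture: a pseudo-cohort whose per-gene and
# per-stratum carrier counts equal the published prevalence tables exactly
# (including the two dual-gene carriers, the zero bilateral NBN cell, and
# the CHEK2 c.1100del founder sub-margins), so the whole burden pipeline can
# be regression-tested against the printed odds ratios. All patient-level
# detail beyond the printed margins (which patient holds which flag, exact
# ages) is synthetic.

# deterministic symmetric age grid with the requested mean
ages_grid <- function(n, mean, sd = 9, lo = 17, hi = 92) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(mean)
  z <- stats::qnorm((seq_len(n) - 0.5) / n)
  pmin(pmax(mean + sd * z, lo), hi)
}

# nested receptor assignment hitting four margins plus the all-negative cell
assign_receptors <- function(s, e, p, h, t) {
  stopifnot(e <= s - t, p <= s - t, h >= (s - t) - max(e, p))
  er <- rep("negative", s); pr <- rep("negative", s)
  her2 <- rep("negative", s)
  if (e > 0) er[seq_len(e)] <- "positive"
  if (p > 0) pr[seq_len(p)] <- "positive"
  cover <- seq_len(s - t)
  cover <- cover[cover > max(e, p, 0L)]
  rest <- h - length(cover)
  hpos <- c(cover, if (rest > 0) seq_len(rest))
  if (length(hpos)) her2[hpos] <- "positive"
  data.frame(er = er, pr = pr, her2 = her2, stringsAsFactors = FALSE)
}

#' Deterministic pseudo-cohort matching the published prevalence tables
#'
#' Emits a classified-variant table, a phenotype table and control carrier
#' counts whose per-gene and per-stratum margins equal the published counts
#' exactly: deleterious-variant and PTV carriers per gene, the CHEK2
#' c.1100del founder sub-counts, bilateral/unilateral splits, the
#' receptor-status subgroup (including the TNBC cell and the founder
#' sub-margins), the two dual-gene carriers (unilateral, receptor status
#' unavailable), per-gene carrier mean ages at first diagnosis, and the
#' damaging-missense carrier counts for CHEK2 and TP53. This is the
#' regression fixture behind the quantitative acceptance checks; it is not a
#' draw from the generative model.
#'
#' @return List with `classified`, `phenotypes`, `controls`.
#' @export
fixture_from_tables <- function() {
  genes <- c("ATM", "CDH1", "CHEK2", "NBN", "PALB2", "RAD51C", "RAD51D",
             "TP53")
  del <- c(81, 8, 138, 12, 68, 11, 6, 17)       # class 4/5 carriers
  ptv <- c(71, 7, 103, 12, 64, 9, 5, 3)         # deleterious PTV carriers
  bil <- c(10, 1, 20, 0, 14, 1, 1, 5)           # bilateral carriers
  sa <- c(47, 7, 90, 5, 40, 4, 3, 10)           # receptor status available
  erp <- c(43, 6, 76, 4, 31, 3, 1, 7)
  prp <- c(39, 4, 70, 3, 29, 2, 1, 8)
  h2p <- c(7, 1, 34, 0, 4, 1, 0, 5)
  tnb <- c(2, 1, 4, 1, 8, 1, 2, 1)
  aad_mean <- c(45.0, 45.1, 47.1, 46.3, 45.8, 44.9, 46.8, 39.7)
  n_cases <- 5589L

  pid <- sprintf("P%04d", seq_len(n_cases))

  # --- patient allocation: gene blocks; two dual carriers fold back ---
  # new-patient blocks per gene (dual variants reuse earlier patients)
  new_n <- c(81, 8, 137, 12, 68, 10, 6, 17)
  block_end <- cumsum(new_n)
  block_start <- c(1, utils::head(block_end, -1) + 1)
  dual_atm_chek2 <- 81L    # ATM carrier also holding the CHEK2 dual variant
  dual_nbn_rad51c <- 238L  # NBN carrier also holding the RAD51C dual variant

  # per-gene variant -> patient index
  var_patient <- list()
  for (i in seq_along(genes)) {
    v <- seq(block_start[i], block_end[i])
    if (genes[i] == "CHEK2") v <- c(v, dual_atm_chek2)
    if (genes[i] == "RAD51C") v <- c(v, dual_nbn_rad51c)
    var_patient[[genes[i]]] <- v
  }
  stopifnot(vapply(var_patient, length, integer(1)) == del)

  # per-gene variant-index subsets
  ptv_sets <- list(
    ATM = c(1:70, 81), CDH1 = 1:7, CHEK2 = c(1:102, 138), NBN = 1:12,
    PALB2 = 1:64, RAD51C = c(1:8, 11), RAD51D = 1:5, TP53 = 1:3)
  founder_set <- 1:79                        # CHEK2 c.1100del variants
  bil_sets <- list(
    ATM = 1:10, CDH1 = 1, CHEK2 = c(1:16, 80:83), NBN = integer(0),
    PALB2 = 1:14, RAD51C = 1, RAD51D = 1, TP53 = 1:5)
  sa_sets <- list(
    ATM = 1:47, CDH1 = 1:7, CHEK2 = c(1:52, 80:117), NBN = 1:5,
    PALB2 = 1:40, RAD51C = 1:4, RAD51D = 1:3, TP53 = 1:10)

  # --- classified variants ---
  rows <- list()
  vn <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    for (j in seq_len(del[i])) {
      vn <- vn + 1L
      is_founder <- g == "CHEK2" && j %in% founder_set
      is_p <- j %in% ptv_sets[[g]]
      rows[[vn]] <- data.frame(
        variant_id = sprintf("fx%04d", vn),
        patient_id = pid[var_patient[[g]][j]],
        gene = g, transcript_id = paste0("SYN_", g),
        chrom = paste0("chr_", g), pos = 10000L + vn,
        ref = "A", alt = "T",
        cdot = if (is_founder) "c.1100del" else NA_character_,
        category = if (is_founder) "frameshift"
          else if (is_p) "nonsense" else "missense",
        splice_detail = NA_character_, cds_anchor = 90L,
        is_ptv = is_p, iarc_class = 5L,
        rationale = if (is_p) "ptv_class5" else "override",
        damaging_missense = FALSE, note = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  # damaging-missense carriers (prevalence rows; distinct patients)
  dm_spec <- list(CHEK2 = list(n = 80L, start = 4500L),
                  TP53 = list(n = 23L, start = 4600L))
  for (g in names(dm_spec)) {
    for (k in seq_len(dm_spec[[g]]$n)) {
      vn <- vn + 1L
      rows[[vn]] <- data.frame(
        variant_id = sprintf("fx%04d", vn),
        patient_id = pid[dm_spec[[g]]$start + k - 1L],
        gene = g, transcript_id = paste0("SYN_", g),
        chrom = paste0("chr_", g), pos = 10000L + vn,
        ref = "G", alt = "C", cdot = NA_character_,
        category = "missense", splice_detail = NA_character_,
        cds_anchor = 120L, is_ptv = FALSE, iarc_class = 3L,
        rationale = "default_vus;missense_vus;damaging_missense_flag",
        damaging_missense = TRUE, note = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  classified <- do.call(rbind, rows)

  # --- phenotypes ---
  bilateral <- rep(FALSE, n_cases)
  for (i in seq_along(genes))
    bilateral[var_patient[[genes[i]]][bil_sets[[genes[i]]]]] <- TRUE
  bilateral[340:916] <- TRUE                 # 577 non-carrier bilateral
  stopifnot(sum(bilateral) == 629L)

  er <- rep("unknown", n_cases); pr <- er; her2 <- er
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (g == "CHEK2") next
    idx <- var_patient[[g]][sa_sets[[g]]]
    rs <- assign_receptors(sa[i], erp[i], prp[i], h2p[i], tnb[i])
    er[idx] <- rs$er; pr[idx] <- rs$pr; her2[idx] <- rs$her2
  }
  # CHEK2: founder and non-founder sub-margins assigned separately
  idx_f <- var_patient$CHEK2[1:52]
  rs_f <- assign_receptors(52, 43, 42, 20, 3)
  er[idx_f] <- rs_f$er; pr[idx_f] <- rs_f$pr; her2[idx_f] <- rs_f$her2
  idx_nf <- var_patient$CHEK2[80:117]
  rs_nf <- assign_receptors(38, 76 - 43, 70 - 42, 34 - 20, 4 - 3)
  er[idx_nf] <- rs_nf$er; pr[idx_nf] <- rs_nf$pr; her2[idx_nf] <- rs_nf$her2
  # non-carrier receptor subgroup
  nc_idx <- 917:3814
  rs_nc <- assign_receptors(2898, 2355 - 171, 2188 - 156, 657 - 52,
                            482 - 20)
  er[nc_idx] <- rs_nc$er; pr[nc_idx] <- rs_nc$pr; her2[nc_idx] <- rs_nc$her2

  oc_fh <- rep(FALSE, n_cases)
  oc_fh[4000:4933] <- TRUE                   # 934 with OC family history

  aad <- rep(NA_real_, n_cases)
  for (i in seq_along(genes)) {
    blk <- seq(block_start[i], block_end[i])
    aad[blk] <- ages_grid(length(blk), aad_mean[i], sd = 9)
  }
  carrier_sum <- sum(aad[1:339])
  nc_age_idx <- setdiff(340:5540, integer(0))
  m_nc <- (46.7 * 5540 - carrier_sum) / length(nc_age_idx)
  aad[nc_age_idx] <- ages_grid(length(nc_age_idx), m_nc, sd = 11)
  # patients 5541..5589 remain NA (age unavailable)

  phenotypes <- data.frame(
    patient_id = pid, aad_years = aad, bilateral = bilateral,
    oc_family_history = oc_fh, er = er, pr = pr, her2 = her2,
    stringsAsFactors = FALSE)

  # --- control carrier counts ---
  ctrl <- function(cohort, n_total, carriers)
    data.frame(cohort = cohort, n_total = n_total,
               gene = c(genes, "CHEK2_c1100del", "ALL"),
               carriers = carriers, metric = "ptv",
               stringsAsFactors = FALSE)
  controls <- rbind(
    ctrl("ExAC", 27173L, c(96, 2, 172, 42, 33, 34, 8, 2, 127, 389)),
    ctrl("FLOSSIES", 7325L, c(14, 0, 28, 14, 7, 2, 2, 0, 22, 67)),
    ctrl("GMC", 2189L, c(9, 0, 11, 9, 2, 2, 0, 0, 8, 33)),
    data.frame(cohort = "ExAC", n_total = 27173L,
               gene = c("CHEK2", "TP53"), carriers = c(193L, 49L),
               metric = "damaging_missense", stringsAsFactors = FALSE))

  list(classified = classified, phenotypes = phenotypes,
       controls = controls)
}
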