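# Gene-level carrier aggregation and case-control / case-case statistics:
# Wald odds ratios with 95% confidence intervals (the closed form of a
# univariate logistic regression on a 2x2 table), two-sided Fisher exact
# tests, and Student t comparisons of age at first diagnosis.

CLASS_FILTERS <- c("ptv_only", "class45", "damaging_missense")

qualifying_rows <- function(classified, class_filter) {
  class_filter <- match.arg(class_filter, CLASS_FILTERS)
  switch(class_filter,
    ptv_only = classified$is_ptv & classified$iarc_class >= 4L,
    class45 = classified$iarc_class >= 4L,
    damaging_missense = classified$damaging_missense)
}

gene_rows <- function(classified, gene) {
  if (gene == "ALL") rep(TRUE, nrow(classified))
  else if (gene == "CHEK2_c1100del")
    classified$gene == "CHEK2" & !is.na(classified$cdot) &
      classified$cdot == "c.1100del"
  else classified$gene == gene
}

#' Count carriers of qualifying variants in a gene
#'
#' A patient with several qualifying variants in the gene counts once; with
#' `gene = "ALL"` a patient with qualifying variants in several genes still
#' counts once. The special key `"CHEK2_c1100del"` counts carriers of the
#' CHEK2 c.1100del founder allele.
#'
#' @param classified Classified-variant data.frame (see
#'   [classify_variants()]); rows must carry `patient_id`.
#' @param patients Phenotype data.frame with a `patient_id` column.
#' @param gene Gene symbol, `"ALL"`, or `"CHEK2_c1100del"`.
#' @param class_filter `"ptv_only"` (deleterious PTVs), `"class45"` (all
#'   class 4/5) or `"damaging_missense"`.
#' @param subgroup Optional predicate: a function of the patient table
#'   returning a logical vector, or a logical vector itself.
#' @return List with `carriers` and `n` (subgroup size).
#' @export
aggregate_carriers <- function(classified, patients, gene,
                               class_filter = "ptv_only", subgroup = NULL) {
  keep <- if (is.null(subgroup)) rep(TRUE, nrow(patients))
    else if (is.function(subgroup)) subgroup(patients)
    else as.logical(subgroup)
  keep[is.na(keep)] <- FALSE
  qual <- qualifying_rows(classified, class_filter) & gene_rows(classified, gene)
  pid <- classified$patient_id[qual]
  unknown <- setdiff(unique(pid), patients$patient_id)
  if (length(unknown))
    stop("classified variants reference unknown patient_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  in_group <- pid %in% patients$patient_id[keep]
  list(carriers = length(unique(pid[in_group])), n = sum(keep))
}

#' Odds ratio and Wald confidence interval from carrier counts
#'
#' OR = `[a/(a_n-a)] / [b/(b_n-b)]`; the 95% CI is
#' `exp(log(OR) +- z * sqrt(1/a + 1/(a_n-a) + 1/b + 1/(b_n-b)))`. This is
#' exactly the exponentiated slope (and Wald interval) of a single-covariate
#' binary-outcome logistic regression on the same 2x2 table. Any zero cell
#' makes the estimate undefined (reported as such; no continuity
#' correction).
#'
#' @param a_carriers,a_n Carriers and total in group A (e.g. cases).
#' @param b_carriers,b_n Carriers and total in group B (e.g. controls).
#' @param z Normal quantile for the interval, default `qnorm(0.975)`.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `defined`.
#' @export
odds_ratio_2x2 <- function(a_carriers, a_n, b_carriers, b_n,
                           z = stats::qnorm(0.975)) {
  if (a_n == 0 || b_n == 0) stop("empty group in 2x2 table")
  if (a_carriers > a_n || b_carriers > b_n)
    stop("carriers exceed group size")
  cells <- c(a_carriers, a_n - a_carriers, b_carriers, b_n - b_carriers)
  if (any(cells == 0))
    return(list(odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, defined = FALSE))
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       defined = TRUE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum, over the
#' hypergeometric distribution with fixed margins, of the probabilities of
#' all tables no more probable than the observed one. A degenerate margin
#' returns p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts (`a` `b` first row, `c` `d` second row).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin in 2x2 table; p = 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Compare age at first diagnosis between carriers and a reference group
#'
#' Pooled-variance two-sample Student t test (two-sided) by default; Welch
#' behind `var_equal = FALSE`. `mode` records whether the reference list is
#' the non-carrier remainder (`"vs_rest"`) or the overall sample including
#' carriers (`"vs_overall"`); the caller builds the reference accordingly
#' (see [aad_scan()]).
#'
#' @param carrier_ages,reference_ages Numeric vectors of ages (years),
#'   missing values removed beforehand.
#' @param mode `"vs_rest"` or `"vs_overall"` (metadata, echoed in output).
#' @param var_equal Pooled variance (TRUE, Student) or Welch (FALSE).
#' @return List with `mean_a`, `mean_b`, `n_a`, `n_b`, `t`, `p`, `mode`.
#' @export
aad_compare <- function(carrier_ages, reference_ages,
                        mode = c("vs_rest", "vs_overall"), var_equal = TRUE) {
  mode <- match.arg(mode)
  carrier_ages <- carrier_ages[!is.na(carrier_ages)]
  reference_ages <- reference_ages[!is.na(reference_ages)]
  if (length(carrier_ages) == 0L || length(reference_ages) == 0L)
    stop("empty age list")
  out <- list(mean_a = mean(carrier_ages), mean_b = mean(reference_ages),
              n_a = length(carrier_ages), n_b = length(reference_ages),
              t = NA_real_, p = NA_real_, mode = mode)
  if (length(carrier_ages) < 2L || length(reference_ages) < 2L)
    return(out)
  tt <- stats::t.test(carrier_ages, reference_ages, var.equal = var_equal)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

burden_row <- function(gene, label_a, label_b, a, a_n, b, b_n) {
  orr <- odds_ratio_2x2(a, a_n, b, b_n)
  p <- fisher_exact_two_sided(a, a_n - a, b, b_n - b)
  data.frame(gene = gene, group_a = label_a, group_b = label_b,
             a_carriers = a, a_n = a_n, a_pct = 100 * a / a_n,
             b_carriers = b, b_n = b_n, b_pct = 100 * b / b_n,
             odds_ratio = orr$odds_ratio, ci_low = orr$ci_low,
             ci_high = orr$ci_high, p_fisher = p, defined = orr$defined,
             stringsAsFactors = FALSE)
}

#' Case-control carrier-burden scan across genes and control cohorts
#'
#' One comparison per gene per control cohort, plus the special rows for the
#' CHEK2 c.1100del founder allele and the any-gene carrier count (`ALL`)
#' when the control table provides them. Rows are ordered gene
#' alphabetically (special keys last), cohorts in input order.
#'
#' @param classified Classified-variant data.frame with `patient_id`.
#' @param patients Phenotype data.frame (cases).
#' @param controls Control-count data.frame with columns `cohort`, `n_total`,
#'   `gene`, `carriers` and optionally `metric` (`"ptv"`,
#'   `"class45"` or `"damaging_missense"`; default `"ptv"`).
#' @param genes Genes to test; default all genes in the control table.
#' @param class_filter Carrier definition on the case side (see
#'   [aggregate_carriers()]).
#' @param metric Which control rows to compare against; defaults to
#'   `"damaging_missense"` when `class_filter` is, else `"ptv"`.
#' @return data.frame of burden results (one row per gene x cohort).
#' @export
burden_scan <- function(classified, patients, controls, genes = NULL,
                        class_filter = "ptv_only", metric = NULL) {
  controls <- as.data.frame(controls)
  if (!"metric" %in% names(controls)) controls$metric <- "ptv"
  if (is.null(metric))
    metric <- if (identical(class_filter, "damaging_missense"))
      "damaging_missense" else "ptv"
  controls <- controls[controls$metric == metric, , drop = FALSE]
  if (nrow(controls) == 0L) stop("no control rows for metric '", metric, "'")
  cohorts <- unique(controls$cohort)
  all_genes <- unique(controls$gene)
  if (is.null(genes)) {
    genes <- sort(setdiff(all_genes, c("ALL", "CHEK2_c1100del")))
    genes <- c(genes, intersect(c("CHEK2_c1100del", "ALL"), all_genes))
  }
  a_n <- nrow(patients)
  out <- list()
  for (g in genes) {
    a <- aggregate_carriers(classified, patients, g, class_filter)$carriers
    for (ch in cohorts) {
      hit <- controls$gene == g & controls$cohort == ch
      if (!any(hit)) {
        warning("gene ", g, " absent from control cohort ", ch,
                "; comparison undefined", call. = FALSE)
        next
      }
      b <- controls$carriers[hit][1]
      b_n <- controls$n_total[hit][1]
      row <- burden_row(g, "cases", ch, a, a_n, b, b_n)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

stratum_groups <- function(patients, stratum) {
  er <- patients$er; pr <- patients$pr; her2 <- patients$her2
  switch(stratum,
    bilateral_vs_unilateral = list(
      a = patients$bilateral %in% TRUE, b = patients$bilateral %in% FALSE,
      label_a = "bilateral", label_b = "unilateral"),
    er = list(a = er %in% "positive", b = er %in% "negative",
              label_a = "ER-positive", label_b = "ER-negative"),
    pr = list(a = pr %in% "positive", b = pr %in% "negative",
              label_a = "PR-positive", label_b = "PR-negative"),
    her2 = list(a = her2 %in% "positive", b = her2 %in% "negative",
                label_a = "HER2-positive", label_b = "HER2-negative"),
    tnbc = {
      known <- er %in% c("positive", "negative") &
        pr %in% c("positive", "negative") &
        her2 %in% c("positive", "negative")
      tn <- known & er == "negative" & pr == "negative" & her2 == "negative"
      list(a = known & !tn, b = tn,
           label_a = "non-TNBC", label_b = "TNBC")
    },
    oc_family_history = list(
      a = patients$oc_family_history %in% TRUE,
      b = patients$oc_family_history %in% FALSE,
      label_a = "OC-FH", label_b = "no-OC-FH"),
    stop("unknown stratum: ", stratum))
}

#' Case-case burden scan across phenotype strata
#'
#' For each gene (plus the CHEK2 c.1100del founder allele and the any-gene
#' `ALL` row) and each requested stratum, compares carrier prevalence
#' between the two arms of the stratum (patients with unknown status are
#' excluded from both arms).
#'
#' @param classified Classified-variant data.frame with `patient_id`.
#' @param patients Phenotype data.frame with columns `bilateral`,
#'   `oc_family_history`, `er`, `pr`, `her2`.
#' @param strata Subset of `c("bilateral_vs_unilateral", "er", "pr", "her2",
#'   "tnbc", "oc_family_history")`.
#' @param class_filter Carrier definition, default `"class45"`.
#' @param genes Genes to test; default the genes present among qualifying
#'   variants.
#' @return data.frame with one row per gene x stratum, including carrier
#'   prevalence percentages per arm.
#' @export
stratified_scan <- function(classified, patients,
                            strata = c("bilateral_vs_unilateral", "er", "pr",
                                       "her2", "tnbc", "oc_family_history"),
                            class_filter = "class45", genes = NULL) {
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.null(genes)) {
    qual <- qualifying_rows(classified, class_filter)
    genes <- sort(unique(classified$gene[qual]))
    if (any(gene_rows(classified, "CHEK2_c1100del") & qual))
      genes <- c(genes, "CHEK2_c1100del")
    genes <- c(genes, "ALL")
  }
  out <- list()
  for (s in strata) {
    grp <- stratum_groups(patients, s)
    for (g in genes) {
      ca <- aggregate_carriers(classified, patients, g, class_filter,
                               subgroup = grp$a)
      cb <- aggregate_carriers(classified, patients, g, class_filter,
                               subgroup = grp$b)
      if (ca$n == 0L || cb$n == 0L) {
        warning("empty stratum arm in ", s, call. = FALSE)
        next
      }
      row <- burden_row(g, grp$label_a, grp$label_b,
                        ca$carriers, ca$n, cb$carriers, cb$n)
      row$stratum <- s
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Damaging-missense carrier burden against control cohorts
#'
#' Same statistics as [burden_scan()] applied to the consensus
#' damaging-missense flag (rare missense variants called damaging by both
#' predictors). Control tables must carry rows with
#' `metric == "damaging_missense"`.
#'
#' @inheritParams burden_scan
#' @return data.frame of burden results.
#' @export
missense_burden <- function(classified, patients, controls, genes = NULL) {
  burden_scan(classified, patients, controls, genes = genes,
              class_filter = "damaging_missense",
              metric = "damaging_missense")
}

#' Summarise variants of uncertain significance
#'
#' Counts over class-3 assignments: patients with at least one VUS, distinct
#' VUS (keyed by gene/chrom/pos/ref/alt), the fraction of affected patients
#' carrying exactly one VUS, and per-gene patient counts.
#'
#' @param classified Classified-variant data.frame with `patient_id`.
#' @param patients Phenotype data.frame.
#' @return List with `patients_with_vus`, `distinct_vus`,
#'   `fraction_single_vus`, `per_gene_vus_patient_counts`.
#' @export
summarize_vus <- function(classified, patients) {
  vus <- classified[classified$iarc_class == 3L, , drop = FALSE]
  per_pat <- table(vus$patient_id)
  per_gene <- vapply(split(vus$patient_id, vus$gene),
                     function(p) length(unique(p)), integer(1))
  list(
    patients_with_vus = length(per_pat),
    distinct_vus = nrow(unique(vus[, c("gene", "chrom", "pos", "ref",
                                       "alt")])),
    fraction_single_vus = if (length(per_pat)) mean(per_pat == 1L)
      else NA_real_,
    per_gene_vus_patient_counts = as.list(per_gene)
  )
}

#' Age-at-diagnosis comparison per gene
#'
#' Builds the carrier / reference age lists per gene from the phenotype
#' table and runs [aad_compare()]. With `mode = "vs_overall"` the reference
#' is the full sample with known age (carriers included); with
#' `mode = "vs_rest"` carriers are removed from the reference.
#'
#' @param classified Classified-variant data.frame with `patient_id`.
#' @param patients Phenotype data.frame with `aad_years`.
#' @param class_filter Carrier definition, default `"class45"`.
#' @param mode Reference construction (see above), default `"vs_rest"`.
#' @param genes Genes; default those with qualifying carriers, plus `"ALL"`.
#' @return data.frame with per-gene carrier count, means and t-test p.
#' @export
aad_scan <- function(classified, patients, class_filter = "class45",
                     mode = c("vs_rest", "vs_overall"), genes = NULL) {
  mode <- match.arg(mode)
  if (is.null(genes)) {
    qual <- qualifying_rows(classified, class_filter)
    genes <- c(sort(unique(classified$gene[qual])), "ALL")
  }
  have_age <- !is.na(patients$aad_years)
  out <- list()
  for (g in genes) {
    qual <- qualifying_rows(classified, class_filter) &
      gene_rows(classified, g)
    cpid <- unique(classified$patient_id[qual])
    is_carrier <- patients$patient_id %in% cpid
    ages_c <- patients$aad_years[is_carrier & have_age]
    ages_r <- if (mode == "vs_overall") patients$aad_years[have_age]
      else patients$aad_years[!is_carrier & have_age]
    if (length(ages_c) == 0L || length(ages_r) == 0L) next
    cmp <- aad_compare(ages_c, ages_r, mode = mode)
    out[[length(out) + 1L]] <- data.frame(
      gene = g, n_carriers = cmp$n_a, mean_carriers = cmp$mean_a,
      median_carriers = stats::median(ages_c),
      min_carriers = min(ages_c), max_carriers = max(ages_c),
      mean_reference = cmp$mean_b, t = cmp$t, p_t = cmp$p, mode = mode,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
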