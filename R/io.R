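# Plain-text table I/O (TSV) and the simulation bundle writer.

#' Read a patient phenotype table
#'
#' TSV with columns `patient_id`, `aad_years` (blank = missing),
#' `bilateral` (0/1), `oc_family_history` (0/1), `er`/`pr`/`her2`
#' (`positive`/`negative`/`unknown`, abbreviations `pos`/`neg` accepted).
#'
#' @param path TSV file path.
#' @return data.frame with typed columns.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "aad_years", "bilateral", "oc_family_history",
            "er", "pr", "her2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  d$aad_years <- suppressWarnings(as.numeric(d$aad_years))
  bad <- which(!is.na(d$aad_years) &
                 (d$aad_years < 10 | d$aad_years > 110))
  if (length(bad))
    stop("aad_years outside [10, 110] for patient(s): ",
         paste(utils::head(d$patient_id[bad], 5), collapse = ", "))
  d$bilateral <- as.logical(as.integer(d$bilateral))
  d$oc_family_history <- as.logical(as.integer(d$oc_family_history))
  fix <- function(x) {
    x <- tolower(x)
    x[x == "pos"] <- "positive"; x[x == "neg"] <- "negative"
    if (!all(x %in% c("positive", "negative", "unknown")))
      stop("receptor status must be positive/negative/unknown")
    x
  }
  d$er <- fix(d$er); d$pr <- fix(d$pr); d$her2 <- fix(d$her2)
  d
}

#' Write a patient phenotype table
#' @param patients Phenotype data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(patients, path) {
  d <- patients
  d$bilateral <- as.integer(d$bilateral)
  d$oc_family_history <- as.integer(d$oc_family_history)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a control carrier-count table
#'
#' Long-format TSV with columns `cohort`, `n_total`, `gene`, `carriers` and
#' optionally `metric` (`ptv` / `damaging_missense`; defaults to `ptv`).
#' Special gene keys: `ALL` (any-gene carriers) and `CHEK2_c1100del`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_controls <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort", "n_total", "gene", "carriers")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("control table missing column(s): ", paste(miss, collapse = ", "))
  if (!"metric" %in% names(d)) d$metric <- "ptv"
  if (any(d$carriers > d$n_total))
    stop("control carriers exceed cohort size")
  d
}

#' Write a control carrier-count table
#' @param controls Control-count data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_controls <- function(controls, path) {
  utils::write.table(controls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a classified-variant table
#'
#' TSV twin of the classification output (rationale tags
#' semicolon-joined).
#'
#' @param classified Classified-variant data.frame.
#' @param path TSV path.
#' @return `path` (write) or data.frame (read).
#' @export
write_classified <- function(classified, path) {
  utils::write.table(classified, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_classified
#' @export
read_classified <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  d$is_ptv <- as.logical(d$is_ptv)
  d$damaging_missense <- as.logical(d$damaging_missense)
  d
}

#' Default per-variant override list
#'
#' Ships the single override of the reference analysis: the recurrent CHEK2
#' missense c.470C>T (p.I157T), kept at VUS (class 3) because it showed no
#' case-control association in the study population despite its literature
#' status as a low-risk allele.
#'
#' @return Override data.frame (see [read_overrides()]).
#' @export
default_overrides <- function() {
  data.frame(
    gene = "CHEK2",
    key = "CHEK2:c.470C>T",
    forced_class = 3L,
    reason = "no case-control association in this population; low-risk allele not counted as deleterious",
    stringsAsFactors = FALSE)
}

#' Write a simulation bundle to disk
#'
#' Emits the standard-format artifacts of one simulated study: case VCF,
#' transcript GFF3 + domain sidecar + CDS FASTA, phenotype TSV, control
#' TSV, truth table TSV and a JSON manifest recording the configuration and
#' seed.
#'
#' @param sim Output of [simulate_cohort()] (with variants).
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cases.vcf"),
    gff3 = file.path(dir, "transcripts.gff3"),
    domains = file.path(dir, "domains.tsv"),
    cds_fasta = file.path(dir, "cds.fa"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    controls = file.path(dir, "controls.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json"))
  if (is.null(sim$variants))
    stop("simulation was run with make_variants = FALSE; nothing to write")
  vcols <- setdiff(names(sim$variants),
                   c("truth_category", "truth_anchor", "truth_class"))
  write_case_vcf(sim$variants[, vcols], paths$vcf,
                 transcripts = sim$transcripts)
  write_transcripts_gff3(sim$transcripts, paths$gff3)
  write_domain_table(sim$transcripts, paths$domains)
  write_cds_fasta(sim$transcripts, paths$cds_fasta)
  write_phenotypes(sim$phenotypes, paths$phenotypes)
  write_controls(sim$controls, paths$controls)
  idx <- which(sim$truth$carrier, arr.ind = TRUE)
  truth_df <- data.frame(
    patient_id = sim$phenotypes$patient_id[idx[, 1]],
    gene = colnames(sim$truth$carrier)[idx[, 2]])
  truth_df <- truth_df[order(truth_df$patient_id, truth_df$gene), ]
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    seed = sim$config$seed, n_cases = sim$config$n_cases,
    genes = sim$config$genes, cohorts = sim$config$cohorts,
    phenotype = sim$config$phenotype, effects = sim$config$effects)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
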