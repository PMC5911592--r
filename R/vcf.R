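# VCF input/output. Writing uses a plain serializer (records are generated
# in-package); reading goes through VariantAnnotation.

#' Write case variants as VCF 4.2
#'
#' One record per (patient, variant-allele) observation; annotations carried
#' as INFO keys `GENE`, `TX`, `PATIENT`, `CDOT`, `MAF_*`, `PRED1`, `PRED2`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `transcript_id`; optional `variant_id`, `patient_id`, `cdot`,
#'   `maf_*`, `pred1`, `pred2`.
#' @param path Output VCF path.
#' @param transcripts Optional transcript list used to emit contig headers.
#' @return `path`, invisibly.
#' @export
write_case_vcf <- function(variants, path, transcripts = NULL) {
  v <- as.data.frame(variants)
  v <- v[order(v$chrom, v$pos,
               if ("patient_id" %in% names(v)) v$patient_id else v$ref), ,
         drop = FALSE]
  maf_cols <- grep("^maf_", names(v), value = TRUE)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ptvburden")
  if (!is.null(transcripts)) {
    for (tx in transcripts)
      hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", tx$chrom,
                            max(tx$exons$end) + 1000L))
  }
  info_defs <- c(
    GENE = "Gene symbol", TX = "Transcript ID", PATIENT = "Patient ID",
    CDOT = "HGVS c. shorthand key", PRED1 = "In-silico predictor 1 verdict",
    PRED2 = "In-silico predictor 2 verdict", HGVSP = "HGVS p. annotation")
  for (k in names(info_defs))
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
      k, info_defs[[k]]))
  for (mc in maf_cols)
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"MAF in %s\">",
      toupper(mc), sub("^maf_", "", mc)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  getcol <- function(nm) if (nm %in% names(v)) as.character(v[[nm]])
    else rep(NA_character_, nrow(v))
  info <- vapply(seq_len(nrow(v)), function(r) {
    kv <- c(GENE = as.character(v$gene[r]),
            TX = as.character(v$transcript_id[r]),
            PATIENT = getcol("patient_id")[r],
            CDOT = getcol("cdot")[r],
            PRED1 = getcol("pred1")[r],
            PRED2 = getcol("pred2")[r],
            HGVSP = getcol("hgvs_p")[r])
    for (mc in maf_cols) {
      val <- v[[mc]][r]
      if (!is.na(val)) kv[toupper(mc)] <- format(val, scientific = FALSE)
    }
    kv <- kv[!is.na(kv) & nzchar(kv)]
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }, character(1))
  recs <- paste(v$chrom, v$pos,
                if ("variant_id" %in% names(v)) v$variant_id else ".",
                v$ref, v$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read an annotated VCF into the variant-table form
#'
#' Expands multi-allelic records to one row per alternate allele and maps
#' the configured INFO keys onto the columns [classify_variants()] expects.
#'
#' @param path VCF file path.
#' @param info_keys Named character vector mapping roles (`gene`, `tx`,
#'   `patient`, `cdot`, `pred1`, `pred2`, `hgvs_p`) to INFO key names.
#' @param maf_keys Character vector of Float INFO keys holding reference
#'   population MAFs (become `maf_<lowercase key>` columns).
#' @return data.frame of variant records.
#' @export
read_variant_vcf <- function(path,
                             info_keys = c(gene = "GENE", tx = "TX",
                                           patient = "PATIENT",
                                           cdot = "CDOT", pred1 = "PRED1",
                                           pred2 = "PRED2",
                                           hgvs_p = "HGVSP"),
                             maf_keys = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (is.null(maf_keys))
    maf_keys <- grep("^MAF_", names(info), value = TRUE)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  ridx <- rep(seq_along(rr), n_alt)

  getinfo <- function(key) {
    if (is.null(key) || !key %in% names(info))
      return(rep(NA_character_, length(rr)))
    x <- info[[key]]
    if (methods::is(x, "List")) x <- vapply(x, function(e)
      if (length(e)) as.character(e)[1] else NA_character_, character(1))
    as.character(x)
  }
  out <- data.frame(
    variant_id = rep(names(rr), n_alt),
    chrom = rep(as.character(GenomicRanges::seqnames(rr)), n_alt),
    pos = rep(GenomicRanges::start(rr), n_alt),
    ref = rep(as.character(VariantAnnotation::ref(vcf)), n_alt),
    alt = as.character(unlist(alt)),
    gene = rep(getinfo(info_keys[["gene"]]), n_alt),
    transcript_id = rep(getinfo(info_keys[["tx"]]), n_alt),
    patient_id = rep(getinfo(info_keys[["patient"]]), n_alt),
    cdot = rep(getinfo(info_keys[["cdot"]]), n_alt),
    pred1 = rep(getinfo(info_keys[["pred1"]]), n_alt),
    pred2 = rep(getinfo(info_keys[["pred2"]]), n_alt),
    hgvs_p = rep(getinfo(info_keys[["hgvs_p"]]), n_alt),
    stringsAsFactors = FALSE)
  out$pred1[is.na(out$pred1)] <- "unknown"
  out$pred2[is.na(out$pred2)] <- "unknown"
  for (mk in maf_keys) {
    x <- info[[mk]]
    if (methods::is(x, "List")) x <- vapply(x, function(e)
      if (length(e)) as.numeric(e)[1] else NA_real_, numeric(1))
    out[[paste0("maf_", tolower(sub("^MAF_", "", mk)))]] <-
      as.numeric(x)[ridx]
  }
  out
}

#' Classify every record of an annotated VCF
#'
#' Streams an annotated VCF through [call_consequence()] /
#' [assign_class()] and returns one classified row per record-allele, plus a
#' per-class / per-gene summary. Records naming a transcript absent from
#' `transcripts` are skipped with a warning and counted in the summary.
#'
#' @param vcf_path Input VCF.
#' @param transcripts Named list of [transcript_model()] objects.
#' @param overrides Optional override table ([read_overrides()]).
#' @param config List of engine options: `maf_threshold` (default 0.01),
#'   `rare_threshold` (0.001), `domain_mode`, `info_keys`, `maf_keys`.
#' @return List with `classified` and `summary` (see [classify_variants()]).
#' @export
classify_vcf <- function(vcf_path, transcripts, overrides = NULL,
                         config = list()) {
  defaults <- list(maf_threshold = 0.01, rare_threshold = 0.001,
                   domain_mode = "intersect", maf_keys = NULL,
                   info_keys = c(gene = "GENE", tx = "TX",
                                 patient = "PATIENT", cdot = "CDOT",
                                 pred1 = "PRED1", pred2 = "PRED2",
                                 hgvs_p = "HGVSP"))
  config <- utils::modifyList(defaults, config)
  variants <- read_variant_vcf(vcf_path, info_keys = config$info_keys,
                               maf_keys = config$maf_keys)
  classify_variants(variants, transcripts, overrides = overrides,
                    maf_threshold = config$maf_threshold,
                    rare_threshold = config$rare_threshold,
                    domain_mode = config$domain_mode)
}
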