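# Report rendering: human-readable tables in the style of the published
# prevalence/association tables ("n.a." for undefined odds ratios), with a
# machine-precision JSON twin.

#' Round half away from zero
#'
#' `round()` in R rounds half to even; report tables use the conventional
#' half-away-from-zero rule so printed values match the reference tables.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Format a p-value the way the reference tables print it
#'
#' Values below 1e-4 print as `<0.0001`, otherwise 4 decimals.
#'
#' @param p Numeric p-value.
#' @return Character.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "n.a.",
         ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", round_half_up(p, 4))))
}

#' Render a burden-result table for reading
#'
#' Collapses each comparison to the familiar
#' `carriers (pct)` / `OR (CI low-CI high, p)` presentation; undefined odds
#' ratios (any zero cell) print `n.a.`.
#'
#' @param results data.frame from [burden_scan()] or [stratified_scan()].
#' @return data.frame of formatted strings.
#' @export
format_burden_table <- function(results) {
  r <- as.data.frame(results)
  out <- data.frame(
    gene = r$gene,
    comparison = paste(r$group_a, "vs.", r$group_b),
    group_a = sprintf("%d (%s)", r$a_carriers, fmt2(r$a_pct)),
    group_b = sprintf("%d (%s)", r$b_carriers, fmt2(r$b_pct)),
    or_ci_p = ifelse(r$defined,
                     sprintf("%s (%s-%s, %s)", fmt2(r$odds_ratio),
                             fmt2(r$ci_low), fmt2(r$ci_high),
                             format_p(r$p_fisher)),
                     sprintf("n.a. (n.a., %s)", format_p(r$p_fisher))),
    stringsAsFactors = FALSE)
  if ("stratum" %in% names(r)) out$stratum <- r$stratum
  out
}

#' Write a burden report as TSV plus a JSON twin
#'
#' The TSV carries the formatted table ([format_burden_table()]); the JSON
#' twin carries the machine-precision values, plus a Benjamini-Hochberg
#' adjusted p column emitted as supplementary output (it never gates
#' significance in the analysis itself).
#'
#' @param results data.frame from [burden_scan()] or [stratified_scan()].
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the results with the `p_bh` column added.
#' @export
write_report <- function(results, path_tsv = NULL, path_json = NULL) {
  r <- as.data.frame(results)
  r$p_bh <- stats::p.adjust(r$p_fisher, method = "BH")
  if (!is.null(path_tsv))
    utils::write.table(format_burden_table(r), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(r, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  invisible(r)
}
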