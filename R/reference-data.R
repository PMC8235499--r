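#' Reference co-deregulation table (pediatric CNS tumor cohort)
#'
#' The published per-miRNA co-deregulation frequency table from a pooled
#' pediatric CNS tumor cohort of 195 tumor and 244 control samples: for each
#' reported miRNA the direction, the count f of tumor samples deregulated in
#' that direction, the reported percentage (denominator 195), the k-means
#' cluster and a mean expression value. The table is used as printed, as the
#' input to frequency-arithmetic and band-census checks; a few rows carry
#' internal rounding inconsistencies (the same f maps to two different
#' percentages in different clusters), which are retained verbatim and never
#' used as expected values for recomputation.
#'
#' @return data.frame with columns inv, symbol, pattern, f, f_pct,
#'   kmeans_cluster, mean_expression.
#' @export
cns_codereg_reference <- function() {
  utils::read.delim(system.file("extdata", "cns_codereg_reference.tsv",
                                package = "coderegmiR"),
                    stringsAsFactors = FALSE)
}

#' Reference cohort count margins (pediatric CNS tumor cohort)
#'
#' Printed category counts of the same cohort: totals, diagnosis at two
#' granularities, tumor grade, gender and sampling status.
#'
#' @return data.frame with columns variable, category, n.
#' @export
cns_cohort_reference <- function() {
  utils::read.delim(system.file("extdata", "cns_cohort_counts.tsv",
                                package = "coderegmiR"),
                    stringsAsFactors = FALSE)
}

#' Reference tumor-cohort denominator
#'
#' The fixed denominator (195 tumor samples) used by the reference
#' co-deregulation table.
#'
#' @return integer scalar.
#' @export
cns_reference_denominator <- function() 195L
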