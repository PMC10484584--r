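#' Bundled severity confusion tables from a published HSAT validation study
#'
#' Cross-tabulations (counts) of sleep-disordered-breathing severity
#' predicted by three HSAT-derived AHI surrogates against the severity from
#' attended polysomnography, for 245 subjects. The three surrogates are the
#' respiratory event index (`rei`, events per hour of recording time), the
#' sleep-staged AHI (`ahi_cress`, events during sleep per hour of estimated
#' sleep) and the sleep-staged AHI with autonomic-arousal confirmation of
#' hypopneas (`ahi_cress_autar`).
#'
#' @return A named list of three 4x4 integer matrices (rows = predicted
#'   class, columns = true class).
#' @export
hsat_confusion_tables <- function() {
  path <- system.file("extdata", "sdb_confusion_counts.csv",
                      package = "hsatscore", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$index), function(d) {
    m <- matrix(0L, 4, 4, dimnames = list(predicted = SEVERITY_LEVELS,
                                          true = SEVERITY_LEVELS))
    m[cbind(d$predicted, d$true)] <- as.integer(d$count)
    m
  })
  out[c("rei", "ahi_cress", "ahi_cress_autar")]
}

#' Bundled p-value families for multiplicity control
#'
#' The 22 p-values of each comparison family (each HSAT surrogate versus the
#' REI across all diagnostic metrics), as printed in the source study's
#' result tables. Values reported as "<0.001" are represented by
#' `below_001`, which defaults to 0.0005; the Benjamini-Yekutieli threshold
#' is insensitive to any representation at or below 0.001.
#'
#' @param below_001 Numeric stand-in for "<0.001" entries.
#' @return Tibble with columns `family`, `task`, `metric`, `p`.
#' @export
hsat_family_pvalues <- function(below_001 = 0.0005) {
  stopifnot(below_001 > 0, below_001 <= 0.001)
  path <- system.file("extdata", "sdb_family_pvalues.csv",
                      package = "hsatscore", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  p <- ifelse(df$p == "<0.001", below_001, suppressWarnings(as.numeric(df$p)))
  tibble::tibble(family = df$family, task = df$task, metric = df$metric, p = p)
}
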