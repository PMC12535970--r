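#' Reference class counts of the published phytolith dataset
#'
#' Per-class train/validation/test/test_other phytolith counts of the
#' Pooideae reference collection at the three classification levels
#' (lineage, species, Triticum subspecies). These counts are the published
#' sampling design; [nir_from_counts()] on a partition column reproduces the
#' reported no-information rates.
#'
#' @param level optional filter: "lineage", "species" or "subspecies".
#' @return data.frame: level, class, train, validation, test, test_other.
#' @export
reference_class_counts <- function(level = NULL) {
  tab <- read.csv(system.file("extdata", "reference_class_counts.csv",
                              package = "dendriform"),
                  stringsAsFactors = FALSE)
  if (!is.null(level)) tab <- tab[tab$level == level, , drop = FALSE]
  tab
}

#' Published domestication logistic model coefficients
#'
#' Log-odds, standard errors, Z statistics, odds ratios with 95% CIs and
#' p-values of the reference binary logistic model of domestication status
#' on seven rotated components ("domesticated" as reference category).
#'
#' @return data.frame: term, b, se, z, or, ci_lo, ci_hi, p.
#' @export
reference_domestication_model <- function() {
  read.csv(system.file("extdata", "reference_domestication_model.csv",
                       package = "dendriform"), stringsAsFactors = FALSE)
}

#' Published ploidy ordinal model coefficients
#'
#' Coefficients and latent-scale thresholds of the reference
#' proportional-odds model of ploidy level (diploid < tetraploid <
#' hexaploid) on seven rotated components.
#'
#' @return data.frame: term, b, se, t, or, ci_lo, ci_hi.
#' @export
reference_ploidy_model <- function() {
  read.csv(system.file("extdata", "reference_ploidy_model.csv",
                       package = "dendriform"), stringsAsFactors = FALSE)
}
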