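default_taxonomy <- function() {
  lineages <- c("Avena", "Hordeum", "Secale", "Triticum", "Poeae", "Triticodae")
  tab <- do.call(rbind, lapply(lineages, function(g) {
    data.frame(lineage = g,
               species = paste0(g, "_sp", 1:2),
               stringsAsFactors = FALSE)
  }))
  tab <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(lineage = tab$lineage[i], species = tab$species[i],
               subspecies = paste0(tab$species[i], "_ssp", 1:2),
               stringsAsFactors = FALSE)
  }))
  tab$domestication <- ifelse(tab$lineage %in% c("Poeae", "Triticodae"),
                              "wild",
                              rep(c("domesticated", "wild"), length.out = nrow(tab)))
  tab$ploidy <- rep(c("diploid", "tetraploid", "hexaploid"), length.out = nrow(tab))
  tab
}

#' Hierarchical cohort simulation design
#'
#' Describes a synthetic stand-in for the confocal trait dataset: phytoliths
#' nested in inflorescence samples nested in taxa, with Gaussian variance at
#' every level, planted domestication/ploidy effects and optional class
#' imbalance. Using a parametric model (rather than resampling data) keeps
#' every effect size and variance exactly known, which is what the type-I and
#' power checks need.
#'
#' @param taxonomy data.frame with columns lineage, species, subspecies,
#'   domestication ("wild"/"domesticated") and ploidy
#'   ("diploid"/"tetraploid"/"hexaploid"); one row per subspecies.
#' @param samples_per_taxon inflorescence samples per subspecies.
#' @param phytoliths_per_sample phytoliths per sample (study protocol:
#'   about 20-25 usable meshes per sample).
#' @param taxon_sd SD of taxon trait means around the base profile.
#' @param between_sample_sd SD of the sample-level random effect.
#' @param within_sample_sd residual SD between phytoliths of one sample.
#' @param domestication_delta named numeric vector of trait shifts added to
#'   domesticated taxa (names must be trait columns); zero by default.
#' @param ploidy_delta named numeric vector of per-ploidy-step shifts
#'   (diploid -> tetraploid -> hexaploid); zero by default.
#' @param imbalance named multipliers on phytoliths_per_sample by lineage.
#' @param seed RNG seed.
#' @export
cohort_design <- function(taxonomy = default_taxonomy(),
                          samples_per_taxon = 3,
                          phytoliths_per_sample = 20,
                          taxon_sd = 1,
                          between_sample_sd = 0.5,
                          within_sample_sd = 1,
                          domestication_delta = NULL,
                          ploidy_delta = NULL,
                          imbalance = NULL,
                          seed = 1L) {
  stopifnot(all(c("lineage", "species", "subspecies", "domestication",
                  "ploidy") %in% names(taxonomy)),
            samples_per_taxon >= 1, phytoliths_per_sample >= 1,
            taxon_sd >= 0, between_sample_sd >= 0, within_sample_sd >= 0)
  tc <- trait_columns()
  for (v in list(domestication_delta, ploidy_delta))
    if (!is.null(v) && !all(names(v) %in% tc))
      stop("effect vector names must be trait columns")
  structure(list(taxonomy = taxonomy,
                 samples_per_taxon = samples_per_taxon,
                 phytoliths_per_sample = phytoliths_per_sample,
                 taxon_sd = taxon_sd,
                 between_sample_sd = between_sample_sd,
                 within_sample_sd = within_sample_sd,
                 domestication_delta = domestication_delta,
                 ploidy_delta = ploidy_delta,
                 imbalance = imbalance,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# baseline trait profile in plausible units (only location matters for the
# statistical stages; variances come from the design)
base_trait_profile <- function() {
  tc <- trait_columns()
  mu <- setNames(numeric(length(tc)), tc)
  mu["Volume"] <- 900; mu["ConvexHullVolume"] <- 1400; mu["SurfaceArea"] <- 800
  mu["Solidity"] <- 0.65; mu["Sphericity"] <- 0.55
  mu["MaxLength"] <- 30; mu["MaxWidth"] <- 15; mu["MaxHeight"] <- 7
  mu[c("PC1sd", "PC2sd", "PC3sd")] <- c(8, 4, 1.6)
  mu["Elongation"] <- 0.5; mu["Flatness"] <- 0.5
  mu["CoreVolume"] <- 700; mu["CoreConvexVolume"] <- 900
  mu["CoreSurfaceArea"] <- 500; mu["CoreOccupancy"] <- 0.8
  mu["CoreSolidity"] <- 0.85; mu["CoreSphericity"] <- 0.6
  mu["CoremaxLength"] <- 26; mu["CoreMaxWidth"] <- 9; mu["CoreMaxHeight"] <- 6
  mu[c("CorePC1sd", "CorePC2sd", "CorePC3sd")] <- c(7, 2.5, 1.4)
  mu["CoreElongation"] <- 0.6; mu["CoreFlatness"] <- 0.3
  mu["AverageDendriticLength"] <- 8; mu["DendriticDensity"] <- 0.25
  mu["DendriticNumber"] <- 6; mu["DendriticTotalLength"] <- 48
  mu[cc_trait_names] <- pmin(6, pmax(0, 6 - (20:1) / 4))
  mu[ph_trait_names] <- 0
  mu
}

#' Simulate a hierarchical trait cohort
#'
#' Trait vectors are drawn as taxon mean + sample random effect + residual,
#' all Gaussian; designated traits are shifted by the domestication and
#' ploidy effect vectors. The output has the exact column schema of the
#' per-phytolith trait table plus metadata/label columns.
#'
#' @param d a [cohort_design()].
#' @return data.frame: phytolith_id, sample_id, lineage, species, subspecies,
#'   domestication, ploidy, then the 71 trait columns.
#' @export
simulate_cohort <- function(d) {
  stopifnot(inherits(d, "cohort_design"))
  with_seed(d$seed, {
    tc <- trait_columns()
    mu0 <- base_trait_profile()
    tax <- d$taxonomy
    rows <- vector("list", 0)
    for (i in seq_len(nrow(tax))) {
      taxon_mu <- mu0 + rnorm(length(tc), 0, d$taxon_sd)
      if (!is.null(d$domestication_delta) &&
          tax$domestication[i] == "domesticated") {
        taxon_mu[names(d$domestication_delta)] <-
          taxon_mu[names(d$domestication_delta)] + d$domestication_delta
      }
      if (!is.null(d$ploidy_delta)) {
        step <- match(tax$ploidy[i],
                      c("diploid", "tetraploid", "hexaploid")) - 1
        taxon_mu[names(d$ploidy_delta)] <-
          taxon_mu[names(d$ploidy_delta)] + step * d$ploidy_delta
      }
      nps <- d$phytoliths_per_sample
      if (!is.null(d$imbalance) && tax$lineage[i] %in% names(d$imbalance))
        nps <- max(1L, round(nps * d$imbalance[[tax$lineage[i]]]))
      for (s in seq_len(d$samples_per_taxon)) {
        sample_mu <- taxon_mu + rnorm(length(tc), 0, d$between_sample_sd)
        X <- matrix(rnorm(nps * length(tc), 0, d$within_sample_sd),
                    nps, length(tc))
        X <- sweep(X, 2, sample_mu, "+")
        colnames(X) <- tc
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_s%02d", tax$subspecies[i], s),
          lineage = tax$lineage[i], species = tax$species[i],
          subspecies = tax$subspecies[i],
          domestication = tax$domestication[i], ploidy = tax$ploidy[i],
          X, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(phytolith_id = sprintf("phy%05d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
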