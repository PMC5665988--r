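#' OtuTable: an OTU count table with optional taxonomy
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' nonnegative count matrix with OTUs as rows (features) and samples/stations
#' as columns, plus an optional semicolon-delimited taxonomy lineage per OTU
#' in `rowData(x)$taxonomy`. Counts become real-valued after median-depth
#' standardization ([standardizeDepth]); the validity method only requires
#' nonnegative finite values.
#'
#' @slot .Data inherited SummarizedExperiment structure (assay `"counts"`).
#' @seealso [readOtuTable], [filterRare], [standardizeDepth],
#'   [relativeAbundance], [aggregateTaxa], [topKOtus]
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
    msg <- character(0)
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (any(!is.finite(m)))
            msg <- c(msg, "counts must be finite")
        else if (any(m < 0))
            msg <- c(msg, "counts must be nonnegative")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate OTU ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "OTU and sample ids are required")
    if (length(msg)) msg else TRUE
})

#' Construct an OtuTable
#'
#' @param counts nonnegative matrix, OTUs x samples, with dimnames.
#' @param taxonomy optional character vector of lineage strings, named by OTU
#'   id or in row order.
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 2L, 8L, 1L), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("st1", "st2")))
#' OtuTable(m, taxonomy = c("Eukaryota;Bacillariophyta", NA, NA))
#' @export
OtuTable <- function(counts, taxonomy = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        if (!is.null(names(taxonomy)))
            taxonomy <- taxonomy[rownames(counts)]
        if (length(taxonomy) != nrow(counts))
            stop("taxonomy length must match the number of OTUs")
        rd$taxonomy <- as.character(taxonomy)
    }
    new("OtuTable", SummarizedExperiment(
        assays = list(counts = counts), rowData = rd))
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [simulateScenario]: a
#' hyperdominant OTU abundance spectrum realized as multinomial reads over a
#' log-normal basis, a sparse linear link from a few OTU relative abundances
#' to NCP, and per-station physical forcing (mixed layer depth, AR(1) wind
#' history, temperature/salinity/density).
#'
#' @slot nStations integer, number of stations (samples).
#' @slot nOtus integer, number of OTUs.
#' @slot meanDepth expected reads per sample.
#' @slot dominanceWeights positive reals (length nOtus), expected basis share.
#' @slot basisLogCov symmetric PSD matrix, covariance of the log basis.
#' @slot plantedEffects data.frame with columns `otu` (index) and `beta`
#'   (mmol C m-2 day-1 per standardized-abundance unit).
#' @slot noiseSd residual NCP standard deviation.
#' @slot alpha NCP intercept, mmol C m-2 day-1.
#' @slot mldRange numeric(2), mixed layer depth range in m.
#' @slot windAr1 numeric(3): mean (m s-1), lag-1 coefficient, innovation sd.
#' @slot windDays length of the daily wind history.
#' @slot pocParams numeric(3): intercept (mmol C m-3), scale, lognormal sd of
#'   the POC model POC = c0 + c1 * relative-biomass * lognormal-noise.
#' @slot seed integer master seed; stages derive independent substreams.
#' @seealso [scenarioConfig]
#' @export
setClass("ScenarioConfig", representation(
    nStations = "integer", nOtus = "integer", meanDepth = "numeric",
    dominanceWeights = "numeric", basisLogCov = "matrix",
    plantedEffects = "data.frame", noiseSd = "numeric", alpha = "numeric",
    mldRange = "numeric", windAr1 = "numeric", windDays = "integer",
    pocParams = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- character(0)
    if (object@nStations < 4L)
        msg <- c(msg, "nStations must be >= 4")
    if (length(object@dominanceWeights) != object@nOtus)
        msg <- c(msg, "dominanceWeights must have length nOtus")
    if (any(object@dominanceWeights <= 0))
        msg <- c(msg, "dominanceWeights must be positive")
    if (nrow(object@plantedEffects) &&
        max(object@plantedEffects$otu) > object@nOtus)
        msg <- c(msg, "planted OTU index exceeds nOtus")
    if (!isTRUE(all.equal(object@basisLogCov, t(object@basisLogCov),
                          tolerance = 1e-8)))
        msg <- c(msg, "basisLogCov must be symmetric")
    if (object@windAr1[2] < 0 || object@windAr1[2] >= 1)
        msg <- c(msg, "wind lag-1 coefficient must be in [0, 1)")
    if (diff(object@mldRange) < 0 || any(object@mldRange <= 0))
        msg <- c(msg, "mldRange must be positive and increasing")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Synthetic scenario bundle with planted ground truth
#'
#' Output of [simulateScenario]: everything a downstream stage consumes plus
#' the exact quantities the generator used, so recovery can be scored.
#'
#' @slot otu [OtuTable-class] of simulated reads.
#' @slot stations data.frame of per-station environment (temperature,
#'   salinity, density, mld, o2ar_sample, o2ar_sat, poc, ...).
#' @slot winds matrix nStations x windDays of daily u10, most recent last.
#' @slot profiles data.frame of CTD density profiles
#'   (station_id, depth_m, sigma_theta).
#' @slot trueNcp numeric, planted NCP (mmol C m-2 day-1).
#' @slot trueEffects named numeric over all OTUs, exact zeros off the support.
#' @slot trueBasisCorrelations correlation matrix of the log basis.
#' @slot config the [ScenarioConfig-class] used.
#' @export
setClass("SyntheticBundle", representation(
    otu = "OtuTable", stations = "data.frame", winds = "matrix",
    profiles = "data.frame", trueNcp = "numeric", trueEffects = "numeric",
    trueBasisCorrelations = "matrix", config = "ScenarioConfig"))

#' Settings for the spike-and-slab Gibbs sampler
#'
#' Priors and MCMC settings for [ssvsFit]. Defaults follow the analysis the
#' package implements: 10000 iterations with the first 5000 discarded,
#' Beta(1, 1) prior on the spike weight, weakly informative Gamma(0.01, 0.01)
#' priors on the slab and noise precisions, and a diffuse normal intercept.
#'
#' @slot iterations total MCMC iterations.
#' @slot burnIn discarded initial iterations.
#' @slot aPsi,bPsi Gamma shape/rate for the slab precision psi_j^-2.
#' @slot aSigma,bSigma Gamma shape/rate for the noise precision sigma^-2.
#' @slot mu0,sigma02 normal prior mean/variance of the intercept.
#' @slot seed RNG seed (the sampler is fully deterministic given the seed).
#' @seealso [ssvsConfig], [ssvsFit]
#' @export
setClass("SsvsConfig", representation(
    iterations = "integer", burnIn = "integer",
    aPsi = "numeric", bPsi = "numeric", aSigma = "numeric", bSigma = "numeric",
    mu0 = "numeric", sigma02 = "numeric", seed = "integer"))

setValidity("SsvsConfig", function(object) {
    msg <- character(0)
    if (object@burnIn >= object@iterations)
        msg <- c(msg, "burnIn must be < iterations")
    if (any(c(object@aPsi, object@bPsi, object@aSigma, object@bSigma,
              object@sigma02) <= 0))
        msg <- c(msg, "prior parameters must be positive")
    if (length(msg)) msg else TRUE
})

#' Posterior summary of a stochastic-search variable selection run
#'
#' @slot betaDraws (iterations - burnIn) x p matrix of kept coefficient draws
#'   (exact zeros when the spike is selected).
#' @slot alphaDraws,sigma2Draws,piDraws kept draws of the intercept, noise
#'   variance, and spike weight.
#' @slot inclusionProbs named posterior inclusion probabilities p(beta_j),
#'   the per-predictor fraction of kept draws with beta_j != 0.
#' @slot ranking predictor ids by descending p(beta_j) (ties: lexicographic).
#' @slot selected ids retained by the sharp-drop rule (a ranking prefix).
#' @slot noSharpDrop TRUE when all inclusion probabilities tie and no cut
#'   exists.
#' @slot config the [SsvsConfig-class] used.
#' @seealso [ssvsFit], [selectBySharpDrop]
#' @export
setClass("SsvsResult", representation(
    betaDraws = "matrix", alphaDraws = "numeric", sigma2Draws = "numeric",
    piDraws = "numeric", inclusionProbs = "numeric", ranking = "character",
    selected = "character", noSharpDrop = "logical", config = "SsvsConfig"))

setValidity("SsvsResult", function(object) {
    msg <- character(0)
    p <- ncol(object@betaDraws)
    if (length(object@inclusionProbs) != p)
        msg <- c(msg, "inclusionProbs length must equal ncol(betaDraws)")
    if (any(object@inclusionProbs < 0 | object@inclusionProbs > 1))
        msg <- c(msg, "inclusion probabilities must lie in [0, 1]")
    if (!all(object@selected == head(object@ranking,
                                     length(object@selected))))
        msg <- c(msg, "selected must be a prefix of ranking")
    if (length(msg)) msg else TRUE
})

#' Settings for SparCC correlation estimation
#'
#' Internal constants of the SparCC procedure (the published defaults):
#' the number of Dirichlet-resampled estimates aggregated by the median, the
#' strong-correlation exclusion threshold and iteration cap used when solving
#' for basis variances, and the permutation count for p-values.
#'
#' @slot nEstimates resampled replicates averaged (median).
#' @slot exclusionThreshold |correlation| above which the most-correlated
#'   pair is dropped from the basis-variance system.
#' @slot maxExclusions maximum exclusion rounds.
#' @slot nPermutations permutations for two-sided p-values.
#' @slot seed RNG seed.
#' @seealso [sparccConfig], [sparccCorrelations], [sparccPvalues]
#' @export
setClass("SparccConfig", representation(
    nEstimates = "integer", exclusionThreshold = "numeric",
    maxExclusions = "integer", nPermutations = "integer", seed = "integer"))

setValidity("SparccConfig", function(object) {
    msg <- character(0)
    if (any(c(object@nEstimates, object@maxExclusions,
              object@nPermutations) < 1L))
        msg <- c(msg, "counts must be >= 1")
    if (object@exclusionThreshold <= 0 || object@exclusionThreshold >= 1)
        msg <- c(msg, "exclusionThreshold must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' A thresholded signed co-occurrence network
#'
#' Undirected simple graph over OTUs whose edges passed both the correlation-
#' magnitude and the p-value thresholds; isolated nodes are dropped from the
#' graph but remembered in `allNodes` so metrics can optionally include them.
#'
#' @slot graph an igraph object (edge attributes `correlation`, `p_value`,
#'   `sign`).
#' @slot edges data.frame: otu_a, otu_b, correlation, p_value, sign.
#' @slot allNodes ids of every OTU the matrices covered, including isolates.
#' @slot label source subset label (e.g. "low NCP/POC").
#' @slot rThreshold,pThreshold the thresholds the edges passed.
#' @seealso [buildNetwork], [topologyMetrics], [compareNetworks]
#' @export
setClass("CooccurrenceNetwork", representation(
    graph = "ANY", edges = "data.frame", allNodes = "character",
    label = "character", rThreshold = "numeric", pThreshold = "numeric"))

setValidity("CooccurrenceNetwork", function(object) {
    msg <- character(0)
    if (nrow(object@edges)) {
        if (any(object@edges$otu_a == object@edges$otu_b))
            msg <- c(msg, "self-loops are not allowed")
        key <- paste(pmin(object@edges$otu_a, object@edges$otu_b),
                     pmax(object@edges$otu_a, object@edges$otu_b))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(msg)) msg else TRUE
})
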