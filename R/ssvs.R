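#' Build a sampler configuration
#'
#' @param iterations total MCMC iterations (default 10000).
#' @param burnIn discarded initial iterations (default 5000).
#' @param aPsi,bPsi Gamma shape/rate prior on each slab precision.
#' @param aSigma,bSigma Gamma shape/rate prior on the noise precision.
#' @param mu0,sigma02 normal prior mean/variance of the intercept.
#' @param seed RNG seed; the sampler is bit-reproducible given the seed.
#' @return A validated [SsvsConfig-class].
#' @export
ssvsConfig <- function(iterations = 10000, burnIn = 5000,
                       aPsi = 0.01, bPsi = 0.01,
                       aSigma = 0.01, bSigma = 0.01,
                       mu0 = 0, sigma02 = 1e4, seed = 1L) {
    new("SsvsConfig", iterations = as.integer(iterations),
        burnIn = as.integer(burnIn), aPsi = aPsi, bPsi = bPsi,
        aSigma = aSigma, bSigma = bSigma, mu0 = mu0, sigma02 = sigma02,
        seed = as.integer(seed))
}

#' Mean-center and variance-scale predictor columns
#'
#' @param X numeric matrix (observations x predictors).
#' @return Matrix with columns of mean 0 and sd 1 (denominator n - 1).
#'   Errors naming the offending column when one is constant.
#' @export
standardizePredictors <- function(X) {
    X <- as.matrix(X)
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
        bad <- colnames(X)[sds == 0]
        if (is.null(bad)) bad <- which(sds == 0)
        stop("constant predictor column(s): ", paste(bad, collapse = ", "))
    }
    z <- scale(X)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    z
}

#' Spike-and-slab stochastic-search variable selection
#'
#' Gibbs sampler for the sparse linear model
#' `y_i ~ N(x_i beta + alpha, sigma^2)` with a Dirac spike at zero and a
#' `N(0, psi_j^2)` slab on each coefficient, a Beta(1, 1) prior on the spike
#' weight, Gamma priors on the slab and noise precisions and a diffuse
#' normal intercept. Each coefficient's update marginalizes it analytically
#' to compute the posterior inclusion odds, then draws from the slab's
#' conditional normal when included. Inclusion probabilities are the
#' per-predictor fraction of kept draws with a nonzero coefficient, and the
#' selected set is the sharp-drop prefix of the inclusion-probability
#' ranking.
#'
#' @param X predictor matrix (observations x predictors); standardized
#'   internally unless `standardize = FALSE`.
#' @param y response vector.
#' @param config an [SsvsConfig-class].
#' @param maxK sharp-drop guard passed to [selectBySharpDrop].
#' @param standardize mean-center and variance-scale X first (default TRUE).
#' @return An [SsvsResult-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(21 * 5), 21, dimnames = list(NULL, paste0("o", 1:5)))
#' fit <- ssvsFit(X, 5 * X[, 1] + rnorm(21, 0, 0.5),
#'                ssvsConfig(iterations = 2000, burnIn = 1000))
#' inclusionProbs(fit)
#' @export
ssvsFit <- function(X, y, config = ssvsConfig(), maxK = 5,
                    standardize = TRUE) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("X and y must be finite")
    if (nrow(X) < 3) stop("need at least 3 observations")
    if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
    validObject(config)
    if (standardize) X <- standardizePredictors(X)
    set.seed(config@seed)
    draws <- .ssvsGibbs(X, as.numeric(y), config@iterations, config@burnIn,
                        config@aPsi, config@bPsi, config@aSigma,
                        config@bSigma, config@mu0, config@sigma02)
    colnames(draws$beta) <- colnames(X)
    probs <- inclusionProbabilities(draws$beta)
    sel <- selectBySharpDrop(probs, maxK = maxK)
    new("SsvsResult", betaDraws = draws$beta, alphaDraws = draws$alpha,
        sigma2Draws = draws$sigma2, piDraws = draws$pi,
        inclusionProbs = probs, ranking = sel$ranking,
        selected = sel$selected, noSharpDrop = sel$noSharpDrop,
        config = config)
}

#' Posterior inclusion probabilities from coefficient draws
#'
#' p(beta_j) = fraction of kept draws in which beta_j != 0.
#'
#' @param betaDraws draws x predictors matrix (post burn-in).
#' @return Named numeric vector in \[0, 1\].
#' @export
inclusionProbabilities <- function(betaDraws) {
    if (!nrow(betaDraws)) stop("need at least one post-burn-in draw")
    colMeans(betaDraws != 0)
}

#' Select predictors at the sharp drop of inclusion probabilities
#'
#' Sorts p(beta_j) descending (ties broken by predictor id) and cuts at the
#' largest consecutive gap among the first `maxK` positions; the prefix
#' before the gap is the selected set. When all probabilities are equal
#' there is no drop and the selection is empty with `noSharpDrop = TRUE`.
#'
#' @param probs named inclusion probabilities.
#' @param maxK deepest allowed cut.
#' @return list: `selected`, `ranking` (full, by descending probability),
#'   `gapPosition`, `gapSize`, `noSharpDrop`.
#' @examples
#' selectBySharpDrop(c(a = 0.98, b = 0.95, c = 0.90, d = 0.15, e = 0.12))
#' @export
selectBySharpDrop <- function(probs, maxK = 5) {
    if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
    if (is.null(names(probs))) names(probs) <- paste0("x", seq_along(probs))
    ord <- order(-probs, names(probs))
    ranking <- names(probs)[ord]
    sorted <- probs[ord]
    nGaps <- min(maxK, length(probs) - 1)
    if (nGaps < 1)
        return(list(selected = ranking, ranking = ranking,
                    gapPosition = NA_integer_, gapSize = NA_real_,
                    noSharpDrop = FALSE))
    gaps <- sorted[seq_len(nGaps)] - sorted[seq_len(nGaps) + 1]
    if (max(gaps) <= 1e-12)
        return(list(selected = character(0), ranking = ranking,
                    gapPosition = NA_integer_, gapSize = 0,
                    noSharpDrop = TRUE))
    cut <- which.max(gaps)
    list(selected = ranking[seq_len(cut)], ranking = ranking,
         gapPosition = cut, gapSize = unname(max(gaps)),
         noSharpDrop = FALSE)
}

#' @describeIn SsvsResult posterior inclusion probabilities.
#' @param x an SsvsResult.
#' @export
setMethod("inclusionProbs", "SsvsResult", function(x) x@inclusionProbs)

#' @describeIn SsvsResult predictor ids by descending p(beta_j).
#' @export
setMethod("predictorRanking", "SsvsResult", function(x) x@ranking)

#' @describeIn SsvsResult sharp-drop selected ids (a ranking prefix).
#' @export
setMethod("selectedPredictors", "SsvsResult", function(x) x@selected)

#' @describeIn SsvsResult kept coefficient draws ((It - B) x p).
#' @export
setMethod("betaDraws", "SsvsResult", function(x) x@betaDraws)

setMethod("show", "SsvsResult", function(object) {
    cfg <- object@config
    cat("SsvsResult:", ncol(object@betaDraws), "predictors,",
        nrow(object@betaDraws), "kept draws (It =", cfg@iterations,
        ", burn-in =", cfg@burnIn, ")\n")
    top <- head(object@inclusionProbs[object@ranking], 5)
    cat("  top p(beta_j):",
        paste(names(top), round(top, 3), sep = "=", collapse = ", "), "\n")
    if (object@noSharpDrop) cat("  no sharp drop; empty selection\n")
    else cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})
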