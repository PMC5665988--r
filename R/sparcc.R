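#' Build a SparCC configuration
#'
#' @param nEstimates Dirichlet-resampled estimates aggregated by the median
#'   (default 20).
#' @param exclusionThreshold |correlation| above which the most-correlated
#'   pair is excluded from the basis-variance system (default 0.1).
#' @param maxExclusions maximum exclusion rounds (default 10).
#' @param nPermutations permutations for p-values (default 100).
#' @param seed RNG seed.
#' @return A validated [SparccConfig-class].
#' @export
sparccConfig <- function(nEstimates = 20, exclusionThreshold = 0.1,
                         maxExclusions = 10, nPermutations = 100,
                         seed = 1L) {
    new("SparccConfig", nEstimates = as.integer(nEstimates),
        exclusionThreshold = exclusionThreshold,
        maxExclusions = as.integer(maxExclusions),
        nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

## One SparCC point estimate from a fraction matrix (samples x OTUs):
## log-ratio variance matrix T_ij = var(log(x_i/x_j)), basis variances from
## the sparse linear approximation t = ((p-2)I + J) omega with iterative
## exclusion of strongly correlated pairs, then correlations.
.sparccFromFractions <- function(fracs, exclusionThreshold, maxExclusions) {
    logs <- log(fracs)
    C <- stats::cov(logs)
    v <- diag(C)
    Tmat <- outer(v, v, `+`) - 2 * C
    p <- ncol(Tmat)
    M <- matrix(1, p, p)
    diag(M) <- p - 1
    tvec <- rowSums(Tmat)
    excluded <- matrix(FALSE, p, p)
    rho <- NULL
    for (round in seq_len(maxExclusions + 1)) {
        omega <- tryCatch(pmax(solve(M, tvec), 1e-12),
                          error = function(e) NULL)
        if (is.null(omega)) break  # system degenerated; keep last estimate
        denom <- 2 * sqrt(outer(omega, omega))
        rho <- (outer(omega, omega, `+`) - Tmat) / denom
        rho[rho > 1] <- 1
        rho[rho < -1] <- -1
        if (round > maxExclusions) break
        cand <- abs(rho)
        cand[excluded] <- 0
        diag(cand) <- 0
        mx <- max(cand)
        if (mx <= exclusionThreshold) break
        idx <- which(cand == mx, arr.ind = TRUE)[1, ]
        i <- idx[1]; j <- idx[2]
        ## keep each component in enough equations for a solvable system
        if (M[i, i] <= 2 || M[j, j] <= 2) break
        excluded[i, j] <- excluded[j, i] <- TRUE
        M[i, i] <- M[i, i] - 1
        M[j, j] <- M[j, j] - 1
        M[i, j] <- M[i, j] - 1
        M[j, i] <- M[j, i] - 1
        tvec[i] <- tvec[i] - Tmat[i, j]
        tvec[j] <- tvec[j] - Tmat[i, j]
    }
    rho
}

## median-aggregated estimate over Dirichlet resamples; does NOT seed
.sparccEstimate <- function(counts, config) {
    p <- nrow(counts); n <- ncol(counts)
    reps <- array(NA_real_, c(p, p, config@nEstimates))
    for (e in seq_len(config@nEstimates)) {
        ## per sample: fractions ~ Dirichlet(counts + 1)
        g <- matrix(rgamma(p * n, shape = counts + 1), p, n)
        fracs <- t(sweep(g, 2, colSums(g), `/`))     # samples x OTUs
        reps[, , e] <- .sparccFromFractions(fracs, config@exclusionThreshold,
                                            config@maxExclusions)
    }
    est <- apply(reps, c(1, 2), median)
    est <- (est + t(est)) / 2
    diag(est) <- 1
    dimnames(est) <- list(rownames(counts), rownames(counts))
    est
}

#' SparCC compositional correlations
#'
#' Estimates OTU-OTU correlations robust to the compositional constraint:
#' counts are perturbed to fractions by Dirichlet resampling, pairwise
#' log-ratio variances `t_ij = var(log(x_i / x_j))` are computed, basis
#' variances are solved from the sparse linear approximation, and
#' correlations are derived, iteratively excluding the most strongly
#' correlated pair from the basis-variance system. The returned matrix is
#' the element-wise median over `nEstimates` resampled replicates, clipped
#' to \[-1, 1\], symmetric with unit diagonal.
#'
#' @param counts an [OtuTable-class] (typically after [filterRare] and
#'   [standardizeDepth]) or an OTUs x samples matrix.
#' @param config a [SparccConfig-class].
#' @return OTU x OTU correlation matrix.
#' @export
sparccCorrelations <- function(counts, config = sparccConfig()) {
    if (is(counts, "OtuTable")) counts <- otuCounts(counts)
    counts <- as.matrix(counts)
    if (ncol(counts) < 4) stop("need at least 4 samples")
    if (nrow(counts) < 3)
        stop("too few OTUs for the basis-variance system (need >= 3)")
    validObject(config)
    set.seed(config@seed)
    .sparccEstimate(counts, config)
}

#' Permutation p-values for SparCC correlations
#'
#' Null distribution by independently shuffling each OTU across samples and
#' re-estimating the SparCC correlation matrix; two-sided add-one estimator
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + nPermutations)`, symmetric with
#' NA diagonal.
#'
#' @param counts as in [sparccCorrelations].
#' @param observedCorr the observed correlation matrix.
#' @param config a [SparccConfig-class].
#' @return Matrix of p-values in (0, 1\].
#' @export
sparccPvalues <- function(counts, observedCorr, config = sparccConfig()) {
    if (is(counts, "OtuTable")) counts <- otuCounts(counts)
    counts <- as.matrix(counts)
    if (!all(dim(observedCorr) == nrow(counts)))
        stop("observedCorr does not match counts")
    validObject(config)
    if (config@nPermutations < 20)
        warning("fewer than 20 permutations: p-value resolution is coarse")
    set.seed(stageSeed(config@seed, "sparcc-permutations"))
    absObs <- abs(observedCorr)
    exceed <- matrix(0, nrow(counts), nrow(counts))
    for (b in seq_len(config@nPermutations)) {
        shuffled <- t(apply(counts, 1, sample))
        rPerm <- .sparccEstimate(shuffled, config)
        exceed <- exceed + (abs(rPerm) >= absObs)
    }
    pv <- (1 + exceed) / (1 + config@nPermutations)
    pv <- (pv + t(pv)) / 2
    diag(pv) <- NA_real_
    dimnames(pv) <- dimnames(observedCorr)
    pv
}
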