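#' Build a scenario configuration
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' 21 stations, 464 OTUs, library sizes log-normal around 105,253 reads
#' (cv 0.3), a power-law dominance spectrum whose exponent (1.3343) puts 78%
#' of the reads into the top-20 OTUs, three planted NCP effects
#' beta = (6, -5, 4) mmol C m-2 day-1 per standardized-abundance unit on
#' dominance ranks 2, 5 and 9 with residual sd 1, NCP intercept
#' 20 mmol C m-2 day-1, MLD uniform on 11-22 m, and a 60-day AR(1) daily
#' wind history (mean 6.5 m s-1, lag-1 coefficient 0.6, innovation sd 2).
#'
#' @param nStations,nOtus problem size.
#' @param meanDepth expected reads per sample.
#' @param dominanceExponent power-law exponent for the default dominance
#'   weights w_j = j^-s (ignored when `dominanceWeights` given).
#' @param dominanceWeights explicit positive weights, length nOtus.
#' @param basisLogSd marginal sd of the log basis (scalar or length nOtus).
#' @param basisCorrelation optional correlation matrix of the log basis
#'   (default identity).
#' @param plantedEffects data.frame(otu = index, beta = effect).
#' @param noiseSd residual NCP sd, mmol C m-2 day-1.
#' @param alpha NCP intercept, mmol C m-2 day-1.
#' @param mldRange MLD range in m.
#' @param windAr1 numeric(3): mean, lag-1 coefficient, innovation sd.
#' @param windDays wind-history length in days.
#' @param pocParams numeric(3): intercept (mmol C m-3), biomass scale,
#'   lognormal noise sd of the POC model.
#' @param seed master seed.
#' @return A validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nStations = 21, nOtus = 464, meanDepth = 105253,
                           dominanceExponent = 1.3343,
                           dominanceWeights = NULL,
                           basisLogSd = 0.6, basisCorrelation = NULL,
                           plantedEffects = data.frame(
                               otu = c(2L, 5L, 9L), beta = c(6, -5, 4)),
                           noiseSd = 1, alpha = 20,
                           mldRange = c(11, 22),
                           windAr1 = c(6.5, 0.6, 2), windDays = 60,
                           pocParams = c(4, 6, 0.2), seed = 1L) {
    if (is.null(dominanceWeights))
        dominanceWeights <- seq_len(nOtus)^(-dominanceExponent)
    dominanceWeights <- dominanceWeights / sum(dominanceWeights)
    sdVec <- rep_len(basisLogSd, nOtus)
    if (is.null(basisCorrelation)) {
        cov <- diag(sdVec^2, nOtus)
    } else {
        if (!all(dim(basisCorrelation) == nOtus))
            stop("basisCorrelation must be nOtus x nOtus")
        cov <- outer(sdVec, sdVec) * basisCorrelation
    }
    new("ScenarioConfig", nStations = as.integer(nStations),
        nOtus = as.integer(nOtus), meanDepth = meanDepth,
        dominanceWeights = dominanceWeights, basisLogCov = cov,
        plantedEffects = plantedEffects, noiseSd = noiseSd, alpha = alpha,
        mldRange = as.numeric(mldRange), windAr1 = as.numeric(windAr1),
        windDays = as.integer(windDays), pocParams = as.numeric(pocParams),
        seed = as.integer(seed))
}

## deterministic per-stage substream seed from the master seed
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

## symmetric matrix square root; errors on non-PSD input
matrixSqrt <- function(sigma) {
    offdiag <- sigma; diag(offdiag) <- 0
    if (all(offdiag == 0)) {
        if (any(diag(sigma) < 0))
            stop("basis log-covariance is not positive semi-definite")
        return(diag(sqrt(diag(sigma)), nrow(sigma)))
    }
    e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
        stop("basis log-covariance is not positive semi-definite")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Basis correlation structures for coupled and loose communities
#'
#' Helpers for the co-occurrence contrast scenarios.
#' `coupledBasisCorrelation` puts a core-periphery block on a single latent
#' factor: `coreSize` OTUs load strongly (`coreRange`) so every core pair's
#' log-basis correlation `l_i * l_j` sits well above typical network
#' thresholds, while `peripherySize` OTUs load moderately
#' (`peripheryRange`), giving core-periphery pairs of mixed strength. The
#' thresholded network is a dense hairball with hubs: many edges, high
#' clustering and centralization, short paths — a tightly coupled
#' community. `ringBasisCorrelation` places the first `ringSize` OTUs on a
#' circle with geometrically decaying correlation `adjacentCor^distance`,
#' whose thresholded network is a sparse degree-regular ring: few edges, no
#' triangles, long paths — a loosely coupled community. Remaining OTUs are
#' independent.
#'
#' @param nOtus total OTUs.
#' @param coreSize,peripherySize,ringSize OTUs in the structured block.
#' @param coreRange,peripheryRange factor-loading ranges.
#' @param adjacentCor adjacent correlation on the ring.
#' @param seed seed for the loading draw.
#' @return An `nOtus` x `nOtus` correlation matrix.
#' @name contrastScenarios
NULL

#' @rdname contrastScenarios
#' @export
coupledBasisCorrelation <- function(nOtus = 30, coreSize = 8,
                                    peripherySize = 7,
                                    coreRange = c(0.95, 0.995),
                                    peripheryRange = c(0.82, 0.92),
                                    seed = 1L) {
    set.seed(stageSeed(seed, "coupled-loadings"))
    l <- c(runif(coreSize, coreRange[1], coreRange[2]),
           runif(peripherySize, peripheryRange[1], peripheryRange[2]))
    corr <- diag(nOtus)
    block <- seq_along(l)
    corr[block, block] <- outer(l, l)
    diag(corr) <- 1
    corr
}

#' @rdname contrastScenarios
#' @export
ringBasisCorrelation <- function(nOtus = 30, ringSize = 12,
                                 adjacentCor = 0.86) {
    idx <- seq_len(ringSize)
    ring <- outer(idx, idx, function(i, j)
        adjacentCor^pmin(abs(i - j), ringSize - abs(i - j)))
    corr <- diag(nOtus)
    corr[idx, idx] <- ring
    corr
}

## PalmerLTER-style "grid line.grid station" labels
stationLabels <- function(n) {
    lines <- 600 - 100 * ((seq_len(n) - 1) %/% 5)
    sts <- 40 + 20 * ((seq_len(n) - 1) %% 5)
    sprintf("%03d.%03d", lines, sts)
}

#' Generate compositional OTU counts from a log-normal basis
#'
#' Per station, basis abundances are `dominanceWeights * exp(z)` with
#' `z ~ MVN(0, basisLogCov)`; the basis is closed to a composition and
#' realized as multinomial reads at a depth drawn log-normally around
#' `meanDepth` (cv 0.3). This is the compositional regime assumed by SparCC:
#' observed counts only carry relative information about the basis.
#'
#' @param config a [ScenarioConfig-class].
#' @return list with `counts` (OTUs x stations integer matrix),
#'   `basis` (OTUs x stations latent absolute abundances),
#'   `depths` (reads per station), and `trueBasisCorrelations`
#'   (correlation matrix of the log basis implied by `basisLogCov`).
#' @export
generateCompositions <- function(config) {
    stopifnot(is(config, "ScenarioConfig"))
    validObject(config)
    set.seed(stageSeed(config@seed, "compositions"))
    n <- config@nStations; p <- config@nOtus
    root <- matrixSqrt(config@basisLogCov)
    z <- matrix(rnorm(n * p), n, p) %*% root      # stations x OTUs
    basis <- t(config@dominanceWeights * t(exp(z)))  # stations x OTUs
    comp <- basis / rowSums(basis)
    cv <- 0.3
    sdlog <- sqrt(log(1 + cv^2))
    depths <- round(exp(rnorm(n, log(config@meanDepth) - sdlog^2 / 2,
                              sdlog)))
    counts <- vapply(seq_len(n), function(i)
        as.numeric(stats::rmultinom(1, depths[i], comp[i, ])),
        numeric(p))
    dimnames(counts) <- list(paste0("OTU_", seq_len(p)), stationLabels(n))
    sdv <- sqrt(diag(config@basisLogCov))
    corr <- config@basisLogCov / outer(sdv, sdv)
    corr[outer(sdv, sdv) == 0] <- 0
    diag(corr) <- 1
    dimnames(corr) <- list(rownames(counts), rownames(counts))
    list(counts = counts, basis = t(basis), depths = depths,
         trueBasisCorrelations = corr)
}

#' Plant a sparse linear NCP link on simulated counts
#'
#' Standardizes the planted OTUs' relative abundances (mean 0, sd 1) and sets
#' `trueNcp = alpha + sum_j beta_j z_j + eps`, `eps ~ N(0, noiseSd^2)`.
#' POC is generated positive and correlated with total biomass:
#' `poc = c0 + c1 * (biomass / mean biomass) * lognormal(1, sd)`, so NCP/POC
#' has a positive denominator.
#'
#' @param counts OTUs x stations count matrix.
#' @param config a [ScenarioConfig-class].
#' @param biomass optional per-station total basis biomass; defaults to the
#'   per-station read totals.
#' @return list with `trueNcp`, `poc`, and `trueEffects` (named over all
#'   OTUs, exact zeros off the planted support).
#' @export
plantNcpLink <- function(counts, config, biomass = NULL) {
    stopifnot(is(config, "ScenarioConfig"))
    set.seed(stageSeed(config@seed, "ncp-link"))
    n <- ncol(counts)
    rel <- t(sweep(counts, 2, colSums(counts), `/`)) * 100  # stations x OTUs
    eff <- config@plantedEffects
    trueEffects <- setNames(numeric(nrow(counts)), rownames(counts))
    mu <- rep(config@alpha, n)
    if (nrow(eff)) {
        cols <- rel[, eff$otu, drop = FALSE]
        sds <- apply(cols, 2, sd)
        if (any(sds == 0))
            stop("zero-variance OTU among planted predictors: ",
                 paste(rownames(counts)[eff$otu[sds == 0]], collapse = ", "))
        zc <- scale(cols)
        mu <- mu + drop(zc %*% eff$beta)
        trueEffects[eff$otu] <- eff$beta
    }
    trueNcp <- mu + rnorm(n, 0, config@noiseSd)
    if (is.null(biomass)) biomass <- colSums(counts)
    pp <- config@pocParams
    lnoise <- exp(rnorm(n, -pp[3]^2 / 2, pp[3]))
    poc <- pp[1] + pp[2] * (biomass / mean(biomass)) * lnoise
    list(trueNcp = as.numeric(trueNcp), poc = as.numeric(poc),
         trueEffects = trueEffects)
}

#' Generate per-station physical environment
#'
#' Per station: MLD uniform on `mldRange`; a `windDays`-long AR(1) daily wind
#' series (stationary start, floored at 0.5 m s-1); polar-surface temperature
#' and salinity; a linearized sigma-theta; and a CTD density profile whose
#' density-threshold MLD (0.03 kg m-3) equals the drawn MLD exactly.
#'
#' @param config a [ScenarioConfig-class].
#' @return list with `stations` (data.frame: station_id, timestamp,
#'   temperature, salinity, sigma_theta, density, mld), `winds`
#'   (matrix stations x windDays, most recent last), and `profiles`
#'   (data.frame: station_id, depth_m, sigma_theta).
#' @export
generateStationEnvironment <- function(config) {
    stopifnot(is(config, "ScenarioConfig"))
    validObject(config)
    set.seed(stageSeed(config@seed, "environment"))
    n <- config@nStations
    ids <- stationLabels(n)
    mld <- runif(n, config@mldRange[1], config@mldRange[2])
    temperature <- runif(n, -1.5, 2.5)
    salinity <- runif(n, 33.2, 34.3)
    sigma0 <- 27.4 - 0.06 * temperature + 0.78 * (salinity - 34)
    density <- 1000 + sigma0
    wa <- config@windAr1
    winds <- t(vapply(seq_len(n), function(i) {
        w <- numeric(config@windDays)
        marginalSd <- if (wa[2] > 0) wa[3] / sqrt(1 - wa[2]^2) else wa[3]
        w[1] <- wa[1] + rnorm(1, 0, marginalSd)
        for (d in seq_len(config@windDays - 1))
            w[d + 1] <- wa[1] + wa[2] * (w[d] - wa[1]) + rnorm(1, 0, wa[3])
        pmax(w, 0.5)
    }, numeric(config@windDays)))
    rownames(winds) <- ids
    profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
        ## kink at mld-1 with slope 0.03/m; threshold crossing interpolates
        ## exactly to the drawn MLD
        z <- sort(unique(c(2, 6, mld[i] - 1, mld[i] + 1, 30, 45, 60)))
        data.frame(station_id = ids[i], depth_m = z,
                   sigma_theta = sigma0[i] +
                       0.03 * pmax(0, z - (mld[i] - 1)))
    }))
    stations <- data.frame(
        station_id = ids,
        timestamp = as.Date("2014-01-05") + seq_len(n) - 1,
        temperature = temperature, salinity = salinity,
        sigma_theta = sigma0, density = density, mld = mld)
    list(stations = stations, winds = winds, profiles = profiles)
}

#' Simulate a full scenario with planted ground truth
#'
#' Chains [generateCompositions], [generateStationEnvironment] and
#' [plantNcpLink] (each on an independent substream of the master seed) and
#' derives a consistent O2/Ar observation per station: the measured ratio is
#' back-computed from the planted NCP through the same flux equations the
#' analysis applies, so running [ncpStations] on the bundle recovers
#' `trueNcp` up to floating-point error.
#'
#' @param config a [ScenarioConfig-class].
#' @param pq photosynthetic quotient used in the back-computation.
#' @return A [SyntheticBundle-class].
#' @examples
#' bundle <- simulateScenario(scenarioConfig(nOtus = 50, seed = 7))
#' bundle
#' @export
simulateScenario <- function(config = scenarioConfig(), pq = 1.4) {
    comp <- generateCompositions(config)
    env <- generateStationEnvironment(config)
    link <- plantNcpLink(comp$counts, config,
                         biomass = colSums(comp$basis))
    st <- env$stations
    o2sat <- o2SaturationConcentration(st$temperature, st$salinity,
                                       st$density)
    kW <- vapply(seq_len(nrow(st)), function(i)
        weightedPistonVelocity(
            pistonVelocity(env$winds[i, ], st$temperature[i]), st$mld[i]),
        0)
    delta <- (link$trueNcp * pq) / (kW * o2sat) * 100
    st$o2ar_sat <- 22.0
    st$o2ar_sample <- st$o2ar_sat * (1 + delta / 100)
    st$poc <- link$poc
    new("SyntheticBundle",
        otu = OtuTable(comp$counts), stations = st, winds = env$winds,
        profiles = env$profiles, trueNcp = link$trueNcp,
        trueEffects = link$trueEffects,
        trueBasisCorrelations = comp$trueBasisCorrelations,
        config = config)
}

#' @describeIn SyntheticBundle planted effect vector (exact zeros off the
#'   support).
#' @param x a SyntheticBundle.
#' @export
setMethod("trueEffects", "SyntheticBundle", function(x) x@trueEffects)

#' @describeIn SyntheticBundle planted NCP vector, mmol C m-2 day-1.
#' @export
setMethod("trueNcp", "SyntheticBundle", function(x) x@trueNcp)

setMethod("show", "SyntheticBundle", function(object) {
    cfg <- object@config
    cat("SyntheticBundle:", cfg@nStations, "stations x", cfg@nOtus,
        "OTUs\n")
    nz <- sum(object@trueEffects != 0)
    cat("  planted effects:", nz, "| NCP range [",
        round(min(object@trueNcp), 2), ",", round(max(object@trueNcp), 2),
        "] mmol C m-2 day-1\n")
    cat("  master seed:", cfg@seed, "\n")
})

#' Write/read the station and wind tables
#'
#' Station tables round-trip as CSV; wind histories as long-format CSV
#' (station_id, day_offset, u10) with day_offset -(windDays-1)..0, most
#' recent day 0.
#'
#' @param stations,winds objects as in [SyntheticBundle-class].
#' @param path output file.
#' @return `path`, invisibly (writers); the parsed object (readers).
#' @name stationIo
NULL

#' @rdname stationIo
#' @export
writeStationTable <- function(stations, path) {
    write.csv(stations, path, row.names = FALSE)
    invisible(path)
}

#' @rdname stationIo
#' @export
readStationTable <- function(path) {
    read.csv(path, check.names = FALSE,
             colClasses = c(station_id = "character"))
}

#' @rdname stationIo
#' @export
writeWindHistory <- function(winds, path) {
    nd <- ncol(winds)
    long <- data.frame(
        station_id = rep(rownames(winds), each = nd),
        day_offset = rep(seq_len(nd) - nd, times = nrow(winds)),
        u10 = as.vector(t(winds)))
    write.csv(long, path, row.names = FALSE)
    invisible(path)
}

#' @rdname stationIo
#' @export
readWindHistory <- function(path) {
    long <- read.csv(path, colClasses = c(station_id = "character"))
    ids <- unique(long$station_id)
    windLongToMatrix(long, ids)
}

#' Write the ground-truth side of a bundle as plain text (for tests)
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenarioTruth <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(station_id = bundle@stations$station_id,
                         true_ncp = bundle@trueNcp),
              file.path(dir, "true_ncp.csv"), row.names = FALSE)
    write.csv(data.frame(otu_id = names(bundle@trueEffects),
                         beta = unname(bundle@trueEffects)),
              file.path(dir, "true_effects.csv"), row.names = FALSE)
    utils::write.table(bundle@trueBasisCorrelations,
                       file.path(dir, "true_basis_correlations.tsv"),
                       sep = "\t", quote = FALSE)
    invisible(dir)
}
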