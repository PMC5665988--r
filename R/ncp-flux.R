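#' Biological oxygen supersaturation from O2/Ar ratios
#'
#' Delta(O2/Ar) = (sample/saturation - 1) x 100, in percent. Argon
#' normalization removes solubility-driven (physical) O2 signals, so the
#' residual supersaturation is attributed to net biological production.
#'
#' @param sampleRatio measured O2/Ar ratio.
#' @param satRatio equilibrium O2/Ar ratio at in-situ temperature/salinity.
#' @return Percent supersaturation (negative for net heterotrophy).
#' @examples
#' deltaO2Ar(21, 20)  # +5 %
#' @export
deltaO2Ar <- function(sampleRatio, satRatio) {
    if (any(satRatio <= 0)) stop("satRatio must be positive")
    (sampleRatio / satRatio - 1) * 100
}

#' Schmidt number of O2 in seawater
#'
#' Quartic polynomial in temperature for O2 in seawater (salinity 35),
#' Wanninkhof (2014) coefficient set; Sc(20 C) = 568.
#'
#' @param temperature deg C.
#' @return Dimensionless Schmidt number.
#' @export
schmidtO2 <- function(temperature) {
    1920.4 - 135.6 * temperature + 5.2122 * temperature^2 -
        0.10939 * temperature^3 + 0.00093777 * temperature^4
}

#' Equilibrium O2 concentration of seawater
#'
#' Garcia-Gordon (1992) solubility fit with the Benson-Krause coefficient
#' set, yielding umol O2 per kg at one atmosphere of water-saturated air.
#' The per-mass value is converted to a volumetric concentration with the
#' supplied mixed-layer density (this mirrors the explicit density factor in
#' the NCP flux formula; see [computeNcp]). Set `perMass = TRUE` to get the
#' raw umol/kg value instead.
#'
#' @param temperature deg C.
#' @param salinity PSU.
#' @param density mixed-layer density, kg m-3 (ignored when `perMass`).
#' @param perMass return umol O2 kg-1 instead of mmol O2 m-3.
#' @return Saturation concentration, mmol O2 m-3 (or umol kg-1). A warning
#'   is raised outside the fit's comfortable T/S range.
#' @examples
#' o2SaturationConcentration(2, 34, 1027)
#' @export
o2SaturationConcentration <- function(temperature, salinity, density = 1027,
                                      perMass = FALSE) {
    if (any(temperature < -2 | temperature > 40) ||
        any(salinity < 0 | salinity > 42))
        warning("temperature/salinity outside the solubility fit range")
    ts <- log((298.15 - temperature) / (273.15 + temperature))
    A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
    B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
    C0 <- -2.75915e-7
    poly <- function(x, co) Reduce(function(acc, k) acc + co[k + 1] * x^k,
                                   seq_along(co) - 1, 0)
    umolkg <- exp(poly(ts, A) + salinity * poly(ts, B) + C0 * salinity^2)
    if (perMass) umolkg else umolkg * density / 1000
}

#' Gas-transfer (piston) velocity for O2
#'
#' Quadratic wind-speed law k = a * u10^2 * (Sc/660)^(-1/2), with
#' a = 0.251 cm hr-1 (m s-1)^-2 (the reanalysis-wind calibration), converted
#' to m day-1. The Schmidt-number function is injectable for testing and for
#' alternative gases.
#'
#' @param u10 wind speed at 10 m, m s-1 (vectorized).
#' @param temperature deg C (scalar or vectorized with u10).
#' @param transferCoef quadratic coefficient a, cm hr-1 (m s-1)^-2.
#' @param schmidt function(temperature) giving the Schmidt number.
#' @return Piston velocity, m day-1.
#' @examples
#' pistonVelocity(8, 0)
#' @export
pistonVelocity <- function(u10, temperature, transferCoef = 0.251,
                           schmidt = schmidtO2) {
    if (any(u10 < 0)) stop("u10 must be nonnegative")
    kCmHr <- transferCoef * u10^2 * (schmidt(temperature) / 660)^(-0.5)
    kCmHr * 24 / 100  # cm hr-1 -> m day-1
}

#' Ventilation-weighted piston velocity over a wind history
#'
#' Walking backwards from the sampling day, each earlier day's piston
#' velocity is weighted by the fraction of the mixed layer not yet ventilated
#' by the more recent days: w_i = prod_{j > i} (1 - f_j) with
#' f_j = min(k_j * dt / mld, 1) and dt = 1 day; weights are normalized to
#' sum to one. For a constant series this reduces to the plain value.
#'
#' @param kDaily daily piston velocities, m day-1, most recent last.
#' @param mld mixed layer depth, m.
#' @return Weighted piston velocity, m day-1.
#' @export
weightedPistonVelocity <- function(kDaily, mld) {
    if (!length(kDaily)) stop("kDaily must be nonempty")
    if (any(kDaily < 0)) stop("kDaily must be nonnegative")
    if (mld <= 0) stop("mld must be positive")
    f <- pmin(kDaily / mld, 1)
    n <- length(f)
    ## w[i] = prod_{j>i} (1 - f_j); w[n] = 1
    tailProd <- rev(cumprod(rev(1 - f)))        # prod_{j>=i}(1-f_j)
    w <- c(tailProd[-1], 1)
    sum(w * kDaily) / sum(w)
}

#' Mixed layer depth by the density-threshold criterion
#'
#' Shallowest depth at which sigma-theta exceeds the surface (shallowest
#' level) value by at least `threshold` (default 0.03 kg m-3), linearly
#' interpolated between the bracketing levels.
#'
#' @param depth depths in m, strictly increasing.
#' @param sigmaTheta potential density anomaly at each depth, kg m-3.
#' @param threshold density offset, kg m-3.
#' @return MLD in m. Errors when the threshold is never crossed.
#' @examples
#' mixedLayerDepth(c(0, 5, 10, 20), 27 + 0.003 * c(0, 5, 10, 20))
#' @export
mixedLayerDepth <- function(depth, sigmaTheta, threshold = 0.03) {
    if (length(depth) < 2) stop("profile needs at least two levels")
    if (length(depth) != length(sigmaTheta))
        stop("depth and sigmaTheta lengths differ")
    if (is.unsorted(depth, strictly = TRUE))
        stop("profile must be sorted by strictly increasing depth")
    target <- sigmaTheta[1] + threshold
    idx <- which(sigmaTheta >= target)[1]
    if (is.na(idx)) stop("MLD undefined: density threshold never crossed")
    if (idx == 1) return(depth[1])
    d0 <- depth[idx - 1]; d1 <- depth[idx]
    s0 <- sigmaTheta[idx - 1]; s1 <- sigmaTheta[idx]
    d0 + (target - s0) / (s1 - s0) * (d1 - d0)
}

#' NCP from the O2 mass balance at the surface ocean
#'
#' NCP_O2 = k * \[O2\]sat * Delta(O2/Ar)/100 (mmol O2 m-2 day-1), assuming
#' steady state and no vertical mixing across the mixed-layer base; converted
#' to carbon with the photosynthetic quotient, NCP_C = NCP_O2 / pq.
#'
#' @param kWeighted (weighted) piston velocity, m day-1.
#' @param o2satConc volumetric saturation concentration, mmol O2 m-3
#'   (per-mass solubility already multiplied by density; see
#'   [o2SaturationConcentration]).
#' @param deltaPct biological supersaturation, percent.
#' @param pq photosynthetic quotient O2/C (default 1.4; 1.0 is the
#'   sensitivity case for regions where the effective PQ is lower).
#' @return list with `ncp_o2` and `ncp_c`.
#' @examples
#' computeNcp(2, 350, 5)  # 35 mmol O2, 25 mmol C m-2 day-1
#' @export
computeNcp <- function(kWeighted, o2satConc, deltaPct, pq = 1.4) {
    if (any(pq <= 0)) stop("pq must be positive")
    if (any(kWeighted < 0)) stop("kWeighted must be nonnegative")
    if (any(o2satConc <= 0)) stop("o2satConc must be positive")
    ncpO2 <- kWeighted * o2satConc * deltaPct / 100
    list(ncp_o2 = ncpO2, ncp_c = ncpO2 / pq)
}

#' Mixed-layer O2 residence time
#'
#' @param mld mixed layer depth, m.
#' @param kWeighted piston velocity, m day-1.
#' @return Residence time in days (mld / k).
#' @export
residenceTime <- function(mld, kWeighted) {
    if (any(kWeighted <= 0)) stop("kWeighted must be positive")
    mld / kWeighted
}

#' POC-normalized NCP
#'
#' NCP/POC (m day-1) is the biomass-normalized export-potential index:
#' mmol C m-2 day-1 divided by mmol C m-3.
#'
#' @param ncpC carbon NCP, mmol C m-2 day-1.
#' @param poc particulate organic carbon, mmol C m-3.
#' @return NCP/POC in m day-1.
#' @export
normalizeNcp <- function(ncpC, poc) {
    if (any(poc <= 0)) stop("poc must be positive")
    ncpC / poc
}

#' Average an underway trace around a sampling time
#'
#' Mean of a continuous underway signal within +/- `halfWindow` days of the
#' sampling instant (default 5 minutes, i.e. a 10-minute window).
#'
#' @param time numeric times (days) of the trace.
#' @param value trace values.
#' @param at sampling time (days).
#' @param halfWindow half-width of the averaging window, days.
#' @return Mean value within the window; errors when the window is empty.
#' @export
underwayAverage <- function(time, value, at, halfWindow = 5 / 1440) {
    sel <- abs(time - at) <= halfWindow + 1e-12  # inclusive boundary
    if (!any(sel)) stop("no trace points within the averaging window")
    mean(value[sel])
}

#' Per-station NCP pipeline
#'
#' Runs the full flux chain for a station table: Delta(O2/Ar), O2 saturation
#' concentration, daily piston velocities from the wind history,
#' ventilation-weighted k, NCP in O2 and carbon units, O2 residence time and
#' NCP/POC. When CTD `profiles` are supplied, MLD is (re)computed from them
#' by the density-threshold criterion; otherwise the `mld` column of
#' `stations` is used.
#'
#' @param stations data.frame with columns station_id, temperature, salinity,
#'   density, o2ar_sample, o2ar_sat, poc, and (unless profiles given) mld.
#' @param winds either a matrix (stations x days, most recent last, rows in
#'   station order) or a long data.frame (station_id, day_offset, u10).
#' @param profiles optional data.frame (station_id, depth_m, sigma_theta).
#' @param pq photosynthetic quotient (default 1.4).
#' @param transferCoef gas-transfer coefficient, cm hr-1 (m s-1)^-2.
#' @param mldThreshold density threshold for MLD, kg m-3.
#' @return data.frame, one row per station: station_id, delta_o2ar,
#'   o2sat_conc, schmidt, mld, k_weighted, ncp_o2, ncp_c, residence_days,
#'   ncp_over_poc.
#' @export
ncpStations <- function(stations, winds, profiles = NULL, pq = 1.4,
                        transferCoef = 0.251, mldThreshold = 0.03) {
    need <- c("station_id", "temperature", "salinity", "density",
              "o2ar_sample", "o2ar_sat", "poc")
    miss <- setdiff(need, names(stations))
    if (length(miss))
        stop("stations is missing column(s): ", paste(miss, collapse = ", "))
    if (is.data.frame(winds)) {
        winds <- windLongToMatrix(winds, stations$station_id)
    } else if (is.null(rownames(winds))) {
        rownames(winds) <- stations$station_id
    }
    n <- nrow(stations)
    out <- lapply(seq_len(n), function(i) {
        st <- stations[i, ]
        mld <- if (!is.null(profiles)) {
            pr <- profiles[profiles$station_id == st$station_id, ]
            if (!nrow(pr)) stop("no profile for station ", st$station_id)
            pr <- pr[order(pr$depth_m), ]
            mixedLayerDepth(pr$depth_m, pr$sigma_theta, mldThreshold)
        } else {
            if (!"mld" %in% names(stations))
                stop("stations needs an mld column when profiles are absent")
            st$mld
        }
        delta <- deltaO2Ar(st$o2ar_sample, st$o2ar_sat)
        o2sat <- o2SaturationConcentration(st$temperature, st$salinity,
                                           st$density)
        kDaily <- pistonVelocity(winds[as.character(st$station_id), ],
                                 st$temperature, transferCoef)
        kW <- weightedPistonVelocity(kDaily, mld)
        flux <- computeNcp(kW, o2sat, delta, pq)
        data.frame(station_id = st$station_id, delta_o2ar = delta,
                   o2sat_conc = o2sat, schmidt = schmidtO2(st$temperature),
                   mld = mld, k_weighted = kW, ncp_o2 = flux$ncp_o2,
                   ncp_c = flux$ncp_c,
                   residence_days = residenceTime(mld, kW),
                   ncp_over_poc = normalizeNcp(flux$ncp_c, st$poc))
    })
    do.call(rbind, out)
}

## long (station_id, day_offset, u10) -> matrix stations x days
windLongToMatrix <- function(long, stationIds) {
    need <- c("station_id", "day_offset", "u10")
    if (!all(need %in% names(long)))
        stop("wind table needs columns: ", paste(need, collapse = ", "))
    ids <- as.character(stationIds)
    days <- sort(unique(long$day_offset))
    m <- matrix(NA_real_, length(ids), length(days),
                dimnames = list(ids, as.character(days)))
    key <- cbind(match(as.character(long$station_id), ids),
                 match(long$day_offset, days))
    m[key] <- long$u10
    if (any(is.na(m))) stop("wind history incomplete for some station/day")
    m
}
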