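#' Specific growth rate from log-linear fluorescence
#'
#' Slope of the ordinary least-squares fit of ln(fluorescence) against time
#' during exponential phase, in day-1, with its standard error. Window
#' selection (e.g. days 3-7) is the caller's responsibility.
#'
#' @param times days.
#' @param fluorescence in vivo chlorophyll a fluorescence, relative units
#'   (> 0).
#' @return list: `rate` (day-1), `se`, `r2`, `n`.
#' @examples
#' t <- 0:6
#' specificGrowthRate(t, 10 * exp(0.3 * t))$rate  # 0.3
#' @export
specificGrowthRate <- function(times, fluorescence) {
    if (length(times) != length(fluorescence))
        stop("times and fluorescence lengths differ")
    if (length(times) < 3) stop("need at least 3 time points")
    if (diff(range(times)) < 2) stop("time points must span at least 2 days")
    if (any(fluorescence <= 0)) stop("fluorescence must be positive")
    ## suppressed warning: summary.lm complains on an exactly exponential
    ## series (zero residual), which is a legitimate input here
    fit <- suppressWarnings(summary(lm(log(fluorescence) ~ times)))
    list(rate = unname(fit$coefficients["times", "Estimate"]),
         se = unname(fit$coefficients["times", "Std. Error"]),
         r2 = fit$r.squared, n = length(times))
}

#' Growth-rate table over isolates, treatments and replicates
#'
#' Applies [specificGrowthRate] within each isolate x treatment x replicate
#' group of a tidy growth series table.
#'
#' @param series data.frame with columns isolate, treatment, replicate, day,
#'   fluorescence.
#' @return data.frame: isolate, treatment, replicate, rate, se, r2, n
#'   (TSV-writable).
#' @export
growthRateTable <- function(series) {
    need <- c("isolate", "treatment", "replicate", "day", "fluorescence")
    miss <- setdiff(need, names(series))
    if (length(miss))
        stop("series is missing column(s): ", paste(miss, collapse = ", "))
    grp <- interaction(series$isolate, series$treatment, series$replicate,
                       drop = TRUE)
    rows <- lapply(split(series, grp), function(d) {
        r <- specificGrowthRate(d$day, d$fluorescence)
        data.frame(isolate = d$isolate[1], treatment = d$treatment[1],
                   replicate = d$replicate[1], rate = r$rate, se = r$se,
                   r2 = r$r2, n = r$n)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Biovolume of a centric diatom (cylinder model)
#'
#' V = pi * (d/2)^2 * h.
#'
#' @param diameter valve diameter, um.
#' @param height pervalvar height, um.
#' @return Volume in um^3.
#' @export
biovolumeCylinder <- function(diameter, height) {
    if (any(diameter <= 0) || any(height <= 0))
        stop("dimensions must be positive")
    pi * (diameter / 2)^2 * height
}

#' Biovolume of a pennate diatom (elliptic prism model)
#'
#' V = (pi/4) * AL * TW * PH, the elliptic cross-section (apical length x
#' transapical width) times the pervalvar height.
#'
#' @param apicalLength AL, um.
#' @param transapicalWidth TW, um.
#' @param pervalvarHeight PH, um.
#' @return Volume in um^3.
#' @export
biovolumeEllipticPrism <- function(apicalLength, transapicalWidth,
                                   pervalvarHeight) {
    if (any(apicalLength <= 0) || any(transapicalWidth <= 0) ||
        any(pervalvarHeight <= 0))
        stop("dimensions must be positive")
    (pi / 4) * apicalLength * transapicalWidth * pervalvarHeight
}

#' Log10 biovolume ratio between two cells or isolates
#'
#' Orders-of-magnitude comparison used when contrasting large and small
#' diatoms.
#'
#' @param v1,v2 volumes, um^3.
#' @return log10(v1 / v2).
#' @export
biovolumeLogRatio <- function(v1, v2) {
    if (any(v1 <= 0) || any(v2 <= 0)) stop("volumes must be positive")
    log10(v1 / v2)
}
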