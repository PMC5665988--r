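#' Ordinary least squares with fit statistics
#'
#' Multiple linear regression with intercept, reporting RSS, R2, adjusted R2
#' and AICc. Errors on rank-deficient designs, listing the collinear
#' columns.
#'
#' @param X predictor matrix (observations x predictors, named columns).
#' @param y response vector.
#' @return list of class `"LinearModelFit"`: coefficients (with
#'   `(Intercept)`), rss, r2, adj_r2, aicc, predictors, n, p.
#' @export
fitMlr <- function(X, y) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    n <- nrow(X); p <- ncol(X)
    if (n <= p + 1) stop("need n > p + 1 observations")
    design <- cbind(`(Intercept)` = 1, X)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
        dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    fit <- lm.fit(design, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
    structure(list(coefficients = fit$coefficients, rss = rss, r2 = r2,
                   adj_r2 = adj,
                   aicc = if (n > p + 3) aicc(rss, n, p + 1) else NA_real_,
                   fitted = fit$fitted.values, residuals = fit$residuals,
                   predictors = colnames(X), n = n, p = p),
              class = "LinearModelFit")
}

#' @export
print.LinearModelFit <- function(x, ...) {
    cat("LinearModelFit:", x$p, "predictor(s), n =", x$n, "\n")
    cat("  R2 =", round(x$r2, 4), " adj R2 =", round(x$adj_r2, 4),
        " AICc =", round(x$aicc, 2), "\n")
    print(round(x$coefficients, 4))
    invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-likelihood AIC, `n * log(rss / n) + 2k`, with
#' `k = nParams + 1` (regression coefficients including the intercept, plus
#' one for the residual variance), plus the small-sample correction
#' `2k(k + 1) / (n - k - 1)`.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param nParams number of regression coefficients including the intercept.
#' @return AICc value (`-Inf` for an exact fit with rss = 0).
#' @export
aicc <- function(rss, n, nParams) {
    k <- nParams + 1
    if (n <= k + 1)
        stop("AICc undefined: need n > nParams + 2")
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Forward stepwise regression under AICc
#'
#' Greedy search starting from the intercept-only model: at each step the
#' predictor whose addition most lowers AICc enters; the search stops when
#' no addition lowers AICc (or when another coefficient would leave AICc
#' undefined at this sample size).
#'
#' @param X candidate predictor matrix (e.g. the top-20 dominance panel).
#' @param y response vector.
#' @return list: `selected` (ids in entry order), `trace` (data.frame with
#'   step, added, aicc), `model` (the final [fitMlr] fit, or NULL when no
#'   predictor entered).
#' @export
forwardStepwiseAicc <- function(X, y) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (!ncol(X)) stop("need at least one candidate predictor")
    n <- length(y)
    rss0 <- sum((y - mean(y))^2)
    current <- character(0)
    best <- aicc(rss0, n, 1)
    trace <- data.frame(step = 0L, added = "(null)", aicc = best,
                        stringsAsFactors = FALSE)
    repeat {
        candidates <- setdiff(colnames(X), current)
        ## adding one more coefficient must keep AICc defined
        if (!length(candidates) || n <= (length(current) + 2) + 2) break
        scores <- vapply(candidates, function(id) {
            fit <- try(fitMlr(X[, c(current, id), drop = FALSE], y),
                       silent = TRUE)
            if (inherits(fit, "try-error")) Inf else fit$aicc
        }, 0)
        if (min(scores) >= best) break
        pick <- candidates[which.min(scores)]
        current <- c(current, pick)
        best <- min(scores)
        trace <- rbind(trace, data.frame(step = length(current),
                                         added = pick, aicc = best))
    }
    model <- if (length(current))
        fitMlr(X[, current, drop = FALSE], y) else NULL
    list(selected = current, trace = trace, model = model)
}

#' Variance partitioning by adjusted-R2 decomposition
#'
#' For 2 or 3 disjoint predictor sets, fits the `2^m - 1` subset-union
#' models, computes each adjusted R2, and solves the inclusion-exclusion
#' system for the unique and shared fractions (the Venn-diagram
#' decomposition). Fractions may be negative and are reported as-is; by
#' construction they recompose the full-model adjusted R2.
#'
#' @param y response vector.
#' @param sets named list of 2 or 3 disjoint character vectors of column
#'   names of `X` (or integer columns).
#' @param X predictor matrix containing all set members.
#' @return list of class `"VariancePartition"`: `fractions` (named numeric
#'   over the 2^m - 1 Venn regions, e.g. `"A"`, `"A&B"`), `unionAdjR2`
#'   (adjusted R2 of every union model), `totalAdjR2`.
#' @export
variancePartition <- function(y, sets, X) {
    m <- length(sets)
    if (m < 2 || m > 3) stop("supply 2 or 3 predictor sets")
    if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(m)]
    ids <- unlist(sets)
    if (anyDuplicated(ids))
        stop("predictor sets must be disjoint: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    X <- as.matrix(X)
    adjR2 <- function(cols) fitMlr(X[, cols, drop = FALSE], y)$adj_r2
    ## all nonempty subsets of sets, as bitmasks 1..2^m-1
    masks <- seq_len(2^m - 1)
    members <- lapply(masks, function(b) which(bitwAnd(b, 2^(0:(m - 1))) > 0))
    unionR2 <- vapply(members, function(idx)
        adjR2(unlist(sets[idx])), 0)
    names(unionR2) <- vapply(members, function(idx)
        paste(names(sets)[idx], collapse = "+"), "")
    ## solve R(U) = sum_{S: S intersects U} x_S for the Venn fractions x_S
    A <- outer(masks, masks, function(u, s) as.numeric(bitwAnd(u, s) > 0))
    fractions <- solve(A, unionR2)
    names(fractions) <- vapply(members, function(idx)
        paste(names(sets)[idx], collapse = "&"), "")
    structure(list(fractions = fractions, unionAdjR2 = unionR2,
                   totalAdjR2 = unname(unionR2[length(unionR2)])),
              class = "VariancePartition")
}

#' @export
print.VariancePartition <- function(x, ...) {
    cat("VariancePartition: total adjusted R2 =",
        round(x$totalAdjR2, 4), "\n")
    print(round(x$fractions, 4))
    invisible(x)
}

#' Univariate r2 / p-value screen
#'
#' Ordinary least squares of `y` on each column alone, reporting r2 and the
#' two-sided slope p-value; constant columns are flagged and skipped.
#'
#' @param X matrix of candidate columns (e.g. taxon relative abundances).
#' @param y response vector.
#' @return data.frame: id, r2, p_value, flagged.
#' @export
simpleR2Scan <- function(X, y) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (length(y) < 3) stop("need at least 3 observations")
    rows <- lapply(colnames(X), function(id) {
        xj <- X[, id]
        if (sd(xj) == 0)
            return(data.frame(id = id, r2 = NA_real_, p_value = NA_real_,
                              flagged = TRUE))
        fit <- summary(lm(y ~ xj))
        data.frame(id = id, r2 = fit$r.squared,
                   p_value = fit$coefficients["xj", "Pr(>|t|)"],
                   flagged = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
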