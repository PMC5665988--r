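# Independent brute-force oracles used across the suite. These are written
# deliberately naively (loops, enumeration) and share no code with the
# package implementations they check.

## Reuer-style ventilation weighting, literal product form
bruteWeightedK <- function(k, mld) {
    n <- length(k)
    w <- numeric(n)
    for (i in seq_len(n)) {
        prod <- 1
        if (i < n) for (j in (i + 1):n) prod <- prod * (1 - min(k[j] / mld, 1))
        w[i] <- prod
    }
    sum(w * k) / sum(w)
}

## OLS through explicit normal equations
bruteOls <- function(X, y) {
    D <- cbind(1, X)
    solve(t(D) %*% D, t(D) %*% y)[, 1]
}

## Garcia-Gordon "combined fit" (ml/L scale) -- an independent coefficient
## set from the same solubility data; converted to mmol m-3 with density.
oracleO2SatMmolM3 <- function(temperature, salinity, density) {
    ts <- log((298.15 - temperature) / (273.15 + temperature))
    A <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
    B <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
    mlL <- exp(sum(A * ts^(0:5)) + salinity * sum(B * ts^(0:3)) -
               4.88682e-7 * salinity^2)
    umolkg <- mlL * 44.6596 / (density / 1000)
    umolkg * density / 1000   # umol kg-1 x kg m-3 -> umol m-3 -> mmol m-3
}

## ---- graph oracles over an adjacency matrix (no igraph) ----

bruteDistances <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    d[adj > 0] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

## enumerate all shortest paths s->t, return list of interior-vertex vectors
.enumShortest <- function(adj, d, s, t) {
    if (!is.finite(d[s, t])) return(list())
    if (s == t) return(list(integer(0)))
    out <- list()
    for (u in which(adj[s, ] > 0)) {
        if (d[u, t] == d[s, t] - 1) {
            for (tail in .enumShortest(adj, d, u, t)) {
                out[[length(out) + 1]] <-
                    if (u == t) tail else c(u, tail)
            }
        }
    }
    out
}

bruteBetweenness <- function(adj) {
    n <- nrow(adj)
    d <- bruteDistances(adj)
    btw <- numeric(n)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        paths <- .enumShortest(adj, d, s, t)
        if (!length(paths)) next
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            through <- sum(vapply(paths, function(p) v %in% p, TRUE))
            btw[v] <- btw[v] + through / length(paths)
        }
    }
    btw
}

bruteCloseness <- function(adj) {
    d <- bruteDistances(adj)
    vapply(seq_len(nrow(adj)), function(i) {
        reach <- is.finite(d[i, ]) & seq_len(ncol(d)) != i
        if (!any(reach)) NA_real_ else 1 / sum(d[i, reach])
    }, 0)
}

bruteClustering <- function(adj) {
    n <- nrow(adj)
    vapply(seq_len(n), function(i) {
        nb <- which(adj[i, ] > 0)
        k <- length(nb)
        if (k < 2) return(0)
        e <- sum(adj[nb, nb]) / 2
        2 * e / (k * (k - 1))
    }, 0)
}

bruteTopology <- function(adj) {
    n <- nrow(adj)
    e <- sum(adj) / 2
    deg <- rowSums(adj)
    d <- bruteDistances(adj)
    fin <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    list(n_nodes = n, n_edges = e,
         avg_connected_neighbors = 2 * e / n,
         density = 2 * e / (n * (n - 1)),
         centralization = if (n > 2)
             sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0,
         clustering_coefficient = mean(bruteClustering(adj)),
         characteristic_path_length = mean(fin),
         diameter = max(fin),
         betweenness = bruteBetweenness(adj),
         closeness = bruteCloseness(adj))
}

## wrap an adjacency matrix as a CooccurrenceNetwork (all edges pass)
networkFromAdjacency <- function(adj) {
    n <- nrow(adj)
    ids <- sprintf("OTU_%02d", seq_len(n))
    corr <- adj * 0.9
    diag(corr) <- 1
    dimnames(corr) <- list(ids, ids)
    pv <- matrix(0.001, n, n, dimnames = dimnames(corr))
    diag(pv) <- NA
    buildNetwork(corr, pv)
}

## small deterministic OTU toy table used by several io tests
toyOtuTable <- function() {
    m <- matrix(c(10, 30, 60,
                  20, 20, 60,
                  5,  45, 50), nrow = 3, byrow = FALSE,
                dimnames = list(c("otu1", "otu2", "otu3"),
                                c("sA", "sB", "sC")))
    OtuTable(m, taxonomy = c(
        otu1 = "Eukaryota;Ochrophyta;Bacillariophyceae;Fragilariopsis",
        otu2 = "Eukaryota;Ochrophyta;Mediophyceae;Thalassiosira",
        otu3 = "Eukaryota;Dinoflagellata;Dinophyceae;Gyrodinium"))
}
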