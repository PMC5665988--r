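#' Split samples at the median NCP/POC
#'
#' Low group: value <= median; high group: value >= median. For even n with
#' distinct values the halves are equal and disjoint; for odd n the median
#' sample belongs to both groups (both behaviors of the ambiguous inclusive
#' split are thereby represented). A warning flags degenerate splits caused
#' by heavy ties across the median.
#'
#' @param sampleIds sample labels.
#' @param values NCP/POC (or any split variable), same length.
#' @return list: `low`, `high` (id vectors), `median`.
#' @examples
#' medianSplit(letters[1:4], c(1, 2, 3, 4))
#' @export
medianSplit <- function(sampleIds, values) {
    if (length(sampleIds) != length(values))
        stop("sampleIds and values lengths differ")
    if (length(values) < 4) stop("need at least 4 samples")
    med <- median(values)
    low <- sampleIds[values <= med]
    high <- sampleIds[values >= med]
    n <- length(values)
    if (length(low) > 0.75 * n || length(high) > 0.75 * n)
        warning("ties across the median make the split strongly unequal")
    list(low = low, high = high, median = med)
}

#' Build a thresholded signed co-occurrence network
#'
#' Edge (i, j) iff |corr_ij| > `rThreshold` and p_ij passes the p-value rule
#' (default p < `pThreshold`; `pDirection = "greater"` keeps the
#' non-significant edges instead, for completeness). Edge sign comes from
#' the correlation; isolated nodes are dropped from the graph but recorded.
#'
#' @param corr symmetric correlation matrix with OTU dimnames.
#' @param pvals matching p-value matrix.
#' @param rThreshold correlation magnitude threshold (default 0.75).
#' @param pThreshold p-value threshold (default 0.05).
#' @param pDirection `"less"` (default) keeps p < threshold.
#' @param label source subset label (e.g. "low NCP/POC").
#' @return A [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(corr, pvals, rThreshold = 0.75, pThreshold = 0.05,
                         pDirection = c("less", "greater"),
                         label = NA_character_) {
    pDirection <- match.arg(pDirection)
    if (!all(dim(corr) == dim(pvals)))
        stop("corr and pvals dimensions differ")
    if (is.null(rownames(corr)))
        dimnames(corr) <- list(paste0("OTU_", seq_len(nrow(corr))),
                               paste0("OTU_", seq_len(nrow(corr))))
    if (!identical(rownames(corr), rownames(pvals)) &&
        !is.null(rownames(pvals)))
        stop("corr and pvals id order differ")
    ids <- rownames(corr)
    ut <- upper.tri(corr)
    pPass <- if (pDirection == "less") pvals < pThreshold
             else pvals > pThreshold
    pPass[is.na(pPass)] <- FALSE
    sel <- which(ut & abs(corr) > rThreshold & pPass, arr.ind = TRUE)
    edges <- data.frame(
        otu_a = ids[sel[, 1]], otu_b = ids[sel[, 2]],
        correlation = corr[sel],
        p_value = pvals[sel],
        sign = ifelse(corr[sel] >= 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    g <- if (nrow(edges))
        igraph::graph_from_data_frame(edges, directed = FALSE)
    else igraph::make_empty_graph(0, directed = FALSE)
    new("CooccurrenceNetwork", graph = g, edges = edges, allNodes = ids,
        label = label, rThreshold = rThreshold, pThreshold = pThreshold)
}

#' @describeIn CooccurrenceNetwork edge table.
#' @param x a CooccurrenceNetwork.
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' @describeIn CooccurrenceNetwork underlying igraph object.
#' @export
setMethod("networkGraph", "CooccurrenceNetwork", function(x) x@graph)

setMethod("show", "CooccurrenceNetwork", function(object) {
    cat("CooccurrenceNetwork", if (!is.na(object@label))
        paste0("[", object@label, "]"), ":",
        igraph::vcount(object@graph), "connected nodes,",
        nrow(object@edges), "edges (|r| >", object@rThreshold, ", p <",
        object@pThreshold, ")\n")
    if (nrow(object@edges))
        cat("  positive:", sum(object@edges$sign == "positive"),
            " negative:", sum(object@edges$sign == "negative"), "\n")
})

#' Topology metrics of a co-occurrence network
#'
#' Computes the comparison panel: node/edge counts by sign, average number
#' of connected neighbors `2E/N`, density `2E/(N(N-1))`, degree
#' centralization `sum(kmax - k_i) / ((N-1)(N-2))`, mean local clustering
#' coefficient (nodes of degree < 2 contribute 0), characteristic path
#' length and diameter over reachable pairs only (disconnected components
#' are averaged within), and per-node degree, betweenness and closeness
#' (closeness within components).
#'
#' @param network a [CooccurrenceNetwork-class] with at least one edge.
#' @param includeIsolates also count the isolated nodes dropped at build
#'   time (affects N-dependent metrics; default FALSE, matching the
#'   convention that isolated nodes are not part of the displayed network).
#' @return list of class `"TopologyMetrics"`: scalar fields plus a
#'   `nodeMetrics` data.frame.
#' @aliases topologyMetrics
#' @export
setMethod("topologyMetrics", "CooccurrenceNetwork",
          function(network, includeIsolates = FALSE) {
    g <- network@graph
    if (!igraph::ecount(g))
        stop("network has no edges; topology metrics undefined")
    if (includeIsolates) {
        iso <- setdiff(network@allNodes, igraph::V(g)$name)
        g <- igraph::add_vertices(g, length(iso), name = iso)
    }
    nNodes <- igraph::vcount(g)
    nEdges <- igraph::ecount(g)
    deg <- igraph::degree(g)
    centralization <- if (nNodes > 2)
        sum(max(deg) - deg) / ((nNodes - 1) * (nNodes - 2)) else 0
    localCc <- igraph::transitivity(g, type = "local", isolates = "zero")
    localCc[deg < 2] <- 0
    D <- igraph::distances(g)
    finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
    btw <- igraph::betweenness(g, directed = FALSE)
    cls <- suppressWarnings(igraph::closeness(g, mode = "all"))
    node <- data.frame(id = igraph::V(g)$name, degree = deg,
                       betweenness = btw, closeness = cls,
                       clustering = localCc, row.names = NULL)
    structure(list(
        n_nodes = nNodes, n_edges = nEdges,
        n_positive_edges = sum(network@edges$sign == "positive"),
        n_negative_edges = sum(network@edges$sign == "negative"),
        avg_connected_neighbors = 2 * nEdges / nNodes,
        density = 2 * nEdges / (nNodes * (nNodes - 1)),
        centralization = centralization,
        clustering_coefficient = mean(localCc),
        characteristic_path_length = mean(finite),
        diameter = max(finite),
        nodeMetrics = node), class = "TopologyMetrics")
})

#' @export
print.TopologyMetrics <- function(x, ...) {
    flds <- setdiff(names(x), "nodeMetrics")
    cat("TopologyMetrics:\n")
    for (f in flds) cat(" ", f, "=", signif(x[[f]], 5), "\n")
    invisible(x)
}

#' Side-by-side comparison of two network topologies
#'
#' @param low,high [CooccurrenceNetwork-class] objects or
#'   `"TopologyMetrics"` lists (e.g. the low and high NCP/POC subsets).
#' @param ... passed to [topologyMetrics] when networks are supplied.
#' @return data.frame: metric, low, high, ratio_low_high.
#' @export
compareNetworks <- function(low, high, ...) {
    toMetrics <- function(obj) {
        if (is(obj, "CooccurrenceNetwork")) topologyMetrics(obj, ...)
        else obj
    }
    low <- toMetrics(low); high <- toMetrics(high)
    flds <- setdiff(names(low), "nodeMetrics")
    data.frame(metric = flds,
               low = vapply(flds, function(f) low[[f]], 0),
               high = vapply(flds, function(f) high[[f]], 0),
               ratio_low_high = vapply(flds, function(f)
                   low[[f]] / high[[f]], 0),
               row.names = NULL)
}

#' Write network tables as TSV
#'
#' `writeEdgeList` writes (otu_a, otu_b, correlation, p_value, sign);
#' `writeNodeMetrics` the per-node table; `writeTopologyTable` a comparison
#' or metrics table. All are plain TSV loadable by standard graph tools.
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param metrics a `"TopologyMetrics"` list.
#' @param table a data.frame (e.g. from [compareNetworks]).
#' @param path output file.
#' @return `path`, invisibly.
#' @name networkIo
NULL

#' @rdname networkIo
#' @export
writeEdgeList <- function(network, path) {
    utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname networkIo
#' @export
writeNodeMetrics <- function(metrics, path) {
    utils::write.table(metrics$nodeMetrics, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname networkIo
#' @export
writeTopologyTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
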