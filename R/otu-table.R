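#' @describeIn OtuTable counts matrix (OTUs x samples).
#' @param x an OtuTable.
#' @export
setMethod("otuCounts", "OtuTable", function(x) assay(x, "counts"))

#' @describeIn OtuTable OTU ids.
#' @export
setMethod("otuIds", "OtuTable", function(x) rownames(x))

#' @describeIn OtuTable sample (station) ids.
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x))

#' @describeIn OtuTable named lineage strings, or NULL when absent.
#' @export
setMethod("taxonomy", "OtuTable", function(x) {
    rd <- rowData(x)
    if (!"taxonomy" %in% colnames(rd)) return(NULL)
    setNames(as.character(rd$taxonomy), rownames(x))
})

setMethod("show", "OtuTable", function(object) {
    cat("OtuTable:", nrow(object), "OTUs x", ncol(object), "samples\n")
    tot <- colSums(otuCounts(object))
    cat("  reads/sample: median", format(median(tot), big.mark = ","),
        " range [", min(tot), ", ", max(tot), "]\n", sep = "")
    cat("  taxonomy:", if (is.null(taxonomy(object))) "absent" else
        "present", "\n")
})

#' Read an OTU table in the QIIME-classic TSV dialect
#'
#' First column is the OTU id (header usually `#OTU ID`), remaining columns
#' are per-sample counts, with an optional trailing `taxonomy` (or
#' `Consensus Lineage`) column. Leading `#` comment lines before the header
#' are skipped.
#'
#' @param path file path.
#' @return An [OtuTable-class] (OTUs x samples).
#' @export
readOtuTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty OTU table: ", path)
    ## header = last leading comment line if any looks like a header,
    ## else the first non-comment line
    isComment <- grepl("^#", lines)
    headerIdx <- if (isComment[1]) max(which(cumsum(!isComment) == 0)) else 1L
    header <- strsplit(lines[headerIdx], "\t", fixed = TRUE)[[1]]
    dataLines <- lines[-seq_len(headerIdx)]
    if (!length(dataLines)) stop("no data rows in ", path)
    fields <- strsplit(dataLines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header))) {
        bad <- which(nf != length(header))[1]
        stop("ragged row at line ", headerIdx + bad, " of ", path,
             " (", nf[bad], " fields, expected ", length(header), ")")
    }
    taxCol <- grep("^(taxonomy|consensus ?lineage)$", header,
                   ignore.case = TRUE)
    countCols <- setdiff(seq_along(header)[-1], taxCol)
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate OTU ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- matrix(NA_real_, nrow = length(ids), ncol = length(countCols),
                  dimnames = list(ids, header[countCols]))
    for (i in seq_along(fields)) {
        v <- suppressWarnings(as.numeric(fields[[i]][countCols]))
        if (any(is.na(v)))
            stop("non-numeric count at line ", headerIdx + i, " of ", path)
        if (any(v < 0))
            stop("negative count at line ", headerIdx + i, " of ", path)
        mat[i, ] <- v
    }
    tax <- if (length(taxCol)) {
        setNames(vapply(fields, `[[`, "", taxCol[1]), ids)
    } else NULL
    OtuTable(mat, taxonomy = tax)
}

#' Write an OTU table in the QIIME-classic TSV dialect
#'
#' @param x an [OtuTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    tax <- taxonomy(x)
    header <- c("#OTU ID", colnames(m), if (!is.null(tax)) "taxonomy")
    body <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], format(m[i, ], trim = TRUE,
                                       scientific = FALSE),
                if (!is.null(tax)) tax[i]), collapse = "\t")
    }, "")
    writeLines(c(paste(header, collapse = "\t"), body), path)
    invisible(path)
}

#' Remove rare OTUs by a count-prevalence rule
#'
#' Retains OTU j iff it has at least `minCount` reads in at least a
#' `minPrevalence` fraction of the samples (boundary included). This is the
#' prevalence filter applied before network construction; the inverse
#' reading of the rule ("drop OTUs that fail in at least 20% of samples") is
#' available via `inverse = TRUE`.
#'
#' @param x an [OtuTable-class].
#' @param minCount minimum reads for a sample to count as an occurrence.
#' @param minPrevalence required occurrence fraction, in (0, 1].
#' @param inverse use the alternative reading of the rule.
#' @return A filtered [OtuTable-class]; OTU order preserved. Emits a warning
#'   when nothing survives.
#' @examples
#' tbl <- OtuTable(matrix(c(5, 0, 0, 0, 0, 3, 3, 3, 3, 3), nrow = 2,
#'     byrow = TRUE, dimnames = list(c("a", "b"), paste0("s", 1:5))))
#' otuIds(filterRare(tbl, minCount = 3, minPrevalence = 0.4))
#' @export
filterRare <- function(x, minCount = 3, minPrevalence = 0.2,
                       inverse = FALSE) {
    stopifnot(is(x, "OtuTable"))
    if (minPrevalence <= 0 || minPrevalence > 1)
        stop("minPrevalence must be in (0, 1]")
    m <- otuCounts(x)
    prevalence <- rowMeans(m >= minCount)
    keep <- if (inverse) (1 - prevalence) < minPrevalence
            else prevalence >= minPrevalence
    if (!any(keep))
        warning("no OTUs survive the rare-taxa filter")
    x[keep, ]
}

#' Standardize samples to the median sequencing depth
#'
#' Scales each sample's counts by (median sample total)/(sample total), so
#' every column sums to the median depth; within-sample proportions are
#' unchanged. Counts become real-valued.
#'
#' @param x an [OtuTable-class].
#' @return An [OtuTable-class] with rescaled counts.
#' @export
standardizeDepth <- function(x) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    scaled <- sweep(m, 2, median(tot) / tot, `*`)
    OtuTable(scaled, taxonomy = taxonomy(x))
}

#' Relative abundances in percent of reads
#'
#' @param x an [OtuTable-class].
#' @return A samples x OTUs matrix of percentages; each row sums to 100.
#'   This orientation is the regression design convention (stations are
#'   observations).
#' @export
relativeAbundance <- function(x) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    t(sweep(m, 2, tot, `/`)) * 100
}

#' Aggregate OTUs into taxonomic groups
#'
#' Sums counts within groups given either a lineage depth (taxonomy must be
#' present) or an explicit OTU-to-group mapping. OTUs without a group land in
#' `"others"`. Optionally, groups whose overall read share falls below
#' `othersThreshold` are pooled into `"others"` as well (the "taxa < 5%
#' combined into others" display convention).
#'
#' @param x an [OtuTable-class].
#' @param level lineage depth (semicolon-separated fields) to group at.
#' @param mapping named character vector OTU id -> group; overrides `level`.
#' @param othersThreshold optional fraction of total reads (e.g. 0.05) below
#'   which a group is pooled into "others".
#' @return An [OtuTable-class] over groups. Total reads per sample conserved.
#' @export
aggregateTaxa <- function(x, level = NULL, mapping = NULL,
                          othersThreshold = NULL) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    if (is.null(mapping)) {
        tax <- taxonomy(x)
        if (is.null(tax) || is.null(level))
            stop("supply either a mapping or a lineage level with taxonomy")
        grp <- vapply(strsplit(tax, ";"), function(f) {
            f <- trimws(f)
            if (length(f) >= level && nzchar(f[level])) f[level]
            else NA_character_
        }, "")
    } else {
        grp <- unname(mapping[rownames(m)])
    }
    grp[is.na(grp) | !nzchar(grp)] <- "others"
    agg <- rowsum(m, group = grp)
    if (!is.null(othersThreshold)) {
        share <- rowSums(agg) / sum(agg)
        small <- share < othersThreshold & rownames(agg) != "others"
        if (any(small)) {
            pooled <- colSums(agg[small, , drop = FALSE])
            agg <- agg[!small, , drop = FALSE]
            if ("others" %in% rownames(agg))
                agg["others", ] <- agg["others", ] + pooled
            else
                agg <- rbind(agg, others = pooled)
        }
    }
    OtuTable(agg)
}

#' Top-k dominant OTUs by total reads
#'
#' Ranks OTUs by total reads across samples (descending; ties broken by
#' lexicographic OTU id) and returns the first `k` ids. Mean relative
#' abundance is also reported as an attribute for reference, but total reads
#' drive the ranking.
#'
#' @param x an [OtuTable-class].
#' @param k panel size (default 20).
#' @return Character vector of `k` OTU ids, most dominant first, with
#'   attribute `totals`.
#' @export
topKOtus <- function(x, k = 20) {
    stopifnot(is(x, "OtuTable"))
    if (k > nrow(x)) stop("k exceeds the number of OTUs")
    tot <- rowSums(otuCounts(x))
    ord <- order(-tot, rownames(x))
    ids <- rownames(x)[ord][seq_len(k)]
    structure(ids, totals = setNames(tot[ord][seq_len(k)], ids))
}
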