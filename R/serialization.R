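## On-disk model layout: one TSV per numeric array plus a JSON metadata
## header. Values are written with 17 significant digits, which round-trips
## IEEE doubles bit-exactly.

.writeArray <- function(x, path) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    lines <- apply(m, 1, function(r)
        paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
}

.readArray <- function(path, vector = FALSE) {
    rows <- strsplit(readLines(path), "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(rows, as.numeric))
    if (vector) as.numeric(m[1, ]) else m
}

.modelArrays <- c("Zlogits", "Wlogits", "gamma", "delta", "Rpos", "Rneg",
                  "Gpos", "Gneg")

#' Write a fitted model to a directory
#'
#' Persists every parameter block as a plain-text array plus a
#' `metadata.json` header (sizes, seed, optimizer settings, loss trace,
#' node labels). [readModel()] reloads it bit-exactly.
#'
#' @param fit a [FittedModel-class].
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
writeModel <- function(fit, dir) {
    stopifnot(is(fit, "FittedModel"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- fit@params
    for (nm in .modelArrays)
        .writeArray(slot(p, nm), file.path(dir, paste0(nm, ".tsv")))
    .writeArray(fit@trace, file.path(dir, "trace.tsv"))
    meta <- list(
        N = ncol(p@Zlogits), Kpos = nrow(p@Zlogits), Kneg = nrow(p@Wlogits),
        seed = fit@seed, control = fit@control,
        nodeLabels = fit@nodeLabels)
    jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a fitted model from a directory written by [writeModel()]
#'
#' @param dir model directory.
#' @return a [FittedModel-class].
#' @export
readModel <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                                simplifyVector = TRUE)
    arr <- lapply(stats::setNames(.modelArrays, .modelArrays), function(nm)
        .readArray(file.path(dir, paste0(nm, ".tsv")),
                   vector = nm %in% c("gamma", "delta")))
    params <- new("ModelParams",
        Zlogits = arr$Zlogits, Wlogits = arr$Wlogits,
        gamma = arr$gamma, delta = arr$delta,
        Rpos = arr$Rpos, Rneg = arr$Rneg,
        Gpos = arr$Gpos, Gneg = arr$Gneg)
    new("FittedModel",
        params = params,
        solution = archetypes(params),
        trace = .readArray(file.path(dir, "trace.tsv"), vector = TRUE),
        seed = as.integer(meta$seed),
        control = as.list(meta$control),
        nodeLabels = as.character(meta$nodeLabels))
}
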