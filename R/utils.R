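#' Evaluate an expression under a local random seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so library functions never disturb user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a reproducible family of sub-seeds from one master seed
#'
#' A single cohort or pipeline seed is fanned out to per-stage (and
#' per-sample) seeds by drawing from the integer range under the master
#' seed; each consumer then seeds its own RNG, so stages are individually
#' reproducible.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length \code{n}, all below 2^31.
#' @export
derive_seeds <- function(seed, n) {
    with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# simplex check used on every composition/proportion vector
check_simplex <- function(p, tol = 1e-9, what = "proportions") {
    if (any(!is.finite(p)) || any(p < 0))
        stop(what, " must be finite and nonnegative")
    if (abs(sum(p) - 1) > tol)
        stop(what, " must sum to 1 (got ", format(sum(p)), ")")
    invisible(TRUE)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}
#'   (Phred+33 quality strings).
#' @export
read_fastq <- function(path) {
    # readQualityScaledDNAStringSet emits a harmless internal warning about
    # dropped metadata columns on some Biostrings versions
    x <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    data.frame(id = names(x),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @param path output path; \code{.gz} suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
    if (nrow(reads) == 0) {
        con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
        close(con)
        return(invisible(path))
    }
    x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(reads$seq),
        Biostrings::PhredQuality(reads$qual))
    names(x) <- reads$id
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = grepl("\\.gz$", path))
    invisible(path)
}

# write a TSV with a provenance comment header
write_tsv <- function(df, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment))
        writeLines(paste0("# ", comment), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
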