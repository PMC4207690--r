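#' Quality-control configuration
#'
#' @param min_quality Phred threshold; bases from the first position below
#'   it are truncated (default 30).
#' @param min_length minimum mate length after truncation (default 100 nt).
#' @param allow_ambiguous keep reads containing non-ACGT characters.
#' @param barcode_mismatches maximum barcode mismatches at demultiplexing.
#' @param quality_mode \code{"truncate"} (3'-truncate at the first base
#'   below \code{min_quality}, then length-filter) or \code{"mean"} (keep
#'   mates whose mean quality is at least \code{min_quality}, untruncated).
#' @return a \code{qc_config} list.
#' @export
qc_config <- function(min_quality = 30, min_length = 100,
                      allow_ambiguous = FALSE, barcode_mismatches = 0,
                      quality_mode = c("truncate", "mean")) {
    stopifnot(min_quality >= 2, min_quality <= 41, min_length >= 1,
              barcode_mismatches >= 0)
    structure(list(min_quality = as.integer(min_quality),
                   min_length = as.integer(min_length),
                   allow_ambiguous = isTRUE(allow_ambiguous),
                   barcode_mismatches = as.integer(barcode_mismatches),
                   quality_mode = match.arg(quality_mode)),
              class = "qc_config")
}

#' Demultiplex pooled paired reads by forward-read barcode
#'
#' The barcode is read off the start of the forward mate, matched against
#' the barcode map within \code{cfg$barcode_mismatches}, and stripped
#' (sequence and quality) from assigned reads. Reads matching no barcode,
#' or matching more than one at the allowed mismatch count, go to the
#' unassigned bin.
#'
#' @param r1,r2 read data.frames (\code{id}, \code{seq}, \code{qual}).
#' @param barcode_map data.frame with columns \code{sample_id},
#'   \code{barcode} (equal-length, unique).
#' @param cfg a [qc_config()].
#' @return list with \code{samples} (named list of \code{list(r1, r2)}) and
#'   \code{unassigned} (\code{list(r1, r2)}).
#' @export
demultiplex <- function(r1, r2, barcode_map, cfg = qc_config()) {
    bl <- unique(nchar(barcode_map$barcode))
    if (length(bl) != 1) stop("barcodes must be of equal length")
    if (anyDuplicated(barcode_map$barcode))
        stop("duplicate barcodes in barcode map")
    if (nrow(r1) != nrow(r2)) stop("mate streams differ in length")
    obs <- substr(r1$seq, 1L, bl)
    if (cfg$barcode_mismatches == 0L) {
        hit <- match(obs, barcode_map$barcode)
    } else {
        n <- nrow(r1)
        obm <- matrix(utf8ToInt(paste(obs, collapse = "")), ncol = bl,
                      byrow = TRUE)
        mm <- matrix(0L, n, nrow(barcode_map))
        for (b in seq_len(nrow(barcode_map))) {
            bc <- utf8ToInt(barcode_map$barcode[b])
            mm[, b] <- bl - rowSums(obm == rep(bc, each = n))
        }
        ok <- mm <= cfg$barcode_mismatches
        nok <- rowSums(ok)
        hit <- ifelse(nok == 1L, max.col(ok, "first"), NA_integer_)
    }
    strip <- function(df, keep) {
        data.frame(id = df$id[keep],
                   seq = substr(df$seq[keep], bl + 1L, nchar(df$seq[keep])),
                   qual = substr(df$qual[keep], bl + 1L, nchar(df$qual[keep])),
                   stringsAsFactors = FALSE)
    }
    samples <- lapply(seq_len(nrow(barcode_map)), function(b) {
        keep <- which(!is.na(hit) & hit == b)
        list(r1 = strip(r1, keep),
             r2 = data.frame(id = r2$id[keep], seq = r2$seq[keep],
                             qual = r2$qual[keep], stringsAsFactors = FALSE))
    })
    names(samples) <- barcode_map$sample_id
    un <- which(is.na(hit))
    list(samples = samples,
         unassigned = list(r1 = r1[un, , drop = FALSE],
                           r2 = r2[un, , drop = FALSE]))
}

#' Quality-filter a set of read pairs
#'
#' In the default \code{"truncate"} mode each mate is 3'-truncated at its
#' first base below \code{min_quality}; a pair is retained iff both
#' truncated mates are at least \code{min_length} nt and (unless
#' \code{allow_ambiguous}) contain only A/C/G/T in the retained portion.
#' Pairs are filtered independently, so the retained set does not depend on
#' input order.
#'
#' @param r1,r2 read data.frames (\code{id}, \code{seq}, \code{qual}) for
#'   the two mates, row-aligned.
#' @param cfg a [qc_config()].
#' @return list with \code{r1}, \code{r2} (retained, truncated),
#'   \code{reason} (per input pair: \code{"retained"},
#'   \code{"discarded_short"}, \code{"discarded_ambiguous"} or
#'   \code{"discarded_quality"}) and \code{report} (one-row accounting
#'   data.frame).
#' @export
filter_pairs <- function(r1, r2, cfg = qc_config()) {
    stopifnot(nrow(r1) == nrow(r2))
    bad <- which(nchar(r1$seq) != nchar(r1$qual) |
                 nchar(r2$seq) != nchar(r2$qual))
    if (length(bad))
        stop("malformed FASTQ record (sequence/quality length mismatch): ",
             r1$id[bad[1]])
    n <- nrow(r1)
    reason <- rep("retained", n)
    if (cfg$quality_mode == "truncate") {
        k1 <- cpp_qual_trunc_len(r1$qual, cfg$min_quality)
        k2 <- cpp_qual_trunc_len(r2$qual, cfg$min_quality)
        s1 <- substr(r1$seq, 1L, k1); q1 <- substr(r1$qual, 1L, k1)
        s2 <- substr(r2$seq, 1L, k2); q2 <- substr(r2$qual, 1L, k2)
        reason[k1 < cfg$min_length | k2 < cfg$min_length] <- "discarded_short"
    } else {
        meanq <- function(q) vapply(q, function(x)
            mean(utf8ToInt(x) - 33L), numeric(1), USE.NAMES = FALSE)
        lowq <- meanq(r1$qual) < cfg$min_quality |
                meanq(r2$qual) < cfg$min_quality
        s1 <- r1$seq; q1 <- r1$qual; s2 <- r2$seq; q2 <- r2$qual
        reason[lowq] <- "discarded_quality"
        reason[nchar(s1) < cfg$min_length |
               nchar(s2) < cfg$min_length] <- "discarded_short"
    }
    if (!cfg$allow_ambiguous) {
        amb <- grepl("[^ACGT]", s1) | grepl("[^ACGT]", s2)
        reason[reason == "retained" & amb] <- "discarded_ambiguous"
    }
    keep <- reason == "retained"
    report <- data.frame(
        input = n, retained = sum(keep),
        discarded_short = sum(reason == "discarded_short"),
        discarded_ambiguous = sum(reason == "discarded_ambiguous"),
        discarded_quality = sum(reason == "discarded_quality"))
    list(r1 = data.frame(id = r1$id[keep], seq = s1[keep], qual = q1[keep],
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = r2$id[keep], seq = s2[keep], qual = q2[keep],
                         stringsAsFactors = FALSE),
         reason = reason, report = report)
}

#' Quality-filter a single read pair
#'
#' @param pair list with \code{r1} and \code{r2}, each \code{list(id, seq,
#'   qual)}.
#' @param cfg a [qc_config()].
#' @return list with \code{retained} (logical), \code{reason}, and the
#'   truncated \code{r1}/\code{r2} when retained.
#' @export
filter_pair <- function(pair, cfg = qc_config()) {
    f <- filter_pairs(
        data.frame(id = pair$r1$id, seq = pair$r1$seq, qual = pair$r1$qual,
                   stringsAsFactors = FALSE),
        data.frame(id = pair$r2$id, seq = pair$r2$seq, qual = pair$r2$qual,
                   stringsAsFactors = FALSE), cfg)
    if (f$reason[1] == "retained")
        list(retained = TRUE, reason = "retained",
             r1 = as.list(f$r1[1, ]), r2 = as.list(f$r2[1, ]))
    else list(retained = FALSE, reason = f$reason[1])
}

#' Demultiplex and quality-filter a pooled cohort
#'
#' Convenience wrapper: [demultiplex()] then [filter_pairs()] per sample,
#' with a per-sample accounting report whose rows satisfy
#' input = retained + discarded categories (unassigned reads are accounted
#' at the cohort level).
#'
#' @param r1,r2 pooled read data.frames.
#' @param barcode_map data.frame (\code{sample_id}, \code{barcode}).
#' @param cfg a [qc_config()].
#' @return list with \code{samples} (named list of filtered
#'   \code{list(r1, r2)}), \code{report} (per-sample QC counts) and
#'   \code{n_unassigned}.
#' @export
run_qc <- function(r1, r2, barcode_map, cfg = qc_config()) {
    dm <- demultiplex(r1, r2, barcode_map, cfg)
    out <- lapply(dm$samples, function(s) filter_pairs(s$r1, s$r2, cfg))
    report <- cbind(sample_id = names(out),
                    do.call(rbind, lapply(out, `[[`, "report")))
    rownames(report) <- NULL
    list(samples = lapply(out, function(x) list(r1 = x$r1, r2 = x$r2)),
         report = report, n_unassigned = nrow(dm$unassigned$r1))
}
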