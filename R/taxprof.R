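#' Align reads against the reference set by seeded banded alignment
#'
#' Candidate references are found by exact k-mer seeding; each candidate
#' diagonal is scored by gapless identity (matches / aligned read length,
#' read bases off the reference ends excluded from the denominator), with a
#' banded semi-global alignment as rescue when the best diagonal falls
#' below threshold. Hits below \code{min_identity} are dropped.
#'
#' @param reads character vector of read sequences (A/C/G/T).
#' @param refdb a \code{reference_db}.
#' @param k seed length (default 15).
#' @param band alignment band half-width for the gapped rescue.
#' @param min_identity identity threshold (default 0.97, inclusive).
#' @param rescue_margin candidates whose gapless identity falls below
#'   \code{min_identity} by at most this margin are re-evaluated with the
#'   banded gapped alignment.
#' @return data.frame with columns \code{read} (input index), \code{seq_id}
#'   and \code{identity}; zero rows for reads with no hit.
#' @export
align_reads <- function(reads, refdb, k = 15, band = 8, min_identity = 0.97,
                        rescue_margin = 0.03) {
    if (length(refdb$sequences) == 0) stop("empty reference database")
    hits <- cpp_align_reads(reads, unname(refdb$sequences), as.integer(k),
                            as.integer(band), min_identity, rescue_margin)
    data.frame(read = hits$read,
               seq_id = names(refdb$sequences)[hits$ref],
               identity = hits$identity, stringsAsFactors = FALSE)
}

#' Assign one read pair from its per-mate hit lists
#'
#' Only references hit by both mates are considered (mate concordance);
#' the best is chosen by mean identity, ties broken by higher minimum mate
#' identity and then lexicographic seq_id, so assignment is deterministic
#' and symmetric in mate order.
#'
#' @param hits_r1,hits_r2 data.frames with columns \code{seq_id},
#'   \code{identity} for the two mates.
#' @return list with \code{seq_id} (or NA), \code{identity} (mean of mate
#'   identities, or NA) and \code{reason} (\code{"assigned"},
#'   \code{"discordant_mates"} or \code{"no_hit"}).
#' @export
assign_pair <- function(hits_r1, hits_r2) {
    if (nrow(hits_r1) == 0 && nrow(hits_r2) == 0)
        return(list(seq_id = NA_character_, identity = NA_real_,
                    reason = "no_hit"))
    common <- intersect(hits_r1$seq_id, hits_r2$seq_id)
    if (length(common) == 0)
        return(list(seq_id = NA_character_, identity = NA_real_,
                    reason = "discordant_mates"))
    i1 <- hits_r1$identity[match(common, hits_r1$seq_id)]
    i2 <- hits_r2$identity[match(common, hits_r2$seq_id)]
    score <- (i1 + i2) / 2
    o <- order(-score, -pmin(i1, i2), common)[1]
    list(seq_id = common[o], identity = score[o], reason = "assigned")
}

#' Assign all read pairs of a sample
#'
#' Vectorized equivalent of [assign_pair()] over the hit tables of the two
#' mates of \code{n_pairs} row-aligned reads.
#'
#' @param hits_r1,hits_r2 data.frames from [align_reads()] on the forward
#'   and reverse mates (read indices refer to the same pair ordering).
#' @param n_pairs number of read pairs.
#' @return data.frame with one row per pair: \code{pair}, \code{seq_id},
#'   \code{identity}, \code{reason}.
#' @export
assign_pairs <- function(hits_r1, hits_r2, n_pairs) {
    m <- merge(hits_r1, hits_r2, by = c("read", "seq_id"))
    res <- data.frame(pair = seq_len(n_pairs), seq_id = NA_character_,
                      identity = NA_real_, reason = "no_hit",
                      stringsAsFactors = FALSE)
    any1 <- unique(hits_r1$read); any2 <- unique(hits_r2$read)
    res$reason[unique(c(any1, any2))] <- "discordant_mates"
    if (nrow(m)) {
        m$score <- (m$identity.x + m$identity.y) / 2
        m$minid <- pmin(m$identity.x, m$identity.y)
        o <- order(m$read, -m$score, -m$minid, m$seq_id)
        m <- m[o, ][!duplicated(m$read[o]), ]
        res$seq_id[m$read] <- m$seq_id
        res$identity[m$read] <- m$score
        res$reason[m$read] <- "assigned"
    }
    res
}

#' Build genus- and species-rank taxonomic profiles
#'
#' Aggregates per-pair assignments into sample x taxon read-count matrices
#' and the corresponding proportion matrices, computed over assigned reads
#' only. Samples with zero assigned reads are flagged invalid and carry NA
#' proportions.
#'
#' @param assignments data.frame with columns \code{sample_id} and
#'   \code{seq_id} (NA for unassigned pairs).
#' @param taxonomy data.frame (\code{seq_id}, \code{genus}, \code{species}).
#' @return list with two \code{taxon_profile} objects, \code{$genus} and
#'   \code{$species}; each holds \code{rank}, \code{counts},
#'   \code{proportions}, \code{unassigned} (per-sample count) and
#'   \code{valid} (logical per sample).
#' @export
build_profiles <- function(assignments, taxonomy) {
    assigned <- assignments[!is.na(assignments$seq_id), ]
    missing <- setdiff(assigned$seq_id, taxonomy$seq_id)
    if (length(missing))
        stop("seq_id missing from taxonomy: ",
             paste(head(missing, 5), collapse = ", "))
    samples <- unique(assignments$sample_id)
    unassigned <- table(factor(assignments$sample_id[is.na(assignments$seq_id)],
                               levels = samples))
    one_rank <- function(rank) {
        lab <- taxonomy[[rank]][match(assigned$seq_id, taxonomy$seq_id)]
        counts <- as.matrix(table(factor(assigned$sample_id, levels = samples),
                                  factor(lab, levels = unique(taxonomy[[rank]]))))
        counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                         dimnames = dimnames(counts))
        rs <- rowSums(counts)
        props <- counts / ifelse(rs == 0, NA, rs)
        valid <- rs > 0
        structure(list(rank = rank, counts = counts, proportions = props,
                       unassigned = as.numeric(unassigned), valid = valid),
                  class = "taxon_profile")
    }
    invalid <- setdiff(samples, unique(assigned$sample_id))
    if (length(invalid))
        warning(length(invalid), " sample(s) with zero assigned reads ",
                "flagged invalid: ", paste(head(invalid, 5), collapse = ", "))
    list(genus = one_rank("genus"), species = one_rank("species"))
}

#' @export
print.taxon_profile <- function(x, ...) {
    cat("taxon_profile (", x$rank, "): ", nrow(x$counts), " samples x ",
        ncol(x$counts), " taxa; ", sum(!x$valid), " invalid\n", sep = "")
    invisible(x)
}

#' Pool minor taxa into an "Others" column
#'
#' Taxa whose cohort-mean proportion is below \code{min_mean_proportion}
#' are summed into a single \code{Others} column; row sums are preserved.
#'
#' @param profile a \code{taxon_profile}.
#' @param min_mean_proportion pooling threshold in [0, 1).
#' @return a \code{taxon_profile} with pooled columns.
#' @export
group_minor_taxa <- function(profile, min_mean_proportion) {
    if (min_mean_proportion < 0 || min_mean_proportion >= 1)
        stop("min_mean_proportion must be in [0, 1)")
    if (min_mean_proportion == 0) return(profile)
    means <- colMeans(profile$proportions[profile$valid, , drop = FALSE])
    minor <- means < min_mean_proportion
    if (all(minor)) stop("all taxa fall below the pooling threshold")
    if (!any(minor)) return(profile)
    pool <- function(m) {
        cbind(m[, !minor, drop = FALSE],
              Others = rowSums(m[, minor, drop = FALSE]))
    }
    profile$counts <- pool(profile$counts)
    profile$proportions <- pool(profile$proportions)
    profile
}

#' Profile a QC-filtered cohort
#'
#' Runs [align_reads()] on both mates, [assign_pairs()] per sample, and
#' [build_profiles()] over all samples.
#'
#' @param samples named list of filtered \code{list(r1, r2)} read sets, as
#'   from [run_qc()].
#' @param refdb a \code{reference_db}.
#' @param k,band,min_identity passed to [align_reads()].
#' @return list with \code{profiles} (genus/species \code{taxon_profile}s)
#'   and \code{assignments} (per-pair data.frame with \code{sample_id}).
#' @export
profile_cohort <- function(samples, refdb, k = 15, band = 8,
                           min_identity = 0.97) {
    asn <- lapply(names(samples), function(s) {
        rd <- samples[[s]]
        n <- nrow(rd$r1)
        if (n == 0)
            return(data.frame(sample_id = character(0), pair = integer(0),
                              seq_id = character(0), identity = numeric(0),
                              reason = character(0)))
        # reverse mates come off the opposite strand: orient before aligning
        h1 <- align_reads(rd$r1$seq, refdb, k, band, min_identity)
        h2 <- align_reads(revcomp(rd$r2$seq), refdb, k, band, min_identity)
        cbind(sample_id = s, assign_pairs(h1, h2, n))
    })
    assignments <- do.call(rbind, asn)
    list(profiles = build_profiles(assignments, refdb$taxonomy),
         assignments = assignments)
}
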