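#' Default community-type specifications (G1, G2, G3)
#'
#' Three seminal community types, each a Dirichlet mean over the default
#' twelve-genus panel plus a Dirichlet precision and the probability that a
#' sample of the type is clinically normal. The anchors are the study
#' conditions the generator emulates: G1 is Pseudomonas-predominant (mean
#' 16.1 percent, 20 percent of samples normal), G2 Lactobacillus-predominant
#' (32.3 percent, 52.7 percent normal), G3 Prevotella-predominant (26.3
#' percent, 12.5 percent normal). Remaining mass is spread over the other
#' named genera and filler genera so that cohort-level genus means are
#' realistic for semen.
#'
#' @param concentration Dirichlet precision (dimensionless); larger values
#'   give tighter sample-to-sample variation around the type mean.
#' @return named list of three \code{community_type_spec} objects.
#' @export
community_type_specs <- function(concentration = 25) {
    genera <- c("Lactobacillus", "Pseudomonas", "Prevotella", "Gardnerella",
                "Haemophilus", "Rhodanobacter", "Streptococcus", "Finegoldia",
                paste0("Other", 1:4))
    mk <- function(name, named, p_normal) {
        m <- setNames(numeric(12), genera)
        m[names(named)] <- named
        rest <- setdiff(genera, names(named))
        m[rest] <- (1 - sum(named)) / length(rest)
        spec <- structure(list(name = name, genus_means = m,
                               concentration = concentration,
                               p_normal = p_normal),
                          class = "community_type_spec")
        validate_type_spec(spec)
        spec
    }
    # Secondary and filler means are type-specific: each community type
    # carries its own co-occurring background flora (the structure the
    # co-occurrence subnetworks reflect), which also keeps the three types
    # identifiable from the planted data at the default precision.
    list(
        G1 = mk("G1", c(Pseudomonas = 0.161, Lactobacillus = 0.04,
                        Prevotella = 0.03, Gardnerella = 0.01,
                        Haemophilus = 0.05, Rhodanobacter = 0.12,
                        Streptococcus = 0.04, Finegoldia = 0.04,
                        Other1 = 0.22, Other2 = 0.18, Other3 = 0.06),
                 0.20),
        G2 = mk("G2", c(Lactobacillus = 0.323, Pseudomonas = 0.03,
                        Prevotella = 0.02, Gardnerella = 0.08,
                        Haemophilus = 0.015, Rhodanobacter = 0.03,
                        Streptococcus = 0.06, Finegoldia = 0.05,
                        Other1 = 0.05, Other2 = 0.06, Other3 = 0.15),
                 0.527),
        G3 = mk("G3", c(Prevotella = 0.263, Lactobacillus = 0.03,
                        Pseudomonas = 0.03, Gardnerella = 0.015,
                        Haemophilus = 0.06, Rhodanobacter = 0.02,
                        Streptococcus = 0.03, Finegoldia = 0.06,
                        Other1 = 0.06, Other2 = 0.05, Other3 = 0.05),
                 0.125))
}

validate_type_spec <- function(spec) {
    check_simplex(spec$genus_means, what = "genus_means")
    if (spec$p_normal < 0 || spec$p_normal > 1) stop("p_normal must be in [0,1]")
    if (!(spec$concentration > 0)) stop("concentration must be positive")
    invisible(TRUE)
}

#' Draw one sample composition from a community-type specification
#'
#' Genus proportions are a Dirichlet draw with mean \code{genus_means} and
#' precision \code{concentration}; each genus mass is then split among its
#' species by the fixed within-genus weights stored in the reference
#' database. An infinite concentration returns the mean exactly.
#'
#' @param spec a \code{community_type_spec}.
#' @param refdb a \code{reference_db} whose genera cover
#'   \code{names(spec$genus_means)}.
#' @param seed integer seed.
#' @return named numeric vector of proportions over \code{refdb} species
#'   (seq_ids), summing to 1.
#' @export
sample_composition <- function(spec, refdb, seed) {
    validate_type_spec(spec)
    tax <- refdb$taxonomy
    if (!all(names(spec$genus_means) %in% tax$genus))
        stop("reference database lacks genera: ",
             paste(setdiff(names(spec$genus_means), tax$genus), collapse = ", "))
    gm <- spec$genus_means
    gp <- if (is.infinite(spec$concentration)) gm else with_seed(seed, {
        g <- setNames(rgamma(length(gm), shape = spec$concentration * gm,
                             rate = 1), names(gm))
        # genera with zero mean stay exactly zero
        g[gm == 0] <- 0
        if (sum(g) == 0) gm else g / sum(g)
    })
    p <- gp[tax$genus] * refdb$species_weights[tax$seq_id]
    p <- setNames(as.numeric(p), tax$seq_id)
    p <- p / sum(p)
    check_simplex(p)
    p
}

# phred+33 ascii for a given quality
.qchar <- function(q) intToUtf8(q + 33L)

#' Simulate paired-end amplicon reads from a composition
#'
#' Each pair is drawn from one species with probability proportional to the
#' composition; the forward read is the 5' prefix of the reference, the
#' reverse read the reverse complement of the 3' end (no indels, i.i.d.
#' substitution errors). Per-base Phred qualities follow a two-state model:
#' reads start in a good state (Q38) and fall into an absorbing bad state
#' (Q15) with a 3'-increasing hazard, so that downstream Q30 truncation is
#' exercised while >95 percent of pairs survive default QC.
#'
#' @param composition named proportions over \code{refdb} species.
#' @param refdb a \code{reference_db}.
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution probability, in [0, 0.01].
#' @param read_len read length (<= reference length).
#' @param seed integer seed.
#' @param barcode optional barcode prepended (with Q38 qualities) to the
#'   forward read.
#' @param sample_id prefix for read ids.
#' @param qual_hazard scale of the bad-state hazard
#'   \code{qual_hazard * (i/read_len)^3} at read position \code{i}.
#' @return data.frame with columns \code{id}, \code{species} (truth),
#'   \code{r1_seq}, \code{r1_qual}, \code{r2_seq}, \code{r2_qual}.
#' @export
simulate_reads <- function(composition, refdb, n_pairs, error_rate = 0.005,
                           read_len = 120, seed = 1, barcode = NULL,
                           sample_id = "S1", qual_hazard = 0.0015) {
    stopifnot(error_rate >= 0, error_rate <= 0.01)
    L <- unique(nchar(refdb$sequences))
    stopifnot(read_len <= L)
    composition <- composition[refdb$taxonomy$seq_id]
    check_simplex(composition)
    if (n_pairs == 0) {
        warning("n_pairs is zero; returning empty read set")
        return(data.frame(id = character(0), species = character(0),
                          r1_seq = character(0), r1_qual = character(0),
                          r2_seq = character(0), r2_qual = character(0)))
    }
    bases <- c("A", "C", "G", "T")
    code <- function(s) match(strsplit(s, "")[[1]], bases) - 1L
    refm <- t(vapply(refdb$sequences, code, integer(L)))
    with_seed(seed, {
        sp <- sample.int(nrow(refm), n_pairs, replace = TRUE,
                         prob = composition)
        fwd <- refm[sp, seq_len(read_len), drop = FALSE]
        rev <- refm[sp, L:(L - read_len + 1L), drop = FALSE]
        rev <- (3L - rev) %% 4L                     # complement (A<->T, C<->G)
        add_err <- function(m) {
            hit <- which(matrix(runif(length(m)) < error_rate, nrow(m)))
            m[hit] <- (m[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
            m
        }
        if (error_rate > 0) { fwd <- add_err(fwd); rev <- add_err(rev) }
        collapse <- function(m) {
            ch <- matrix(bases[m + 1L], nrow(m))
            do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
        }
        hazard <- qual_hazard * (seq_len(read_len) / read_len) ^ 3
        qual_strings <- function(n) {
            u <- matrix(runif(n * read_len), n)
            bad <- sweep(u, 2, hazard, "<")
            fb <- rep.int(read_len + 1L, n)
            w <- which(bad, arr.ind = TRUE)
            if (nrow(w)) {
                first <- tapply(w[, 2], w[, 1], min)
                fb[as.integer(names(first))] <- as.integer(first)
            }
            paste0(strrep(.qchar(38L), fb - 1L),
                   strrep(.qchar(15L), read_len - fb + 1L))
        }
        r1 <- collapse(fwd); r2 <- collapse(rev)
        q1 <- qual_strings(n_pairs); q2 <- qual_strings(n_pairs)
        if (!is.null(barcode)) {
            r1 <- paste0(barcode, r1)
            q1 <- paste0(strrep(.qchar(38L), nchar(barcode)), q1)
        }
        data.frame(id = sprintf("%s_p%06d", sample_id, seq_len(n_pairs)),
                   species = refdb$taxonomy$seq_id[sp],
                   r1_seq = r1, r1_qual = q1, r2_seq = r2, r2_qual = q2,
                   stringsAsFactors = FALSE)
    })
}

#' Simulate one clinical record coupled to a community type
#'
#' With probability \code{p_normal} all seven semen-quality criteria are
#' drawn in their normal ranges; otherwise at least \code{min_abnormal_case}
#' criteria are drawn abnormal (uniformly beyond the clinical threshold),
#' chosen with probabilities proportional to the abnormality margins of the
#' study population. The nine CASA kinematic/morphometric metrics are drawn
#' from configured normal ranges, with head elongation increasing in the
#' sample's Lactobacillus proportion (the planted morphology link).
#'
#' @param p_normal probability the record is fully normal.
#' @param seed integer seed.
#' @param lacto Lactobacillus proportion of the sample (drives the planted
#'   head-elongation shift).
#' @param min_abnormal_case minimum number of abnormal criteria drawn for a
#'   non-normal record, so such records qualify as cases downstream.
#' @return one-row data.frame with raw clinical values (volume ml,
#'   concentration cells/ml, motility %, kruger %, iga %, atypical %,
#'   leukocytes cells/ml) and CASA metrics.
#' @export
simulate_clinical <- function(p_normal, seed = 1, lacto = 0.2,
                              min_abnormal_case = 2) {
    with_seed(seed, {
        normal_draw <- list(
            volume = runif(1, 1.5, 6.0),
            concentration = runif(1, 20e6, 150e6),
            motility = runif(1, 45, 85),
            kruger = runif(1, 6, 20),
            iga = runif(1, 0, 25),
            atypical = runif(1, 0, 0.9),
            leukocytes = runif(1, 0, 0.8e6))
        abnormal_draw <- list(
            volume = if (runif(1) < 0.5) runif(1, 6.4, 9) else runif(1, 0.3, 1.2),
            concentration = runif(1, 1e6, 14.9e6),
            motility = runif(1, 5, 39.9),
            kruger = runif(1, 0, 5),
            iga = runif(1, 30.5, 80),
            atypical = runif(1, 1, 5),
            leukocytes = runif(1, 1e6, 5e6))
        crit <- names(normal_draw)
        rec <- normal_draw
        if (runif(1) >= p_normal) {
            # Table-1 abnormality margins drive which criteria go abnormal
            margins <- c(volume = 10, concentration = 13, motility = 12,
                         kruger = 44, iga = 10, atypical = 8, leukocytes = 18)
            n_ab <- min(7L, min_abnormal_case + rbinom(1, 3, 0.3))
            ab <- sample(crit, n_ab, prob = margins)
            rec[ab] <- abnormal_draw[ab]
        }
        casa <- list(
            VAP = max(0, rnorm(1, 50, 10)), VSL = max(0, rnorm(1, 40, 8)),
            VCL = max(0, rnorm(1, 80, 15)), ALH = max(0, rnorm(1, 5, 1)),
            BCF = max(0, rnorm(1, 25, 5)),
            STR = min(100, max(0, rnorm(1, 80, 5))),
            LIN = min(100, max(0, rnorm(1, 50, 8))),
            head_elongation = 50 + 20 * lacto + rnorm(1, 0, 3),
            area = max(0, rnorm(1, 12, 2)))
        as.data.frame(c(rec, casa))
    })
}

# deterministic unique barcodes: base-4 expansion of spaced indices
make_barcodes <- function(n, len = 8) {
    stopifnot(n <= 4 ^ len)
    idx <- floor(seq(0, 4 ^ len - 1, length.out = n))
    bases <- c("A", "C", "G", "T")
    vapply(idx, function(i) {
        d <- integer(len)
        for (j in len:1) { d[j] <- i %% 4; i <- i %/% 4 }
        paste(bases[d + 1], collapse = "")
    }, character(1))
}

#' Simulate a full synthetic cohort
#'
#' Generates the self-contained inputs the downstream analysis consumes:
#' a reference database (unless supplied), per-sample true community type
#' and composition, barcoded paired-end reads, and clinical metadata. All
#' randomness flows from the single \code{seed}; identical seeds give
#' identical cohorts.
#'
#' @param n_per_type named integer vector of sample counts per community
#'   type; the default 25/55/16 mirrors the study's group sizes.
#' @param refdb a \code{reference_db}; built from the cohort seed if NULL.
#' @param specs community-type specifications, as from
#'   [community_type_specs()].
#' @param n_pairs read pairs per sample (desk-scale stand-in for the
#'   study's per-sample depth).
#' @param error_rate,read_len,qual_hazard passed to [simulate_reads()].
#' @param seed master cohort seed.
#' @return an object of class \code{simulated_cohort}: list with
#'   \code{refdb}, \code{samples} (sample_id, type, barcode),
#'   \code{compositions} (samples x species matrix of true proportions),
#'   \code{reads} (list of per-sample read data.frames) and \code{clinical}
#'   (data.frame keyed by sample_id).
#' @export
simulate_cohort <- function(n_per_type = c(G1 = 25, G2 = 55, G3 = 16),
                            refdb = NULL, specs = community_type_specs(),
                            n_pairs = 5000, error_rate = 0.005,
                            read_len = 120, seed = 1, qual_hazard = 0.0015) {
    stopifnot(all(names(n_per_type) %in% names(specs)))
    seeds <- derive_seeds(seed, 2 + 3 * sum(n_per_type))
    if (is.null(refdb)) refdb <- make_reference(seed = seeds[1])
    n <- sum(n_per_type)
    types <- rep(names(n_per_type), n_per_type)
    ids <- sprintf("S%03d", seq_len(n))
    barcodes <- make_barcodes(n)
    comp <- matrix(0, n, nrow(refdb$taxonomy),
                   dimnames = list(ids, refdb$taxonomy$seq_id))
    reads <- vector("list", n); names(reads) <- ids
    clin <- NULL
    lg <- refdb$taxonomy$genus == "Lactobacillus"
    for (i in seq_len(n)) {
        spec <- specs[[types[i]]]
        s <- seeds[2 + 3 * (i - 1) + 1:3]
        comp[i, ] <- sample_composition(spec, refdb, seed = s[1])
        reads[[i]] <- simulate_reads(comp[i, ], refdb, n_pairs,
                                     error_rate = error_rate,
                                     read_len = read_len, seed = s[2],
                                     barcode = barcodes[i], sample_id = ids[i],
                                     qual_hazard = qual_hazard)
        clin <- rbind(clin, simulate_clinical(spec$p_normal, seed = s[3],
                                              lacto = sum(comp[i, lg])))
    }
    rownames(clin) <- ids
    structure(list(refdb = refdb,
                   samples = data.frame(sample_id = ids, type = types,
                                        barcode = barcodes,
                                        stringsAsFactors = FALSE),
                   compositions = comp, reads = reads,
                   clinical = cbind(sample_id = ids, clin)),
              class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
    cat("simulated_cohort:", nrow(x$samples), "samples (",
        paste(sprintf("%s=%d", names(table(x$samples$type)),
                      as.integer(table(x$samples$type))), collapse = ", "),
        "),", nrow(x$reads[[1]]), "read pairs/sample\n")
    invisible(x)
}

#' Pool a cohort's per-sample reads into one multiplexed pair of streams
#'
#' @param cohort a \code{simulated_cohort}.
#' @return list with \code{r1} and \code{r2} read data.frames (columns
#'   \code{id}, \code{seq}, \code{qual}); barcodes remain on the forward
#'   read, as produced by the sequencer.
#' @export
pool_reads <- function(cohort) {
    all <- do.call(rbind, cohort$reads)
    list(r1 = data.frame(id = all$id, seq = all$r1_seq, qual = all$r1_qual,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = all$id, seq = all$r2_seq, qual = all$r2_qual,
                         stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Writes the reference database, per-sample paired FASTQ files, the
#' barcode map, clinical metadata and the ground truth (type + composition).
#'
#' @param cohort a \code{simulated_cohort}.
#' @param dir output directory.
#' @param gzip compress FASTQ output.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_reference(cohort$refdb, file.path(dir, "reference"))
    fq <- file.path(dir, "fastq")
    dir.create(fq, showWarnings = FALSE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    for (s in cohort$samples$sample_id) {
        rd <- cohort$reads[[s]]
        write_fastq(data.frame(id = rd$id, seq = rd$r1_seq, qual = rd$r1_qual),
                    file.path(fq, paste0(s, "_R1", ext)))
        write_fastq(data.frame(id = rd$id, seq = rd$r2_seq, qual = rd$r2_qual),
                    file.path(fq, paste0(s, "_R2", ext)))
    }
    write_tsv(cohort$samples[c("sample_id", "barcode")],
              file.path(dir, "barcodes.tsv"))
    write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
    truth <- cbind(cohort$samples[c("sample_id", "type")],
                   as.data.frame(cohort$compositions))
    write_tsv(truth, file.path(dir, "truth.tsv"))
    invisible(dir)
}
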