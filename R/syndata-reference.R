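#' Build a synthetic 16S reference database with taxonomy and phylogeny
#'
#' Generates one ~\code{seq_len}-nt reference sequence per species, grouped
#' into genera, together with a rooted branch-length phylogeny whose leaves
#' are the sequence ids. Sequences are evolved from a common root by
#' per-branch substitution so that every cross-species pair is below 97
#' percent identity (the assignment threshold), while reads simulated from
#' a species at the configured error rate stay at or above it. The database
#' stands in for a curated 16S reference set plus core tree.
#'
#' @param n_genera number of genera (>= 2). The first eight use the
#'   abundant-genus panel (Lactobacillus, Pseudomonas, Prevotella,
#'   Gardnerella, Haemophilus, Rhodanobacter, Streptococcus, Finegoldia);
#'   any further genera are filler ("Other1", ...).
#' @param species_per_genus species (= reference sequences) per genus.
#' @param seq_len reference length in nucleotides (>= 150).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param genus_divergence,species_divergence per-site substitution
#'   probabilities on the genus and species branches
#'   (units: substitutions/site; also used as branch lengths).
#' @param max_attempts resampling attempts to satisfy the identity bound.
#' @return an object of class \code{reference_db}: list with
#'   \code{sequences} (named character), \code{taxonomy} (data.frame
#'   \code{seq_id}, \code{genus}, \code{species}), \code{tree}
#'   (\code{ape::phylo}, rooted, with branch lengths) and
#'   \code{species_weights} (fixed within-genus species split used by the
#'   composition sampler).
#' @export
make_reference <- function(n_genera = 12, species_per_genus = 3,
                           seq_len = 250, seed = 1,
                           genus_divergence = 0.15,
                           species_divergence = 0.05,
                           max_attempts = 20) {
    stopifnot(n_genera >= 2, seq_len >= 150, species_per_genus >= 1)
    panel <- c("Lactobacillus", "Pseudomonas", "Prevotella", "Gardnerella",
               "Haemophilus", "Rhodanobacter", "Streptococcus", "Finegoldia")
    genera <- if (n_genera <= length(panel)) panel[seq_len(n_genera)]
              else c(panel, paste0("Other", seq_len(n_genera - length(panel))))

    bases <- c("A", "C", "G", "T")
    mutate <- function(codes, p) {
        hit <- which(runif(length(codes)) < p)
        codes[hit] <- (codes[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
        codes
    }
    seeds <- derive_seeds(seed, max_attempts)
    best_id <- NA_real_
    for (att in seq_len(max_attempts)) {
        res <- with_seed(seeds[att], {
            root <- sample.int(4L, seq_len, replace = TRUE) - 1L
            seqs <- character(0); tax <- NULL
            for (g in genera) {
                anc <- mutate(root, genus_divergence)
                for (s in seq_len(species_per_genus)) {
                    sp <- mutate(anc, species_divergence)
                    id <- paste0(g, "_sp", s)
                    seqs[id] <- paste(bases[sp + 1L], collapse = "")
                    tax <- rbind(tax, data.frame(seq_id = id, genus = g,
                                                 species = id,
                                                 stringsAsFactors = FALSE))
                }
            }
            list(seqs = seqs, tax = tax)
        })
        idm <- pairwise_identity(res$seqs)
        cross <- idm[upper.tri(idm)]
        best_id <- max(cross)
        if (best_id < 0.97) {
            clades <- vapply(genera, function(g) {
                ids <- res$tax$seq_id[res$tax$genus == g]
                if (length(ids) == 1)
                    sprintf("%s:%g", ids, genus_divergence + species_divergence)
                else sprintf("(%s):%g",
                             paste(sprintf("%s:%g", ids, species_divergence),
                                   collapse = ","),
                             genus_divergence)
            }, character(1))
            tree <- ape::read.tree(
                text = paste0("(", paste(clades, collapse = ","), ");"))
            # fixed within-genus species split (geometric 2^-i, normalized)
            w <- 2 ^ -(seq_len(species_per_genus) - 1L)
            w <- w / sum(w)
            sw <- setNames(rep(w, n_genera), res$tax$seq_id)
            db <- structure(list(sequences = res$seqs, taxonomy = res$tax,
                                 tree = tree, species_weights = sw),
                            class = "reference_db")
            return(db)
        }
    }
    stop("could not reach < 97% cross-species identity in ", max_attempts,
         " attempts (achieved max identity ", format(best_id), ")")
}

#' Pairwise identity matrix for equal-length ungapped sequences
#'
#' Identity is the fraction of matching positions; reference sequences are
#' generated under a substitution-only model, so positional comparison
#' coincides with global-alignment identity (asserted against a full
#' alignment oracle in the test suite).
#'
#' @param seqs named character vector of equal-length sequences.
#' @return symmetric matrix of identities with unit diagonal.
#' @export
pairwise_identity <- function(seqs) {
    n <- length(seqs)
    L <- unique(nchar(seqs))
    stopifnot(length(L) == 1)
    m <- t(vapply(seqs, function(s) utf8ToInt(s), integer(L)))
    out <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        out[i, j] <- out[j, i] <- mean(m[i, ] == m[j, ])
    out
}

#' @export
print.reference_db <- function(x, ...) {
    cat("reference_db:", length(x$sequences), "sequences,",
        length(unique(x$taxonomy$genus)), "genera,",
        unique(nchar(x$sequences)), "nt\n")
    invisible(x)
}

#' Write a reference database to disk
#'
#' Writes \code{reference.fasta}, \code{taxonomy.tsv} (seq_id, genus,
#' species) and \code{tree.nwk} under \code{dir}.
#'
#' @param refdb a \code{reference_db}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_reference <- function(refdb, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(refdb$sequences),
                                file.path(dir, "reference.fasta"))
    write_tsv(refdb$taxonomy, file.path(dir, "taxonomy.tsv"))
    ape::write.tree(refdb$tree, file.path(dir, "tree.nwk"))
    invisible(dir)
}

#' Read a reference database written by [write_reference()]
#'
#' @param dir directory holding \code{reference.fasta}, \code{taxonomy.tsv}
#'   and \code{tree.nwk}.
#' @return a \code{reference_db} (without species weights, which are a
#'   simulation-time construct; they default to a uniform split).
#' @export
read_reference <- function(dir) {
    seqs <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
    tax <- read.delim(file.path(dir, "taxonomy.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
    tree <- ape::read.tree(file.path(dir, "tree.nwk"))
    sq <- setNames(as.character(seqs), names(seqs))
    spg <- table(tax$genus)[tax$genus]
    structure(list(sequences = sq, taxonomy = tax, tree = tree,
                   species_weights = setNames(1 / as.numeric(spg), tax$seq_id)),
              class = "reference_db")
}
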