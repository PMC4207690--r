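test_that("reference database satisfies its invariants", {
    db <- default_ref
    expect_setequal(db$tree$tip.label, db$taxonomy$seq_id)
    expect_false(anyDuplicated(db$tree$tip.label) > 0)
    expect_true(all(grepl("^[ACGT]+$", db$sequences)))
    expect_true(all(db$tree$edge.length >= 0))
    idm <- pairwise_identity(db$sequences)
    expect_lt(max(idm[upper.tri(idm)]), 0.97)
    # the divergence bound also holds under a full global-alignment oracle
    # for the most similar (within-genus) pairs, where gaps could help most
    ut <- which(upper.tri(idm), arr.ind = TRUE)
    top <- ut[order(idm[upper.tri(idm)], decreasing = TRUE)[1:3], ,
              drop = FALSE]
    for (r in seq_len(nrow(top))) {
        aln <- Biostrings::pairwiseAlignment(db$sequences[top[r, 1]],
                                             db$sequences[top[r, 2]],
                                             type = "global")
        expect_lt(Biostrings::nmatch(aln) / Biostrings::nchar(aln), 0.97)
    }
})

test_that("two-species reference and determinism", {
    db <- make_reference(n_genera = 2, species_per_genus = 1,
                         seq_len = 150, seed = 3)
    expect_length(db$sequences, 2)
    expect_lt(pairwise_identity(db$sequences)[1, 2], 0.97)
    # identical seed gives byte-identical FASTA and Newick
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    write_reference(make_reference(seed = 11), d1)
    write_reference(make_reference(seed = 11), d2)
    for (f in c("reference.fasta", "tree.nwk", "taxonomy.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    # round-trip through disk preserves sequences, taxonomy and topology
    back <- read_reference(d1)
    expect_identical(back$sequences, make_reference(seed = 11)$sequences)
})

test_that("sample compositions are simplex-valued and recover type means", {
    specs <- community_type_specs()
    for (s in seq_len(25)) {
        p <- sample_composition(specs$G1, default_ref, seed = s)
        expect_true(all(p >= 0))
        expect_equal(sum(p), 1, tolerance = 1e-9)
    }
    # infinite precision collapses to the mean exactly
    sp <- specs$G2; sp$concentration <- Inf
    p <- sample_composition(sp, default_ref, seed = 1)
    gm <- tapply(p, default_ref$taxonomy$genus, sum)
    expect_equal(gm[names(sp$genus_means)], sp$genus_means,
                 tolerance = 1e-12, ignore_attr = TRUE)
    # Monte-Carlo recovery of the anchored predominant-genus means
    tax <- default_ref$taxonomy
    lacto <- vapply(1:1000, function(s)
        sum(sample_composition(specs$G2, default_ref, s)[
            tax$genus == "Lactobacillus"]), numeric(1))
    expect_lt(abs(mean(lacto) - 0.323), 0.03)
    prevo <- vapply(1:1000, function(s)
        sum(sample_composition(specs$G3, default_ref, s + 5000)[
            tax$genus == "Prevotella"]), numeric(1))
    expect_lt(abs(mean(prevo) - 0.263), 0.03)
})

test_that("read simulator honors composition, errors and determinism", {
    db <- tiny_ref
    # error-free reads from a single species map back perfectly
    comp <- setNames(numeric(6), db$taxonomy$seq_id)
    comp[3] <- 1
    rd <- simulate_reads(comp, db, 200, error_rate = 0, seed = 2)
    expect_true(all(rd$species == db$taxonomy$seq_id[3]))
    h <- align_reads(rd$r1_seq, db)
    best <- h[h$identity == 1, ]
    expect_true(all(tapply(best$seq_id == db$taxonomy$seq_id[3],
                           best$read, any)))
    # 50/50 composition: per-species fractions within a 3-sigma binomial bound
    comp2 <- setNames(numeric(6), db$taxonomy$seq_id)
    comp2[c(1, 4)] <- 0.5
    rd2 <- simulate_reads(comp2, db, 1000, error_rate = 0, seed = 9)
    frac <- mean(rd2$species == db$taxonomy$seq_id[1])
    expect_lt(abs(frac - 0.5), 0.05)
    # byte-identical on reseed
    expect_identical(simulate_reads(comp2, db, 50, seed = 4),
                     simulate_reads(comp2, db, 50, seed = 4))
    expect_warning(out <- simulate_reads(comp2, db, 0, seed = 1), "zero")
    expect_equal(nrow(out), 0)
})

test_that("simulated qualities exercise truncation but pass QC mostly", {
    db <- tiny_ref
    comp <- setNames(rep(1 / 6, 6), db$taxonomy$seq_id)
    rd <- simulate_reads(comp, db, 2000, seed = 5)
    f <- filter_pairs(
        data.frame(id = rd$id, seq = rd$r1_seq, qual = rd$r1_qual),
        data.frame(id = rd$id, seq = rd$r2_seq, qual = rd$r2_qual))
    expect_gt(f$report$retained / f$report$input, 0.95)
    # some truncation happens across a large batch
    expect_true(any(nchar(f$r1$seq) < 120) || f$report$discarded_short > 0)
})

test_that("clinical simulator reproduces the per-type normal rates", {
    rec <- simulate_clinical(p_normal = 1, seed = 1)
    expect_equal(flag_clinical(rec)$n_abnormal, 0)
    draw_normal <- function(p, off) vapply(1:1000, function(s)
        flag_clinical(simulate_clinical(p, seed = s + off))$n_abnormal == 0,
        logical(1))
    g2 <- draw_normal(0.527, 0)
    expect_lt(abs(mean(g2) - 0.527), 0.05)
    g3 <- draw_normal(0.125, 2000)
    expect_lt(abs(mean(g3) - 0.125), 0.04)
    # abnormal records qualify as cases under the default class rule
    nab <- vapply(1:200, function(s)
        flag_clinical(simulate_clinical(0, seed = s))$n_abnormal, numeric(1))
    expect_true(all(nab >= 2))
})

test_that("cohort generation is deterministic with unique barcodes", {
    c1 <- simulate_cohort(n_per_type = c(G1 = 3, G2 = 4, G3 = 2),
                          refdb = default_ref, n_pairs = 50, seed = 21)
    c2 <- simulate_cohort(n_per_type = c(G1 = 3, G2 = 4, G3 = 2),
                          refdb = default_ref, n_pairs = 50, seed = 21)
    expect_identical(c1$compositions, c2$compositions)
    expect_identical(c1$reads, c2$reads)
    expect_identical(c1$clinical, c2$clinical)
    expect_false(anyDuplicated(c1$samples$barcode) > 0)
    expect_true(all(rowSums(c1$compositions) - 1 < 1e-9))
})
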