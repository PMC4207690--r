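mid_normal <- data.frame(volume = 3, concentration = 60e6, motility = 60,
                         kruger = 10, iga = 5, atypical = 0.2,
                         leukocytes = 1e5)

test_that("clinical flagging applies the criterion thresholds", {
    f <- flag_clinical(mid_normal)
    expect_equal(f$n_abnormal, 0)
    expect_true(flag_clinical(transform(mid_normal, volume = 7.0))$volume)
    expect_true(flag_clinical(transform(mid_normal, volume = 1.0))$volume)
    expect_true(flag_clinical(transform(mid_normal, kruger = 4))$kruger)
    expect_false(flag_clinical(transform(mid_normal, kruger = 6))$kruger)
    expect_true(flag_clinical(transform(mid_normal, atypical = 1))$atypical)
    expect_true(flag_clinical(transform(mid_normal, iga = 31))$iga)
    expect_true(flag_clinical(transform(mid_normal,
                                        concentration = 14e6))$concentration)
    expect_true(flag_clinical(transform(mid_normal, motility = 39))$motility)
    expect_true(flag_clinical(transform(mid_normal,
                                        leukocytes = 2e6))$leukocytes)
    expect_error(flag_clinical(mid_normal[, -2]), "concentration")
})

test_that("class construction separates normal, case and excluded", {
    flags <- data.frame(n_abnormal = c(0, 3, 1, 2, 7))
    rownames(flags) <- sprintf("s%d", 1:5)
    cls <- define_classes(flags)
    expect_equal(as.character(cls),
                 c("normal", "case", "excluded", "case", "case"))
    cls3 <- define_classes(flags, min_abnormal_case = 3)
    expect_equal(as.character(cls3)[4], "excluded")
})

test_that("Mann-Whitney is exact for small untied samples", {
    expect_equal(mann_whitney(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
    expect_warning(p <- mann_whitney(c(2, 2), c(2, 2)), "identical")
    expect_equal(p, 1)
    expect_error(mann_whitney(numeric(0), 1), "nonempty")
    # exact path agrees with full enumeration for n <= 10 untied samples
    set.seed(71)
    for (i in 1:25) {
        nx <- sample(2:5, 1); ny <- sample(2:5, 1)
        v <- sample(1000, nx + ny)          # untied
        x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
        expect_equal(mann_whitney(x, y), oracle_mw_exact(x, y),
                     tolerance = 1e-12)
    }
    # large samples: agrees with the tie-corrected normal approximation
    set.seed(72)
    x <- rnorm(40); y <- rnorm(45, 0.5)
    expect_equal(mann_whitney(x, y),
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("abundance filter is strict at the 0.25 percent threshold", {
    P <- cbind(a = rep(0.003, 10), b = rep(0.0025, 10), c = rep(0.9945, 10))
    expect_setequal(abundance_filter(P), c("a", "c"))
    expect_setequal(abundance_filter(P, 0), c("a", "b", "c"))
})

test_that("adaptive BH runs the two-stage procedure", {
    ab <- adaptive_bh(rep(1, 5))
    expect_equal(sum(ab$rejected), 0)
    expect_equal(ab$m0, 5)
    # hand execution: stage 1 at alpha' = 0.05/1.05 rejects p = 0.001,
    # m0 = 3, stage 2 at 0.05 * 4/3 still rejects only the first
    ab2 <- adaptive_bh(c(0.001, 0.8, 0.9, 0.95))
    expect_equal(ab2$m0, 3)
    expect_equal(which(ab2$rejected), 1L)
    expect_error(adaptive_bh(c(0.5, 1.2)), "0, 1")
    # adaptive rejections always contain the plain BH rejections
    set.seed(13)
    for (i in 1:100) {
        p <- runif(sample(5:60, 1)) ^ sample(1:3, 1)
        ab <- adaptive_bh(p, 0.05)
        bh <- p.adjust(p, "BH") <= 0.05
        expect_true(all(!bh | ab$rejected))
        expect_true(all(ab$q >= p * ab$m0 / length(p) - 1e-12))
    }
})

test_that("significance tiers pick the finest threshold above p", {
    expect_equal(tier(0.03), "0.05")
    expect_equal(tier(0.0005), "0.001")
    expect_equal(tier(0.2), "ns")
    expect_equal(tier(0.05), "ns")          # not strictly below
    expect_equal(tier(0.001), "0.01")
    # monotone in p
    p <- sort(runif(50))
    lv <- c("0.001", "0.01", "0.05", "ns")
    expect_true(!is.unsorted(match(tier(p), lv)))
})

test_that("Fisher test reproduces the printed group comparisons", {
    g1 <- fisher_or(matrix(c(5, 20, 29, 26), 2, byrow = TRUE))
    expect_equal(signif(g1$p.value, 3), 7.38e-3)
    g3 <- fisher_or(matrix(c(2, 14, 29, 26), 2, byrow = TRUE))
    expect_equal(signif(g3$p.value, 3), 4.48e-3)
    flat <- fisher_or(matrix(c(5, 5, 5, 5), 2))
    expect_equal(flat$p.value, 1)
    expect_equal(flat$odds_ratio, 1)
    # invariance to transposition and simultaneous row+column swap
    tab <- matrix(c(3, 11, 9, 4), 2)
    expect_equal(fisher_or(t(tab))$p.value, fisher_or(tab)$p.value)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_or(swapped)$p.value, fisher_or(tab)$p.value)
    # zero margin is degenerate
    z <- fisher_or(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))
    expect_equal(z$p.value, 1)
    expect_true(z$degenerate)
    # Haldane correction on a zero cell
    h <- fisher_or(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))
    expect_true(h$haldane)
    expect_equal(h$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("Spearman network links strict-threshold correlations", {
    set.seed(8)
    x <- rnorm(30)
    P <- cbind(a = x, b = 2 * x, c = rnorm(30), d = rep(0.1, 30))
    expect_warning(net <- spearman_network(P, 0.4), "constant")
    expect_false("d" %in% net$nodes)
    e_ab <- net$edges[net$edges$g1 == "a" & net$edges$g2 == "b", ]
    expect_equal(e_ab$rho, 1)
    # threshold is strict: an edge exactly at the threshold is dropped
    rho_ac <- cor(x, P[, "c"], method = "spearman")
    net2 <- spearman_network(P[, 1:3], threshold = abs(rho_ac))
    expect_false(any(net2$edges$g1 == "a" & net2$edges$g2 == "c"))
    expect_error(spearman_network(P[1:2, ]), "three samples")
    # definition-level oracle: rho equals correlation of average ranks
    for (i in 1:20) {
        u <- sample(20, replace = TRUE); v <- sample(20, replace = TRUE)
        expect_equal(cor(cbind(u, v), method = "spearman")[1, 2],
                     cor(rank(u), rank(v)), tolerance = 1e-12)
    }
})

test_that("ego networks cut the graph at the requested depth", {
    net <- structure(list(nodes = c("a", "b", "c", "d", "e"),
                          edges = data.frame(g1 = c("a", "b", "c"),
                                             g2 = c("b", "c", "d"),
                                             rho = c(.5, .6, .7)),
                          threshold = 0.4),
                     class = "cooccurrence_network")
    expect_setequal(ego_network(net, "a", 2)$nodes, c("a", "b", "c"))
    expect_setequal(ego_network(net, "e", 2)$nodes, "e")   # isolated center
    one <- ego_network(net, "b", 1)
    expect_setequal(one$nodes, c("a", "b", "c"))
    expect_error(ego_network(net, "zz"), "unknown center")
})

test_that("differential abundance recovers a planted case enrichment", {
    set.seed(31)
    gm_norm <- rsimplex(12)
    gm_case <- gm_norm
    gm_case[1] <- 2 * gm_case[1]             # 2x mean in cases
    gm_case <- gm_case / sum(gm_case)
    draw <- function(n, m) t(replicate(n, {
        g <- rgamma(12, 25 * m); g / sum(g)
    }))
    P <- rbind(draw(36, gm_norm), draw(33, gm_case))
    colnames(P) <- paste0("g", 1:12)
    rownames(P) <- sprintf("s%02d", 1:69)
    grp <- setNames(rep(c("normal", "case"), c(36, 33)), rownames(P))
    res <- diff_abundance(make_profile(P), factor(grp))
    hit <- res[res$taxon == "g1", ]
    expect_true(hit$rejected)
    expect_equal(hit$direction, "case")
    expect_true(all(res$q >= 0 & res$q <= 1))
    expect_true(all(res$tier[!res$rejected] == "ns"))
})

test_that("CASA associations find the planted morphology link", {
    set.seed(44)
    n <- 96
    P <- t(replicate(n, rsimplex(8)))
    colnames(P) <- paste0("g", 1:8)
    rownames(P) <- sprintf("s%02d", 1:n)
    casa <- data.frame(
        head_elongation = 50 + 20 * P[, "g1"] + rnorm(n, 0, 2),
        VAP = rnorm(n, 50, 10),
        flat = rep(1, n))
    rownames(casa) <- rownames(P)
    expect_warning(res <- casa_association(make_profile(P), casa), "constant")
    hit <- res[res$taxon == "g1" & res$metric == "head_elongation", ]
    expect_true(hit$rejected)
    expect_gt(hit$rho, 0)
    expect_false("flat" %in% res$metric)
})
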