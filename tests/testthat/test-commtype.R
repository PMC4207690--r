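test_that("weighted UniFrac matches hand values and handles errors", {
    t2 <- ape::read.tree(text = "(L1:1,L2:1);")
    expect_equal(weighted_unifrac(c(L1 = 1, L2 = 0), c(L1 = 0, L2 = 1), t2), 1)
    expect_equal(weighted_unifrac(c(L1 = .3, L2 = .7), c(L1 = .3, L2 = .7),
                                  t2), 0)
    t4 <- ape::read.tree(text = "((L1:1,L2:1):1,(L3:1,L4:1):1);")
    pa <- c(L1 = .5, L2 = .5, L3 = 0, L4 = 0)
    pb <- c(L1 = 0, L2 = 0, L3 = .5, L4 = .5)
    expect_equal(weighted_unifrac(pa, pb, t4),
                 oracle_unifrac(pa, pb, t4), tolerance = 1e-12)
    expect_equal(weighted_unifrac(pa, pb, t4, normalized = FALSE),
                 oracle_unifrac(pa, pb, t4, normalized = FALSE),
                 tolerance = 1e-12)
    expect_error(weighted_unifrac(c(L1 = 1, L9 = 0), pb, t4), "absent")
    expect_error(weighted_unifrac(c(L1 = .5, L2 = .1, L3 = 0, L4 = 0), pb,
                                  t4), "sum to 1")
})

test_that("UniFrac equals the branch-enumeration oracle on random trees", {
    set.seed(20240601)
    for (i in 1:200) {
        n <- sample(3:8, 1)
        tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
        pa <- setNames(rsimplex(n), tr$tip.label)
        pb <- setNames(rsimplex(n), tr$tip.label)
        got <- weighted_unifrac(pa, pb, tr)
        expect_equal(got, oracle_unifrac(pa, pb, tr), tolerance = 1e-10)
        # symmetry and bounds
        expect_equal(weighted_unifrac(pb, pa, tr), got, tolerance = 1e-12)
        expect_gte(got, 0); expect_lte(got, 1 + 1e-12)
        expect_equal(weighted_unifrac(pa, pa, tr), 0)
    }
})

test_that("UPGMA merges at half the pair distance", {
    D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
    hc <- upgma_cluster(D)
    expect_equal(hc$height[1], 0.5)
    expect_setequal(hc$merge[1, ], c(-1, -2))   # first merge joins a and b
    # n = 2: single merge
    D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    expect_length(upgma_cluster(D2)$height, 1)
    expect_error(upgma_cluster(matrix(0, 1, 1)), "two samples")
})

test_that("pseudo-F matches direct arithmetic and null behavior", {
    x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
    lab <- c("a", "a", "b", "b")
    # hand: WSS = 2*(0.05^2)*2 = 0.01, TSS = sum((x-5.05)^2) = 100.01
    f <- pseudo_f(x, lab)
    expect_equal(f, ((100.01 - 0.01) / 1) / (0.01 / 2), tolerance = 1e-9)
    # identical cluster centroids: WSS = TSS, F = 0
    xx <- matrix(c(0, 1, 0, 1), ncol = 1)
    expect_equal(pseudo_f(xx, c("a", "a", "b", "b")), 0)
    expect_error(pseudo_f(x, rep("a", 4)), "clusters")
    expect_error(pseudo_f(x, letters[1:4]), "clusters")
    # random labels on a structureless cloud: F ~ 1 in expectation
    set.seed(5)
    cloud <- matrix(rnorm(200), ncol = 2)
    fs <- replicate(300, pseudo_f(cloud, sample(rep(1:2, 50))))
    expect_lt(abs(mean(fs) - 1), 0.15)
    # distance-based variant agrees with coordinates on Euclidean input
    D <- as.matrix(dist(x))
    expect_equal(pseudo_f(D, lab, from = "distance"), f, tolerance = 1e-9)
})

test_that("pseudo-F selects the planted number of clusters", {
    set.seed(17)
    three <- rbind(cbind(rnorm(20, 0), rnorm(20, 0)),
                   cbind(rnorm(20, 6), rnorm(20, 6)),
                   cbind(rnorm(20, 12), rnorm(20, 0)))
    rownames(three) <- sprintf("p%02d", 1:60)
    D3 <- as.matrix(dist(three))
    expect_equal(choose_k(D3)$chosen_k, 3)
    two <- rbind(cbind(rnorm(20, 0), rnorm(20, 0)),
                 cbind(rnorm(20, 8), rnorm(20, 8)))
    rownames(two) <- sprintf("p%02d", 1:40)
    expect_equal(choose_k(as.matrix(dist(two)))$chosen_k, 2)
})

test_that("planted cluster count is recovered across replicates", {
    set.seed(99)
    hit <- replicate(100, {
        pts <- rbind(cbind(rnorm(15, 0), rnorm(15, 0)),
                     cbind(rnorm(15, 6), rnorm(15, 6)),
                     cbind(rnorm(15, 12), rnorm(15, 0)))
        rownames(pts) <- sprintf("p%02d", 1:45)
        choose_k(as.matrix(dist(pts)))$chosen_k == 3
    })
    expect_gte(mean(hit), 0.95)
})

test_that("Shannon and Chao1 agree with closed forms and vegan", {
    expect_equal(shannon(c(1)), 0)
    expect_equal(shannon(rep(1 / 7, 7)), log(7))
    expect_equal(shannon(c(.5, .25, .25)), 1.039721, tolerance = 1e-6)
    expect_equal(shannon(c(.5, .25, .25)),
                 unname(vegan::diversity(c(.5, .25, .25))),
                 tolerance = 1e-12)
    expect_equal(chao1(c(5, 3, 2)), 3)                 # no singletons
    expect_equal(chao1(c(1, 1, 2, 2, 5)), 5 + 2 * 1 / (2 * 3))
    expect_equal(chao1(c(1, 1, 1)), 6)
    counts <- c(1, 1, 1, 2, 2, 3, 7, 10)
    expect_equal(chao1(counts),
                 unname(vegan::estimateR(counts)["S.chao1"]),
                 tolerance = 1e-9)
    expect_error(chao1(c(0.5, 1)), "integer")
    expect_gte(chao1(c(1, 1, 2)), sum(c(1, 1, 2) > 0))
})

test_that("PCoA embeds Euclidean matrices exactly", {
    x <- c(0, 1, 3)
    D <- as.matrix(dist(x))
    rownames(D) <- colnames(D) <- c("a", "b", "c")
    pc <- pcoa(D)
    expect_lt(pc$reconstruction_error, 1e-8)
    expect_equal(as.matrix(dist(pc$points[, 1])), D, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # sign convention: largest-magnitude coordinate positive
    expect_gt(pc$points[which.max(abs(pc$points[, 1])), 1], 0)
    # agreement with classical MDS up to sign
    cm <- cmdscale(D, k = 1)
    expect_equal(abs(as.numeric(pc$points[, 1])), abs(as.numeric(cm)),
                 tolerance = 1e-8)
    # all-zero distances: zero coordinates
    Z <- matrix(0, 3, 3)
    expect_true(all(pcoa(Z)$points == 0))
    expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
    # 10-point Euclidean cloud reconstructs to 1e-8
    set.seed(3)
    Y <- matrix(rnorm(30), ncol = 3)
    expect_lt(pcoa(as.matrix(dist(Y)))$reconstruction_error, 1e-8)
})

test_that("group diversity comparisons detect planted shifts", {
    db <- tiny_ref
    # planted shift: group A 50% higher diversity than B
    set.seed(12)
    mkcounts <- function(n, even) t(replicate(n, {
        p <- rsimplex(6) ^ (1 / even)
        as.numeric(rmultinom(1, 2000, p / sum(p)))
    }))
    counts <- rbind(mkcounts(25, 3), mkcounts(55, 1))
    colnames(counts) <- db$taxonomy$seq_id
    rownames(counts) <- sprintf("s%02d", 1:80)
    prof <- make_profile(counts / rowSums(counts))
    prof$counts <- counts
    tab <- diversity_table(prof)
    grp <- setNames(rep(c("A", "B"), c(25, 55)), tab$sample_id)
    res <- compare_group_diversity(tab, grp)
    expect_lt(res$p[res$metric == "shannon"], 0.05)
    expect_error(compare_group_diversity(tab, rep("A", 80)), "two groups")
})
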