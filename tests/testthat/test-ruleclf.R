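five <- function(L, G, Pre, Pse, H) {
    m <- cbind(Lactobacillus = L, Gardnerella = G, Prevotella = Pre,
               Pseudomonas = Pse, Haemophilus = H)
    rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
    m
}

test_that("featurization builds proportions, ratios and the composite", {
    x <- featurize(five(0.6, 0.1, 0.1, 0.1, 0.1))
    expect_equal(unname(x[1, "composite_lacto"]), 2.0)
    expect_equal(unname(x[1, "prop_Lactobacillus"]), 0.6)
    expect_equal(unname(x[1, "ratio_Prevotella_Pseudomonas"]), 1.0)
    expect_equal(unname(x[1, "vsrest_Lactobacillus"]), 0.6 / 0.4)
    expect_equal(ncol(x), 5 + 20 + 5 + 1)
    # zero denominators are sentinel-coded and flagged
    z <- featurize(five(0, 0, 0, 0, 0))
    und <- attr(z, "undefined")
    expect_true(all(und[1, grep("^ratio_|^vsrest_|composite",
                                colnames(z))]))
    # column order of the input does not matter
    p <- five(0.5, 0.2, 0.1, 0.1, 0.1)
    expect_equal(featurize(p), featurize(p[, c(3, 1, 5, 2, 4), drop = FALSE]))
})

test_that("the fixed published rule reproduces its worked classifications", {
    p <- five(c(0.60, 0.05, 0.05), c(0, 0, 0), c(0.10, 0.30, 0.10),
              c(0.10, 0.10, 0.30), c(0.10, 0.05, 0.05))
    expect_equal(as.character(fixed_rule_classify(p)),
                 c("G2", "G3", "G1"))
    # scale invariance: the rule uses ratios only
    expect_equal(fixed_rule_classify(p * 0.5), fixed_rule_classify(p))
    # infinite composite ratio classifies to G2
    expect_equal(as.character(fixed_rule_classify(five(0.3, 0, 0, 0, 0))),
                 "G2")
    expect_warning(cls <- fixed_rule_classify(five(0, 0.5, 0, 0, 0)),
                   "classified G1")
    expect_equal(as.character(cls), "G1")
})

test_that("threshold edges of the fixed rule are honored", {
    # composite exactly 0.57 is NOT greater than 0.57 -> falls through
    at <- five(0.57, 0, 0.5, 0.5, 0)      # composite = 0.57, Pre/Pse = 1
    expect_equal(as.character(fixed_rule_classify(at)), "G1")
    above <- five(0.5701, 0, 0.5, 0.5, 0)
    expect_equal(as.character(fixed_rule_classify(above)), "G2")
    at2 <- five(0.1, 0, 1.37, 1, 0)       # Pre/Pse = 1.37 exactly
    expect_equal(as.character(fixed_rule_classify(at2)), "G1")
})

test_that("tree induction recovers a planted rule", {
    set.seed(61)
    P <- t(replicate(500, rsimplex(5)))
    colnames(P) <- c("Lactobacillus", "Gardnerella", "Prevotella",
                     "Pseudomonas", "Haemophilus")
    rownames(P) <- sprintf("s%03d", 1:500)
    y <- fixed_rule_classify(P)
    x <- featurize(P)
    model <- train_tree(x, y, seed = 1)
    expect_equal(mean(predict(model, x) == y), 1)       # noiseless recovery
    rs <- root_split(model)
    expect_equal(rs$feature, "composite_lacto")
    expect_lt(abs(rs$threshold - 0.57), 0.05)
    # decision regions agree with the rule on a fresh grid
    set.seed(62)
    Pnew <- t(replicate(2000, rsimplex(5)))
    colnames(Pnew) <- colnames(P)
    agree <- mean(predict(model, featurize(Pnew)) == fixed_rule_classify(Pnew))
    expect_gte(agree, 0.99)
    expect_error(train_tree(x, rep("G1", 500)), "single class")
})

test_that("label permutation drops accuracy to the majority rate", {
    set.seed(63)
    P <- t(replicate(120, rsimplex(5)))
    colnames(P) <- c("Lactobacillus", "Gardnerella", "Prevotella",
                     "Pseudomonas", "Haemophilus")
    rownames(P) <- sprintf("s%03d", 1:120)
    x <- featurize(P)
    y <- factor(rep(c("G1", "G2"), 60))
    accs <- vapply(1:10, function(s) {
        yp <- with_seed(s, sample(y))
        evaluate_cv(x, yp, folds = 5, seed = s)$accuracy
    }, numeric(1))
    expect_lt(mean(accs), 0.65)             # near the 0.5 majority rate
})

test_that("cross-validation pools folds and scores sanely", {
    set.seed(64)
    P <- t(replicate(150, rsimplex(5)))
    colnames(P) <- c("Lactobacillus", "Gardnerella", "Prevotella",
                     "Pseudomonas", "Haemophilus")
    rownames(P) <- sprintf("s%03d", 1:150)
    x <- featurize(P)
    y <- fixed_rule_classify(P)
    cv <- evaluate_cv(x, y, folds = 5, seed = 2)
    # every sample appears in exactly one test fold
    expect_equal(sort(unique(cv$fold)), 1:5)
    expect_length(cv$fold, 150)
    # folds are stratified: each class spread over all folds
    expect_true(all(table(y, cv$fold) > 0))
    # near-separable synthetic data: high AUC for every class
    expect_true(all(cv$auc > 0.9))
    expect_equal(sum(cv$confusion), 150)
    # AUC invariant to class renaming
    y2 <- factor(as.character(y), levels = c("G1", "G2", "G3"),
                 labels = c("Z", "Q", "A"))
    cv2 <- evaluate_cv(x, y2, folds = 5, seed = 2)
    expect_equal(unname(sort(cv2$auc)), unname(sort(cv$auc)),
                 tolerance = 1e-12)
    expect_error(evaluate_cv(x, y, folds = 500), "smallest class")
})

test_that("rank AUC equals trapezoidal ROC integration", {
    set.seed(65)
    for (i in 1:10) {
        score <- round(runif(60), 2)         # ties included
        truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
        got <- semtype:::.auc(score, truth)
        ref <- as.numeric(suppressMessages(
            pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                direction = "<"))))
        expect_equal(got, ref, tolerance = 1e-12)
    }
})

test_that("perfectly separable data reaches AUC 1", {
    x <- cbind(f = c(rnorm(30, 0), rnorm(30, 30)))
    rownames(x) <- sprintf("s%d", 1:60)
    y <- factor(rep(c("A", "B"), each = 30))
    cv <- evaluate_cv(x, y, folds = 5, seed = 3)
    expect_equal(unname(cv$auc), c(1, 1))
    expect_equal(cv$accuracy, 1)
})
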