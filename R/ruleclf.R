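.marker_genera <- c("Lactobacillus", "Gardnerella", "Prevotella",
                    "Pseudomonas", "Haemophilus")
.ratio_sentinel <- 1e6

#' Build the five-genus proportion and ratio feature set
#'
#' Features per sample: the proportions of the five marker genera
#' (Lactobacillus, Gardnerella, Prevotella, Pseudomonas, Haemophilus;
#' zero when absent), all 20 ordered pairwise ratios, each genus against
#' the sum of the other four, and the composite ratio
#' Lactobacillus / (Prevotella + Pseudomonas + Haemophilus). Ratios with a
#' zero denominator are encoded as a large sentinel (1e6) and flagged in
#' the \code{"undefined"} attribute; samples lacking a genus are
#' biologically meaningful and are kept.
#'
#' @param props samples x genera proportion matrix (column order is
#'   irrelevant; absent marker genera count as zero).
#' @return numeric feature matrix (one row per sample) with attribute
#'   \code{"undefined"} (logical matrix marking sentinel-coded cells).
#' @export
featurize <- function(props) {
    props <- as.matrix(props)
    g <- matrix(0, nrow(props), 5,
                dimnames = list(rownames(props), .marker_genera))
    have <- intersect(colnames(props), .marker_genera)
    g[, have] <- props[, have]
    ratio <- function(num, den) ifelse(den > 0, num / den,
                                       .ratio_sentinel)
    feats <- list()
    for (nm in .marker_genera) feats[[paste0("prop_", nm)]] <- g[, nm]
    for (a in .marker_genera) for (b in .marker_genera) if (a != b)
        feats[[paste0("ratio_", a, "_", b)]] <- ratio(g[, a], g[, b])
    for (a in .marker_genera)
        feats[[paste0("vsrest_", a)]] <-
            ratio(g[, a], rowSums(g[, setdiff(.marker_genera, a),
                                    drop = FALSE]))
    feats[["composite_lacto"]] <-
        ratio(g[, "Lactobacillus"],
              g[, "Prevotella"] + g[, "Pseudomonas"] + g[, "Haemophilus"])
    x <- do.call(cbind, feats)
    rownames(x) <- rownames(props)
    attr(x, "undefined") <- x == .ratio_sentinel
    x
}

#' Classify samples with the fixed published decision rule
#'
#' The two-step rule: a sample with
#' Lactobacillus / (Prevotella + Pseudomonas + Haemophilus) > 0.57 is G2;
#' otherwise it is G3 if Prevotella / Pseudomonas > 1.37, else G1. An
#' infinite composite ratio (positive numerator over zero denominator)
#' classifies to G2; a 0/0 composite is flagged and classified G1 with a
#' warning. The rule depends only on ratios, so it is invariant to
#' rescaling all five proportions.
#'
#' @param props samples x genera proportion matrix (marker genera absent
#'   from the columns count as zero).
#' @return factor of classes G1/G2/G3, one per row.
#' @export
fixed_rule_classify <- function(props) {
    props <- as.matrix(props)
    g <- matrix(0, nrow(props), 5,
                dimnames = list(rownames(props), .marker_genera))
    have <- intersect(colnames(props), .marker_genera)
    g[, have] <- props[, have]
    L <- g[, "Lactobacillus"]; Pre <- g[, "Prevotella"]
    Pse <- g[, "Pseudomonas"]; H <- g[, "Haemophilus"]
    den <- Pre + Pse + H
    tie <- den == 0 & L == 0
    if (any(tie))
        warning(sum(tie), " sample(s) with all rule genera absent; ",
                "classified G1")
    comp <- ifelse(den > 0, L / den, ifelse(L > 0, Inf, 0))
    rr <- ifelse(Pse > 0, Pre / Pse, ifelse(Pre > 0, Inf, 0))
    cls <- ifelse(comp > 0.57, "G2", ifelse(rr > 1.37, "G3", "G1"))
    factor(setNames(cls, rownames(props)), levels = c("G1", "G2", "G3"))
}

# entropy (nats) of class-count rows; zero-safe
.entropy_rows <- function(counts) {
    tot <- rowSums(counts)
    p <- counts / ifelse(tot == 0, 1, tot)
    -rowSums(ifelse(p > 0, p * log(p), 0))
}

# best (threshold, gain ratio) of one feature column; NULL when no
# admissible split has positive information gain
.best_split <- function(v, ymat, min_leaf) {
    o <- order(v)
    vo <- v[o]
    cum <- apply(ymat[o, , drop = FALSE], 2, cumsum)
    n <- length(v)
    tot <- cum[n, ]
    cand <- which(vo[-n] < vo[-1])           # cuts between distinct values
    cand <- cand[cand >= min_leaf & n - cand >= min_leaf]
    if (length(cand) == 0) return(NULL)
    left <- cum[cand, , drop = FALSE]
    right <- rep(tot, each = length(cand)) - left
    nl <- cand; nr <- n - cand
    h_parent <- .entropy_rows(matrix(tot, 1))[1]
    gain <- h_parent - (nl * .entropy_rows(left) +
                        nr * .entropy_rows(right)) / n
    pi_l <- nl / n
    split_info <- -(pi_l * log(pi_l) + (1 - pi_l) * log(1 - pi_l))
    ok <- gain > 1e-12 & split_info > 0
    if (!any(ok)) return(NULL)
    gr <- gain[ok] / split_info[ok]
    best <- which.max(gr)
    cut <- cand[ok][best]
    list(threshold = (vo[cut] + vo[cut + 1]) / 2, gain_ratio = gr[best])
}

.grow_tree <- function(x, y, min_leaf) {
    counts <- table(y)
    leaf <- function() list(leaf = TRUE,
                            class = names(counts)[which.max(counts)],
                            freq = setNames(as.numeric(counts) / sum(counts),
                                            names(counts)),
                            n = length(y))
    if (length(unique(y)) == 1 || length(y) < 2 * min_leaf) return(leaf())
    ymat <- outer(y, levels(y), "==") * 1
    best <- NULL
    for (j in seq_len(ncol(x))) {
        s <- .best_split(x[, j], ymat, min_leaf)
        if (!is.null(s) &&
            (is.null(best) || s$gain_ratio > best$gain_ratio + 1e-12))
            best <- c(s, feature = colnames(x)[j])
    }
    if (is.null(best)) return(leaf())
    go_left <- x[, best$feature] <= best$threshold
    node <- leaf()
    node$leaf <- FALSE
    node$feature <- best$feature
    node$threshold <- best$threshold
    node$left <- .grow_tree(x[go_left, , drop = FALSE],
                            droplevels(y[go_left]), min_leaf)
    node$right <- .grow_tree(x[!go_left, , drop = FALSE],
                             droplevels(y[!go_left]), min_leaf)
    node
}

# reduced-error pruning: replace a subtree by its majority leaf whenever
# that does not reduce accuracy on the held-out prune set
.prune_tree <- function(node, x, y) {
    if (node$leaf) return(node)
    if (nrow(x) == 0) {
        return(list(leaf = TRUE, class = node$class, freq = node$freq,
                    n = node$n))
    }
    go_left <- x[, node$feature] <= node$threshold
    node$left <- .prune_tree(node$left, x[go_left, , drop = FALSE],
                             y[go_left])
    node$right <- .prune_tree(node$right, x[!go_left, , drop = FALSE],
                              y[!go_left])
    acc_sub <- mean(.predict_node(node, x) == y)
    acc_leaf <- mean(node$class == y)
    if (acc_leaf >= acc_sub)
        return(list(leaf = TRUE, class = node$class, freq = node$freq,
                    n = node$n))
    node
}

.predict_node <- function(node, x) {
    if (node$leaf) return(rep(node$class, nrow(x)))
    out <- character(nrow(x))
    go_left <- x[, node$feature] <= node$threshold
    out[go_left] <- .predict_node(node$left, x[go_left, , drop = FALSE])
    out[!go_left] <- .predict_node(node$right, x[!go_left, , drop = FALSE])
    out
}

.predict_prob <- function(node, x, levels) {
    if (nrow(x) == 0)
        return(matrix(numeric(0), 0, length(levels),
                      dimnames = list(NULL, levels)))
    if (node$leaf) {
        freq <- setNames(numeric(length(levels)), levels)
        freq[names(node$freq)] <- node$freq
        return(matrix(freq, nrow(x), length(levels), byrow = TRUE,
                      dimnames = list(rownames(x), levels)))
    }
    out <- matrix(0, nrow(x), length(levels),
                  dimnames = list(rownames(x), levels))
    go_left <- x[, node$feature] <= node$threshold
    out[go_left, ] <- .predict_prob(node$left, x[go_left, , drop = FALSE],
                                    levels)
    out[!go_left, ] <- .predict_prob(node$right, x[!go_left, , drop = FALSE],
                                     levels)
    out
}

#' Train a C4.5-style decision tree over ratio features
#'
#' Recursive partitioning with numeric splits at midpoints of consecutive
#' distinct feature values, chosen to maximize the gain ratio
#' (information gain divided by split information), stopping at pure
#' nodes, the minimum leaf size, or when no split has positive gain.
#' Optional reduced-error pruning holds out a fraction of the training
#' data and collapses subtrees that do not help held-out accuracy.
#' Deterministic given the seed.
#'
#' @param x feature matrix, e.g. from [featurize()].
#' @param y class labels (>= 2 classes present).
#' @param min_leaf minimum samples per leaf.
#' @param prune apply reduced-error pruning.
#' @param prune_fraction held-out fraction used for pruning.
#' @param seed seed for the pruning holdout.
#' @return object of class \code{rule_tree} with the fitted tree, class
#'   levels and training metadata.
#' @export
train_tree <- function(x, y, min_leaf = 2, prune = FALSE,
                       prune_fraction = 0.25, seed = 1) {
    x <- as.matrix(x)
    y <- droplevels(factor(y))
    if (nlevels(y) < 2) stop("training data contains a single class")
    if (prune) {
        idx <- with_seed(seed, sample.int(nrow(x)))
        n_hold <- max(1, floor(prune_fraction * nrow(x)))
        hold <- idx[seq_len(n_hold)]
        grow <- setdiff(idx, hold)
        if (nlevels(droplevels(y[grow])) < 2) {
            grow <- seq_len(nrow(x)); hold <- integer(0)
        }
        root <- .grow_tree(x[grow, , drop = FALSE], droplevels(y[grow]),
                           min_leaf)
        if (length(hold))
            root <- .prune_tree(root, x[hold, , drop = FALSE],
                                as.character(y[hold]))
    } else {
        root <- .grow_tree(x, y, min_leaf)
    }
    structure(list(root = root, levels = levels(y), min_leaf = min_leaf,
                   pruned = prune, n_train = nrow(x)),
              class = "rule_tree")
}

#' @export
predict.rule_tree <- function(object, newdata, type = c("class", "prob"),
                              ...) {
    type <- match.arg(type)
    x <- as.matrix(newdata)
    if (type == "class")
        return(factor(.predict_node(object$root, x), levels = object$levels))
    .predict_prob(object$root, x, object$levels)
}

#' @export
print.rule_tree <- function(x, ...) {
    show <- function(node, indent) {
        pad <- strrep("  ", indent)
        if (node$leaf) {
            cat(pad, "-> ", node$class, " (n=", node$n, ")\n", sep = "")
        } else {
            cat(pad, "if ", node$feature, " <= ",
                format(node$threshold, digits = 4), ":\n", sep = "")
            show(node$left, indent + 1)
            cat(pad, "else:\n", sep = "")
            show(node$right, indent + 1)
        }
    }
    cat("rule_tree (", length(x$levels), " classes, n_train = ",
        x$n_train, ")\n", sep = "")
    show(x$root, 0)
    invisible(x)
}

#' Root split of a fitted rule tree
#'
#' @param model a \code{rule_tree}.
#' @return list with \code{feature} and \code{threshold} (NULL for a
#'   stump).
#' @export
root_split <- function(model) {
    if (model$root$leaf) return(NULL)
    list(feature = model$root$feature, threshold = model$root$threshold)
}

# rank-based one-vs-rest AUC (equals trapezoidal ROC integration)
.auc <- function(score, positive) {
    n_pos <- sum(positive); n_neg <- sum(!positive)
    if (n_pos == 0 || n_neg == 0) return(NA_real_)
    r <- rank(score)
    (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified cross-validation of the rule-tree classifier
#'
#' Stratified k-fold assignment (seeded, every sample in exactly one test
#' fold); per-class one-vs-rest ROC AUC is computed from leaf
#' class-frequency scores pooled over all folds. If a class is entirely
#' absent from some training split, folds are redrawn with a warning.
#'
#' @param x feature matrix.
#' @param y class labels; \code{folds} must not exceed the smallest class
#'   count.
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @param min_leaf,prune passed to [train_tree()].
#' @return list with \code{auc} (named per class), \code{accuracy},
#'   \code{confusion} (truth x prediction table), \code{scores} (pooled
#'   class-frequency matrix) and \code{fold} assignment.
#' @export
evaluate_cv <- function(x, y, folds = 5, seed = 1, min_leaf = 2,
                        prune = FALSE) {
    x <- as.matrix(x)
    y <- droplevels(factor(y))
    if (folds > min(table(y)))
        stop("folds exceeds the smallest class count")
    make_folds <- function(s) with_seed(s, {
        f <- integer(length(y))
        for (l in levels(y)) {
            i <- sample(which(y == l))
            f[i] <- rep_len(seq_len(folds), length(i))
        }
        f
    })
    fold <- make_folds(seed)
    for (retry in 1:10) {
        ok <- all(vapply(seq_len(folds), function(k)
            nlevels(droplevels(y[fold != k])) == nlevels(y), logical(1)))
        if (ok) break
        warning("a class was absent from a training split; refolding")
        fold <- make_folds(seed + retry)
    }
    scores <- matrix(NA_real_, length(y), nlevels(y),
                     dimnames = list(rownames(x), levels(y)))
    pred <- factor(rep(NA, length(y)), levels = levels(y))
    for (k in seq_len(folds)) {
        tr <- fold != k
        model <- train_tree(x[tr, , drop = FALSE], y[tr],
                            min_leaf = min_leaf, prune = prune, seed = seed)
        prob <- predict(model, x[!tr, , drop = FALSE], type = "prob")
        scores[!tr, colnames(prob)] <- prob
        pred[!tr] <- predict(model, x[!tr, , drop = FALSE])
    }
    scores[is.na(scores)] <- 0
    auc <- vapply(levels(y), function(l) .auc(scores[, l], y == l),
                  numeric(1))
    list(auc = auc, accuracy = mean(pred == y),
         confusion = table(truth = y, predicted = pred),
         scores = scores, fold = fold)
}
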