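# branch structure of a rooted phylo tree: per-edge lengths, the leaf set
# descending through each edge, and root-to-leaf path lengths
tree_branches <- function(tree) {
    if (is.null(tree$edge.length)) stop("tree must have branch lengths")
    n_tip <- length(tree$tip.label)
    n_edge <- nrow(tree$edge)
    inc <- matrix(FALSE, n_edge, n_tip,
                  dimnames = list(NULL, tree$tip.label))
    # accumulate descendant tips per edge in reverse (post)order
    desc <- vector("list", n_tip + tree$Nnode)
    for (i in seq_len(n_tip)) desc[[i]] <- i
    # iterate until every internal node has its descendant tip set
    repeat {
        done <- TRUE
        for (e in seq_len(n_edge)) {
            ch <- tree$edge[e, 2]
            if (ch > n_tip && is.null(desc[[ch]])) {
                kids <- tree$edge[tree$edge[, 1] == ch, 2]
                if (all(!vapply(desc[kids], is.null, logical(1))))
                    desc[[ch]] <- unlist(desc[kids])
                else done <- FALSE
            }
        }
        if (done) break
    }
    for (e in seq_len(n_edge)) inc[e, desc[[tree$edge[e, 2]]]] <- TRUE
    depths <- as.numeric(t(inc) %*% tree$edge.length)
    names(depths) <- tree$tip.label
    list(lengths = tree$edge.length, incidence = inc, depths = depths)
}

#' Weighted UniFrac distance between two communities
#'
#' The raw distance sums, over every branch, the branch length times the
#' absolute difference in the fraction of each community descending through
#' that branch; the normalized variant (default) divides by
#' \eqn{\sum_j d_j (p_{Aj} + p_{Bj})} with \eqn{d_j} the root-to-leaf path
#' length, which bounds the distance in [0, 1].
#'
#' @param p_a,p_b named proportion vectors over the tree's leaves, each
#'   summing to 1 (missing leaves are not allowed; use
#'   [expand_to_leaves()]).
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param normalized divide by the abundance-weighted depth sum.
#' @return nonnegative distance (in [0, 1] when normalized).
#' @export
weighted_unifrac <- function(p_a, p_b, tree, normalized = TRUE) {
    br <- tree_branches(tree)
    leaves <- tree$tip.label
    miss <- setdiff(union(names(p_a), names(p_b)), leaves)
    if (length(miss))
        stop("taxa absent from tree: ", paste(head(miss, 5), collapse = ", "))
    pa <- setNames(numeric(length(leaves)), leaves); pa[names(p_a)] <- p_a
    pb <- setNames(numeric(length(leaves)), leaves); pb[names(p_b)] <- p_b
    check_simplex(pa, what = "p_a"); check_simplex(pb, what = "p_b")
    raw <- sum(br$lengths * abs(br$incidence %*% (pa - pb)))
    if (!normalized) return(raw)
    D <- sum(br$depths * (pa + pb))
    if (D == 0) return(0)
    raw / D
}

#' Expand a proportion matrix to a tree's full leaf set
#'
#' @param P samples x taxa proportion matrix.
#' @param tree \code{ape::phylo}.
#' @return matrix with one column per tree leaf (zeros for absent taxa).
#' @export
expand_to_leaves <- function(P, tree) {
    miss <- setdiff(colnames(P), tree$tip.label)
    if (length(miss))
        stop("taxa absent from tree: ", paste(head(miss, 5), collapse = ", "))
    out <- matrix(0, nrow(P), length(tree$tip.label),
                  dimnames = list(rownames(P), tree$tip.label))
    out[, colnames(P)] <- P
    out
}

#' Weighted UniFrac distance matrix for a cohort
#'
#' @param P samples x leaves proportion matrix (rows summing to 1).
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param normalized as in [weighted_unifrac()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
unifrac_matrix <- function(P, tree, normalized = TRUE) {
    P <- expand_to_leaves(P, tree)
    for (i in seq_len(nrow(P))) check_simplex(P[i, ],
                                              what = rownames(P)[i])
    br <- tree_branches(tree)
    A <- P %*% t(br$incidence)          # samples x branches
    s <- as.numeric(P %*% br$depths)    # abundance-weighted depths
    n <- nrow(P)
    D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        raw <- sum(br$lengths * abs(A[i, ] - A[j, ]))
        D[i, j] <- D[j, i] <- if (normalized) {
            den <- s[i] + s[j]
            if (den == 0) 0 else raw / den
        } else raw
    }
    D
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; merge heights are the ultrametric node
#' heights (half the average between-cluster distance), so a pair at
#' distance d merges at height d/2. Ties are resolved by the deterministic
#' ordering of \code{stats::hclust}.
#'
#' @param D symmetric distance matrix or \code{dist}.
#' @return an \code{hclust} object with halved heights.
#' @export
upgma_cluster <- function(D) {
    d <- as.dist(D)
    if (attr(d, "Size") < 2) stop("need at least two samples")
    hc <- hclust(d, method = "average")
    hc$height <- hc$height / 2
    hc$method <- "upgma"
    hc
}

#' Calinski-Harabasz pseudo-F statistic
#'
#' F = [(TSS - WSS)/(k - 1)] / [WSS/(n - k)], with TSS and WSS the total
#' and within-cluster sums of squared Euclidean deviations from the
#' overall and cluster centroids. With \code{from = "coords"} (default) x
#' is a coordinate matrix (e.g. PCoA axes); with \code{from = "distance"}
#' the sums of squares are computed directly from pairwise distances.
#'
#' @param x coordinate matrix (samples x axes) or distance matrix.
#' @param labels cluster labels (one per sample, every cluster nonempty).
#' @param from \code{"coords"} or \code{"distance"}.
#' @return the pseudo-F value.
#' @export
pseudo_f <- function(x, labels, from = c("coords", "distance")) {
    from <- match.arg(from)
    labels <- as.factor(labels)
    k <- nlevels(droplevels(labels))
    n <- length(labels)
    if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
    if (any(table(labels) == 0)) stop("empty cluster")
    if (from == "coords") {
        x <- as.matrix(x)
        tss <- sum(scale(x, scale = FALSE) ^ 2)
        wss <- sum(vapply(levels(labels), function(l) {
            xi <- x[labels == l, , drop = FALSE]
            sum(scale(xi, scale = FALSE) ^ 2)
        }, numeric(1)))
    } else {
        d2 <- as.matrix(x) ^ 2
        tss <- sum(d2[upper.tri(d2)]) / n
        wss <- sum(vapply(levels(labels), function(l) {
            i <- labels == l
            di <- d2[i, i, drop = FALSE]
            sum(di[upper.tri(di)]) / sum(i)
        }, numeric(1)))
    }
    if (tss == 0) return(0)
    ((tss - wss) / (k - 1)) / (wss / (n - k))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition; axes
#' with eigenvalue above 1e-10 are retained and scaled by the square root
#' of their eigenvalue. Sign convention: on each axis the coordinate of
#' largest magnitude is positive. For non-Euclidean matrices (negative
#' eigenvalues, as UniFrac can produce) only the positive axes are kept and
#' the worst-case reconstruction error is reported.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return list with \code{points} (samples x axes), \code{eigenvalues}
#'   (all, descending) and \code{reconstruction_error} (max absolute
#'   difference between input and embedded distances).
#' @export
pcoa <- function(D) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
    n <- nrow(D)
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% (D ^ 2) %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    keep <- which(e$values > 1e-10)
    if (length(keep) == 0) {
        pts <- matrix(0, n, 1, dimnames = list(rownames(D), "Axis1"))
        return(list(points = pts, eigenvalues = e$values,
                    reconstruction_error = max(abs(D))))
    }
    pts <- e$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(e$values[keep]), length(keep))
    for (j in seq_len(ncol(pts)))
        if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
    dimnames(pts) <- list(rownames(D), paste0("Axis", seq_len(ncol(pts))))
    emb <- as.matrix(dist(pts))
    list(points = pts, eigenvalues = e$values,
         reconstruction_error = max(abs(emb - D)))
}

#' Choose the number of community types by pseudo-F
#'
#' Cuts the dendrogram at each k in \code{k_range}, evaluates the
#' Calinski-Harabasz pseudo-F on the positive PCoA axes of the distance
#' matrix, and picks the maximizing k (ties to the smallest k). Group
#' labels are G1..Gk in dendrogram cut order.
#'
#' @param D distance matrix.
#' @param dendrogram an \code{hclust}, e.g. from [upgma_cluster()]; built
#'   from \code{D} if NULL.
#' @param k_range candidate cluster numbers.
#' @return object of class \code{community_typing}: list with
#'   \code{dendrogram}, \code{chosen_k}, \code{labels} (named character,
#'   "G1".."Gk"), \code{pseudo_f} (named trace over k) and \code{pcoa}.
#' @export
choose_k <- function(D, dendrogram = NULL, k_range = 2:10) {
    n <- nrow(as.matrix(D))
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(k_range) == 0) stop("k_range outside [2, n-1]")
    if (is.null(dendrogram)) dendrogram <- upgma_cluster(D)
    pc <- pcoa(D)
    trace <- vapply(k_range, function(k)
        pseudo_f(pc$points, cutree(dendrogram, k = k)), numeric(1))
    names(trace) <- k_range
    chosen <- k_range[which.max(trace)]  # which.max takes the first (smallest k)
    cut <- cutree(dendrogram, k = chosen)
    labels <- setNames(paste0("G", cut), names(cut))
    structure(list(dendrogram = dendrogram, chosen_k = chosen,
                   labels = labels, pseudo_f = trace, pcoa = pc),
              class = "community_typing")
}

#' @export
print.community_typing <- function(x, ...) {
    cat("community_typing: k =", x$chosen_k, "(",
        paste(sprintf("%s=%d", names(table(x$labels)),
                      as.integer(table(x$labels))), collapse = ", "), ")\n")
    cat("pseudo-F trace:",
        paste(sprintf("k=%s:%.1f", names(x$pseudo_f), x$pseudo_f),
              collapse = "  "), "\n")
    invisible(x)
}

#' Shannon diversity index (natural log)
#'
#' @param p proportion vector summing to 1.
#' @return entropy in nats, \eqn{-\sum_{p_i>0} p_i \ln p_i}.
#' @export
shannon <- function(p) {
    check_simplex(p)
    p <- p[p > 0]
    -sum(p * log(p))
}

#' Chao1 richness estimate (bias-corrected)
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1} singleton
#' and \eqn{F_2} doubleton counts; the bias-corrected form is defined even
#' when no doubletons are observed. Requires integer read counts, not
#' proportions.
#'
#' @param counts nonnegative integer vector of per-taxon read counts.
#' @return the richness estimate (>= observed taxa).
#' @export
chao1 <- function(counts) {
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
        stop("chao1 requires nonnegative integer read counts")
    s_obs <- sum(counts > 0)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample diversity and richness table
#'
#' @param profile a \code{taxon_profile} (typically species rank) holding
#'   integer counts.
#' @return data.frame with \code{sample_id}, \code{shannon} (nats),
#'   \code{chao1} and \code{observed_taxa}; invalid samples are dropped.
#' @export
diversity_table <- function(profile) {
    keep <- which(profile$valid)
    data.frame(
        sample_id = rownames(profile$counts)[keep],
        shannon = vapply(keep, function(i)
            shannon(profile$proportions[i, ]), numeric(1)),
        chao1 = vapply(keep, function(i)
            chao1(profile$counts[i, ]), numeric(1)),
        observed_taxa = vapply(keep, function(i)
            sum(profile$counts[i, ] > 0), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise group comparisons of diversity metrics
#'
#' Two-sided Mann-Whitney tests of each diversity metric between every
#' pair of groups.
#'
#' @param table a [diversity_table()] result.
#' @param grouping factor/character of group labels, named by or aligned
#'   with \code{table$sample_id}.
#' @return data.frame with \code{metric}, \code{group1}, \code{group2},
#'   \code{p}.
#' @export
compare_group_diversity <- function(table, grouping) {
    if (!is.null(names(grouping))) grouping <- grouping[table$sample_id]
    grouping <- droplevels(as.factor(grouping))
    if (nlevels(grouping) < 2) stop("need at least two groups")
    if (any(table(grouping) == 0)) stop("empty group")
    metrics <- c("shannon", "chao1", "observed_taxa")
    pairs <- combn(levels(grouping), 2)
    out <- NULL
    for (m in metrics) for (j in seq_len(ncol(pairs))) {
        g1 <- pairs[1, j]; g2 <- pairs[2, j]
        p <- mann_whitney(table[[m]][grouping == g1],
                          table[[m]][grouping == g2])
        out <- rbind(out, data.frame(metric = m, group1 = g1, group2 = g2,
                                     p = p, stringsAsFactors = FALSE))
    }
    out
}
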