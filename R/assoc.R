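.criteria <- c("volume", "concentration", "motility", "kruger", "iga",
               "atypical", "leukocytes")

#' Flag the seven semen-quality criteria of a clinical table
#'
#' Applies the clinical abnormality thresholds: semen volume abnormal iff
#' >= 6.4 or <= 1.2 ml; sperm concentration abnormal iff < 15e6 cells/ml;
#' motility abnormal iff < 40 percent; Kruger strict morphology abnormal
#' iff <= 5 percent; antisperm antibody (IgA) abnormal iff > 30 percent;
#' atypical (very small sperm heads) abnormal iff >= 1 percent; leukocytes
#' abnormal iff observed, i.e. at least 1e6 cells/ml.
#'
#' @param clinical data.frame (or one-row record) with numeric columns
#'   \code{volume}, \code{concentration}, \code{motility}, \code{kruger},
#'   \code{iga}, \code{atypical} and either numeric \code{leukocytes}
#'   (cells/ml) or logical \code{leukocytes_observed}.
#' @return data.frame of logical abnormality flags per criterion plus
#'   \code{n_abnormal}; row names follow \code{clinical}.
#' @export
flag_clinical <- function(clinical) {
    clinical <- as.data.frame(clinical)
    need <- setdiff(.criteria, "leukocytes")
    miss <- setdiff(need, names(clinical))
    leuk <- if ("leukocytes" %in% names(clinical)) clinical$leukocytes >= 1e6
            else if ("leukocytes_observed" %in% names(clinical))
                as.logical(clinical$leukocytes_observed)
            else { miss <- c(miss, "leukocytes"); NULL }
    if (length(miss))
        stop("missing clinical fields: ", paste(miss, collapse = ", "))
    flags <- data.frame(
        volume = clinical$volume >= 6.4 | clinical$volume <= 1.2,
        concentration = clinical$concentration < 15e6,
        motility = clinical$motility < 40,
        kruger = clinical$kruger <= 5,
        iga = clinical$iga > 30,
        atypical = clinical$atypical >= 1,
        leukocytes = leuk,
        row.names = rownames(clinical))
    flags$n_abnormal <- rowSums(flags)
    flags
}

#' Assign case / normal / excluded classes from criterion flags
#'
#' A sample is \code{normal} iff it has no abnormal criterion, a
#' \code{case} iff it has at least \code{min_abnormal_case} abnormal
#' criteria, and \code{excluded} otherwise (such samples sit outside the
#' supervised comparison).
#'
#' @param flags a [flag_clinical()] result (needs \code{n_abnormal}).
#' @param min_abnormal_case abnormal-criterion count defining a case.
#' @return factor with levels \code{normal}, \code{case}, \code{excluded}.
#' @export
define_classes <- function(flags, min_abnormal_case = 2) {
    n_ab <- flags$n_abnormal
    cls <- ifelse(n_ab == 0, "normal",
                  ifelse(n_ab >= min_abnormal_case, "case", "excluded"))
    factor(setNames(cls, rownames(flags)),
           levels = c("normal", "case", "excluded"))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of the U null distribution when the pooled sample is
#' small (at most \code{exact_max_n}) and tie-free; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact_max_n pooled-size limit for the exact test.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(x, y, exact_max_n = 20) {
    if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
    if (length(unique(c(x, y))) == 1) {
        warning("all values identical in both groups; p = 1")
        return(1)
    }
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && (length(x) + length(y)) <= exact_max_n
    suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Filter taxa by cohort-mean proportion
#'
#' Retains taxa whose mean proportion across valid samples strictly
#' exceeds \code{min_proportion} (default 0.25 percent), the screen
#' applied before multiple testing.
#'
#' @param profile a \code{taxon_profile} or a proportions matrix.
#' @param min_proportion strict lower bound on the cohort-mean proportion.
#' @return character vector of retained taxon names.
#' @export
abundance_filter <- function(profile, min_proportion = 0.0025) {
    P <- if (inherits(profile, "taxon_profile"))
        profile$proportions[profile$valid, , drop = FALSE] else as.matrix(profile)
    means <- colMeans(P)
    names(means)[means > min_proportion]
}

#' Adaptive (two-stage) Benjamini-Hochberg FDR procedure
#'
#' Two-stage linear step-up: stage 1 runs BH at level
#' \eqn{\alpha' = \alpha/(1+\alpha)} and estimates the number of true
#' nulls as \eqn{m_0 = m - r_1} (with \eqn{m_0 = m} when nothing is
#' rejected); stage 2 reruns BH at level \eqn{\alpha m/m_0}. The adjusted
#' values are the plain BH values scaled by \eqn{m_0/m}, so the adaptive
#' rejection set always contains the plain BH set at the same level.
#'
#' @param pvalues p-values in [0, 1].
#' @param alpha target false discovery rate.
#' @return list with \code{rejected} (logical), \code{q} (adjusted
#'   values), \code{m0} (estimated true nulls) and \code{alpha}.
#' @export
adaptive_bh <- function(pvalues, alpha = 0.05) {
    if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues)))
        stop("p-values must lie in [0, 1]")
    m <- length(pvalues)
    bh <- p.adjust(pvalues, method = "BH")
    r1 <- sum(bh <= alpha / (1 + alpha))
    m0 <- if (r1 == 0) m else m - r1
    q <- pmin(1, bh * m0 / m)
    list(rejected = q <= alpha, q = q, m0 = m0, alpha = alpha)
}

#' Significance tier of a p-value
#'
#' The finest of the conventional thresholds 0.001, 0.01, 0.05 strictly
#' above p, or \code{"ns"}.
#'
#' @param p p-values in [0, 1].
#' @return character vector in \{"0.001", "0.01", "0.05", "ns"\}.
#' @export
tier <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    ifelse(p < 0.001, "0.001",
           ifelse(p < 0.01, "0.01",
                  ifelse(p < 0.05, "0.05", "ns")))
}

#' Fisher's exact test and odds ratio for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood tail convention (the sum of
#' hypergeometric probabilities, at fixed margins, of tables no more
#' likely than the observed one). The odds ratio is the sample
#' cross-product ratio ad/bc, with a 0.5 Haldane-Anscombe correction to
#' every cell when any cell is zero.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with \code{p.value}, \code{odds_ratio}, \code{haldane}
#'   (whether the correction was applied) and \code{degenerate} (TRUE when
#'   a margin is zero, in which case p = 1 and the odds ratio is NA).
#' @export
fisher_or <- function(table) {
    table <- as.matrix(table)
    stopifnot(dim(table) == c(2, 2), all(table >= 0),
              all(abs(table - round(table)) < 1e-8))
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(list(p.value = 1, odds_ratio = NA_real_, haldane = FALSE,
                    degenerate = TRUE))
    p <- fisher.test(table)$p.value
    hald <- any(table == 0)
    t2 <- if (hald) table + 0.5 else table
    or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    list(p.value = p, odds_ratio = or, haldane = hald, degenerate = FALSE)
}

#' Differential abundance between two groups of samples
#'
#' The study's two-step screen: taxa passing the cohort-mean abundance
#' filter are tested by two-sided Mann-Whitney between the groups, and the
#' family is corrected by the adaptive Benjamini-Hochberg procedure.
#' Significance tiers (0.05 / 0.01 / 0.001 on the raw p) are reported only
#' for taxa surviving the FDR screen; direction is the group with the
#' higher mean proportion.
#'
#' @param profile a \code{taxon_profile}.
#' @param group factor with two used levels (e.g. normal/case), named by
#'   sample id or aligned with profile rows; samples at other levels are
#'   ignored.
#' @param comparison label stored in the result.
#' @param min_proportion abundance filter threshold.
#' @param alpha FDR level.
#' @return data.frame with \code{taxon}, \code{rank}, \code{comparison},
#'   \code{direction}, \code{p}, \code{q}, \code{tier}, \code{rejected}.
#' @export
diff_abundance <- function(profile, group, comparison = "case_vs_normal",
                           min_proportion = 0.0025, alpha = 0.05) {
    P <- profile$proportions[profile$valid, , drop = FALSE]
    if (!is.null(names(group))) group <- group[rownames(P)]
    group <- droplevels(factor(group))
    if (nlevels(group) != 2) stop("group must have exactly two used levels")
    taxa <- abundance_filter(profile, min_proportion)
    if (length(taxa) == 0)
        return(data.frame(taxon = character(0), rank = character(0),
                          comparison = character(0), direction = character(0),
                          p = numeric(0), q = numeric(0), tier = character(0),
                          rejected = logical(0)))
    g1 <- levels(group)[1]; g2 <- levels(group)[2]
    keep <- !is.na(group)
    p <- vapply(taxa, function(t)
        suppressWarnings(mann_whitney(P[keep & group == g1, t],
                                      P[keep & group == g2, t])), numeric(1))
    ab <- adaptive_bh(p, alpha)
    dir <- vapply(taxa, function(t) {
        if (mean(P[keep & group == g1, t]) >= mean(P[keep & group == g2, t]))
            g1 else g2
    }, character(1))
    data.frame(taxon = taxa, rank = profile$rank, comparison = comparison,
               direction = dir, p = p, q = ab$q,
               tier = ifelse(ab$rejected, tier(p), "ns"),
               rejected = ab$rejected,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Taxon associations with each clinical criterion
#'
#' Runs [diff_abundance()] once per semen-quality criterion, comparing
#' samples with a normal versus abnormal flag, mirroring the
#' per-criterion association tables.
#'
#' @param profile a \code{taxon_profile}.
#' @param flags a [flag_clinical()] result with rows named by sample id.
#' @param min_proportion,alpha as in [diff_abundance()].
#' @return data.frame stacking the per-criterion results (column
#'   \code{comparison} names the criterion; \code{direction} is
#'   \code{"normal"} or \code{"abnormal"}).
#' @export
clinical_associations <- function(profile, flags, min_proportion = 0.0025,
                                  alpha = 0.05) {
    out <- NULL
    for (crit in .criteria) {
        f <- flags[[crit]]
        grp <- factor(ifelse(f, "abnormal", "normal"),
                      levels = c("normal", "abnormal"))
        names(grp) <- rownames(flags)
        if (length(unique(grp[!is.na(grp)])) < 2) next
        out <- rbind(out, diff_abundance(profile, grp, comparison = crit,
                                         min_proportion = min_proportion,
                                         alpha = alpha))
    }
    out
}

#' Genus co-occurrence network from Spearman correlations
#'
#' Pairwise Spearman correlation (average ranks under ties) of genus
#' proportions across samples; pairs with absolute correlation strictly
#' above the threshold become edges. Constant-valued genera are excluded
#' with a warning.
#'
#' @param props samples x genera proportion matrix (>= 3 samples).
#' @param threshold absolute-correlation threshold (strict).
#' @return object of class \code{cooccurrence_network}: list with
#'   \code{nodes}, \code{edges} (data.frame \code{g1}, \code{g2},
#'   \code{rho}) and \code{threshold}.
#' @export
spearman_network <- function(props, threshold = 0.4) {
    props <- as.matrix(props)
    if (nrow(props) < 3) stop("need at least three samples")
    const <- apply(props, 2, function(v) length(unique(v)) == 1)
    if (any(const)) {
        warning("excluding constant genera: ",
                paste(colnames(props)[const], collapse = ", "))
        props <- props[, !const, drop = FALSE]
    }
    rho <- cor(props, method = "spearman")
    idx <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
    edges <- data.frame(g1 = colnames(props)[idx[, 1]],
                        g2 = colnames(props)[idx[, 2]],
                        rho = rho[idx], stringsAsFactors = FALSE)
    structure(list(nodes = colnames(props), edges = edges,
                   threshold = threshold),
              class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
    cat("cooccurrence_network:", length(x$nodes), "nodes,",
        nrow(x$edges), "edges (|rho| >", x$threshold, ")\n")
    invisible(x)
}

# cooccurrence_network -> igraph
as_igraph <- function(net) {
    igraph::graph_from_data_frame(net$edges[c("g1", "g2")], directed = FALSE,
                                  vertices = data.frame(name = net$nodes))
}

#' Ego subnetwork around a genus
#'
#' Nodes within graph distance \code{depth} of the center, with the edges
#' they induce.
#'
#' @param net a [spearman_network()] result.
#' @param center_genus the focal genus (must be a node).
#' @param depth neighborhood radius.
#' @return a \code{cooccurrence_network} restricted to the ego set.
#' @export
ego_network <- function(net, center_genus, depth = 2) {
    if (!center_genus %in% net$nodes)
        stop("unknown center genus: ", center_genus)
    g <- as_igraph(net)
    keep <- names(igraph::ego(g, order = depth, nodes = center_genus)[[1]])
    edges <- net$edges[net$edges$g1 %in% keep & net$edges$g2 %in% keep, ,
                       drop = FALSE]
    structure(list(nodes = keep, edges = edges, threshold = net$threshold),
              class = "cooccurrence_network")
}

#' Taxon associations with CASA metrics
#'
#' Spearman correlation of each abundance-filtered taxon against each
#' numeric CASA metric, with adaptive Benjamini-Hochberg correction across
#' the whole taxon x metric family. Metrics with zero variance are skipped
#' with a warning.
#'
#' @param profile a \code{taxon_profile}.
#' @param casa data.frame of numeric CASA metrics, rows aligned with (or
#'   named by) profile samples.
#' @param min_proportion,alpha as in [diff_abundance()].
#' @return data.frame with \code{taxon}, \code{metric}, \code{rho},
#'   \code{p}, \code{q}, \code{rejected}.
#' @export
casa_association <- function(profile, casa, min_proportion = 0.0025,
                             alpha = 0.05) {
    P <- profile$proportions[profile$valid, , drop = FALSE]
    casa <- as.data.frame(casa)
    if (!is.null(rownames(casa)) && all(rownames(P) %in% rownames(casa)))
        casa <- casa[rownames(P), , drop = FALSE]
    taxa <- abundance_filter(profile, min_proportion)
    metrics <- names(casa)[vapply(casa, is.numeric, logical(1))]
    const <- vapply(metrics, function(m) var(casa[[m]]) == 0, logical(1))
    if (any(const)) {
        warning("skipping constant CASA metrics: ",
                paste(metrics[const], collapse = ", "))
        metrics <- metrics[!const]
    }
    grid <- expand.grid(taxon = taxa, metric = metrics,
                        stringsAsFactors = FALSE)
    if (nrow(grid) == 0) return(cbind(grid, rho = numeric(0), p = numeric(0)))
    res <- t(vapply(seq_len(nrow(grid)), function(i) {
        ct <- suppressWarnings(
            cor.test(P[, grid$taxon[i]], casa[[grid$metric[i]]],
                     method = "spearman", exact = FALSE))
        c(ct$estimate, ct$p.value)
    }, numeric(2)))
    ab <- adaptive_bh(res[, 2], alpha)
    data.frame(grid, rho = res[, 1], p = res[, 2], q = ab$q,
               rejected = ab$rejected, row.names = NULL)
}
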