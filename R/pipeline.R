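.pipeline_defaults <- list(
    seed = 1,
    n_per_type = c(G1 = 25, G2 = 55, G3 = 16),
    n_pairs = 5000,
    error_rate = 0.005,
    read_len = 120,
    concentration = 25,
    qual_hazard = 0.0015,
    min_quality = 30,
    min_length = 100,
    barcode_mismatches = 0,
    kmer = 15,
    band = 8,
    min_identity = 0.97,
    k_range = 2:10,
    others_threshold = 0.01,
    min_proportion = 0.0025,
    alpha = 0.05,
    spearman_threshold = 0.4,
    min_abnormal_case = 2,
    cv_folds = 5,
    min_leaf = 2)

#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()] from the package
#' defaults; unknown keys are rejected. The configuration round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' @param ... named overrides of the defaults (see
#'   \code{semtype:::.pipeline_defaults}).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
    over <- list(...)
    unknown <- setdiff(names(over), names(.pipeline_defaults))
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg <- .pipeline_defaults
    cfg[names(over)] <- over
    structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{path} / the configuration.
#' @export
write_config <- function(cfg, path) {
    yaml::write_yaml(lapply(unclass(cfg), function(v)
        if (is.null(names(v))) v else as.list(v)), path)
    invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
    raw <- yaml::read_yaml(path)
    raw <- lapply(raw, function(v)
        if (is.list(v)) unlist(v) else v)
    do.call(pipeline_config, raw)
}

#' Summarize community typing against clinical classes
#'
#' Computes per-group sizes and normal fractions, then tests each group
#' against the predominant (highest normal-fraction) group with Fisher's
#' exact test on the normal / non-normal 2x2 table, reporting the odds
#' ratio of non-normality.
#'
#' @param labels community-type labels (named by sample).
#' @param classes clinical classes as from [define_classes()] (aligned or
#'   named; anything other than \code{"normal"} counts as non-normal).
#' @return data.frame with \code{group}, \code{size}, \code{n_normal},
#'   \code{normal_fraction}, \code{fisher_p}, \code{odds_ratio} (NA for
#'   the predominant group); attribute \code{"predominant"} names the
#'   reference group. Also reports attribute
#'   \code{"normals_in_predominant"}: the fraction of all normal samples
#'   falling in the predominant group.
#' @export
summarize_typing <- function(labels, classes) {
    if (!is.null(names(classes)) && !is.null(names(labels)))
        classes <- classes[names(labels)]
    stopifnot(length(labels) == length(classes))
    normal <- as.character(classes) == "normal"
    groups <- sort(unique(as.character(labels)))
    size <- vapply(groups, function(g) sum(labels == g), numeric(1))
    n_norm <- vapply(groups, function(g) sum(normal[labels == g]), numeric(1))
    frac <- n_norm / size
    pred <- groups[which.max(frac)]
    out <- data.frame(group = groups, size = size, n_normal = n_norm,
                      normal_fraction = frac, fisher_p = NA_real_,
                      odds_ratio = NA_real_, row.names = NULL,
                      stringsAsFactors = FALSE)
    if (length(groups) > 1) {
        for (g in setdiff(groups, pred)) {
            tab <- matrix(c(n_norm[g], size[g] - n_norm[g],
                            n_norm[pred], size[pred] - n_norm[pred]),
                          2, byrow = TRUE)
            ft <- fisher_or(tab)
            i <- out$group == g
            out$fisher_p[i] <- ft$p.value
            # odds of being non-normal in g relative to the predominant group
            out$odds_ratio[i] <- if (ft$degenerate) NA_real_ else
                (tab[1, 2] * tab[2, 1]) / (tab[1, 1] * tab[2, 2])
        }
    }
    attr(out, "predominant") <- pred
    attr(out, "normals_in_predominant") <-
        if (sum(normal) > 0) n_norm[pred] / sum(normal) else NA_real_
    out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> demultiplex/QC -> taxonomic profiling -> weighted
#' UniFrac community typing -> diversity -> association statistics ->
#' decision-rule classification under one configuration and seed, and
#' returns a cohort report. When \code{outdir} is given, stage artifacts
#' (reference files, QC report, profiles, distance matrix, dendrogram,
#' PCoA coordinates, association tables, network edges, classifier
#' metrics) are written as text files.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for stage artifacts.
#' @param cohort optionally, a pre-built \code{simulated_cohort} (must
#'   match the configuration's seed to keep runs reproducible).
#' @return an object of class \code{cohort_report}.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         cohort = NULL) {
    stopifnot(inherits(config, "pipeline_config"))
    seeds <- derive_seeds(config$seed, 4)
    stage <- function(name, expr) {
        t0 <- Sys.time()
        v <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        message(sprintf("[semtype] %-10s %6.1fs", name,
                        as.numeric(Sys.time() - t0, units = "secs")))
        v
    }
    if (is.null(cohort))
        cohort <- stage("simulate", simulate_cohort(
            n_per_type = unlist(config$n_per_type),
            specs = community_type_specs(config$concentration),
            n_pairs = config$n_pairs, error_rate = config$error_rate,
            read_len = config$read_len, seed = seeds[1],
            qual_hazard = config$qual_hazard))
    cfg_qc <- qc_config(min_quality = config$min_quality,
                        min_length = config$min_length,
                        barcode_mismatches = config$barcode_mismatches)
    pooled <- pool_reads(cohort)
    qc <- stage("qc", run_qc(pooled$r1, pooled$r2,
                             cohort$samples[c("sample_id", "barcode")],
                             cfg_qc))
    prof <- stage("profile", profile_cohort(qc$samples, cohort$refdb,
                                            k = config$kmer,
                                            band = config$band,
                                            min_identity = config$min_identity))
    typing <- stage("cluster", {
        P <- prof$profiles$species$proportions
        P <- P[prof$profiles$species$valid, , drop = FALSE]
        D <- unifrac_matrix(P, cohort$refdb$tree)
        choose_k(D, upgma_cluster(D), config$k_range)
    })
    truth <- setNames(cohort$samples$type, cohort$samples$sample_id)
    ari <- mclust::adjustedRandIndex(typing$labels,
                                     truth[names(typing$labels)])
    divers <- stage("diversity", {
        tab <- diversity_table(prof$profiles$species)
        list(table = tab,
             by_type = compare_group_diversity(tab, typing$labels))
    })
    assoc <- stage("assoc", {
        flags <- flag_clinical(cohort$clinical[.criteria])
        rownames(flags) <- cohort$clinical$sample_id
        classes <- define_classes(flags, config$min_abnormal_case)
        genus <- prof$profiles$genus
        cl2 <- droplevels(classes[classes != "excluded"])
        da <- diff_abundance(genus, cl2,
                             min_proportion = config$min_proportion,
                             alpha = config$alpha)
        net <- spearman_network(
            genus$proportions[genus$valid,
                              abundance_filter(genus, config$min_proportion),
                              drop = FALSE],
            threshold = config$spearman_threshold)
        list(flags = flags, classes = classes, diff = da, network = net,
             typing_summary = summarize_typing(typing$labels,
                                               classes[names(typing$labels)]))
    })
    clf <- stage("classify", {
        G <- prof$profiles$genus$proportions
        G <- G[prof$profiles$genus$valid, , drop = FALSE]
        feats <- featurize(G)
        labels <- typing$labels[rownames(G)]
        cv <- evaluate_cv(feats, labels, folds = config$cv_folds,
                          seed = seeds[4], min_leaf = config$min_leaf)
        model <- train_tree(feats, labels, min_leaf = config$min_leaf,
                            seed = seeds[4])
        list(model = model, cv = cv,
             fixed_rule = fixed_rule_classify(G),
             fixed_rule_agreement = mean(fixed_rule_classify(G) == labels))
    })
    report <- structure(list(
        config = config, cohort = cohort, qc_report = qc$report,
        n_unassigned = qc$n_unassigned, profiles = prof$profiles,
        typing = typing, ari_vs_truth = ari, diversity = divers,
        assoc = assoc, classifier = clf), class = "cohort_report")
    if (!is.null(outdir)) write_report(report, outdir)
    report
}

#' @export
print.cohort_report <- function(x, ...) {
    ts <- x$assoc$typing_summary
    cat("cohort_report:", nrow(x$cohort$samples), "samples\n")
    cat("  chosen k =", x$typing$chosen_k,
        sprintf("(ARI vs planted types: %.3f)\n", x$ari_vs_truth))
    for (i in seq_len(nrow(ts)))
        cat(sprintf("  %s: n=%d, normal %.1f%%%s\n", ts$group[i], ts$size[i],
                    100 * ts$normal_fraction[i],
                    if (is.na(ts$fisher_p[i])) " (predominant)" else
                        sprintf(", fisher p=%.2e, OR=%.1f", ts$fisher_p[i],
                                ts$odds_ratio[i])))
    cat(sprintf("  classifier: accuracy %.3f, AUC %s\n",
                x$classifier$cv$accuracy,
                paste(sprintf("%s=%.3f", names(x$classifier$cv$auc),
                              x$classifier$cv$auc), collapse = " ")))
    cat(sprintf("  %d differentially abundant genera (FDR %.2f)\n",
                sum(x$assoc$diff$rejected), x$config$alpha))
    invisible(x)
}

#' Write cohort-report artifacts as text files
#'
#' @param report a \code{cohort_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prov <- sprintf("semtype pipeline, seed=%s", report$config$seed)
    write_reference(report$cohort$refdb, file.path(dir, "reference"))
    write_tsv(report$qc_report, file.path(dir, "qc_report.tsv"), prov)
    for (rank in c("genus", "species")) {
        pr <- report$profiles[[rank]]
        write_tsv(data.frame(sample_id = rownames(pr$counts), pr$counts),
                  file.path(dir, paste0(rank, "_counts.tsv")), prov)
        write_tsv(data.frame(sample_id = rownames(pr$proportions),
                             pr$proportions),
                  file.path(dir, paste0(rank, "_proportions.tsv")), prov)
    }
    labs <- report$typing$labels
    write_tsv(data.frame(sample_id = names(labs), group = labs,
                         class = as.character(
                             report$assoc$classes[names(labs)])),
              file.path(dir, "community_types.tsv"), prov)
    write_tsv(data.frame(k = names(report$typing$pseudo_f),
                         pseudo_f = report$typing$pseudo_f),
              file.path(dir, "pseudo_f.tsv"), prov)
    pts <- report$typing$pcoa$points
    write_tsv(data.frame(sample_id = rownames(pts), pts),
              file.path(dir, "pcoa.tsv"), prov)
    ape::write.tree(ape::as.phylo(report$typing$dendrogram),
                    file.path(dir, "dendrogram.nwk"))
    write_tsv(report$diversity$table, file.path(dir, "diversity.tsv"), prov)
    write_tsv(report$assoc$diff, file.path(dir, "diff_abundance.tsv"), prov)
    write_tsv(report$assoc$network$edges, file.path(dir, "network_edges.tsv"),
              prov)
    write_tsv(report$assoc$typing_summary,
              file.path(dir, "typing_summary.tsv"), prov)
    cv <- report$classifier$cv
    write_tsv(data.frame(class = names(cv$auc), auc = cv$auc,
                         accuracy = cv$accuracy),
              file.path(dir, "classifier_metrics.tsv"), prov)
    sink(file.path(dir, "rule_tree.txt"))
    print(report$classifier$model)
    sink()
    invisible(dir)
}
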