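# Shared fixtures (built in code once per test run) and independent oracles.

# small reference database used across modules
tiny_ref <- make_reference(n_genera = 3, species_per_genus = 2,
                           seq_len = 160, seed = 7)
default_ref <- make_reference(seed = 5)

# wrap a proportions matrix as a taxon_profile (counts at a nominal depth)
make_profile <- function(P, rank = "genus", depth = 5000) {
    P <- as.matrix(P)
    structure(list(rank = rank, counts = round(P * depth), proportions = P,
                   unassigned = numeric(nrow(P)),
                   valid = rep(TRUE, nrow(P))),
              class = "taxon_profile")
}

# independent weighted-UniFrac oracle: enumerate every branch and its
# descendant leaf set via phangorn, sum lengths times abundance differences
oracle_unifrac <- function(p_a, p_b, tree, normalized = TRUE) {
    n_tip <- length(tree$tip.label)
    pa <- setNames(numeric(n_tip), tree$tip.label); pa[names(p_a)] <- p_a
    pb <- setNames(numeric(n_tip), tree$tip.label); pb[names(p_b)] <- p_b
    desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
    raw <- 0
    for (e in seq_len(nrow(tree$edge))) {
        tips <- tree$tip.label[desc[[e]]]
        raw <- raw + tree$edge.length[e] * abs(sum(pa[tips]) - sum(pb[tips]))
    }
    if (!normalized) return(raw)
    depth <- setNames(numeric(n_tip), tree$tip.label)
    for (i in seq_len(n_tip)) {
        node <- i; d <- 0
        repeat {
            e <- which(tree$edge[, 2] == node)
            if (length(e) == 0) break
            d <- d + tree$edge.length[e]
            node <- tree$edge[e, 1]
        }
        depth[i] <- d
    }
    den <- sum(depth * (pa + pb))
    if (den == 0) 0 else raw / den
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
    pooled <- c(x, y)
    nx <- length(x)
    u_of <- function(idx) {
        xs <- pooled[idx]; ys <- pooled[-idx]
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    u_obs <- u_of(seq_len(nx))
    all_u <- apply(combn(length(pooled), nx), 2, u_of)
    min(1, 2 * min(mean(all_u <= u_obs + 1e-9),
                   mean(all_u >= u_obs - 1e-9)))
}

# random simplex vector
rsimplex <- function(n) { v <- rgamma(n, 1); v / sum(v) }
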